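#' Sensitivity (Jacobian) matrix of the measurement frame
#'
#' Computes the Geselowitz sensitivity matrix of the linearized difference
#' imaging model \eqn{y = A x}: row \eqn{i} (drive pair \eqn{p}, measured
#' pair \eqn{q}) and element \eqn{j} carry
#' \deqn{A_{ij} = -\frac{1}{I}\int_{elem_j} \nabla\phi_p \cdot \nabla\phi_q\, d\Omega,}
#' where \eqn{\phi_p} and \eqn{\phi_q} are the forward potentials when
#' current \eqn{I} is driven through pairs \eqn{p} and \eqn{q} at the
#' reference conductivity. For the P1 discretization this is the exact
#' derivative of the discrete forward map, so a perturbation
#' finite-difference check agrees to first order in the step.
#'
#' @param mesh An \code{eit_mesh}.
#' @param em An \code{eit_electrode_model}.
#' @param protocol An \code{eit_protocol}; defaults to the adjacent protocol.
#' @param sigma_ref Reference conductivity (\code{eit_conductivity} or a
#'   scalar S/m, default homogeneous 1 S/m) at which the linearization is
#'   taken.
#' @return An \code{eit_sensitivity}: \code{entries} (M x N matrix, Volts
#'   per (S/m)), \code{basis = "mesh-element"}, \code{reference_conductivity},
#'   plus the protocol and mesh radius.
#' @export
compute_jacobian <- function(mesh, em, protocol = NULL, sigma_ref = 1) {
  if (is.null(protocol)) protocol <- adjacent_protocol(length(mesh$electrodes))
  if (!inherits(sigma_ref, "eit_conductivity"))
    sigma_ref <- conductivity_field(mesh, sigma_ref)
  system <- assemble_cem_system(mesh, sigma_ref, em)
  S <- system$n_electrodes
  wrap <- function(i) ((i - 1L) %% S) + 1L
  # all adjacent pairs double as drive and measurement-adjoint fields
  pairs <- cbind(seq_len(S), wrap(seq_len(S) + 1L))
  I0 <- em$current_amplitude
  sol <- .solve_excitations(system, pairs, I0)
  gx <- system$grads$gx; gy <- system$grads$gy
  area <- system$grads$area
  tr <- mesh$triangles
  # element-wise gradient components of each of the S fields
  phin <- sol$phi
  GX <- gx[, 1L] * phin[tr[, 1L], ] + gx[, 2L] * phin[tr[, 2L], ] +
        gx[, 3L] * phin[tr[, 3L], ]
  GY <- gy[, 1L] * phin[tr[, 1L], ] + gy[, 2L] * phin[tr[, 2L], ] +
        gy[, 3L] * phin[tr[, 3L], ]
  key <- paste(pairs[, 1L], pairs[, 2L])
  pcol <- match(paste(protocol$drive_a, protocol$drive_b), key)
  qcol <- match(paste(protocol$meas_a, protocol$meas_b), key)
  M <- nrow(protocol)
  A <- matrix(0, M, nrow(tr))
  for (i in seq_len(M)) {
    p <- pcol[i]; q <- qcol[i]
    A[i, ] <- -(area / I0) * (GX[, p] * GX[, q] + GY[, p] * GY[, q])
  }
  structure(list(entries = A, basis = "mesh-element",
                 reference_conductivity = sigma_ref$values[1L],
                 protocol = protocol, radius = mesh$radius),
            class = "eit_sensitivity")
}

#' @export
print.eit_sensitivity <- function(x, ...) {
  cat(sprintf("eit_sensitivity: %d x %d (%s basis), sigma_ref = %g S/m\n",
              nrow(x$entries), ncol(x$entries), x$basis,
              x$reference_conductivity))
  invisible(x)
}

#' Square pixel grid over the disk
#'
#' A \code{size x size} Cartesian grid covering the bounding square
#' \code{[-radius, radius]^2}; a pixel belongs to the imaging domain when
#' its center lies inside the disk.
#'
#' @param size Pixels per side (default 64).
#' @param radius Disk radius in meters.
#' @return An \code{eit_pixel_grid}: \code{size}, \code{radius},
#'   \code{pixel_size}, \code{centers_x}/\code{centers_y} (per-axis center
#'   coordinates), \code{inside_mask} (size x size logical), and
#'   \code{inside_index} (size x size integer, \code{NA} outside; pixels
#'   are numbered column-major over the masked set).
#' @export
pixel_grid <- function(size = 64L, radius = 0.095) {
  size <- as.integer(size)
  h <- 2 * radius / size
  cx <- -radius + h * (seq_len(size) - 0.5)
  mask <- outer(cx, cx, function(x, y) x^2 + y^2 < radius^2)
  idx <- matrix(NA_integer_, size, size)
  idx[mask] <- seq_len(sum(mask))
  structure(list(size = size, radius = radius, pixel_size = h,
                 centers_x = cx, centers_y = cx,
                 inside_mask = mask, inside_index = idx,
                 n_inside = sum(mask)),
            class = "eit_pixel_grid")
}

# pixel (row = x bin, col = y bin) of a point; clamped to the grid
.pixel_of <- function(grid, x, y) {
  h <- grid$pixel_size
  ix <- pmin(pmax(floor((x + grid$radius) / h) + 1, 1), grid$size)
  iy <- pmin(pmax(floor((y + grid$radius) / h) + 1, 1), grid$size)
  cbind(ix, iy)
}

#' Aggregate a mesh-element sensitivity matrix onto the pixel grid
#'
#' Each element's column is distributed over the pixels it intersects,
#' weighted by the fraction of the element's area falling in each pixel, so
#' the aggregation is a partition of unity (row sums are preserved).
#' Overlap fractions are computed by deterministic barycentric subdivision
#' of every triangle into congruent sub-triangles finer than half a pixel;
#' each sub-area is assigned to the in-disk pixel containing (or, for the
#' few boundary slivers whose pixel center falls outside the disk, nearest
#' to) its centroid.
#'
#' @param A An \code{eit_sensitivity} in mesh-element basis.
#' @param mesh The \code{eit_mesh} that produced it.
#' @param grid An \code{eit_pixel_grid} with the same radius.
#' @return An \code{eit_sensitivity} with \code{basis = "pixel"} and
#'   \code{grid} attached; columns follow \code{grid$inside_index}.
#' @export
aggregate_to_pixels <- function(A, mesh, grid) {
  if (!identical(A$basis, "mesh-element"))
    stop("A must be in mesh-element basis")
  if (abs(grid$radius - mesh$radius) > 1e-12)
    stop("grid radius does not match mesh radius")
  tr <- mesh$triangles
  p <- mesh$node_coords
  area <- triangle_areas(mesh)
  hmax <- sqrt(max(rowSums((p[tr[, 1L], ] - p[tr[, 2L], ])^2),
                   rowSums((p[tr[, 2L], ] - p[tr[, 3L], ])^2),
                   rowSums((p[tr[, 3L], ] - p[tr[, 1L], ])^2)))
  s <- max(2L, min(10L, ceiling(2 * hmax / grid$pixel_size)))

  # barycentric centroids of the s^2 congruent sub-triangles
  bc <- NULL
  for (a in 0L:(s - 1L)) for (b in 0L:(s - 1L - a)) {
    bc <- rbind(bc, c(a + 1 / 3, b + 1 / 3))          # upward sub-triangle
    if (a + b <= s - 2L) bc <- rbind(bc, c(a + 2 / 3, b + 2 / 3))  # downward
  }
  bc <- bc / s
  lam <- cbind(1 - bc[, 1L] - bc[, 2L], bc[, 1L], bc[, 2L])

  m <- nrow(tr)
  nsub <- nrow(lam)
  x1 <- p[tr[, 1L], 1L]; y1 <- p[tr[, 1L], 2L]
  x2 <- p[tr[, 2L], 1L]; y2 <- p[tr[, 2L], 2L]
  x3 <- p[tr[, 3L], 1L]; y3 <- p[tr[, 3L], 2L]
  # all sub-centroids, element-major
  sx <- outer(x1, lam[, 1L]) + outer(x2, lam[, 2L]) + outer(x3, lam[, 3L])
  sy <- outer(y1, lam[, 1L]) + outer(y2, lam[, 2L]) + outer(y3, lam[, 3L])
  px <- .pixel_of(grid, as.vector(sx), as.vector(sy))
  pid <- grid$inside_index[px]
  if (anyNA(pid)) {
    # snap boundary slivers to the nearest in-disk pixel center
    bad <- which(is.na(pid))
    ins <- which(grid$inside_mask, arr.ind = TRUE)
    insx <- grid$centers_x[ins[, 1L]]; insy <- grid$centers_y[ins[, 2L]]
    for (b in bad) {
      d2 <- (insx - as.vector(sx)[b])^2 + (insy - as.vector(sy)[b])^2
      pid[b] <- grid$inside_index[ins[which.min(d2), , drop = FALSE]]
    }
  }
  elem <- rep(seq_len(m), times = nsub)
  W <- Matrix::sparseMatrix(i = elem, j = pid, x = rep(1 / nsub, length(pid)),
                            dims = c(m, grid$n_inside))
  entries <- as.matrix(A$entries %*% W)
  structure(list(entries = entries, basis = "pixel",
                 reference_conductivity = A$reference_conductivity,
                 protocol = A$protocol, radius = mesh$radius, grid = grid),
            class = "eit_sensitivity")
}

#' Expand a masked pixel vector to a full square image
#'
#' @param x Numeric vector over the in-disk pixels of \code{grid}.
#' @param grid An \code{eit_pixel_grid}.
#' @param fill Value for out-of-disk pixels.
#' @return A \code{size x size} matrix.
#' @export
pixels_to_image <- function(x, grid, fill = NA_real_) {
  img <- matrix(fill, grid$size, grid$size)
  img[grid$inside_mask] <- x
  img
}
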