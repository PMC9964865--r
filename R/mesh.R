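#' Build a triangulated disk mesh with boundary electrodes
#'
#' Constructs a deterministic, structured triangulation of a disk of the
#' given radius: \code{n_rings} concentric rings of nodes, ring \code{k}
#' carrying \code{n_electrodes * k} equally spaced nodes, triangulated
#' sector by sector so the mesh is exactly symmetric under rotation by one
#' electrode pitch. The element count is quantized to
#' \code{n_electrodes * n_rings^2}; the ring count is chosen to land as
#' close as possible to \code{target_elements}.
#'
#' Electrodes are modelled as arcs of the boundary: electrode \code{L} is
#' centred at angle \code{2*pi*(L-1)/n_electrodes} (electrode 1 at angle 0,
#' numbering counter-clockwise) and owns every boundary edge whose midpoint
#' lies within \code{electrode_arc/2} of that centre along the circle.
#'
#' @param radius Disk radius in meters.
#' @param n_electrodes Number of boundary electrodes (the adjacent-drive
#'   protocol assumes 16).
#' @param electrode_arc Arc length in meters covered by each electrode.
#'   Must be smaller than the electrode pitch \code{2*pi*radius/n_electrodes}.
#' @param target_elements Requested number of triangles; the realized count
#'   is the nearest achievable \code{n_electrodes * n_rings^2}.
#' @return An object of class \code{eit_mesh}: a list with
#'   \code{node_coords} (n x 2, meters), \code{triangles} (m x 3 node
#'   indices, counter-clockwise), \code{boundary_edges} (node-index pairs on
#'   the circle, counter-clockwise), \code{electrodes} (list of
#'   \code{n_electrodes} integer vectors indexing rows of
#'   \code{boundary_edges}), \code{radius}, \code{n_rings},
#'   \code{n_sectors}.
#' @examples
#' m <- build_disk_mesh(0.095, 16, 0.01, 800)
#' nrow(m$triangles)
#' @export
build_disk_mesh <- function(radius, n_electrodes = 16L, electrode_arc = 0.01,
                            target_elements = 3000L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive scalar (meters)")
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes < 3L) stop("n_electrodes must be at least 3")
  pitch <- 2 * pi * radius / n_electrodes
  if (electrode_arc <= 0 || electrode_arc >= pitch)
    stop("infeasible electrode_arc: must be in (0, circumference/n_electrodes)")
  if (target_elements < 100L)
    stop("target_elements < 100: mesh too coarse for the complete electrode model")

  S <- n_electrodes
  # nearest achievable ring count for S*N^2 elements
  n0 <- sqrt(target_elements / S)
  cand <- unique(pmax(2L, c(floor(n0), ceiling(n0))))
  N <- cand[which.min(abs(S * cand^2 - target_elements))]

  # node layout: center (index 1), then ring k = 1..N with S*k nodes
  ring_offset <- function(k) {
    if (k == 0L) return(1L)               # center node
    2L + (S * (k - 1L) * k) %/% 2L        # 2 + S*sum(1..k-1)
  }
  n_nodes <- ring_offset(N) + S * N - 1L
  coords <- matrix(0, n_nodes, 2L)
  for (k in seq_len(N)) {
    nk <- S * k
    th <- 2 * pi * (seq_len(nk) - 1L) / nk
    r <- radius * k / N
    idx <- ring_offset(k) + seq_len(nk) - 1L
    coords[idx, 1L] <- r * cos(th)
    coords[idx, 2L] <- r * sin(th)
  }

  ring_node <- function(k, j) {
    # j is a 0-based angular index on ring k, wrapped
    nk <- S * k
    ring_offset(k) + (j %% nk)
  }

  tris <- vector("list", N)
  # innermost band: fan around the center
  tris[[1L]] <- cbind(1L, ring_node(1L, 0L:(S - 1L)), ring_node(1L, 1L:S))
  if (N >= 2L) for (k in 2L:N) {
    up <- dn <- NULL
    for (s in 0L:(S - 1L)) {
      jo <- s * k          # outer ring angular origin of this sector
      ji <- s * (k - 1L)   # inner ring angular origin
      j <- 0L:(k - 1L)
      up <- rbind(up, cbind(ring_node(k, jo + j), ring_node(k, jo + j + 1L),
                            ring_node(k - 1L, ji + j)))
      if (k >= 2L) {
        j2 <- 0L:(k - 2L)
        dn <- rbind(dn, cbind(ring_node(k - 1L, ji + j2), ring_node(k, jo + j2 + 1L),
                              ring_node(k - 1L, ji + j2 + 1L)))
      }
    }
    tris[[k]] <- rbind(up, dn)
  }
  triangles <- do.call(rbind, tris)
  storage.mode(triangles) <- "integer"

  # enforce counter-clockwise orientation
  a <- coords[triangles[, 1L], , drop = FALSE]
  b <- coords[triangles[, 2L], , drop = FALSE]
  cc <- coords[triangles[, 3L], , drop = FALSE]
  sa <- (b[, 1L] - a[, 1L]) * (cc[, 2L] - a[, 2L]) -
        (cc[, 1L] - a[, 1L]) * (b[, 2L] - a[, 2L])
  flip <- sa < 0
  if (any(flip)) triangles[flip, c(2L, 3L)] <- triangles[flip, c(3L, 2L)]

  nb <- S * N
  bidx <- ring_offset(N) + 0L:(nb - 1L)
  boundary_edges <- cbind(bidx, c(bidx[-1L], bidx[1L]))
  storage.mode(boundary_edges) <- "integer"

  # assign boundary edges to electrodes by midpoint angle
  mid <- (coords[boundary_edges[, 1L], , drop = FALSE] +
          coords[boundary_edges[, 2L], , drop = FALSE]) / 2
  mid_angle <- atan2(mid[, 2L], mid[, 1L]) %% (2 * pi)
  half_ang <- electrode_arc / (2 * radius)
  electrodes <- vector("list", S)
  for (L in seq_len(S)) {
    center <- 2 * pi * (L - 1L) / S
    d <- abs(((mid_angle - center + pi) %% (2 * pi)) - pi)
    electrodes[[L]] <- which(d <= half_ang)
    # on a coarse mesh the arc may straddle no midpoint: take the nearest edge
    if (length(electrodes[[L]]) == 0L) electrodes[[L]] <- which.min(d)
  }
  if (anyDuplicated(unlist(electrodes)))
    stop("electrode arcs overlap; shorten electrode_arc")

  structure(
    list(node_coords = coords, triangles = triangles,
         boundary_edges = boundary_edges, electrodes = electrodes,
         radius = radius, n_rings = N, n_sectors = S),
    class = "eit_mesh")
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("eit_mesh: disk r = %g m, %d nodes, %d triangles, %d electrodes\n",
              x$radius, nrow(x$node_coords), nrow(x$triangles),
              length(x$electrodes)))
  invisible(x)
}

#' Triangle areas of a mesh
#'
#' @param mesh An \code{eit_mesh}.
#' @return Numeric vector of signed areas (all positive for a valid mesh), m^2.
#' @export
triangle_areas <- function(mesh) {
  tr <- mesh$triangles
  p <- mesh$node_coords
  a <- p[tr[, 1L], , drop = FALSE]
  b <- p[tr[, 2L], , drop = FALSE]
  cc <- p[tr[, 3L], , drop = FALSE]
  0.5 * ((b[, 1L] - a[, 1L]) * (cc[, 2L] - a[, 2L]) -
         (cc[, 1L] - a[, 1L]) * (b[, 2L] - a[, 2L]))
}

#' Triangle centroids of a mesh
#'
#' @param mesh An \code{eit_mesh}.
#' @return m x 2 matrix of centroid coordinates, meters.
#' @export
triangle_centroids <- function(mesh) {
  tr <- mesh$triangles
  p <- mesh$node_coords
  (p[tr[, 1L], , drop = FALSE] + p[tr[, 2L], , drop = FALSE] +
     p[tr[, 3L], , drop = FALSE]) / 3
}

#' Validate mesh invariants
#'
#' Checks positive triangle orientation, absence of duplicate nodes,
#' boundary nodes on the circle, and disjoint electrode edge sets.
#'
#' @param mesh An \code{eit_mesh}.
#' @param tol Geometric tolerance, meters.
#' @return \code{TRUE} invisibly; otherwise an error is raised.
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  if (any(triangle_areas(mesh) <= 0)) stop("non-positive triangle area")
  key <- paste(round(mesh$node_coords[, 1L] / 1e-12),
               round(mesh$node_coords[, 2L] / 1e-12))
  if (anyDuplicated(key)) stop("duplicate nodes within 1e-12 m")
  bn <- unique(as.vector(mesh$boundary_edges))
  r <- sqrt(rowSums(mesh$node_coords[bn, , drop = FALSE]^2))
  if (any(abs(r - mesh$radius) > tol * max(1, mesh$radius)))
    stop("boundary node off the circle")
  if (anyDuplicated(unlist(mesh$electrodes))) stop("electrode edge sets overlap")
  invisible(TRUE)
}
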