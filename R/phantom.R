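#' Evaluate an expression with a private RNG stream
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded draws (phantoms, noise) never perturb
#' the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Conductivity phantom specification
#'
#' Describes a disk phantom as a homogeneous background plus circular
#' inclusions. Inclusions must lie fully inside the disk with at least a
#' 2 mm margin and must not overlap.
#'
#' @param inclusions List of inclusions, each a list with \code{center}
#'   (2-vector, meters), \code{radius} (meters) and \code{conductivity}
#'   (S/m).
#' @param background_conductivity Background conductivity, S/m.
#' @param disk_radius Radius of the disk the phantom lives in, meters.
#' @param seed Optional integer recording how a randomized spec was drawn.
#' @return An \code{eit_phantom_spec}.
#' @export
phantom_spec <- function(inclusions = list(), background_conductivity = 1,
                         disk_radius = 0.095, seed = NULL) {
  margin <- 2e-3
  for (inc in inclusions) {
    if (inc$radius <= 0) stop("inclusion radius must be positive")
    if (sqrt(sum(inc$center^2)) + inc$radius > disk_radius - margin)
      stop("inclusion does not fit inside the disk with a 2 mm margin")
  }
  if (length(inclusions) >= 2L) {
    for (i in seq_len(length(inclusions) - 1L))
      for (j in (i + 1L):length(inclusions)) {
        d <- sqrt(sum((inclusions[[i]]$center - inclusions[[j]]$center)^2))
        if (d < inclusions[[i]]$radius + inclusions[[j]]$radius)
          stop("inclusions overlap")
      }
  }
  if (background_conductivity <= 0) stop("background must be positive")
  structure(list(inclusions = inclusions,
                 background_conductivity = background_conductivity,
                 disk_radius = disk_radius, seed = seed),
            class = "eit_phantom_spec")
}

#' @export
print.eit_phantom_spec <- function(x, ...) {
  cat(sprintf("eit_phantom_spec: %d inclusion(s), background %g S/m, disk r = %g m\n",
              length(x$inclusions), x$background_conductivity, x$disk_radius))
  for (inc in x$inclusions)
    cat(sprintf("  center (%.4f, %.4f) m, r = %.4f m, sigma = %g S/m\n",
                inc$center[1L], inc$center[2L], inc$radius, inc$conductivity))
  invisible(x)
}

#' Draw a random phantom specification
#'
#' Places \code{n_inclusions} non-overlapping near-insulating circular
#' inclusions uniformly in the disk (2 mm wall margin), with radii uniform
#' in \code{radius_range}. Deterministic for a fixed seed; the global RNG
#' state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_inclusions Number of inclusions, 1 to 4.
#' @param radius_range Length-2 numeric, inclusion radius bounds in meters.
#' @param disk_radius Disk radius, meters.
#' @param inclusion_conductivity Conductivity of the inclusions, S/m
#'   (default the near-insulator floor 1e-12).
#' @param background_conductivity Background conductivity, S/m.
#' @param max_tries Placement attempts per inclusion before giving up.
#' @return An \code{eit_phantom_spec}.
#' @export
random_phantom <- function(seed, n_inclusions = 1L,
                           radius_range = c(0.012, 0.025),
                           disk_radius = 0.095,
                           inclusion_conductivity = 1e-12,
                           background_conductivity = 1,
                           max_tries = 200L) {
  if (n_inclusions < 1L || n_inclusions > 4L)
    stop("n_inclusions must be between 1 and 4")
  margin <- 2e-3
  with_seed(seed, {
    placed <- list()
    for (i in seq_len(n_inclusions)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        r <- stats::runif(1, radius_range[1L], radius_range[2L])
        rmax <- disk_radius - margin - r
        # uniform over the admissible center disk
        rho <- rmax * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        ctr <- c(rho * cos(th), rho * sin(th))
        clear <- all(vapply(placed, function(q)
          sqrt(sum((q$center - ctr)^2)) >= q$radius + r + 1e-4, logical(1)))
        if (clear) {
          placed[[i]] <- list(center = ctr, radius = r,
                              conductivity = inclusion_conductivity)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place inclusions without overlap")
    }
    phantom_spec(placed, background_conductivity, disk_radius, seed = seed)
  })
}

#' Realize a phantom on a mesh as a conductivity field
#'
#' Element conductivity is the inclusion's value when the element centroid
#' lies inside an inclusion, else the background (centroid membership,
#' consistent with the piecewise-constant element basis). Conductivities
#' are floored at 1e-12 S/m.
#'
#' @param spec An \code{eit_phantom_spec}.
#' @param mesh An \code{eit_mesh} of the same radius.
#' @return An \code{eit_conductivity}.
#' @export
make_phantom <- function(spec, mesh) {
  if (abs(spec$disk_radius - mesh$radius) > 1e-12)
    stop("phantom disk radius does not match mesh radius")
  ctr <- triangle_centroids(mesh)
  v <- rep(spec$background_conductivity, nrow(ctr))
  for (inc in spec$inclusions) {
    inside <- (ctr[, 1L] - inc$center[1L])^2 +
              (ctr[, 2L] - inc$center[2L])^2 < inc$radius^2
    v[inside] <- inc$conductivity
  }
  conductivity_field(mesh, pmax(v, 1e-12))
}

#' Rasterize a phantom to the pixel grid as a ground-truth image
#'
#' Pixel value is the conductivity difference (inclusion minus background)
#' where the pixel center lies inside an inclusion, zero elsewhere —
#' i.e. the ground-truth \eqn{x = \sigma - \sigma_0} for difference
#' imaging.
#'
#' @param spec An \code{eit_phantom_spec}.
#' @param grid An \code{eit_pixel_grid} with the phantom's disk radius.
#' @return An \code{eit_truth}: \code{pixel_values} over the in-disk
#'   pixels, plus the grid.
#' @export
rasterize <- function(spec, grid) {
  if (abs(spec$disk_radius - grid$radius) > 1e-12)
    stop("grid radius does not match phantom disk radius")
  ins <- which(grid$inside_mask, arr.ind = TRUE)
  x <- grid$centers_x[ins[, 1L]]
  y <- grid$centers_y[ins[, 2L]]
  v <- numeric(length(x))
  for (inc in spec$inclusions) {
    hit <- (x - inc$center[1L])^2 + (y - inc$center[2L])^2 < inc$radius^2
    v[hit] <- inc$conductivity - spec$background_conductivity
  }
  structure(list(pixel_values = v, grid = grid), class = "eit_truth")
}

#' Write a phantom spec as structured key-value text
#'
#' @param spec An \code{eit_phantom_spec}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  ln <- c(sprintf("background_conductivity = %.17g", spec$background_conductivity),
          sprintf("disk_radius = %.17g", spec$disk_radius),
          if (!is.null(spec$seed)) sprintf("seed = %d", spec$seed),
          sprintf("n_inclusions = %d", length(spec$inclusions)))
  for (i in seq_along(spec$inclusions)) {
    inc <- spec$inclusions[[i]]
    ln <- c(ln, sprintf("inclusion_%d = %.17g %.17g %.17g %.17g", i,
                        inc$center[1L], inc$center[2L], inc$radius,
                        inc$conductivity))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a phantom spec written by \code{\link{write_phantom_spec}}
#'
#' @param path File path.
#' @return An \code{eit_phantom_spec}.
#' @export
read_phantom_spec <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  val <- function(k) kv[[match(k, keys)]][2L]
  n <- as.integer(val("n_inclusions"))
  incs <- lapply(seq_len(n), function(i) {
    v <- as.numeric(strsplit(val(sprintf("inclusion_%d", i)), "\\s+")[[1L]])
    list(center = v[1:2], radius = v[3L], conductivity = v[4L])
  })
  phantom_spec(incs, as.numeric(val("background_conductivity")),
               as.numeric(val("disk_radius")),
               seed = if ("seed" %in% keys) as.integer(val("seed")) else NULL)
}

#' Add Gaussian white noise at an exact signal-to-noise ratio
#'
#' Draws zero-mean Gaussian noise and rescales the realized draw so that
#' \code{10*log10(sum(v^2)/sum(e^2))} equals \code{snr_db} exactly, then
#' adds it to the frame voltages. SNR is defined on the raw voltage vector
#' of the frame (sensor noise). Deterministic per seed; the global RNG
#' state is untouched.
#'
#' @param frame An \code{eit_frame}.
#' @param snr_db Target SNR in dB; \code{Inf} returns the frame unchanged.
#' @param seed Integer seed.
#' @return The noisy \code{eit_frame} with \code{noise_snr_db} recorded.
#' @export
add_noise <- function(frame, snr_db, seed) {
  if (is.infinite(snr_db)) return(frame)
  if (!is.finite(snr_db)) stop("snr_db must be finite or Inf")
  pv <- sum(frame$voltages^2)
  if (pv == 0) stop("zero-power frame cannot carry a finite SNR")
  e <- with_seed(seed, stats::rnorm(length(frame$voltages)))
  e <- e * sqrt(pv / sum(e^2)) * 10^(-snr_db / 20)
  frame$voltages <- frame$voltages + e
  frame$noise_snr_db <- snr_db
  frame
}
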