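#' @export
print.eit_recon <- function(x, ...) {
  cat(sprintf("eit_recon (%s): %d unknowns, %d iteration(s)\n",
              x$method, length(x$x), x$iterations))
  if (length(x$residual_history))
    cat(sprintf("  final residual ||y - Ax|| = %.4g V\n",
                x$residual_history[length(x$residual_history)]))
  invisible(x)
}

#' @export
summary.eit_recon <- function(object, ...) {
  r <- residuals(object)
  out <- list(method = object$method, iterations = object$iterations,
              n_unknowns = length(object$x),
              residual_norm = sqrt(sum(r^2)),
              x_range = range(object$x),
              final_objective = if (length(object$objective_history))
                object$objective_history[length(object$objective_history)]
              else NA_real_)
  class(out) <- "summary.eit_recon"
  out
}

#' @export
print.summary.eit_recon <- function(x, ...) {
  cat(sprintf("EIT reconstruction, method %s\n", x$method))
  cat(sprintf("  unknowns:        %d\n", x$n_unknowns))
  cat(sprintf("  iterations:      %d\n", x$iterations))
  cat(sprintf("  ||y - Ax||:      %.6g V\n", x$residual_norm))
  cat(sprintf("  x range (S/m):   [%.4g, %.4g]\n", x$x_range[1L], x$x_range[2L]))
  cat(sprintf("  final objective: %.6g\n", x$final_objective))
  invisible(x)
}

#' @export
coef.eit_recon <- function(object, ...) object$x

#' @export
fitted.eit_recon <- function(object, ...) {
  as.numeric(.as_matrix(object$A) %*% object$x)
}

#' @export
residuals.eit_recon <- function(object, ...) {
  object$y - fitted(object)
}

#' Plot a reconstructed conductivity-difference image
#'
#' Renders the pixel-basis solution as an image over the disk (requires
#' the reconstruction to carry a pixel grid, i.e. a pixel-basis
#' sensitivity matrix was used).
#'
#' @param x An \code{eit_recon}.
#' @param main Title; defaults to the method name.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.eit_recon <- function(x, main = x$method, ...) {
  if (is.null(x$grid))
    stop("no pixel grid attached; reconstruct from a pixel-basis sensitivity matrix to plot")
  img <- pixels_to_image(x$x, x$grid)
  graphics::image(x$grid$centers_x, x$grid$centers_y, img, asp = 1,
                  xlab = "x (m)", ylab = "y (m)", main = main,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}
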