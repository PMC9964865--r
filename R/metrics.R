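#' Min-max normalize an image to the 8-bit range
#'
#' Scales the (masked) pixel values affinely so the minimum maps to 0 and
#' the maximum to 255 (\code{k = 8} bits). A constant image maps to all
#' zeros by convention. Values stay floating point; no quantization.
#'
#' @param img Numeric vector or matrix of pixel values.
#' @param mask Optional logical vector/matrix; only masked pixels are
#'   scaled (and define min/max), others are set to 0.
#' @return Object of the same shape with masked values in [0, 255].
#' @export
normalize_to_8bit <- function(img, mask = NULL) {
  out <- img
  if (is.null(mask)) mask <- rep(TRUE, length(img))
  v <- img[mask]
  rng <- range(v)
  out[] <- 0
  if (rng[2L] > rng[1L])
    out[mask] <- (v - rng[1L]) / (rng[2L] - rng[1L]) * 255
  out
}

#' Global structural similarity (SSIM)
#'
#' Single-window SSIM over the masked pixels of two 8-bit-normalized
#' images:
#' \deqn{SSIM = \frac{(2\mu_1\mu_2 + C_1)(2\,cov + C_2)}
#'                   {(\mu_1^2 + \mu_2^2 + C_1)(\sigma_1^2 + \sigma_2^2 + C_2)}}
#' with the standard stability constants \eqn{C_1 = (0.01 \cdot 255)^2},
#' \eqn{C_2 = (0.03 \cdot 255)^2} (population moments). \code{raw = TRUE}
#' drops the constants (and errors on a vanishing denominator).
#'
#' @param true_img Reference image (vector or matrix), 8-bit normalized.
#' @param rec_img Reconstructed image, same shape.
#' @param mask Optional logical mask.
#' @param raw Use the constant-free form.
#' @return SSIM scalar in [-1, 1].
#' @export
eit_ssim <- function(true_img, rec_img, mask = NULL, raw = FALSE) {
  if (length(true_img) != length(rec_img)) stop("image shapes differ")
  if (is.null(mask)) mask <- rep(TRUE, length(true_img))
  a <- as.numeric(true_img[mask]); b <- as.numeric(rec_img[mask])
  n <- length(a)
  mu1 <- mean(a); mu2 <- mean(b)
  v1 <- sum((a - mu1)^2) / n; v2 <- sum((b - mu2)^2) / n
  cv <- sum((a - mu1) * (b - mu2)) / n
  if (raw) {
    den <- (mu1^2 + mu2^2) * (v1 + v2)
    if (den == 0) stop("raw SSIM undefined: zero denominator")
    return((2 * mu1 * mu2) * (2 * cv) / den)
  }
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  (2 * mu1 * mu2 + C1) * (2 * cv + C2) /
    ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))
}

#' Root-mean-square error between images
#'
#' @inheritParams eit_ssim
#' @return RMSE over the masked pixels (8-bit pixel units).
#' @export
eit_rmse <- function(true_img, rec_img, mask = NULL) {
  if (length(true_img) != length(rec_img)) stop("image shapes differ")
  if (is.null(mask)) mask <- rep(TRUE, length(true_img))
  sqrt(mean((as.numeric(true_img[mask]) - as.numeric(rec_img[mask]))^2))
}

#' Peak signal-to-noise ratio
#'
#' \eqn{PSNR = 10\log_{10}\!\big((2^8 - 1)^2 / RMSE^2\big)} dB; identical
#' images give \code{Inf}.
#'
#' @inheritParams eit_ssim
#' @return PSNR in dB.
#' @export
eit_psnr <- function(true_img, rec_img, mask = NULL) {
  r <- eit_rmse(true_img, rec_img, mask)
  if (r == 0) return(Inf)
  10 * log10(255^2 / r^2)
}

#' Change of average metric (CAM)
#'
#' Relative change of a method's average metric against a comparison
#' method: \eqn{CAM = |AVE_{ref} - AVE_{other}| / AVE_{other} \times 100}.
#'
#' @param ave_ref Average metric of the reference method.
#' @param ave_other Average metric of the comparison method.
#' @return Percent change.
#' @export
cam <- function(ave_ref, ave_other) {
  if (ave_other == 0) stop("comparison average is zero; CAM undefined")
  abs(ave_ref - ave_other) / ave_other * 100
}

#' Evaluate a reconstruction against the ground truth
#'
#' Normalizes both images to 8 bits over the in-disk mask and reports
#' SSIM, RMSE and PSNR.
#'
#' @param recon An \code{eit_recon} in pixel basis, or a numeric vector of
#'   in-disk pixel values.
#' @param truth An \code{eit_truth} (or matching numeric vector).
#' @param grid The \code{eit_pixel_grid}; taken from the inputs when
#'   omitted.
#' @param method_name Optional label.
#' @return An \code{eit_metrics} list: \code{ssim}, \code{rmse},
#'   \code{psnr}, \code{method_name}.
#' @export
metrics_report <- function(recon, truth, grid = NULL, method_name = NULL) {
  if (inherits(recon, "eit_recon")) {
    if (is.null(method_name)) method_name <- recon$method
    if (is.null(grid)) grid <- recon$grid
    xr <- recon$x
  } else xr <- as.numeric(recon)
  xt <- if (inherits(truth, "eit_truth")) truth$pixel_values else as.numeric(truth)
  if (length(xr) != length(xt)) stop("reconstruction and truth sizes differ")
  a <- normalize_to_8bit(xt)
  b <- normalize_to_8bit(xr)
  r <- eit_rmse(a, b)
  structure(list(ssim = eit_ssim(a, b), rmse = r,
                 psnr = if (r == 0) Inf else 10 * log10(255^2 / r^2),
                 method_name = method_name),
            class = "eit_metrics")
}

#' @export
print.eit_metrics <- function(x, ...) {
  cat(sprintf("%s: SSIM %.4f, RMSE %.4f, PSNR %.4f dB\n",
              if (is.null(x$method_name)) "reconstruction" else x$method_name,
              x$ssim, x$rmse, x$psnr))
  invisible(x)
}

#' SSIM-versus-iteration convergence curve
#'
#' Runs the solver once with snapshots at the requested iteration
#' checkpoints and reports the SSIM of the reconstruction at each
#' checkpoint against the ground truth (identical inputs at every
#' checkpoint).
#'
#' @param method Solver name as in \code{\link{eit_reconstruct}}.
#' @param A Pixel-basis sensitivity matrix.
#' @param y Measurement difference vector.
#' @param truth An \code{eit_truth}.
#' @param checkpoints Increasing integer iteration counts.
#' @param config Base \code{eit_solver_config}; \code{iter_max},
#'   \code{epsilon} and \code{snapshot_iters} are overridden so the run
#'   reaches every checkpoint.
#' @return data.frame with columns \code{iteration}, \code{ssim}.
#' @export
convergence_curve <- function(method, A, y, truth,
                              checkpoints = c(1, seq(5, 100, by = 5)),
                              config = solver_config()) {
  if (is.unsorted(checkpoints, strictly = TRUE))
    stop("checkpoints must be strictly increasing")
  config$iter_max <- max(checkpoints)
  config$epsilon <- 0                   # run through every checkpoint
  config$snapshot_iters <- as.integer(checkpoints)
  fit <- eit_reconstruct(A, y, method, config)
  xt <- normalize_to_8bit(truth$pixel_values)
  ss <- vapply(as.character(checkpoints), function(k) {
    xs <- fit$snapshots[[k]]
    if (is.null(xs)) xs <- fit$x        # solver stopped before this checkpoint
    eit_ssim(xt, normalize_to_8bit(xs))
  }, numeric(1))
  data.frame(iteration = as.integer(checkpoints), ssim = as.numeric(ss))
}
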