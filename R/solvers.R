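#' Solver configuration
#'
#' Shared configuration for the linearized difference-imaging solvers.
#'
#' @param alpha Shrinkage (denoising) threshold applied by the soft
#'   thresholding step of ISTA/FISTA/RS-FISTA; default 1e-9. The implied
#'   LASSO weight is \code{alpha / mu}.
#' @param epsilon Relative convergence tolerance, default 1e-5. FISTA-type
#'   loops stop when the relative change of the residual norm
#'   \eqn{\|y - Ax^{(k)}\|_2} falls below it; ISTA stops when the residual
#'   falls below \code{epsilon * ||y||}.
#' @param iter_max Maximum iterations.
#' @param mu Optional explicit gradient step size; when \code{NULL} each
#'   method uses its own rule (\code{1/L} for FISTA-type methods,
#'   \code{1/(lambda_min + lambda_max)} of \eqn{A^TA} for ISTA).
#' @param lipschitz_mode \code{"paper-doubled"} uses
#'   \eqn{L = 2\lambda_{max}(A^TA)}; \code{"half-objective"} uses
#'   \eqn{L = \lambda_{max}(A^TA)}, the Lipschitz constant consistent with
#'   the half-quadratic data term.
#' @param newton_r Regularization parameter of the NOSER and Newton-Raphson
#'   steps, default 0.1.
#' @param rs_lambda0 Initial Tikhonov weight of the adaptive regularization
#'   solver; default \code{0.01 * lambda_max(A^TA)}.
#' @param rs_gamma Step of the adaptive lambda update
#'   \eqn{\lambda^{k+1} = \max(floor, \lambda^k - \gamma\,\|Ax^k-y\|_1)};
#'   default \code{1e-3 * rs_lambda0 / ||y||_1}.
#' @param rs_tol Stopping threshold on \eqn{\|Ax^k - y\|_1}, default 1e-2.
#' @param rs_iter_max Maximum adaptive-regularization iterations, default 50.
#' @param snapshot_iters Optional integer vector of iteration counts at
#'   which the iterate is recorded (for convergence curves).
#' @param seed Optional integer recorded in results for provenance.
#' @return An \code{eit_solver_config} list.
#' @export
solver_config <- function(alpha = 1e-9, epsilon = 1e-5, iter_max = 200L,
                          mu = NULL,
                          lipschitz_mode = c("paper-doubled", "half-objective"),
                          newton_r = 0.1, rs_lambda0 = NULL, rs_gamma = NULL,
                          rs_tol = 1e-2, rs_iter_max = 50L,
                          snapshot_iters = NULL, seed = NULL) {
  lipschitz_mode <- match.arg(lipschitz_mode)
  if (alpha < 0) stop("alpha must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (iter_max < 1L) stop("iter_max must be >= 1")
  if (newton_r <= 0) stop("newton_r must be > 0")
  if (rs_tol <= 0) stop("rs_tol must be > 0")
  structure(list(alpha = alpha, epsilon = epsilon, iter_max = as.integer(iter_max),
                 mu = mu, lipschitz_mode = lipschitz_mode, newton_r = newton_r,
                 rs_lambda0 = rs_lambda0, rs_gamma = rs_gamma, rs_tol = rs_tol,
                 rs_iter_max = as.integer(rs_iter_max),
                 snapshot_iters = snapshot_iters, seed = seed),
            class = "eit_solver_config")
}

.as_matrix <- function(A) {
  if (inherits(A, "eit_sensitivity")) A$entries else as.matrix(A)
}

# extreme eigenvalues of A'A through the smaller Gram matrix
.gram_extremes <- function(A) {
  A <- .as_matrix(A)
  G <- if (nrow(A) <= ncol(A)) tcrossprod(A) else crossprod(A)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  pos <- ev[ev > lmax * 1e-12]
  list(lambda_max = lmax, lambda_min_pos = min(pos))
}

#' Soft-thresholding (shrinkage) operator
#'
#' The proximal map of the L1 norm:
#' \eqn{T_a(v_i) = sign(v_i) max(|v_i| - a, 0)}.
#'
#' @param v Numeric vector.
#' @param a Threshold, must be >= 0.
#' @return Shrunk vector of the same length.
#' @export
soft_threshold <- function(v, a) {
  if (a < 0) stop("threshold must be >= 0")
  sign(v) * pmax(abs(v) - a, 0)
}

#' Lipschitz constant of the LASSO gradient by power iteration
#'
#' Estimates \eqn{\lambda_{max}(A^TA)} by power iteration (deterministic
#' internal start, relative tolerance 1e-10) and doubles it under the
#' default \code{"paper-doubled"} mode, giving the gradient Lipschitz bound
#' \eqn{L = 2\lambda_{max}(A^TA)} used to set the FISTA step \code{1/L}.
#'
#' @param A Sensitivity matrix (\code{eit_sensitivity} or plain matrix).
#' @param mode \code{"paper-doubled"} or \code{"half-objective"}.
#' @return Scalar \code{L}.
#' @export
lipschitz_bound <- function(A, mode = c("paper-doubled", "half-objective")) {
  mode <- match.arg(mode)
  A <- .as_matrix(A)
  if (all(A == 0)) stop("zero matrix has no positive spectral bound")
  v <- with_seed(171717L, stats::rnorm(ncol(A)))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(10000L)) {
    w <- crossprod(A, A %*% v)
    nw <- sqrt(sum(w^2))
    lam_new <- nw            # ||A'A v|| with unit v -> top eigenvalue
    v <- as.numeric(w) / nw
    if (abs(lam_new - lam) <= 1e-10 * lam_new) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  if (mode == "paper-doubled") 2 * lam else lam
}

#' Nesterov momentum parameter sequence
#'
#' \eqn{t^{(1)} = 1}, \eqn{t^{(k+1)} = (1 + \sqrt{1 + 4 (t^{(k)})^2})/2};
#' the momentum weight of step \eqn{k} is \eqn{(t^{(k)} - 1)/t^{(k+1)}}.
#'
#' @param k Number of terms.
#' @return Numeric vector \eqn{t^{(1)}, \dots, t^{(k)}}.
#' @export
nesterov_t_sequence <- function(k) {
  t <- numeric(k)
  t[1L] <- 1
  if (k > 1L) for (i in 2L:k) t[i] <- (1 + sqrt(1 + 4 * t[i - 1L]^2)) / 2
  t
}

#' LASSO objective
#'
#' \eqn{F(x) = \frac12\|Ax - y\|_2^2 + \lambda\|x\|_1}.
#'
#' @param A Sensitivity matrix.
#' @param y Measurement (difference) vector.
#' @param x Candidate solution.
#' @param lam L1 weight.
#' @return Scalar objective value.
#' @export
objective <- function(A, y, x, lam) {
  A <- .as_matrix(A)
  r <- A %*% x - y
  0.5 * sum(r^2) + lam * sum(abs(x))
}

new_eit_recon <- function(x, method, iterations, residual_history,
                          objective_history, config, A, y, grid = NULL,
                          extra = list()) {
  structure(c(list(x = as.numeric(x), method = method,
                   iterations = as.integer(iterations),
                   residual_history = residual_history,
                   objective_history = objective_history,
                   config = config, A = A, y = as.numeric(y), grid = grid),
              extra),
            class = "eit_recon")
}

# shared bookkeeping for snapshot collection
.snap_init <- function(config) {
  if (is.null(config$snapshot_iters)) NULL else
    stats::setNames(vector("list", length(config$snapshot_iters)),
                    as.character(config$snapshot_iters))
}
.snap_take <- function(snaps, k, x, config) {
  if (!is.null(snaps) && k %in% config$snapshot_iters)
    snaps[[as.character(k)]] <- as.numeric(x)
  snaps
}

#' Iterative shrinkage-thresholding (ISTA)
#'
#' Proximal-gradient LASSO iteration from the zero vector:
#' \eqn{x^{(k+1)} = T_\alpha[x^{(k)} - \mu A^T(Ax^{(k)} - y)]} with step
#' \eqn{\mu = 1/(\lambda_{min} + \lambda_{max})} of \eqn{A^TA} (positive
#' eigenvalues) unless overridden. Stops when
#' \eqn{\|y - Ax^{(k)}\| < \epsilon\|y\|} or at \code{iter_max}.
#'
#' @param A Sensitivity matrix.
#' @param y Measurement difference vector.
#' @param config An \code{eit_solver_config}.
#' @return An \code{eit_recon}.
#' @export
ista <- function(A, y, config = solver_config()) {
  Am <- .as_matrix(A)
  grid <- if (inherits(A, "eit_sensitivity")) A$grid else NULL
  y <- as.numeric(y)
  mu <- config$mu
  if (is.null(mu)) {
    ex <- .gram_extremes(Am)
    mu <- 1 / (ex$lambda_min_pos + ex$lambda_max)
  }
  lam_eff <- config$alpha / mu
  x <- numeric(ncol(Am))
  ny <- sqrt(sum(y^2))
  res <- obj <- numeric(0)
  snaps <- .snap_init(config)
  bad_run <- 0L
  k <- 0L
  repeat {
    k <- k + 1L
    x <- soft_threshold(x - mu * as.numeric(crossprod(Am, Am %*% x - y)),
                        config$alpha)
    r <- sqrt(sum((y - Am %*% x)^2))
    f <- 0.5 * r^2 + lam_eff * sum(abs(x))
    if (length(obj) && f > obj[length(obj)]) bad_run <- bad_run + 1L
    else bad_run <- 0L
    res <- c(res, r); obj <- c(obj, f)
    snaps <- .snap_take(snaps, k, x, config)
    if (bad_run >= 10L) stop("ISTA diverging: objective increased 10 consecutive steps")
    if (r < config$epsilon * ny || ny == 0 || k >= config$iter_max) break
  }
  new_eit_recon(x, "ISTA", k, res, obj, config, A, y, grid,
                extra = list(mu = mu, snapshots = snaps))
}

# FISTA main loop, shared by fista() and rs_fista()
.fista_loop <- function(Am, y, x0, config, method, grid, A_orig,
                        extra = list()) {
  mu <- config$mu
  if (is.null(mu)) mu <- 1 / lipschitz_bound(Am, config$lipschitz_mode)
  lam_eff <- config$alpha / mu
  x_prev <- x <- as.numeric(x0)
  z <- x
  t_k <- 1
  res <- obj <- numeric(0)
  snaps <- .snap_init(config)
  k <- 0L
  repeat {
    k <- k + 1L
    x_new <- soft_threshold(z - mu * as.numeric(crossprod(Am, Am %*% z - y)),
                            config$alpha)
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- x_new + ((t_k - 1) / t_next) * (x_new - x)
    x_prev <- x; x <- x_new; t_k <- t_next
    r <- sqrt(sum((y - Am %*% x)^2))
    res <- c(res, r)
    obj <- c(obj, 0.5 * r^2 + lam_eff * sum(abs(x)))
    snaps <- .snap_take(snaps, k, x, config)
    if (k >= config$iter_max) break
    if (r <= .Machine$double.xmin) break
    if (k >= 2L) {
      rel <- abs(res[k] - res[k - 1L]) / res[k - 1L]
      if (is.finite(rel) && rel < config$epsilon) break
    }
  }
  new_eit_recon(x, method, k, res, obj, config, A_orig, y, grid,
                extra = c(list(mu = mu, x0 = as.numeric(x0),
                               snapshots = snaps), extra))
}

#' Fast iterative shrinkage-thresholding (FISTA)
#'
#' The Nesterov-accelerated proximal-gradient iteration
#' \deqn{x^{(k)} = T_\alpha[z^{(k)} - \mu A^T(Az^{(k)} - y)],\quad
#'       t^{(k+1)} = \frac{1 + \sqrt{1 + 4 (t^{(k)})^2}}{2},\quad
#'       z^{(k+1)} = x^{(k)} + \frac{t^{(k)} - 1}{t^{(k+1)}}(x^{(k)} - x^{(k-1)})}
#' with \eqn{t^{(1)} = 1} and step \eqn{\mu = 1/L}. Stops when the relative
#' change of the residual norm drops below \code{config$epsilon} or at
#' \code{iter_max}.
#'
#' @param A Sensitivity matrix.
#' @param y Measurement difference vector.
#' @param x0 Initial iterate (zero vector for the cold-started comparison).
#' @param config An \code{eit_solver_config}.
#' @return An \code{eit_recon}.
#' @export
fista <- function(A, y, x0 = NULL, config = solver_config()) {
  Am <- .as_matrix(A)
  grid <- if (inherits(A, "eit_sensitivity")) A$grid else NULL
  if (is.null(x0)) x0 <- numeric(ncol(Am))
  .fista_loop(Am, as.numeric(y), x0, config, "FISTA", grid, A)
}

#' Adaptive-regularization Tikhonov solver (warm start for RS-FISTA)
#'
#' Repeatedly solves the Tikhonov problem
#' \eqn{x^k = (A^TA + \lambda^k I)^{-1} A^T y} (through the thin SVD of
#' \code{A}) while shrinking the regularization weight proportionally to
#' the L1 data misfit,
#' \eqn{\lambda^{k+1} = \max(\lambda_{floor},\ \lambda^k - \gamma\|Ax^k - y\|_1)},
#' until \eqn{\|Ax^k - y\|_1 <} \code{rs_tol} or \code{rs_iter_max} passes.
#' The positivity floor is \code{1e-12 * lambda0}.
#'
#' @param A Sensitivity matrix.
#' @param y Measurement difference vector.
#' @param config An \code{eit_solver_config}; \code{rs_lambda0},
#'   \code{rs_gamma}, \code{rs_tol} and \code{rs_iter_max} apply.
#' @return List with \code{x0} (the final Tikhonov solution) and
#'   \code{trace}, a data.frame of per-iteration \code{lambda} and
#'   \code{residual_l1}.
#' @export
regularization_solver <- function(A, y, config = solver_config()) {
  Am <- .as_matrix(A)
  y <- as.numeric(y)
  sv <- svd(Am)
  uy <- as.numeric(crossprod(sv$u, y))
  lam0 <- config$rs_lambda0
  if (is.null(lam0)) lam0 <- 0.01 * max(sv$d)^2
  if (lam0 <= 0) stop("rs_lambda0 must be positive")
  gam <- config$rs_gamma
  if (is.null(gam)) {
    ny1 <- sum(abs(y))
    gam <- if (ny1 > 0) 1e-3 * lam0 / ny1 else 0
  }
  floor_ <- 1e-12 * lam0
  lam <- lam0
  x <- numeric(ncol(Am))
  trace <- data.frame(iter = integer(), lambda = numeric(),
                      residual_l1 = numeric())
  for (k in seq_len(config$rs_iter_max)) {
    x <- as.numeric(sv$v %*% (sv$d * uy / (sv$d^2 + lam)))
    r1 <- sum(abs(Am %*% x - y))
    trace <- rbind(trace, data.frame(iter = k, lambda = lam, residual_l1 = r1))
    if (r1 < config$rs_tol) break
    lam <- max(floor_, lam - gam * r1)
  }
  list(x0 = x, trace = trace)
}

#' Regularization-solver-guided FISTA (RS-FISTA)
#'
#' FISTA warm-started at the adaptive-regularization Tikhonov solution:
#' \code{\link{regularization_solver}} supplies \eqn{x^{(0)}} (and
#' \eqn{z^{(1)} = x^{(0)}}), after which the accelerated shrinkage
#' iteration of \code{\link{fista}} runs with the residual norm
#' \eqn{\|y - Ax^{(k)}\|} recorded at every step.
#'
#' @param A Sensitivity matrix.
#' @param y Measurement difference vector.
#' @param config An \code{eit_solver_config}.
#' @return An \code{eit_recon}; \code{$x0} holds the warm start and
#'   \code{$rs_trace} the adaptive-lambda trace.
#' @export
rs_fista <- function(A, y, config = solver_config()) {
  Am <- .as_matrix(A)
  grid <- if (inherits(A, "eit_sensitivity")) A$grid else NULL
  rs <- regularization_solver(Am, y, config)
  .fista_loop(Am, as.numeric(y), rs$x0, config, "RS-FISTA", grid, A,
              extra = list(rs_trace = rs$trace))
}

#' Landweber iteration
#'
#' \eqn{x^{(k+1)} = x^{(k)} + \lambda A^T(y - Ax^{(k)})} from the zero
#' vector, with relaxation
#' \eqn{\lambda = 2/(\lambda_{max} + \lambda_{min})} over the positive
#' eigenvalues of \eqn{A^TA}; runs for \code{iter_max} iterations.
#'
#' @inheritParams ista
#' @return An \code{eit_recon}.
#' @export
landweber <- function(A, y, config = solver_config()) {
  Am <- .as_matrix(A)
  grid <- if (inherits(A, "eit_sensitivity")) A$grid else NULL
  y <- as.numeric(y)
  relax <- config$mu
  if (is.null(relax)) {
    ex <- .gram_extremes(Am)
    relax <- 2 / (ex$lambda_max + ex$lambda_min_pos)
  }
  x <- numeric(ncol(Am))
  res <- obj <- numeric(0)
  snaps <- .snap_init(config)
  for (k in seq_len(config$iter_max)) {
    x <- x + relax * as.numeric(crossprod(Am, y - Am %*% x))
    r <- sqrt(sum((y - Am %*% x)^2))
    res <- c(res, r); obj <- c(obj, 0.5 * r^2)
    snaps <- .snap_take(snaps, k, x, config)
  }
  new_eit_recon(x, "Landweber", config$iter_max, res, obj, config, A, y, grid,
                extra = list(relaxation = relax, snapshots = snaps))
}

#' Conjugate gradients on the normal equations (CGNR)
#'
#' Standard CG applied to \eqn{A^TA x = A^T y} from the zero vector; the
#' search directions are mutually \eqn{A^TA}-conjugate. Stops at
#' \code{iter_max}, on a vanishing direction (breakdown, flagged), or when
#' the normal-equation residual underflows.
#'
#' @inheritParams ista
#' @return An \code{eit_recon} with \code{$breakdown} flag.
#' @export
cg_normal <- function(A, y, config = solver_config()) {
  Am <- .as_matrix(A)
  grid <- if (inherits(A, "eit_sensitivity")) A$grid else NULL
  y <- as.numeric(y)
  x <- numeric(ncol(Am))
  r <- as.numeric(crossprod(Am, y))     # normal-equation residual at x = 0
  p <- r
  rr <- sum(r^2)
  res <- obj <- numeric(0)
  snaps <- .snap_init(config)
  directions <- list()
  breakdown <- FALSE
  k <- 0L
  while (k < config$iter_max) {
    k <- k + 1L
    directions[[k]] <- p
    q <- as.numeric(Am %*% p)
    qq <- sum(q^2)                      # p' A'A p
    if (qq <= .Machine$double.xmin || rr <= .Machine$double.xmin) {
      breakdown <- qq <= .Machine$double.xmin && rr > .Machine$double.xmin
      k <- k - 1L
      break
    }
    a <- rr / qq
    x <- x + a * p
    r <- r - a * as.numeric(crossprod(Am, q))
    rr_new <- sum(r^2)
    p <- r + (rr_new / rr) * p
    rr <- rr_new
    rn <- sqrt(sum((y - Am %*% x)^2))
    res <- c(res, rn); obj <- c(obj, 0.5 * rn^2)
    snaps <- .snap_take(snaps, k, x, config)
  }
  new_eit_recon(x, "CG", max(k, 0L), res, obj, config, A, y, grid,
                extra = list(breakdown = breakdown, snapshots = snaps,
                             directions = directions[seq_len(max(k, 0L))]))
}

#' NOSER: Newton's one-step error reconstructor
#'
#' A single regularized Gauss-Newton step from zero with diagonal scaling:
#' \eqn{x = (A^TA + r\,\mathrm{diag}(A^TA))^{-1} A^T y}, evaluated through
#' the push-through identity so only an M x M system is factorized.
#'
#' @inheritParams ista
#' @return An \code{eit_recon} with \code{iterations = 1}.
#' @export
noser <- function(A, y, config = solver_config()) {
  Am <- .as_matrix(A)
  grid <- if (inherits(A, "eit_sensitivity")) A$grid else NULL
  y <- as.numeric(y)
  d <- config$newton_r * colSums(Am^2)
  if (all(d == 0)) stop("diag(A'A) is identically zero")
  if (any(d <= 0)) stop("diag(A'A) has zero entries; NOSER scaling undefined")
  Ad <- sweep(Am, 2L, d, "/")           # A D^{-1}
  K <- tcrossprod(Ad, Am)               # A D^{-1} A'
  diag(K) <- diag(K) + 1
  w <- solve(K, y)
  x <- as.numeric(crossprod(Ad, w))     # D^{-1} A' (I + A D^{-1} A')^{-1} y
  r <- sqrt(sum((y - Am %*% x)^2))
  new_eit_recon(x, "NOSER", 1L, r, 0.5 * r^2, config, A, y, grid,
                extra = list(snapshots = NULL))
}

#' Newton-Raphson iteration with fixed Tikhonov damping
#'
#' \eqn{x^{(k+1)} = x^{(k)} - (A^TA + rI)^{-1} A^T (Ax^{(k)} - y)} from the
#' zero vector with fixed \code{r}; the first step is exactly the Tikhonov
#' solution \eqn{(A^TA + rI)^{-1}A^Ty}. Stops at \code{iter_max} or when
#' the update becomes negligible (relative step below \code{epsilon}).
#'
#' @inheritParams ista
#' @return An \code{eit_recon}.
#' @export
newton_raphson <- function(A, y, config = solver_config()) {
  Am <- .as_matrix(A)
  grid <- if (inherits(A, "eit_sensitivity")) A$grid else NULL
  y <- as.numeric(y)
  r_reg <- config$newton_r
  K <- tcrossprod(Am)
  diag(K) <- diag(K) + r_reg
  Kc <- chol(K)
  x <- numeric(ncol(Am))
  res <- obj <- numeric(0)
  snaps <- .snap_init(config)
  k <- 0L
  repeat {
    k <- k + 1L
    g <- as.numeric(Am %*% x - y)
    step <- as.numeric(crossprod(Am, backsolve(Kc, backsolve(Kc, g, transpose = TRUE))))
    x <- x - step
    rn <- sqrt(sum((y - Am %*% x)^2))
    res <- c(res, rn); obj <- c(obj, 0.5 * rn^2)
    snaps <- .snap_take(snaps, k, x, config)
    if (k >= config$iter_max) break
    nx <- sqrt(sum(x^2))
    if (sqrt(sum(step^2)) <= config$epsilon * max(nx, .Machine$double.xmin))
      break
  }
  new_eit_recon(x, "Newton-Raphson", k, res, obj, config, A, y, grid,
                extra = list(snapshots = snaps))
}

#' Reconstruct a conductivity-difference image
#'
#' Central fitting function: solves the linearized EIT difference-imaging
#' problem \eqn{y = Ax} with the chosen method and returns a classed
#' result with \code{print}, \code{summary}, \code{coef}, \code{fitted},
#' \code{residuals} and \code{plot} methods.
#'
#' @param A Sensitivity matrix (\code{eit_sensitivity}, typically in pixel
#'   basis, or a plain matrix).
#' @param y Measurement difference vector (inhomogeneous frame minus
#'   reference frame), Volts, or an \code{eit_frame} pair via
#'   \code{\link{frame_difference}}.
#' @param method One of \code{"rs-fista"}, \code{"fista"}, \code{"ista"},
#'   \code{"landweber"}, \code{"cg"}, \code{"noser"},
#'   \code{"newton-raphson"} (case and punctuation insensitive).
#' @param config An \code{eit_solver_config}.
#' @param x0 Optional initial iterate (FISTA only; RS-FISTA computes its
#'   own warm start).
#' @return An \code{eit_recon}.
#' @examples
#' A <- matrix(rnorm(60), 6, 10)
#' xt <- c(2, rep(0, 9))
#' fit <- eit_reconstruct(A, A %*% xt, "rs-fista",
#'                        solver_config(iter_max = 100))
#' round(coef(fit)[1], 2)
#' @export
eit_reconstruct <- function(A, y,
                            method = c("rs-fista", "fista", "ista",
                                       "landweber", "cg", "noser",
                                       "newton-raphson"),
                            config = solver_config(), x0 = NULL) {
  key <- gsub("[^a-z]", "", tolower(method[1L]))
  known <- c(rsfista = "rs_fista", fista = "fista", ista = "ista",
             landweber = "landweber", cg = "cg", cgnr = "cg",
             noser = "noser", newtonraphson = "newton", newton = "newton")
  if (!key %in% names(known))
    stop("unknown method '", method[1L], "'; available: ",
         "RS-FISTA, FISTA, ISTA, Landweber, CG, NOSER, Newton-Raphson")
  if (inherits(y, "eit_frame")) y <- y$voltages
  switch(known[[key]],
         rs_fista = rs_fista(A, y, config),
         fista = fista(A, y, x0, config),
         ista = ista(A, y, config),
         landweber = landweber(A, y, config),
         cg = cg_normal(A, y, config),
         noser = noser(A, y, config),
         newton = newton_raphson(A, y, config))
}

#' Difference signal between a frame and its reference
#'
#' @param frame Inhomogeneous \code{eit_frame}.
#' @param reference Homogeneous reference \code{eit_frame}.
#' @return Numeric vector \code{frame$voltages - reference$voltages}.
#' @export
frame_difference <- function(frame, reference) {
  if (length(frame$voltages) != length(reference$voltages))
    stop("frame lengths differ")
  frame$voltages - reference$voltages
}
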