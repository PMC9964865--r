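#' Standard study setup: meshes, reference frame and pixel sensitivity
#'
#' Builds the shared objects of the simulation studies: a fine forward
#' mesh, a distinct coarser mesh for the Jacobian (the inverse-crime
#' guard: simulation data and inversion operator never share a
#' discretization), the adjacent protocol, the homogeneous reference
#' frame, and the pixel-basis sensitivity matrix on the reconstruction
#' grid.
#'
#' @param radius Disk radius, meters.
#' @param n_electrodes Electrode count.
#' @param electrode_arc Electrode arc length, meters.
#' @param forward_elements Target element count of the simulation mesh.
#' @param jacobian_elements Target element count of the Jacobian mesh;
#'   must differ from the realized forward count.
#' @param grid_size Reconstruction grid resolution (pixels per side).
#' @param background_conductivity Reference conductivity, S/m.
#' @param em An \code{eit_electrode_model}.
#' @return An \code{eit_study_setup} list with \code{mesh_forward},
#'   \code{mesh_jacobian}, \code{protocol}, \code{grid}, \code{em},
#'   \code{reference_frame}, \code{A} (pixel basis) and
#'   \code{background_conductivity}.
#' @export
study_setup <- function(radius = 0.095, n_electrodes = 16L,
                        electrode_arc = 0.01,
                        forward_elements = 3000L, jacobian_elements = 1500L,
                        grid_size = 64L, background_conductivity = 1,
                        em = electrode_model()) {
  mesh_f <- build_disk_mesh(radius, n_electrodes, electrode_arc,
                            forward_elements)
  mesh_j <- build_disk_mesh(radius, n_electrodes, electrode_arc,
                            jacobian_elements)
  if (nrow(mesh_f$triangles) == nrow(mesh_j$triangles))
    stop("forward and Jacobian meshes have equal element counts; ",
         "choose distinct targets to avoid the inverse crime")
  protocol <- adjacent_protocol(n_electrodes)
  grid <- pixel_grid(grid_size, radius)
  sigma0 <- conductivity_field(mesh_f, background_conductivity)
  ref <- simulate_frame(mesh_f, sigma0, em, protocol, is_reference = TRUE)
  Aj <- compute_jacobian(mesh_j, em, protocol,
                         conductivity_field(mesh_j, background_conductivity))
  A <- aggregate_to_pixels(Aj, mesh_j, grid)
  structure(list(mesh_forward = mesh_f, mesh_jacobian = mesh_j,
                 protocol = protocol, grid = grid, em = em,
                 reference_frame = ref, A = A,
                 background_conductivity = background_conductivity),
            class = "eit_study_setup")
}

#' Simulate the measurement data for one phantom
#'
#' @param setup An \code{eit_study_setup}.
#' @param spec An \code{eit_phantom_spec}.
#' @param snr_db Optional SNR of added Gaussian noise (Inf = noiseless).
#' @param noise_seed Seed for the noise draw (required for finite SNR).
#' @return List with \code{frame} (the possibly noisy inhomogeneous
#'   frame), \code{y} (difference signal against the noiseless
#'   reference), and \code{truth} (rasterized ground truth).
#' @export
simulate_phantom_data <- function(setup, spec, snr_db = Inf,
                                  noise_seed = NULL) {
  sigma <- make_phantom(spec, setup$mesh_forward)
  frame <- simulate_frame(setup$mesh_forward, sigma, setup$em,
                          setup$protocol)
  if (is.finite(snr_db)) {
    if (is.null(noise_seed)) stop("finite SNR needs an explicit noise_seed")
    frame <- add_noise(frame, snr_db, noise_seed)
  }
  list(frame = frame, y = frame_difference(frame, setup$reference_frame),
       truth = rasterize(spec, setup$grid))
}

.all_methods <- c("Landweber", "CG", "NOSER", "Newton-Raphson", "ISTA",
                  "FISTA", "RS-FISTA")

#' Per-method averages and CAM from per-model metric values
#'
#' Given one metric's per-model values for several methods, appends the
#' per-method \code{Average} and the change-of-average-metric \code{CAM}
#' of the reference method against every other method.
#'
#' @param per_model data.frame: first column \code{method}, remaining
#'   columns numeric per-model values.
#' @param reference Reference method name (default \code{"RS-FISTA"}).
#' @return The input with \code{Average} and \code{CAM} columns appended
#'   (\code{CAM} is \code{NA} on the reference row).
#' @export
comparison_table <- function(per_model, reference = "RS-FISTA") {
  vals <- as.matrix(per_model[, -1L, drop = FALSE])
  avg <- rowMeans(vals)
  iref <- match(reference, per_model$method)
  if (is.na(iref)) stop("reference method not present")
  camv <- vapply(seq_along(avg), function(i)
    if (i == iref) NA_real_ else cam(avg[iref], avg[i]), numeric(1))
  out <- per_model
  out$Average <- avg
  out$CAM <- camv
  out
}

#' Benchmark the seven solvers over a set of phantoms
#'
#' Reproduces the structure of the method-comparison study: for each
#' phantom, simulate the difference frame on the forward mesh, reconstruct
#' with every method on the pixel-basis sensitivity matrix, and score
#' SSIM/RMSE/PSNR against the rasterized truth; then average per method
#' and compute CAM against the reference method.
#'
#' @param setup An \code{eit_study_setup}.
#' @param specs List of \code{eit_phantom_spec} (the "models").
#' @param methods Character vector of solver names.
#' @param config An \code{eit_solver_config} shared by all methods.
#' @param reference CAM reference method.
#' @return An \code{eit_benchmark}: \code{results} (long data.frame),
#'   \code{tables} (per-metric \code{\link{comparison_table}}s) and
#'   \code{reconstructions} (last phantom's fits, for inspection).
#' @export
run_benchmark <- function(setup, specs, methods = .all_methods,
                          config = solver_config(), reference = "RS-FISTA") {
  rows <- list()
  recons <- list()
  for (im in seq_along(specs)) {
    dat <- simulate_phantom_data(setup, specs[[im]])
    for (meth in methods) {
      fit <- eit_reconstruct(setup$A, dat$y, meth, config)
      mr <- metrics_report(fit, dat$truth)
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, model = im, ssim = mr$ssim,
                   rmse = mr$rmse, psnr = mr$psnr)
      if (im == length(specs)) recons[[meth]] <- fit
    }
  }
  results <- do.call(rbind, rows)
  tables <- lapply(c(ssim = "ssim", rmse = "rmse", psnr = "psnr"),
                   function(metric) {
    wide <- stats::reshape(results[c("method", "model", metric)],
                           idvar = "method", timevar = "model",
                           direction = "wide")
    names(wide) <- c("method", paste0("model_", seq_along(specs)))
    rownames(wide) <- NULL
    comparison_table(wide, reference)
  })
  structure(list(results = results, tables = tables,
                 reconstructions = recons),
            class = "eit_benchmark")
}

#' @export
print.eit_benchmark <- function(x, ...) {
  cat("eit_benchmark over", length(unique(x$results$model)), "phantom(s)\n")
  for (m in names(x$tables)) {
    cat("\n", toupper(m), ":\n", sep = "")
    tb <- x$tables[[m]]
    print(data.frame(method = tb$method,
                     Average = round(tb$Average, 4),
                     CAM = round(tb$CAM, 2)), row.names = FALSE)
  }
  invisible(x)
}

#' Write benchmark tables as CSV
#'
#' One CSV per metric, methods by models plus Average and CAM columns.
#'
#' @param bench An \code{eit_benchmark}.
#' @param dir Output directory (created if needed).
#' @return Written paths, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(bench$tables), function(m) {
    p <- file.path(dir, sprintf("table_%s.csv", m))
    utils::write.csv(bench$tables[[m]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Noise-robustness study
#'
#' Mean reconstruction quality of one method across SNR levels, with
#' several independent noise realizations per level.
#'
#' @param setup An \code{eit_study_setup}.
#' @param spec Phantom to image.
#' @param snr_levels SNR levels in dB (Inf = noiseless), default the
#'   study levels \code{c(Inf, 60, 50, 40, 30)}.
#' @param noise_seeds Integer seeds, one noise draw per seed per level.
#' @param method Solver name.
#' @param config An \code{eit_solver_config}.
#' @return An \code{eit_noise_study}: \code{results} (snr x seed long
#'   data.frame with ssim/rmse/psnr) and \code{summary} (mean per SNR).
#' @export
run_noise_study <- function(setup, spec,
                            snr_levels = c(Inf, 60, 50, 40, 30),
                            noise_seeds = 1:10, method = "RS-FISTA",
                            config = solver_config()) {
  rows <- list()
  for (snr in snr_levels) {
    seeds <- if (is.finite(snr)) noise_seeds else noise_seeds[1L]
    for (sd in seeds) {
      dat <- simulate_phantom_data(setup, spec, snr_db = snr, noise_seed = sd)
      fit <- eit_reconstruct(setup$A, dat$y, method, config)
      mr <- metrics_report(fit, dat$truth)
      rows[[length(rows) + 1L]] <-
        data.frame(snr_db = snr, seed = sd, ssim = mr$ssim,
                   rmse = mr$rmse, psnr = mr$psnr)
    }
  }
  results <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(results, results$snr_db), function(d)
    data.frame(snr_db = d$snr_db[1L], mean_ssim = mean(d$ssim),
               mean_rmse = mean(d$rmse), mean_psnr = mean(d$psnr))))
  smry <- smry[order(-smry$snr_db), ]
  rownames(smry) <- NULL
  structure(list(results = results, summary = smry, method = method),
            class = "eit_noise_study")
}

#' @export
print.eit_noise_study <- function(x, ...) {
  cat("eit_noise_study,", x$method, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Iteration-convergence study
#'
#' SSIM-versus-iteration curves of the iterative methods on one phantom
#' (NOSER is excluded: it is a one-step method).
#'
#' @param setup An \code{eit_study_setup}.
#' @param spec Phantom to image.
#' @param methods Iterative solvers to sweep.
#' @param checkpoints Increasing iteration counts.
#' @param config An \code{eit_solver_config}.
#' @return data.frame with columns \code{method}, \code{iteration},
#'   \code{ssim}.
#' @export
run_convergence_study <- function(setup, spec,
                                  methods = setdiff(.all_methods, "NOSER"),
                                  checkpoints = c(1, seq(5, 100, by = 5)),
                                  config = solver_config()) {
  if ("NOSER" %in% methods)
    stop("NOSER is a one-step method; it has no convergence curve")
  dat <- simulate_phantom_data(setup, spec)
  out <- lapply(methods, function(meth) {
    cv <- convergence_curve(meth, setup$A, dat$y, dat$truth, checkpoints,
                            config)
    cbind(method = meth, cv)
  })
  do.call(rbind, out)
}

#' Bundled published comparison tables
#'
#' Loads the package's bundled per-model SSIM/RMSE/PSNR tables from a
#' published 16-electrode EIT solver comparison (10 simulation models and
#' 5 tank models, seven methods), including the printed Average and CAM
#' columns. Used to validate the package's Average/CAM arithmetic against
#' independently printed values.
#'
#' @return List of two data.frames, \code{simulation} and \code{tank},
#'   with columns \code{metric, method, model..., average_printed,
#'   cam_printed}.
#' @export
reference_comparison_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "eitrecon"), check.names = FALSE)
  list(simulation = rd("benchmark_metrics_simulation.csv"),
       tank = rd("benchmark_metrics_tank.csv"))
}
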