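#' Electrode model parameters
#'
#' Contact impedances and drive-current amplitude for the complete electrode
#' model (CEM). The CEM augments the interior conduction equation
#' \eqn{\nabla\cdot(\sigma\nabla\phi) = 0} with electrode boundary
#' conditions: zero normal current off the electrodes, prescribed total
#' current through each electrode, a contact-impedance voltage drop
#' \eqn{\phi + \rho_L \sigma \partial\phi/\partial n = U_L} on electrode
#' \code{L}, and the charge/potential conservation constraints
#' \eqn{\sum_L I_L = 0}, \eqn{\sum_L U_L = 0}.
#'
#' @param contact_impedance Contact impedance(s) in Ohm m^2; recycled to one
#'   value per electrode.
#' @param current_amplitude Drive current in Amperes.
#' @param n_electrodes Number of electrodes.
#' @return An \code{eit_electrode_model} list.
#' @export
electrode_model <- function(contact_impedance = 1e-5,
                            current_amplitude = 4.5e-3,
                            n_electrodes = 16L) {
  rho <- rep_len(contact_impedance, n_electrodes)
  if (any(rho <= 0)) stop("contact impedances must be positive")
  if (current_amplitude <= 0) stop("current_amplitude must be positive")
  structure(list(contact_impedances = rho,
                 current_amplitude = current_amplitude,
                 n_electrodes = as.integer(n_electrodes)),
            class = "eit_electrode_model")
}

#' Piecewise-constant conductivity field on a mesh
#'
#' @param mesh An \code{eit_mesh}.
#' @param values Conductivity in S/m, either a scalar (homogeneous) or one
#'   value per triangle. Must be strictly positive; near-insulating
#'   inclusions are represented by a small positive floor (1e-12 S/m).
#' @return An \code{eit_conductivity} list.
#' @export
conductivity_field <- function(mesh, values) {
  m <- nrow(mesh$triangles)
  values <- rep_len(as.numeric(values), if (length(values) == 1L) m else length(values))
  if (length(values) != m) stop("need one conductivity per triangle")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("conductivities must be finite and > 0")
  structure(list(values = values, n_elements = m, radius = mesh$radius),
            class = "eit_conductivity")
}

#' Adjacent-drive, adjacent-measurement protocol
#'
#' Enumerates the standard 16-electrode adjacent protocol: each of the
#' \code{n_electrodes} adjacent electrode pairs is driven in turn
#' (counter-clockwise, starting with pair 1-2), and for each drive the
#' voltage is read on every adjacent pair not sharing an electrode with the
#' drive pair (13 pairs for 16 electrodes, ordered 3-4, 4-5, ..., 15-16 for
#' drive 1-2), for \code{16 * 13 = 208} measurements per frame.
#'
#' @param n_electrodes Number of electrodes (16 gives the 208-measurement
#'   frame).
#' @return An \code{eit_protocol}: a data.frame with columns
#'   \code{meas_index}, \code{drive_a}, \code{drive_b}, \code{meas_a},
#'   \code{meas_b} and attribute \code{n_electrodes}.
#' @export
adjacent_protocol <- function(n_electrodes = 16L) {
  S <- as.integer(n_electrodes)
  if (S < 5L) stop("adjacent protocol needs at least 5 electrodes")
  wrap <- function(i) ((i - 1L) %% S) + 1L
  rows <- vector("list", S)
  for (a in seq_len(S)) {
    m <- wrap(a + 2L + 0L:(S - 4L))
    rows[[a]] <- data.frame(drive_a = a, drive_b = wrap(a + 1L),
                            meas_a = m, meas_b = wrap(m + 1L))
  }
  out <- do.call(rbind, rows)
  out <- cbind(meas_index = seq_len(nrow(out)), out)
  attr(out, "n_electrodes") <- S
  class(out) <- c("eit_protocol", "data.frame")
  out
}

# P1 gradient coefficients for one triangle: rows are the two gradient
# components of the three nodal hat functions; A is the signed area.
.tri_grads <- function(p1, p2, p3) {
  det <- (p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
         (p3[1L] - p1[1L]) * (p2[2L] - p1[2L])
  gx <- c(p2[2L] - p3[2L], p3[2L] - p1[2L], p1[2L] - p2[2L]) / det
  gy <- c(p3[1L] - p2[1L], p1[1L] - p3[1L], p2[1L] - p1[1L]) / det
  list(gx = gx, gy = gy, area = det / 2)
}

#' Assemble the complete-electrode-model FEM system
#'
#' Standard P1 Galerkin discretization of the CEM: piecewise-linear nodal
#' potential basis, piecewise-constant conductivity per triangle. Unknowns
#' are the node potentials, the electrode potentials \eqn{U_L}, and one
#' Lagrange multiplier enforcing \eqn{\sum_L U_L = 0} (the grounding
#' convention). The assembled matrix is symmetric.
#'
#' @param mesh An \code{eit_mesh}.
#' @param sigma An \code{eit_conductivity} on the same mesh.
#' @param em An \code{eit_electrode_model}.
#' @return An \code{eit_cem_system} holding the sparse system matrix and
#'   index bookkeeping; pass to \code{\link{solve_excitation}} or
#'   \code{\link{simulate_frame}}.
#' @export
assemble_cem_system <- function(mesh, sigma, em) {
  if (!inherits(mesh, "eit_mesh")) stop("mesh must be an eit_mesh")
  if (sigma$n_elements != nrow(mesh$triangles))
    stop("conductivity field does not match mesh")
  if (any(sigma$values <= 0)) stop("nonpositive conductivity")
  S <- length(mesh$electrodes)
  if (em$n_electrodes != S) stop("electrode model does not match mesh")
  n <- nrow(mesh$node_coords)
  tr <- mesh$triangles
  p <- mesh$node_coords

  # interior stiffness, vectorized over triangles
  x1 <- p[tr[, 1L], 1L]; y1 <- p[tr[, 1L], 2L]
  x2 <- p[tr[, 2L], 1L]; y2 <- p[tr[, 2L], 2L]
  x3 <- p[tr[, 3L], 1L]; y3 <- p[tr[, 3L], 2L]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  ii <- jj <- vv <- vector("list", 9L)
  idx <- 1L
  for (a in 1L:3L) for (b in 1L:3L) {
    ii[[idx]] <- tr[, a]
    jj[[idx]] <- tr[, b]
    vv[[idx]] <- sigma$values * area * (gx[, a] * gx[, b] + gy[, a] * gy[, b])
    idx <- idx + 1L
  }
  ti <- unlist(ii); tj <- unlist(jj); tv <- unlist(vv)

  # electrode boundary terms
  be <- mesh$boundary_edges
  elen <- sqrt(rowSums((p[be[, 1L], , drop = FALSE] -
                        p[be[, 2L], , drop = FALSE])^2))
  ei <- ej <- ev <- list(); ci <- cj <- cv <- list()
  Dd <- numeric(S)
  for (L in seq_len(S)) {
    zL <- em$contact_impedances[L]
    for (e in mesh$electrodes[[L]]) {
      nds <- be[e, ]
      l <- elen[e]
      # edge mass matrix l/6 * [[2,1],[1,2]] scaled by 1/rho_L
      ei <- c(ei, list(c(nds[1L], nds[1L], nds[2L], nds[2L])))
      ej <- c(ej, list(c(nds[1L], nds[2L], nds[1L], nds[2L])))
      ev <- c(ev, list((l / (6 * zL)) * c(2, 1, 1, 2)))
      # node-electrode coupling -l/(2 rho_L) per endpoint
      ci <- c(ci, list(nds))
      cj <- c(cj, list(c(L, L)))
      cv <- c(cv, list(rep(-l / (2 * zL), 2L)))
      Dd[L] <- Dd[L] + l / zL
    }
  }
  nu <- n + S + 1L   # nodes + electrodes + grounding multiplier
  iall <- c(ti, unlist(ei), unlist(ci), n + unlist(cj),
            n + seq_len(S), rep(nu, S), n + seq_len(S))
  jall <- c(tj, unlist(ej), n + unlist(cj), unlist(ci),
            n + seq_len(S), n + seq_len(S), rep(nu, S))
  vall <- c(tv, unlist(ev), unlist(cv), unlist(cv),
            Dd, rep(1, S), rep(1, S))
  Z <- Matrix::sparseMatrix(i = iall, j = jall, x = vall, dims = c(nu, nu))

  structure(list(matrix = Z, n_nodes = n, n_electrodes = S,
                 mesh = mesh, sigma = sigma, em = em,
                 grads = list(gx = gx, gy = gy, area = area)),
            class = "eit_cem_system")
}

#' Solve one current excitation of an assembled CEM system
#'
#' @param system An \code{eit_cem_system}.
#' @param drive_pair Integer pair \code{c(positive, negative)} of electrode
#'   indices; current \code{+I} enters the first, \code{-I} the second.
#' @param current Drive current in Amperes.
#' @return An \code{eit_forward_solution} with \code{node_potentials},
#'   \code{electrode_potentials} (summing to zero by the grounding
#'   constraint), \code{drive_pair} and \code{current}.
#' @export
solve_excitation <- function(system, drive_pair, current) {
  sol <- .solve_excitations(system, matrix(drive_pair, ncol = 2L), current)
  structure(list(node_potentials = sol$phi[, 1L],
                 electrode_potentials = sol$U[, 1L],
                 drive_pair = as.integer(drive_pair), current = current),
            class = "eit_forward_solution")
}

# solve several drive pairs against one factorization; pairs is k x 2
.solve_excitations <- function(system, pairs, current) {
  S <- system$n_electrodes
  n <- system$n_nodes
  if (any(pairs[, 1L] == pairs[, 2L])) stop("drive electrodes must be distinct")
  k <- nrow(pairs)
  rhs <- matrix(0, n + S + 1L, k)
  for (q in seq_len(k)) {
    rhs[n + pairs[q, 1L], q] <- current
    rhs[n + pairs[q, 2L], q] <- -current
  }
  sol <- tryCatch(as.matrix(Matrix::solve(system$matrix, rhs)),
                  error = function(e) stop("singular CEM system: ", conditionMessage(e)))
  list(phi = sol[seq_len(n), , drop = FALSE],
       U = sol[n + seq_len(S), , drop = FALSE])
}

#' Simulate one boundary-voltage measurement frame
#'
#' Runs the forward solver over every drive pair of the protocol and reads
#' the adjacent-pair voltages, in drive-major order.
#'
#' @param mesh An \code{eit_mesh}.
#' @param sigma An \code{eit_conductivity}.
#' @param em An \code{eit_electrode_model}.
#' @param protocol An \code{eit_protocol} (defaults to the adjacent protocol
#'   for the mesh's electrode count).
#' @param is_reference Flag marking the frame as a homogeneous reference.
#' @return An \code{eit_frame}: \code{voltages} (length \code{M}, Volts),
#'   the protocol, \code{is_reference}, and \code{noise_snr_db}
#'   (\code{NULL} until noise is added).
#' @export
simulate_frame <- function(mesh, sigma, em, protocol = NULL,
                           is_reference = FALSE) {
  if (is.null(protocol)) protocol <- adjacent_protocol(length(mesh$electrodes))
  system <- assemble_cem_system(mesh, sigma, em)
  drives <- unique(protocol[, c("drive_a", "drive_b")])
  sol <- .solve_excitations(system, as.matrix(drives), em$current_amplitude)
  key <- paste(drives$drive_a, drives$drive_b)
  col <- match(paste(protocol$drive_a, protocol$drive_b), key)
  v <- sol$U[cbind(protocol$meas_a, col)] - sol$U[cbind(protocol$meas_b, col)]
  structure(list(voltages = as.numeric(v), protocol = protocol,
                 is_reference = is_reference, noise_snr_db = NULL),
            class = "eit_frame")
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("eit_frame: %d voltages [%.3g, %.3g] V%s%s\n",
              length(x$voltages), min(x$voltages), max(x$voltages),
              if (isTRUE(x$is_reference)) ", reference" else "",
              if (!is.null(x$noise_snr_db))
                sprintf(", SNR %g dB", x$noise_snr_db) else ""))
  invisible(x)
}
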