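test_that("adjacent protocol enumerates 208 measurements, drive-major", {
  pr <- test_protocol()
  expect_equal(nrow(pr), 208L)
  # drive 1-2 comes first, measuring 3-4, 4-5, ..., 15-16
  b1 <- pr[pr$drive_a == 1L, ]
  expect_equal(b1$meas_a, 3:15)
  expect_equal(b1$meas_b, 4:16)
  # no measurement pair touches its drive pair
  expect_false(any(pr$meas_a == pr$drive_a | pr$meas_a == pr$drive_b |
                   pr$meas_b == pr$drive_a | pr$meas_b == pr$drive_b))
})

test_that("assembled CEM system is symmetric and null at zero current", {
  m <- test_mesh()
  sys <- assemble_cem_system(m, conductivity_field(m, 1), test_em())
  expect_lt(max(abs(sys$matrix - Matrix::t(sys$matrix))), 1e-10)
  sol <- solve_excitation(sys, c(1L, 2L), 0)
  expect_equal(max(abs(sol$node_potentials)), 0, tolerance = 1e-15)
  expect_equal(max(abs(sol$electrode_potentials)), 0, tolerance = 1e-15)
})

test_that("electrode potentials sum to zero and scale with conductivity", {
  m <- test_mesh()
  em <- test_em()
  sys <- assemble_cem_system(m, conductivity_field(m, 1), em)
  sol <- solve_excitation(sys, c(1L, 2L), em$current_amplitude)
  expect_lt(abs(sum(sol$electrode_potentials)) /
              max(abs(sol$electrode_potentials)), 1e-9)
  # sigma doubled, contact impedance halved -> potentials halve
  em2 <- electrode_model(contact_impedance = 0.5e-5)
  sys2 <- assemble_cem_system(m, conductivity_field(m, 2), em2)
  sol2 <- solve_excitation(sys2, c(1L, 2L), em$current_amplitude)
  expect_equal(sol2$electrode_potentials, sol$electrode_potentials / 2,
               tolerance = 1e-10)
})

test_that("homogeneous-disk potentials are antisymmetric across the drive axis", {
  m <- test_mesh()
  em <- test_em()
  sys <- assemble_cem_system(m, conductivity_field(m, 1), em)
  U <- solve_excitation(sys, c(1L, 2L), em$current_amplitude)$electrode_potentials
  # reflection through the 1-2 bisector maps electrode L to (3 - L) mod 16
  mirror <- ((3L - seq_len(16L)) %% 16L) + c(rep(0L, 16L))
  mirror[mirror == 0L] <- 16L
  expect_equal(U, -U[mirror], tolerance = 1e-9)
})

test_that("homogeneous frame: reciprocity, rotation invariance, sigma scaling", {
  m <- test_mesh()
  em <- test_em()
  pr <- test_protocol()
  fr <- simulate_frame(m, conductivity_field(m, 1), em, pr)
  expect_length(fr$voltages, 208L)
  vmax <- max(abs(fr$voltages))
  # reciprocity: drive p measure q == drive q measure p
  key <- paste(pr$drive_a, pr$drive_b, pr$meas_a, pr$meas_b)
  rev_idx <- match(paste(pr$meas_a, pr$meas_b, pr$drive_a, pr$drive_b), key)
  expect_false(anyNA(rev_idx))
  expect_lt(max(abs(fr$voltages - fr$voltages[rev_idx])) / vmax, 1e-8)
  # rotation by one electrode = cyclic shift of the 13-measurement blocks
  blocks <- matrix(fr$voltages, nrow = 13L)
  expect_lt(max(abs(sweep(blocks, 1L, blocks[, 1L]))) / vmax, 1e-9)
  # sigma * c with rho / c -> voltages / c
  em3 <- electrode_model(contact_impedance = 1e-5 / 3)
  fr3 <- simulate_frame(m, conductivity_field(m, 3), em3, pr)
  expect_equal(fr3$voltages, fr$voltages / 3, tolerance = 1e-9)
})

test_that("forward solution is stable under mesh refinement", {
  em <- test_em()
  pr <- test_protocol()
  f1 <- simulate_frame(test_mesh(), conductivity_field(test_mesh(), 1), em, pr)
  m2 <- build_disk_mesh(0.095, 16, 0.01, 3000)
  f2 <- simulate_frame(m2, conductivity_field(m2, 1), em, pr)
  expect_lt(max(abs(f1$voltages - f2$voltages)) / max(abs(f2$voltages)), 0.02)
})

test_that("invalid inputs are rejected", {
  m <- test_mesh()
  expect_error(conductivity_field(m, -1), "> 0")
  expect_error(conductivity_field(m, rep(1, 5)), "per triangle")
  sys <- assemble_cem_system(m, conductivity_field(m, 1), test_em())
  expect_error(solve_excitation(sys, c(2L, 2L), 1e-3), "distinct")
})
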