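# shared fixtures, built once per test run and cached
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# coarse mesh for forward/Jacobian unit tests (784 elements)
test_mesh <- function() memo("mesh800", build_disk_mesh(0.095, 16, 0.01, 800))

test_em <- function() electrode_model()

test_protocol <- function() memo("protocol", adjacent_protocol(16))

# small end-to-end setup: coarse meshes, 32 px grid, fast to build
test_setup <- function() memo("setup", study_setup(
  forward_elements = 800, jacobian_elements = 400, grid_size = 32))

# full-size study setup used by the acceptance checks
accept_setup <- function() memo("accept_setup", study_setup())

# the packaged single-inclusion phantom of the convergence/recovery studies
packaged_phantom <- function() random_phantom(7, 1)

# seeded small LASSO instance: n x p Gaussian design, sparse truth
tiny_lasso <- function(seed = 42, n = 30, p = 100, k = 5) {
  with_seed(seed, {
    A <- matrix(rnorm(n * p), n, p)
    xt <- numeric(p)
    xt[sample(p, k)] <- c(2, -1.5, 1, 3, -2)[seq_len(k)]
    list(A = A, xt = xt, y = as.numeric(A %*% xt))
  })
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
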