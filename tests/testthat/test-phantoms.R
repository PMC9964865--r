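test_that("make_phantom paints inclusions by centroid membership", {
  m <- test_mesh()
  empty <- make_phantom(phantom_spec(), m)
  expect_true(all(empty$values == 1))

  spec <- phantom_spec(list(list(center = c(0, 0), radius = 0.02,
                                 conductivity = 1e-12)))
  ph <- make_phantom(spec, m)
  ctr <- triangle_centroids(m)
  inside <- sqrt(rowSums(ctr^2)) < 0.02
  expect_true(all(ph$values[inside] == 1e-12))
  expect_true(all(ph$values[!inside] == 1))
  # modified-element count tracks the area ratio
  frac_area <- (pi * 0.02^2) / (pi * 0.095^2)
  frac_elem <- mean(inside)
  expect_lt(abs(frac_elem - frac_area) / frac_area, 0.15)
})

test_that("phantom specs enforce margin and non-overlap", {
  expect_error(phantom_spec(list(list(center = c(0.08, 0), radius = 0.02,
                                      conductivity = 1e-12))), "margin")
  expect_error(phantom_spec(list(
    list(center = c(0, 0), radius = 0.02, conductivity = 1e-12),
    list(center = c(0.03, 0), radius = 0.02, conductivity = 1e-12))),
    "overlap")
})

test_that("random phantoms are reproducible and always valid", {
  a <- random_phantom(123, 3)
  b <- random_phantom(123, 3)
  expect_identical(a, b)
  expect_length(a$inclusions, 3L)
  expect_error(random_phantom(1, 5), "between 1 and 4")
  # property sweep: margin and overlap invariants over many seeds
  for (sd in 1:1000) {
    sp <- random_phantom(sd, 1L + (sd %% 4L))
    for (inc in sp$inclusions)
      expect_lte(sqrt(sum(inc$center^2)) + inc$radius, 0.095 - 2e-3 + 1e-12)
    if (length(sp$inclusions) > 1L)
      for (i in 1:(length(sp$inclusions) - 1L))
        for (j in (i + 1L):length(sp$inclusions))
          expect_gte(sqrt(sum((sp$inclusions[[i]]$center -
                               sp$inclusions[[j]]$center)^2)),
                     sp$inclusions[[i]]$radius + sp$inclusions[[j]]$radius)
  }
})

test_that("rasterization matches geometry and symmetry", {
  g <- pixel_grid(64, 0.095)
  expect_true(all(rasterize(phantom_spec(), g)$pixel_values == 0))

  spec <- phantom_spec(list(list(center = c(0, 0), radius = 0.025,
                                 conductivity = 1e-12)))
  gt <- rasterize(spec, g)
  img <- pixels_to_image(gt$pixel_values, g, fill = 0)
  rot90 <- t(img)[g$size:1, ]
  expect_equal(img, rot90)
  n_hit <- sum(gt$pixel_values != 0)
  expected <- pi * 0.025^2 / g$pixel_size^2
  perimeter <- 2 * pi * 0.025 / g$pixel_size
  expect_lt(abs(n_hit - expected), perimeter + 2)
  # pixel values are the conductivity difference
  expect_equal(unique(gt$pixel_values[gt$pixel_values != 0]), 1e-12 - 1)
})

test_that("rasterize and make_phantom agree on covered area fraction", {
  m <- test_mesh()
  g <- pixel_grid(64, 0.095)
  spec <- phantom_spec(list(list(center = c(0.02, -0.01), radius = 0.025,
                                 conductivity = 1e-12)))
  frac_pix <- mean(rasterize(spec, g)$pixel_values != 0)
  frac_elem <- mean(make_phantom(spec, m)$values != 1)
  expect_lt(abs(frac_pix - frac_elem) / frac_elem, 0.10)
})

test_that("noise injection hits the requested SNR exactly and is seeded", {
  m <- test_mesh()
  fr <- simulate_frame(m, conductivity_field(m, 1), test_em())
  expect_identical(add_noise(fr, Inf, 1), fr)
  nf <- add_noise(fr, 40, 1)
  e <- nf$voltages - fr$voltages
  snr <- 10 * log10(sum(fr$voltages^2) / sum(e^2))
  expect_equal(snr, 40, tolerance = 1e-9)
  nf2 <- add_noise(fr, 40, 2)
  e2 <- nf2$voltages - fr$voltages
  expect_false(isTRUE(all.equal(e, e2)))
  expect_equal(sum(e^2), sum(e2^2), tolerance = 1e-12)
  expect_identical(add_noise(fr, 40, 1)$voltages, nf$voltages)
  zfr <- fr
  zfr$voltages <- rep(0, length(fr$voltages))
  expect_error(add_noise(zfr, 40, 1), "zero-power")
})

test_that("phantom spec text round-trips", {
  spec <- random_phantom(5, 2)
  path <- tempfile(fileext = ".txt")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$background_conductivity, spec$background_conductivity)
  expect_equal(back$disk_radius, spec$disk_radius)
  expect_equal(length(back$inclusions), length(spec$inclusions))
  for (i in seq_along(spec$inclusions))
    expect_equal(back$inclusions[[i]], spec$inclusions[[i]])
})
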