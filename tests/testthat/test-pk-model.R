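test_that("enhancement curve obeys its closed form and trivial limits", {
  # zero amplitude and t = 0 give no enhancement
  expect_equal(brix_enhancement(c(0, 60, 600), 0, 0.7, 0.1), rep(0, 3))
  expect_identical(brix_enhancement(0, 3.2, 1.1, 0.2), 0)

  # independent literal evaluation of the infusion closed form at t = 120 s
  A <- 2; kep <- 0.8; kel <- 0.05; tau <- 7 / 60; t <- 2
  h <- function(k, t) (exp(k * min(t, tau)) - 1) / k * exp(-k * t)
  expected <- (A / tau) * kep * (h(kel, t) - h(kep, t)) / (kep - kel)
  expect_equal(brix_enhancement(120, A, kep, kel, 7), expected,
               tolerance = 1e-12)

  # degenerate k_ep == k_el branch agrees with the numeric continuation
  # of the generic branch (symmetrized central difference around the
  # diagonal, which cancels the O(d) term of the k_ep prefactor)
  for (t_s in c(30, 120, 480)) {
    d <- 1e-5
    lim <- (brix_enhancement(t_s, 2, 0.5 + d, 0.5 - d) +
              brix_enhancement(t_s, 2, 0.5 - d, 0.5 + d)) / 2
    expect_equal(brix_enhancement(t_s, 2, 0.5, 0.5), lim, tolerance = 1e-8)
  }

  # continuity across t = tau
  eps <- 1e-7
  expect_equal(brix_enhancement(7 - eps, 2, 0.8, 0.05),
               brix_enhancement(7 + eps, 2, 0.8, 0.05), tolerance = 1e-6)

  expect_error(brix_enhancement(-1, 1, 0.5, 0.1), "non-negative")
  expect_error(brix_enhancement(10, 1, -0.5, 0.1), "non-negative")
  expect_error(brix_enhancement(10, 1, 0.5, 0.1, tau = 0), "positive")
})

test_that("enhancement is non-negative and continuous in the rates", {
  set.seed(7)
  for (i in 1:50) {
    A <- runif(1, 0, 5); kep <- runif(1, 0, 3); kel <- runif(1, 0, 1)
    tt <- sort(runif(5, 0, 900))
    expect_true(all(brix_enhancement(tt, A, kep, kel) >= -1e-12))
  }
})

test_that("noiseless curves are recovered to 0.1% by the multi-start fit", {
  t <- seq(0, 600, by = 120)
  cases <- list(c(2.0, 0.8, 0.05), c(1.0, 0.4, 0.02), c(0.2, 0.2, 0.01),
                c(3.0, 2.5, 0.3))
  for (p in cases) {
    s <- 100 * (1 + brix_enhancement(t, p[1], p[2], p[3]))
    f <- fit_voxel_curve(t, s)
    expect_true(f$converged)
    expect_lt(abs(f$A_amp - p[1]) / p[1], 1e-3)
    expect_lt(abs(f$k_ep - p[2]) / p[2], 1e-3)
    expect_lt(abs(f$k_el - p[3]) / p[3], 1e-3)
  }
})

test_that("parameters survive 1% noise with < 5% median error", {
  # noise sd defined as a fraction of the baseline signal, matching the
  # phantom's noise convention
  t <- seq(0, 600, by = 120)
  E <- brix_enhancement(t, 2, 0.8, 0.05)
  errs <- sapply(1:100, function(i) {
    set.seed(1000 + i)
    s <- 100 * (1 + E) + rnorm(length(t), 0, 0.01 * 100)
    f <- fit_voxel_curve(t, s)
    abs(c(f$A_amp, f$k_ep, f$k_el) - c(2, 0.8, 0.05)) / c(2, 0.8, 0.05)
  })
  expect_true(all(apply(errs, 1, median) < 0.05))
})

test_that("flat and unfittable voxels are handled", {
  t <- seq(0, 600, by = 120)
  f <- fit_voxel_curve(t, rep(100, 6))
  expect_lt(abs(f$A_amp), 1e-6)
  expect_lt(f$A_peak, 1e-6)

  f0 <- fit_voxel_curve(t, c(0, 10, 10, 10, 10, 10))
  expect_false(f0$converged)
  expect_identical(f0$A_amp, 0)
})

test_that("A_peak matches the analytic curve maximum", {
  t <- seq(0, 600, by = 120)
  s <- 100 * (1 + brix_enhancement(t, 2, 0.8, 0.05))
  f <- fit_voxel_curve(t, s)
  tg <- seq(0, 600, by = 0.25)
  expect_equal(f$A_peak,
               max(brix_enhancement(tg, f$A_amp, f$k_ep, f$k_el)),
               tolerance = 1e-5)
})

test_that("fit_volume conserves shape, honors the mask, is deterministic", {
  spec <- small_spec(noise_sd = 0.01, seed = 3L)
  ph <- generate_phantom(spec)
  # empty mask -> all-zero pseudoimages
  empty <- array(FALSE, spec$shape)
  pk0 <- fit_volume(ph$series, empty)
  expect_true(all(pk0$A == 0) && all(pk0$k_ep == 0) && all(pk0$k_el == 0))

  pk <- fit_volume(ph$series, ph$body_mask)
  expect_identical(dim(pk$A), spec$shape)
  expect_identical(dim(pk$k_ep), spec$shape)
  expect_identical(dim(pk$k_el), spec$shape)
  expect_true(all(pk$A[!ph$body_mask] == 0))

  pk2 <- fit_volume(ph$series, ph$body_mask)
  expect_identical(pk, pk2)

  expect_error(fit_volume(ph$series, array(TRUE, c(4, 4, 4))), "shape")
})

test_that("fitted k_ep separates the phantom kinetic classes", {
  ph <- generate_phantom(small_spec(noise_sd = 0.01, seed = 11L))
  pk <- fit_volume(ph$series, ph$body_mask)
  kep_norm <- pk$k_ep[ph$class_map == 1L]
  kep_mal <- pk$k_ep[ph$class_map == 3L]
  # interquartile ranges must not overlap
  expect_lt(quantile(kep_norm, 0.75), quantile(kep_mal, 0.25))
})
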