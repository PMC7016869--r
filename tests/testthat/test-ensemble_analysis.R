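test_that("GA selection finds a planted single conformer", {
  pools <- fx_pools_small()
  set.seed(55)
  k <- 137
  sig <- pools$closed$curves[, k]
  sgm <- sqrt(sig) * sqrt(sig[1]) / 500
  dat <- scattering_curve(pools$q, sig + rnorm(length(sig), 0, sgm), sgm)
  fit <- select_ensemble(pools$closed, dat, generations = 150, seed = 8)
  expect_lte(fit$chi2, 1.1)
  # dominated by the planted member or its Rg-equivalents
  rg_true <- pools$closed$rg_values[k]
  rg_sel <- pools$closed$rg_values[fit$member_refs]
  expect_gte(mean(abs(rg_sel - rg_true) < 0.75), 0.8)
})

test_that("GA selection recovers a planted two-state split within 7
           points", {
  pools <- fx_pools_small()
  fr <- vapply(1:3, function(r) {
    pl <- plant_two_state(pools, 17, 3, seed = 200 + r)
    fit <- select_ensemble(list(pools$closed, pools$extended), pl$curve,
                           generations = 150, seed = 210 + r)
    stopifnot(abs(sum(fit$weights) - 1) < 1e-9)
    fit$pool_weights[["closed"]]
  }, 1)
  expect_lt(abs(mean(fr) - 0.85), 0.07)
})

test_that("GA fitness is monotone under elitism and seeded runs are
           identical", {
  pools <- fx_pools_small()
  pl <- plant_two_state(pools, 17, 3, seed = 300)
  f1 <- select_ensemble(list(pools$closed, pools$extended), pl$curve,
                        generations = 60, seed = 77)
  f2 <- select_ensemble(list(pools$closed, pools$extended), pl$curve,
                        generations = 60, seed = 77)
  expect_identical(f1$member_refs, f2$member_refs)
  expect_identical(f1$chi2, f2$chi2)
  expect_true(all(diff(f1$best_trace) <= 1e-12))

  # independent seeds agree on the attainable chi2 within 5%
  f3 <- select_ensemble(list(pools$closed, pools$extended), pl$curve,
                        generations = 150, seed = 177)
  f4 <- select_ensemble(list(pools$closed, pools$extended), pl$curve,
                        generations = 150, seed = 277)
  expect_lt(abs(f3$chi2 - f4$chi2) / f3$chi2, 0.05)
})

test_that("monomer/dimer mass-scaled selection identifies pure dimer", {
  pools <- fx_pools_small()
  set.seed(401)
  idx <- sample(length(pools$dimer$members), 20, TRUE)
  Dn <- sweep(pools$dimer$curves[, idx], 2,
              2 / pools$dimer$curves[1, idx], `*`)
  sig <- rowMeans(Dn) * 1e5
  sgm <- sqrt(sig) * sqrt(sig[1]) / 300
  dat <- scattering_curve(pools$q, sig + rnorm(length(sig), 0, sgm), sgm)
  fit <- select_ensemble(list(pools$closed, pools$dimer), dat,
                         mass_scales = c(1, 2), generations = 150,
                         seed = 402)
  expect_gte(fit$pool_weights[["dimer"]], 0.95)
})

test_that("rg_distribution reports selected and pool histograms", {
  pools <- fx_pools_small()
  n <- length(pools$closed$members)
  # degenerate fit: one member selected 20 times
  fit1 <- structure(list(member_refs = rep(17L, 20)),
                    class = "ensemble_fit")
  d1 <- rg_distribution(fit1, pools$closed)
  expect_equal(sum(d1$selected_freq > 0), 1L)
  expect_equal(max(d1$selected_freq), 1)
  expect_equal(sum(d1$pool_freq), 1, tolerance = 1e-12)

  # uniform selection reproduces the pool distribution exactly
  fit2 <- structure(list(member_refs = seq_len(n)), class = "ensemble_fit")
  d2 <- rg_distribution(fit2, pools$closed)
  expect_equal(d2$selected_freq, d2$pool_freq)

  expect_error(rg_distribution(
    structure(list(member_refs = n + 50L), class = "ensemble_fit"),
    pools$closed), "outside")
})

test_that("peak decomposition resolves an 85/15 double Gaussian", {
  set.seed(3)
  x <- seq(28, 44, by = 0.25)
  y <- 0.85 * dnorm(x, 33, 1) + 0.15 * dnorm(x, 38.5, 1.1)
  cnt <- rmultinom(1, 2000, y / sum(y))[, 1]
  pk <- decompose_peaks(mk_rg_dist(x, cnt))
  expect_equal(pk$n_peaks, 2L)
  expect_equal(pk$peaks[[1]]$area_fraction, 85, tolerance = 3 / 85)
  expect_equal(pk$peaks[[1]]$center, 33, tolerance = 0.2 / 33)
  expect_equal(pk$peaks[[2]]$center, 38.5, tolerance = 0.2 / 38.5)
})

test_that("a flat-top pair is reported as one double-Gaussian peak", {
  x <- seq(28, 40, by = 0.25)
  y <- dnorm(x, 32.6, 0.5) + dnorm(x, 33.4, 0.5)
  pk <- decompose_peaks(mk_rg_dist(x, y))
  expect_equal(pk$n_peaks, 1L)
  expect_equal(pk$peaks[[1]]$shape, "double_gaussian")
  expect_equal(pk$peaks[[1]]$center, 33, tolerance = 0.01)
  expect_equal(pk$peaks[[1]]$area_fraction, 100)
})

test_that("a clean single Gaussian yields one peak with the right FWHM", {
  x <- seq(28, 40, by = 0.25)
  y <- dnorm(x, 33, 1)
  pk <- decompose_peaks(mk_rg_dist(x, y))
  expect_equal(pk$n_peaks, 1L)
  expect_equal(pk$peaks[[1]]$shape, "gaussian")
  expect_equal(pk$peaks[[1]]$center, 33, tolerance = 0.1 / 33)
  expect_equal(pk$peaks[[1]]$fwhm, 2.3548, tolerance = 0.1 / 2.35)
  expect_equal(pk$peaks[[1]]$area_fraction, 100, tolerance = 1e-6)

  expect_error(decompose_peaks(mk_rg_dist(x[1:4], y[1:4])), "occupied")
})

test_that("peak areas are stable under bin-width halving", {
  pools <- fx_pools_small()
  pl <- plant_two_state(pools, 17, 3, seed = 500)
  fit <- select_ensemble(list(pools$closed, pools$extended), pl$curve,
                         generations = 150, seed = 501)
  pools_l <- list(pools$closed, pools$extended)
  d1 <- rg_distribution(fit, pools_l, bin_width = 0.5)
  d2 <- rg_distribution(fit, pools_l, bin_width = 0.25)
  p1 <- decompose_peaks(d1)
  p2 <- decompose_peaks(d2)
  expect_equal(p1$peaks[[1]]$area_fraction, p2$peaks[[1]]$area_fraction,
               tolerance = 2 / p1$peaks[[1]]$area_fraction)
})
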