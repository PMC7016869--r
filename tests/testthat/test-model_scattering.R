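test_that("Debye curve matches the two-bead closed form and I(0) = W^2", {
  q <- seq(0.01, 0.5, length.out = 60)
  d <- 10
  m2 <- coordinate_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  dc <- debye_curve(m2, q, method = "exact")
  expect_equal(dc$intensity / 4, (1 + sin(q * d) / (q * d)) / 2,
               tolerance = 1e-12)

  set.seed(1)
  w <- runif(15, 0.5, 2)
  mw <- coordinate_model(matrix(rnorm(45, sd = 10), 15, 3), weights = w)
  q0 <- 1e-6
  expect_equal(debye_curve(mw, q0, method = "exact")$intensity, sum(w)^2,
               tolerance = 1e-6)
})

test_that("histogram Debye matches the exact double sum within 0.2%", {
  set.seed(12)
  q <- seq(0.01, 0.5, length.out = 50)
  worst <- 0
  for (i in 1:50) {
    m <- coordinate_model(make_globule(200))
    e <- debye_curve(m, q, method = "exact")$intensity
    h <- debye_curve(m, q, method = "histogram", bin_width = 0.5)$intensity
    worst <- max(worst, max(abs(h - e) / e))
  }
  expect_lt(worst, 0.002)
})

test_that("Guinier Rg of a Debye curve matches the model geometry", {
  set.seed(13)
  m <- coordinate_model(make_globule(500))
  q <- seq(0.004, 0.2, length.out = 200)
  cv <- debye_curve(m, q)
  # a tight qRg window removes the Guinier truncation bias
  g <- guinier_fit(scattering_curve(q, cv$intensity, rep(1, length(q))),
                   qrg_limit = 0.8)
  expect_equal(g$rg, radius_of_gyration(m), tolerance = 0.005)
  expect_equal(cv$meta$model_rg, radius_of_gyration(m), tolerance = 1e-9)
})

test_that("fit_scale recovers exact scale and constant, and calibrates
           noise to chi2 ~ 1", {
  q <- seq(0.01, 0.3, length.out = 300)
  th <- scattering_curve(q, 1e4 * exp(-q^2 * 30^2 / 3), rep(0, length(q)))
  exp_c <- scattering_curve(q, 3 * th$intensity + 7, rep(2, length(q)))
  ft <- fit_scale(th, exp_c)
  expect_equal(ft$scale, 3, tolerance = 1e-10)
  expect_equal(ft$constant, 7, tolerance = 1e-8)
  expect_lt(ft$chi2, 1e-15)

  set.seed(2)
  chis <- replicate(40, {
    y <- th$intensity + rnorm(length(q), 0, 5)
    fit_scale(th, scattering_curve(q, y, rep(5, length(q))))$chi2
  })
  expect_equal(mean(chis), 1.0, tolerance = 0.15)

  # joint rescaling of experiment and sigma leaves chi2 unchanged
  set.seed(3)
  y <- th$intensity + rnorm(length(q), 0, 5)
  f1 <- fit_scale(th, scattering_curve(q, y, rep(5, length(q))))
  f2 <- fit_scale(th, scattering_curve(q, 10 * y, rep(50, length(q))))
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-9)
  expect_equal(f2$scale, 10 * f1$scale, tolerance = 1e-9)

  flat <- scattering_curve(q, rep(5, length(q)), rep(0, length(q)))
  expect_error(fit_scale(flat, exp_c), "singular")
})

test_that("mixture_curve: limits, mass convention and linearity", {
  q <- seq(0.01, 0.3, length.out = 80)
  c1 <- scattering_curve(q, 1e4 * exp(-q^2 * 25^2 / 3), rep(0, length(q)))
  c2 <- scattering_curve(q, 2e4 * exp(-q^2 * 40^2 / 3), rep(0, length(q)))
  expect_equal(mixture_curve(list(c1, c2), c(1, 0))$intensity, c1$intensity)
  expect_error(mixture_curve(list(c1, c2), c(0.6, 0.6)), "sum to 1")

  # equal-mass monomer/dimer convention: I(0) = 1.5 x monomer I(0)
  mx <- mixture_curve(list(c1, c2), c(0.5, 0.5), mass_scale = c(1, 2))
  expect_equal(mx$intensity[1], 1.5, tolerance = 1e-9)

  # apparent Rg of a mixture lies between the component Rg values
  mx2 <- mixture_curve(list(c1, c2), c(0.5, 0.5))
  g <- guinier_fit(scattering_curve(q, mx2$intensity, rep(1, length(q))))
  expect_gt(g$rg, 25)
  expect_lt(g$rg, 40)

  # mixture of mixtures equals the flat mixture
  mA <- mixture_curve(list(c1, c2), c(0.5, 0.5))
  mB <- mixture_curve(list(mA, c2), c(0.8, 0.2))
  mflat <- mixture_curve(list(c1, c2), c(0.4, 0.6))
  expect_equal(mB$intensity, mflat$intensity, tolerance = 1e-12)
})
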