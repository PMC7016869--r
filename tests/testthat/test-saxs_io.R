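test_that("read_curve parses 3-column text, drops bad rows, keeps headers", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# toy curve", "# concentration: 0.5",
               "0.01 100 1", "0.02 99 1", "0.03 97 1",
               "-0.01 5 1",            # non-positive q: dropped
               "0.04 96 0",            # non-positive sigma: dropped
               "0.05 95 1", "0.06 93 1", "0.07 90 1"), f)
  cv <- read_curve(f)
  expect_s3_class(cv, "scattering_curve")
  expect_equal(cv$q, c(0.01, 0.02, 0.03, 0.05, 0.06, 0.07))
  expect_equal(cv$meta$n_dropped, 2)
  expect_true(any(grepl("concentration", cv$meta$header)))

  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 1 1", "0.02 1 1", "0.03 oops 1", "0.04 1 1",
               "0.05 1 1"), bad)
  expect_error(read_curve(bad), "line 3")
  few <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 1 1", "0.02 1 1"), few)
  expect_error(read_curve(few), "insufficient")
})

test_that("write_curve/read_curve round trip preserves 6 significant digits", {
  set.seed(1)
  q <- sort(runif(40, 0.01, 0.5))
  cv <- scattering_curve(q, 1e5 * exp(-q^2 * 300) * (1 + rnorm(40, 0, .01)),
                         runif(40, 0.5, 2),
                         meta = list(concentration = 0.5, label = "toy"))
  f <- withr::local_tempfile(fileext = ".dat")
  write_curve(cv, f)
  expect_true(any(grepl("0.5", readLines(f)[1:5])))
  back <- read_curve(f)
  expect_equal(back$q, cv$q, tolerance = 1e-6)
  expect_equal(back$intensity, cv$intensity, tolerance = 1e-6)
  expect_equal(back$sigma, cv$sigma, tolerance = 1e-6)
})

test_that("scattering_curve validates its invariants", {
  expect_error(scattering_curve(c(0.2, 0.1), c(1, 1), c(1, 1)),
               "increasing")
  expect_error(scattering_curve(c(-0.1, 0.1), c(1, 1), c(1, 1)), "positive")
  expect_error(scattering_curve(c(0.1, 0.2), c(1, 1, 1), c(1, 1)), "length")
})

test_that("average_frames combines identical frames and rejects outliers", {
  q <- seq(0.01, 0.5, length.out = 120)
  I <- 1e4 * exp(-q^2 * 33^2 / 3) + 20
  f1 <- scattering_curve(q, I, sqrt(I))

  av1 <- average_frames(list(f1))
  expect_equal(av1$intensity, f1$intensity)

  av3 <- average_frames(list(f1, f1, f1))
  expect_equal(av3$intensity, f1$intensity)
  expect_equal(av3$sigma, f1$sigma / sqrt(3))
  expect_true(all(av3$sigma <= f1$sigma))  # never noisier than one frame

  # a frame scaled x2 (e.g. aggregation) is rejected, survivors kept
  fout <- scattering_curve(q, 2 * I, sqrt(I))
  av <- average_frames(list(f1, f1, fout))
  expect_equal(av$meta$rejected, 3L)
  expect_equal(av$meta$n_frames_used, 2L)
  expect_equal(av$intensity, f1$intensity)

  f_badgrid <- scattering_curve(q + 1e-3, I, sqrt(I))
  expect_error(average_frames(list(f1, f_badgrid)), "grid")
})

test_that("subtract_buffer identity: sample equal to buffer gives t = 1", {
  q <- seq(0.012, 0.67, length.out = 220)
  B <- 40 * exp(-q / 0.2) + 12
  b <- scattering_curve(q, B, 0.05 * sqrt(B))
  out <- subtract_buffer(b, b)
  expect_equal(out$meta$transmission, 1, tolerance = 1e-10)
  expect_true(all(abs(out$intensity) < 1e-9))
})

test_that("subtract_buffer recovers a planted transmission factor", {
  # construction per the stated assumption: the signal is far below the
  # buffer everywhere in the fit window
  q <- seq(0.012, 0.67, length.out = 250)
  B <- 50 * exp(-q / 0.25) + 15
  S <- 2000 * exp(-q^2 * 40^2 / 3)     # < 1e-10 of buffer beyond q = 0.1
  for (t_true in c(0.92, 0.97, 1.05)) {
    set.seed(round(100 * t_true))
    ss <- 0.02 * sqrt(S + t_true * B); sbs <- 0.02 * sqrt(B)
    samp <- scattering_curve(q, S + t_true * B + rnorm(length(q), 0, ss), ss)
    bufc <- scattering_curve(q, B + rnorm(length(q), 0, sbs), sbs)
    out <- suppressWarnings(subtract_buffer(samp, bufc))
    expect_equal(out$meta$transmission, t_true, tolerance = 0.01)
    expect_lt(out$meta$window_residual_sigma, 1)
  }
})

test_that("fixing t = 1 on mismatched transmission leaves a buffer-shaped
           offset", {
  q <- seq(0.012, 0.67, length.out = 250)
  B <- 50 * exp(-q / 0.25) + 15
  S <- 2000 * exp(-q^2 * 40^2 / 3)
  samp <- scattering_curve(q, S + 0.97 * B, 0.02 * sqrt(S + B))
  bufc <- scattering_curve(q, B, 0.02 * sqrt(B))
  out <- subtract_buffer(samp, bufc, transmission = 1.0)
  win <- q > 0.2
  expect_equal(out$intensity[win], -0.03 * B[win], tolerance = 1e-6)
  expect_error(subtract_buffer(samp, bufc, q_window = c(5, 6)), "window")
})

test_that("calibrate_intensity rescales to MW units and is linear in 1/c", {
  cv <- fx_sphere_curve()
  expect_equal(calibrate_intensity(cv, 1, 1)$intensity, cv$intensity)
  cal <- calibrate_intensity(cv, 0.5, 2)
  expect_equal(cal$intensity, cv$intensity * 4)
  expect_equal(cal$sigma, cv$sigma * 4)
  expect_true(isTRUE(cal$meta$calibrated))
  # doubling concentration at fixed constant halves calibrated I(0)
  cal2 <- calibrate_intensity(cv, 1.0, 2)
  expect_equal(cal2$intensity, cal$intensity / 2)
  expect_error(calibrate_intensity(cv, -1, 1), "positive")
  expect_error(calibrate_intensity(cv, 1, 0), "positive")
})
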