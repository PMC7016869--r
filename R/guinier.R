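#' Guinier analysis of the low-q region
#'
#' Weighted linear fit of ln I versus q^2 over a self-consistently chosen
#' window: the upper limit qmax is iterated until qmax * Rg <= `qrg_limit`
#' (the classical validity bound of the Guinier approximation).  With
#' `auto_range = TRUE` the lowest-q points are additionally trimmed when a
#' run of positive residuals indicates an aggregation upturn.
#'
#' @param curve a [scattering_curve()] with positive intensities at low q.
#' @param qrg_limit maximum allowed qmax * Rg (default 1.3).
#' @param auto_range trim low-q upturns by a positive-residual run test.
#' @return A list of class `guinier_result`: `rg`, `rg_err` (Angstrom),
#'   `i0`, `i0_err`, `q_range_used`, `qrg_max`, `fit_r2`, `n_points`.
#' @export
guinier_fit <- function(curve, qrg_limit = 1.3, auto_range = FALSE) {
  stopifnot(is_scattering_curve(curve))
  pos <- curve$intensity > 0
  q <- curve$q[pos]; I <- curve$intensity[pos]; s <- curve$sigma[pos]
  if (length(q) < 10) stop("need at least 10 positive-intensity points")
  # sigma of ln I; fall back to unweighted for theory curves (sigma = 0)
  sl <- ifelse(s > 0, s / I, NA)
  if (anyNA(sl)) sl <- rep(1, length(q))
  w <- 1 / sl^2

  i_lo <- 1L
  fit_window <- function(i_lo, i_hi) {
    x <- q[i_lo:i_hi]^2; y <- log(I[i_lo:i_hi]); ww <- w[i_lo:i_hi]
    fit <- stats::lm.wfit(cbind(1, x), y, ww)
    list(b = unname(fit$coefficients[2]), a = unname(fit$coefficients[1]),
         fit = fit, x = x, y = y, ww = ww)
  }

  i_hi <- max(10L, min(length(q), ceiling(length(q) / 3)))
  # self-consistent qmax * Rg <= limit iteration
  for (iter in 1:50) {
    f <- fit_window(i_lo, i_hi)
    if (f$b >= 0) {
      # shrink until a negative slope emerges
      if (i_hi > i_lo + 9) { i_hi <- i_hi - 1L; next }
      stop("Guinier fit error: non-negative slope (Rg^2 < 0)")
    }
    rg <- sqrt(-3 * f$b)
    i_new <- max(i_lo + 9L, sum(q * rg <= qrg_limit))
    if (i_new < i_lo + 9L)
      stop("Guinier range error: no q window satisfies qmax*Rg <= ",
           qrg_limit)
    if (i_new == i_hi) break
    i_hi <- i_new
  }
  if (auto_range) {
    # trim a leading run of positive residuals (low-q upturn)
    repeat {
      f <- fit_window(i_lo, i_hi)
      r <- f$y - (f$a + f$b * f$x)
      run <- 0L
      for (k in seq_along(r)) { if (r[k] > 0) run <- run + 1L else break }
      if (run >= 3 && i_hi - (i_lo + run) >= 10) i_lo <- i_lo + run
      else break
    }
    # re-iterate the upper limit after trimming
    for (iter in 1:50) {
      f <- fit_window(i_lo, i_hi)
      rg <- sqrt(-3 * min(f$b, -1e-300))
      i_new <- max(i_lo + 9L, sum(q * rg <= qrg_limit))
      if (i_new == i_hi) break
      i_hi <- i_new
    }
  }
  f <- fit_window(i_lo, i_hi)
  if (f$b >= 0) stop("Guinier fit error: non-negative slope")
  n <- i_hi - i_lo + 1L
  # covariance of the weighted fit
  X <- cbind(1, f$x)
  XtWX <- crossprod(X * sqrt(f$ww))
  cov_u <- solve(XtWX)
  r <- f$y - X %*% c(f$a, f$b)
  s2 <- sum(f$ww * r^2) / (n - 2)
  cov <- cov_u * s2
  rg <- sqrt(-3 * f$b)
  rg_err <- sqrt(9 * cov[2, 2] / (4 * -3 * f$b))  # delta method on sqrt(-3b)
  i0 <- exp(f$a)
  i0_err <- i0 * sqrt(cov[1, 1])
  ybar <- sum(f$ww * f$y) / sum(f$ww)
  r2 <- 1 - sum(f$ww * r^2) / sum(f$ww * (f$y - ybar)^2)
  structure(list(rg = rg, rg_err = rg_err, i0 = i0, i0_err = i0_err,
                 q_range_used = c(q[i_lo], q[i_hi]),
                 qrg_max = q[i_hi] * rg, fit_r2 = r2, n_points = n),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.2f +/- %.2f A, I(0) = %.4g +/- %.2g\n",
              x$rg, x$rg_err, x$i0, x$i0_err))
  cat(sprintf("  window q = %.4f..%.4f (qmax*Rg = %.2f, n = %d, R2 = %.4f)\n",
              x$q_range_used[1], x$q_range_used[2], x$qrg_max, x$n_points,
              x$fit_r2))
  invisible(x)
}
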