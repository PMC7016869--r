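#' Average repeated exposure frames with outlier rejection
#'
#' Frames are compared against the running median curve (elementwise
#' median across frames, robust to a minority of aberrant frames) by
#' reduced chi-squared; frames exceeding the similarity threshold
#' (the upper `similarity_alpha` tail quantile of the chi-squared
#' distribution, per degree of freedom) are rejected, e.g. because of
#' radiation-induced aggregation.  Survivors are combined by
#' inverse-variance weighted mean with propagated sigma.
#'
#' @param frames list of [scattering_curve()] objects on identical q grids.
#' @param similarity_alpha significance level for rejection (default 0.01:
#'   reject frames whose reduced chi2 exceeds the 99th percentile).
#' @return A [scattering_curve()] with attribute-free metadata entries
#'   `n_frames_in`, `n_frames_used`, `rejected` (indices) and
#'   `frame_chi2` (per-frame reduced chi2 against the others).
#' @export
average_frames <- function(frames, similarity_alpha = 0.01) {
  if (length(frames) < 1) stop("need at least one frame")
  stopifnot(all(vapply(frames, is_scattering_curve, TRUE)))
  q0 <- frames[[1]]$q
  for (f in frames)
    if (length(f$q) != length(q0) || max(abs(f$q - q0)) > 1e-9)
      stop("frames must share an identical q grid")
  n <- length(frames)
  if (n == 1) {
    out <- frames[[1]]
    out$meta$n_frames_in <- 1L; out$meta$n_frames_used <- 1L
    out$meta$rejected <- integer(0)
    return(out)
  }
  I <- vapply(frames, `[[`, numeric(length(q0)), "intensity")
  S <- vapply(frames, `[[`, numeric(length(q0)), "sigma")
  S[S <= 0] <- min(S[S > 0], 1e-12)
  npt <- length(q0)
  med <- apply(I, 1, stats::median)
  chi2 <- vapply(seq_len(n), function(k)
    sum((I[, k] - med)^2 / S[, k]^2) / npt, 1)
  thresh <- stats::qchisq(1 - similarity_alpha, df = npt) / npt
  keep <- chi2 <= thresh
  if (!any(keep)) stop("all frames rejected at alpha = ", similarity_alpha)
  w <- 1 / S[, keep, drop = FALSE]^2
  mean_i <- rowSums(I[, keep, drop = FALSE] * w) / rowSums(w)
  mean_s <- sqrt(1 / rowSums(w))
  out <- scattering_curve(q0, mean_i, mean_s, meta = frames[[1]]$meta)
  out$meta$n_frames_in <- n
  out$meta$n_frames_used <- sum(keep)
  out$meta$rejected <- which(!keep)
  out$meta$frame_chi2 <- chi2
  out
}

#' Buffer subtraction with differential-transmission correction
#'
#' Dilute biomolecules contribute negligibly at high q, so within the
#' high-q window the net signal I/sigma should approach zero.  The buffer
#' transmission scale t is solved so that the error-weighted mean of
#' I_sample(q) - t * I_buffer(q) over the window is zero, which corrects
#' small transmission mismatches between the sample and buffer exposures.
#'
#' @param sample,buffer [scattering_curve()] objects; the buffer is
#'   linearly interpolated onto the sample grid (overlap only).
#' @param q_window numeric length-2: the high-q fit window in 1/Angstrom
#'   (default `c(0.1, 0.7)`), clipped to the available data.
#' @param transmission fix the scale externally instead of solving (e.g.
#'   `1.0` for plain subtraction); `NULL` (default) solves for it.
#' @return A [scattering_curve()] of the subtracted intensity with sigma
#'   combined in quadrature; `meta$transmission` holds t and
#'   `meta$window_residual_sigma` the error-weighted mean residual over the
#'   window in sigma units.
#' @export
subtract_buffer <- function(sample, buffer, q_window = c(0.1, 0.7),
                            transmission = NULL) {
  stopifnot(is_scattering_curve(sample), is_scattering_curve(buffer))
  qlo <- max(min(sample$q), min(buffer$q))
  qhi <- min(max(sample$q), max(buffer$q))
  keep <- sample$q >= qlo & sample$q <= qhi
  if (sum(keep) < 5) stop("sample and buffer q grids barely overlap")
  q <- sample$q[keep]
  is <- sample$intensity[keep]; ss <- sample$sigma[keep]
  ib <- stats::approx(buffer$q, buffer$intensity, xout = q)$y
  sb <- stats::approx(buffer$q, buffer$sigma, xout = q)$y
  win <- q >= q_window[1] & q <= q_window[2]
  if (!any(win)) stop("q window (", q_window[1], ", ", q_window[2],
                      ") outside the data range")
  if (is.null(transmission)) {
    if (sum(win) < 20) {
      warning("fewer than 20 points in the transmission window; using t = 1")
      t <- 1
    } else {
      # error-weighted mean of (Is - t*Ib) over the signal-free part of
      # the window = 0.  "Signal-free" is established iteratively: points
      # whose net intensity exceeds 1 sigma are excluded and t re-solved,
      # operationalizing the assumption that I/sigma approaches zero
      # (< 1 sigma) within the window
      wi <- which(win)
      sn <- sqrt(ss[wi]^2 + sb[wi]^2)
      w_all <- 1 / sn^2
      # initialize from the top of the window, where any residual signal
      # has decayed furthest; the exclusion pass then extends the set to
      # every signal-free point
      n_hi <- max(20L, ceiling(0.12 * length(wi)))
      hi <- utils::tail(order(q[wi]), n_hi)
      t <- sum(w_all[hi] * is[wi][hi]) / sum(w_all[hi] * ib[wi][hi])
      smooth9 <- function(v) stats::filter(v, rep(1 / 9, 9), sides = 2) |>
        (\(x) { x[is.na(x)] <- v[is.na(x)]; as.numeric(x) })()
      for (it in 1:4) {
        net <- is[wi] - t * ib[wi]
        # a 9-point running mean sees coherent signal well below the
        # per-point noise, so the exclusion is sharper than 1 sigma
        z <- pmax(abs(net) / sn, abs(smooth9(net)) / (sn / 3))
        keep <- z <= 1
        if (sum(keep) < 20) keep <- rank(z, ties.method = "first") <= 20
        t_new <- sum(w_all[keep] * is[wi][keep]) /
          sum(w_all[keep] * ib[wi][keep])
        if (abs(t_new - t) < 1e-5) { t <- t_new; break }
        t <- t_new
      }
      if (t <= 0) stop("transmission fit failed: non-positive t = ", t)
      if (abs(t - 1) > 0.1)
        warning(sprintf("fitted transmission t = %.3f far from 1", t))
    }
  } else {
    t <- transmission
  }
  inet <- is - t * ib
  snet <- sqrt(ss^2 + (t * sb)^2)
  # residual criterion over the signal-free part of the window (the same
  # subset the solve used); for a fixed t the whole window is used
  ri <- which(win)
  if (exists("keep", inherits = FALSE) && is.logical(keep) &&
      length(keep) == length(ri)) ri <- ri[keep]
  w <- 1 / snet[ri]^2
  resid_sigma <- abs(sum(w * inet[ri]) / sum(w)) / sqrt(1 / sum(w))
  meta <- sample$meta
  meta$transmission <- t
  meta$window_residual_sigma <- resid_sigma
  meta$q_window <- q_window
  scattering_curve(q, inet, snet, meta = meta)
}

#' Calibrate intensities to an absolute molecular-weight scale
#'
#' Rescales intensity and sigma by `calibration_constant / concentration`
#' so that the extrapolated forward scattering I(0) reads directly as
#' molecular weight in Da (the standard known-MW protein calibration).
#'
#' @param curve a [scattering_curve()].
#' @param concentration sample concentration, mg/mL, positive.
#' @param calibration_constant instrument constant in
#'   (Da * mL/mg) per intensity unit, positive.
#' @return The calibrated [scattering_curve()]; `meta$calibrated = TRUE`
#'   and the constants are recorded.
#' @export
calibrate_intensity <- function(curve, concentration, calibration_constant) {
  stopifnot(is_scattering_curve(curve))
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be positive")
  if (!is.numeric(calibration_constant) || calibration_constant <= 0)
    stop("calibration_constant must be positive")
  f <- calibration_constant / concentration
  out <- scattering_curve(curve$q, curve$intensity * f, curve$sigma * f,
                          meta = curve$meta)
  out$meta$calibrated <- TRUE
  out$meta$concentration <- concentration
  out$meta$calibration_constant <- calibration_constant
  out
}
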