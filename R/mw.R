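#' Molecular-weight estimates from a scattering curve
#'
#' Three standard estimators:
#' \itemize{
#'   \item `mw_i0`: the calibrated forward scattering read directly as MW
#'     (requires [calibrate_intensity()] metadata; omitted otherwise).
#'   \item `mw_porod`: from the Porod volume
#'     Vp = 2 * pi^2 * I(0) / Q with the invariant
#'     Q = integral(q^2 I(q) dq) taken over (0, q_cutoff], after
#'     subtracting a constant background B fitted as I = K/q^4 + B at high
#'     q; MW[Da] = Vp[A^3] / porod_ratio (default 1.6).
#'   \item `mw_vc`: the concentration-independent volume-of-correlation
#'     route: Vc = I(0) / integral(q I(q) dq), QR = Vc^2 / Rg,
#'     MW[Da] = QR / 0.1231 (protein constants).
#' }
#' The low-q parts of both integrals below the first measured point are
#' completed analytically with the Guinier form.
#'
#' @param curve a [scattering_curve()] (calibrated or not).
#' @param guinier the [guinier_fit()] result for the same curve.
#' @param concentration mg/mL (recorded; used only via calibration meta).
#' @param q_cutoff_porod upper integration limit for the Porod invariant
#'   (default 0.25 1/Angstrom).
#' @param q_cutoff_vc upper integration limit for the volume-of-correlation
#'   integral (default 0.3 1/Angstrom, the cited method's protein
#'   convention).
#' @param reference_monomer_mw optional reference monomer MW in kDa; when
#'   given, `oligomer_n` (MW / reference) is reported per estimator.
#' @param porod_ratio Vp-to-Da divisor (default 1.6).
#' @return A list of class `mw_estimates` with elements `mw_i0`,
#'   `mw_porod`, `mw_vc` (kDa; `mw_i0` may be `NA`), `oligomer_n`,
#'   `porod_volume`, `vc`, and the constants used.
#' @export
estimate_mw <- function(curve, guinier, concentration = NULL,
                        q_cutoff_porod = 0.25, reference_monomer_mw = NULL,
                        porod_ratio = 1.6, q_cutoff_vc = 0.3) {
  stopifnot(is_scattering_curve(curve), inherits(guinier, "guinier_result"))
  q <- curve$q; I <- curve$intensity
  i0 <- guinier$i0; rg <- guinier$rg

  # constant-background correction: fit I = K/q^4 + B over the top of the
  # available range (requires decay; warn when the Porod term is negative)
  hi <- q >= stats::quantile(q, 0.75)
  X <- cbind(1 / q[hi]^4, 1)
  cf <- stats::lm.fit(X, I[hi])$coefficients
  B <- cf[2]
  if (cf[1] <= 0) {
    warning("no q^-4 decay detected at high q; skipping background correction")
    B <- 0
  }
  Ic <- I - B

  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

  # Guinier completion of (0, qmin)
  qlo <- seq(0, q[1], length.out = 50)
  glo <- i0 * exp(-qlo^2 * rg^2 / 3)

  keep <- q <= q_cutoff_porod
  if (sum(keep) < 5) stop("q_cutoff_porod leaves too few points")
  Qinv <- trapz(qlo, qlo^2 * glo) + trapz(q[keep], q[keep]^2 * Ic[keep])
  vp <- 2 * pi^2 * i0 / Qinv
  mw_porod <- vp / porod_ratio / 1000  # kDa

  # volume of correlation to the protein-convention cutoff
  kv <- q <= q_cutoff_vc
  qi_int <- trapz(qlo, qlo * glo) + trapz(q[kv], q[kv] * Ic[kv])
  vc <- i0 / qi_int
  qr_inv <- vc^2 / rg
  mw_vc <- qr_inv / 0.1231 / 1000  # kDa

  calibrated <- isTRUE(curve$meta$calibrated)
  mw_i0 <- if (calibrated) i0 / 1000 else NA_real_
  if (!calibrated)
    message("curve not calibrated; mw_i0 omitted")

  out <- list(mw_i0 = mw_i0, mw_porod = mw_porod, mw_vc = mw_vc,
              porod_volume = vp, vc = vc,
              constants = list(porod_ratio = porod_ratio, qr_const = 0.1231,
                               q_cutoff_porod = q_cutoff_porod,
                               q_cutoff_vc = q_cutoff_vc,
                               background = unname(B)),
              concentration = concentration)
  if (!is.null(reference_monomer_mw)) {
    out$oligomer_n <- c(i0 = unname(mw_i0 / reference_monomer_mw),
                        porod = unname(mw_porod / reference_monomer_mw),
                        vc = unname(mw_vc / reference_monomer_mw))
  }
  class(out) <- "mw_estimates"
  out
}

#' @export
print.mw_estimates <- function(x, ...) {
  cat(sprintf("MW estimates: I0 = %s, Porod = %.1f kDa, Vc = %.1f kDa\n",
              if (is.na(x$mw_i0)) "n/a" else sprintf("%.1f kDa", x$mw_i0),
              x$mw_porod, x$mw_vc))
  if (!is.null(x$oligomer_n))
    cat("  oligomer N:", paste(sprintf("%s %.2f", names(x$oligomer_n),
                                       x$oligomer_n), collapse = ", "), "\n")
  invisible(x)
}
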