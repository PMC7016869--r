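#' Normalized spatial discrepancy between two point models
#'
#' The NSD is the standard dissimilarity for bead/coordinate models: the
#' symmetric mean, over both directions, of nearest-neighbour squared
#' cross-distances, each direction normalized by that model's mean
#' nearest-neighbour spacing, then square-rooted.  Values near 0 mean the
#' superposed models coincide; values around 1 mean similar shapes.
#'
#' `superpose_nsd()` minimizes the NSD over rigid transforms of `model`
#' (principal-axis alignment over all proper sign combinations, followed by
#' local Nelder-Mead refinement), and optionally over the mirror image,
#' since scattering is invariant under inversion.
#'
#' @param model,reference [coordinate_model()] objects.
#' @param try_inversion also try the mirror image of `model` (default TRUE).
#' @param refine run local refinement (default TRUE).
#' @return A list of class `superposition_result`: `nsd`, `rotation`,
#'   `translation`, `inverted`, and `model` (the transformed copy).
#' @export
superpose_nsd <- function(model, reference, try_inversion = TRUE,
                          refine = TRUE) {
  stopifnot(is_coordinate_model(model), is_coordinate_model(reference))
  # the NSD itself is symmetric in the two point sets, so the transform
  # search always runs in a canonical order (smaller set moved onto the
  # larger, deterministic tie-break); for the swapped caller order the
  # optimal rigid transform is inverted.  This makes nsd(A, B) and
  # nsd(B, A) identical by construction.
  key <- function(m) c(nrow(m$positions), sum(abs(m$positions)))
  ka <- key(model); kb <- key(reference)
  swap <- ka[1] > kb[1] || (ka[1] == kb[1] && ka[2] > kb[2])
  if (swap) {
    res <- nsd_solve(reference, model, try_inversion, refine)
    Rf <- res$rotation; tr <- res$translation
    Md <- diag(if (res$inverted) c(-1, 1, 1) else c(1, 1, 1))
    aligned <- (sweep(model$positions, 2, tr) %*% Rf) %*% Md
    out_model <- model
    out_model$positions <- aligned
    return(structure(list(nsd = res$nsd,
                          rotation = t(Md %*% t(Rf) %*% Md),
                          translation = -as.numeric((tr %*% Rf) %*% Md),
                          inverted = res$inverted, model = out_model),
                     class = "superposition_result"))
  }
  nsd_solve(model, reference, try_inversion, refine)
}

nsd_solve <- function(model, reference, try_inversion = TRUE,
                      refine = TRUE) {
  A <- reference$positions
  dA <- mean_nn_spacing(A)

  cands <- list()
  for (inverted in if (try_inversion) c(FALSE, TRUE) else FALSE) {
    B0 <- model$positions
    if (inverted) B0[, 1] <- -B0[, 1]
    cB <- colMeans(B0); cA <- colMeans(A)
    Bc <- sweep(B0, 2, cB)
    eA <- principal_axes(sweep(A, 2, cA))
    eB <- principal_axes(Bc)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      s3 <- sign(s1 * s2 * det(eA) * det(eB))  # keep the rotation proper
      R <- eA %*% diag(c(s1, s2, s3)) %*% t(eB)
      if (det(R) < 0) next
      Bt <- sweep(Bc %*% t(R), 2, cA, `+`)
      v <- nsd_value(Bt, A, dB = mean_nn_spacing(Bt), dA = dA)
      cands[[length(cands) + 1]] <- list(nsd = v, R = R, cB = cB, cA = cA,
                                         inverted = inverted, B0 = B0)
    }
  }
  if (length(cands) == 0) stop("superposition failed")
  cands <- cands[order(vapply(cands, `[[`, 1, "nsd"))]

  # refine the top candidates: Nelder-Mead with parameter scaling
  # (radians vs Angstrom) and a restart at the optimum
  n_ref <- if (refine) min(3L, length(cands)) else 0L
  best <- cands[[1]]
  best$par <- rep(0, 6)
  for (k in seq_len(n_ref)) {
    cand <- cands[[k]]
    Bc <- sweep(cand$B0, 2, cand$cB)
    dBc <- mean_nn_spacing(Bc)
    obj <- function(p) {
      Rl <- rotation_about_axis(c(1, 0, 0), p[1]) %*%
        rotation_about_axis(c(0, 1, 0), p[2]) %*%
        rotation_about_axis(c(0, 0, 1), p[3])
      Bt <- sweep(Bc %*% t(Rl %*% cand$R), 2, cand$cA + p[4:6], `+`)
      nsd_value(Bt, A, dB = dBc, dA = dA)
    }
    ctrl <- list(maxit = 400, reltol = 1e-10,
                 parscale = c(rep(0.1, 3), rep(1, 3)))
    opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = ctrl)
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = ctrl)
    if (opt$value < best$nsd) {
      best <- cand
      best$nsd <- opt$value
      best$par <- opt$par
    } else if (is.null(best$par)) best$par <- rep(0, 6)
  }
  p <- best$par %||% rep(0, 6)
  Rl <- rotation_about_axis(c(1, 0, 0), p[1]) %*%
    rotation_about_axis(c(0, 1, 0), p[2]) %*%
    rotation_about_axis(c(0, 0, 1), p[3])
  Rfin <- Rl %*% best$R
  tfin <- best$cA + p[4:6]
  Bt <- sweep(sweep(best$B0, 2, best$cB) %*% t(Rfin), 2, tfin, `+`)
  out_model <- model
  out_model$positions <- Bt
  structure(list(nsd = best$nsd, rotation = Rfin,
                 translation = tfin - as.numeric(Rfin %*% best$cB),
                 inverted = best$inverted, model = out_model),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("NSD = %.4f%s\n", x$nsd,
              if (x$inverted) " (mirror image used)" else ""))
  invisible(x)
}

# NSD of two position matrices as placed (no transform search)
nsd_value <- function(B, A, dB = NULL, dA = NULL) {
  if (is.null(dA)) dA <- mean_nn_spacing(A)
  if (is.null(dB)) dB <- mean_nn_spacing(B)
  d2 <- cross_dist2(A, B)
  minA <- do.call(pmin, as.data.frame(d2))        # per row of A
  minB <- do.call(pmin, as.data.frame(t(d2)))     # per row of B
  sqrt(0.5 * (mean(minA) / dA^2 + mean(minB) / dB^2))
}

# squared cross-distance matrix, rows = A, cols = B
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# mean distance to the nearest other point within a set
mean_nn_spacing <- function(P) {
  n <- nrow(P)
  if (n < 2) return(1)
  d2 <- cross_dist2(P, P)
  diag(d2) <- Inf
  mean(sqrt(do.call(pmin, as.data.frame(d2))))
}

# principal axes (eigenvectors of the covariance), columns ordered by
# decreasing variance; degenerate (collinear) sets fall back to a padded
# basis with a warning
principal_axes <- function(Pc) {
  C <- crossprod(Pc) / nrow(Pc)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] < 1e-12 * max(e$values[1], 1))
    warning("degenerate (collinear) point set; PCA axes ill-defined")
  e$vectors
}
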