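#' Simplified ab initio bead-shape reconstruction
#'
#' A light-weight dummy-bead annealer in the DAMMIF tradition: beads on a
#' cubic lattice (spacing = bead diameter) inside a search sphere of
#' diameter `dmax` are switched on/off by simulated annealing to minimize
#'   energy = fit chi2 (Debye curve of the occupied beads)
#'          + connectivity penalty (number of extra components)
#'          + looseness penalty (fraction of occupied beads with fewer
#'            than 3 occupied neighbours).
#' With `symmetry = "P2"` beads are flipped in two-fold pairs about the z
#' axis, so the output is exactly symmetric.  This is a shape-level
#' reconstruction: acceptance is via Rg, NSD and axis ratios, not
#' bead-level identity with the reference tools.
#'
#' @param curve a [scattering_curve()] (positive sigma recommended).
#' @param dmax search-sphere diameter, Angstrom (from [ift_pr()] or known).
#' @param bead_radius lattice bead radius (default 3 Angstrom).
#' @param symmetry `"P1"` or `"P2"`.
#' @param seed integer seed.
#' @param n_steps annealing steps (default 4000).
#' @param t_start,t_end geometric cooling endpoints.
#' @param connect_weight,loose_weight penalty weights.
#' @return A list of class `bead_model_fit`: `model` (a
#'   [coordinate_model()] of the occupied beads), `fit` ([fit_scale()]
#'   result), `energy`, `n_beads`, `lattice_spacing`, `symmetry`.
#' @export
reconstruct_shape <- function(curve, dmax, bead_radius = 3,
                              symmetry = c("P1", "P2"), seed = 1,
                              n_steps = 4000, t_start = 1.0, t_end = 0.005,
                              connect_weight = 1.0, loose_weight = 2.0) {
  stopifnot(is_scattering_curve(curve))
  symmetry <- match.arg(symmetry)
  if (dmax < 4 * bead_radius)
    stop("resolution error: dmax must be at least 4 * bead_radius")
  set.seed(seed)
  a <- 2 * bead_radius
  m <- ceiling(dmax / 2 / a)
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  P <- as.matrix(g) * a
  inside <- rowSums(P^2) <= (dmax / 2)^2
  P <- P[inside, , drop = FALSE]
  ns <- nrow(P)
  # mirror partner for P2 flips: (x,y,z) -> (-x,-y,z)
  key <- function(M) paste(round(M[, 1] / a), round(M[, 2] / a),
                           round(M[, 3] / a))
  partner <- match(key(cbind(-P[, 1], -P[, 2], P[, 3])), key(P))
  # neighbour lists (18-connectivity: within sqrt(2)*a)
  nb <- build_neighbours(P, 1.45 * a)

  q <- curve$q; Ie <- curve$intensity
  s <- curve$sigma
  if (all(s <= 0)) s <- pmax(abs(Ie) * 0.01, max(abs(Ie)) * 1e-4)
  s[s <= 0] <- min(s[s > 0])
  w <- 1 / s^2

  chi2_of <- function(Ith) {
    X <- cbind(Ith, 1)
    cf <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X, w * Ie)),
                   error = function(e) c(sum(w * Ith * Ie) /
                                           sum(w * Ith^2), 0))
    sum(w * (Ie - X %*% cf)^2) / (length(q) - 2)
  }
  # start: random half-occupancy inside a Guinier-sized core
  rg0 <- tryCatch(guinier_fit(curve)$rg, error = function(e) dmax / 3.5)
  core <- rowSums(P^2) <= (1.4 * rg0)^2
  occ <- core & stats::runif(ns) < 0.6
  if (symmetry == "P2") occ <- occ | occ[partner]
  if (sum(occ) < 10) occ[sample.int(ns, 20)] <- TRUE

  # running intensity
  Ith <- debye_I_occupied(P[occ, , drop = FALSE], q)
  energy <- function(occv, Ithv) {
    comp <- n_components(occv, nb)
    loose <- looseness(occv, nb)
    chi2_of(Ithv) + connect_weight * (comp - 1) + loose_weight * loose
  }
  cur_e <- energy(occ, Ith)
  best <- list(occ = occ, e = cur_e, Ith = Ith)
  temps <- t_start * (t_end / t_start)^((seq_len(n_steps) - 1) /
                                          max(n_steps - 1, 1))
  for (step in seq_len(n_steps)) {
    kflip <- sample.int(ns, 1)
    flips <- kflip
    if (symmetry == "P2" && partner[kflip] != kflip)
      flips <- c(kflip, partner[kflip])
    occ2 <- occ; Ith2 <- Ith
    for (f in flips) {
      occ_idx <- which(occ2)
      others <- setdiff(occ_idx, f)
      if (length(others) == 0 && occ2[f]) next
      if (length(others) > 0) {
        dd <- sqrt(rowSums(sweep(P[others, , drop = FALSE], 2, P[f, ])^2))
        sincs <- vapply(q, function(qq) {
          x <- qq * dd
          sum(ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x)))
        }, 1)
      } else sincs <- numeric(length(q))
      if (occ2[f]) { Ith2 <- Ith2 - 1 - 2 * sincs; occ2[f] <- FALSE }
      else { Ith2 <- Ith2 + 1 + 2 * sincs; occ2[f] <- TRUE }
    }
    if (sum(occ2) < 5) next
    e2 <- energy(occ2, Ith2)
    if (e2 <= cur_e || stats::runif(1) < exp((cur_e - e2) / temps[step])) {
      occ <- occ2; Ith <- Ith2; cur_e <- e2
      if (cur_e < best$e) best <- list(occ = occ, e = cur_e, Ith = Ith)
    }
  }
  occ <- best$occ
  model <- coordinate_model(P[occ, , drop = FALSE])
  th <- scattering_curve(q, best$Ith, rep(0, length(q)))
  ft <- fit_scale(th, scattering_curve(q, Ie, s))
  structure(list(model = model, fit = ft, energy = best$e,
                 n_beads = sum(occ), lattice_spacing = a,
                 symmetry = symmetry, seed = seed),
            class = "bead_model_fit")
}

debye_I_occupied <- function(pos, q) {
  n <- nrow(pos)
  if (n < 2) return(rep(n, length(q)))
  d <- as.numeric(stats::dist(pos))
  vapply(q, function(qq) {
    x <- qq * d
    n + 2 * sum(ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x)))
  }, 1)
}

build_neighbours <- function(P, cutoff) {
  d2 <- cross_dist2(P, P)
  diag(d2) <- Inf
  apply(d2 <= cutoff^2, 1, which, simplify = FALSE)
}

n_components <- function(occ, nb) {
  idx <- which(occ)
  if (length(idx) == 0) return(0L)
  lab <- integer(length(occ))
  comp <- 0L
  for (start in idx) {
    if (lab[start] > 0) next
    comp <- comp + 1L
    queue <- start; lab[start] <- comp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in nb[[v]]) if (occ[u] && lab[u] == 0) {
        lab[u] <- comp; queue <- c(queue, u)
      }
    }
  }
  comp
}

looseness <- function(occ, nb) {
  idx <- which(occ)
  nn <- vapply(idx, function(v) sum(occ[nb[[v]]]), 1L)
  mean(nn < 3)
}

#' Align, average and filter repeated shape reconstructions
#'
#' All models are superposed (inversion-corrected) onto the member with
#' the lowest mean NSD to the others; bead occupancies are accumulated on
#' the reference lattice, cells present in at least half the runs are
#' retained, and the result is trimmed to the median model volume.  The
#' mean pairwise NSD and its spread quantify run-to-run reproducibility.
#'
#' @param models list of [coordinate_model()] bead models (>= 2) from the
#'   same curve settings, or `bead_model_fit` objects.
#' @param lattice_spacing grid spacing for accumulation (default: median
#'   nearest-neighbour spacing of the reference).
#' @param discord_warn warn when the mean pairwise NSD exceeds this
#'   (default 1.5).
#' @return A list of class `averaged_shape`: `model`, `mean_nsd`,
#'   `sd_nsd`, `pairwise_nsd`, `reference_index`.
#' @export
average_shapes <- function(models, lattice_spacing = NULL,
                           discord_warn = 1.5) {
  models <- lapply(models, function(m)
    if (inherits(m, "bead_model_fit")) m$model else m)
  if (length(models) < 2) stop("need at least 2 models to average")
  stopifnot(all(vapply(models, is_coordinate_model, TRUE)))
  n <- length(models)
  nsd_mat <- matrix(0, n, n)
  sup <- vector("list", n * n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- superpose_nsd(models[[i]], models[[j]])
    nsd_mat[i, j] <- nsd_mat[j, i] <- sp$nsd
  }
  mean_to_others <- rowSums(nsd_mat) / (n - 1)
  ref <- which.min(mean_to_others)
  pw <- nsd_mat[upper.tri(nsd_mat)]
  if (mean(pw) > discord_warn)
    warning(sprintf("discordant reconstructions: mean pairwise NSD = %.2f",
                    mean(pw)))
  a <- lattice_spacing
  if (is.null(a)) a <- stats::median(mean_nn_spacing(models[[ref]]$positions))
  # accumulate snapped occupancies
  counts <- new.env(hash = TRUE)
  addcells <- function(pos) {
    cells <- unique(paste(round(pos[, 1] / a), round(pos[, 2] / a),
                          round(pos[, 3] / a)))
    for (cl in cells)
      assign(cl, (if (exists(cl, counts)) get(cl, counts) else 0) + 1,
             counts)
  }
  addcells(models[[ref]]$positions)
  for (i in setdiff(seq_len(n), ref)) {
    sp <- superpose_nsd(models[[i]], models[[ref]])
    addcells(sp$model$positions)
  }
  cells <- ls(counts)
  cnt <- vapply(cells, get, 1, envir = counts)
  keep <- cnt >= n / 2
  coords <- do.call(rbind, lapply(strsplit(cells[keep], " "), as.numeric)) * a
  # trim to the median model volume, keeping the most agreed-on cells
  vol_target <- stats::median(vapply(models, function(m)
    nrow(m$positions), 1))
  if (nrow(coords) > vol_target) {
    o <- order(-cnt[keep])
    coords <- coords[o[seq_len(vol_target)], , drop = FALSE]
  }
  structure(list(model = coordinate_model(coords),
                 mean_nsd = mean(pw), sd_nsd = stats::sd(pw),
                 pairwise_nsd = pw, reference_index = ref,
                 lattice_spacing = a),
            class = "averaged_shape")
}

#' @export
print.averaged_shape <- function(x, ...) {
  cat(sprintf("<averaged_shape> %d beads, mean pairwise NSD = %.2f +/- %.2f\n",
              nrow(x$model$positions), x$mean_nsd, x$sd_nsd))
  invisible(x)
}
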