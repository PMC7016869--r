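#' Genetic-algorithm sub-ensemble selection (EOM-style)
#'
#' Selects a fixed-size multiset of conformers (repeats allowed) from one
#' or more precomputed pools such that the average of their theory curves
#' best fits the experimental curve.  Fitness is the reduced chi-squared
#' from [fit_scale()].  Operators: elite carryover, uniform crossover of
#' member lists, and per-gene mutation swapping a member for a random pool
#' draw.  Elitism makes the best-so-far fitness non-increasing across
#' generations.
#'
#' When `mass_scales` is given (one relative mass per pool, e.g. monomer 1
#' and dimer 2) each member curve is first normalized so its forward
#' scattering is proportional to the pool mass, representing equal mass
#' concentrations under the calibrated-I(0) convention.
#'
#' @param pools list of [build_pool()] results sharing one q grid, with
#'   precomputed curves.
#' @param experiment a [scattering_curve()] with positive sigma.
#' @param ensemble_size members per individual (default 20).
#' @param population GA population size (default 50).
#' @param generations number of generations (default 500).
#' @param elitism_fraction fraction carried over unchanged (default 0.1).
#' @param mutation_rate per-gene mutation probability (default 0.1).
#' @param mass_scales optional per-pool relative masses.
#' @param seed integer seed.
#' @param fit_constant passed to [fit_scale()].
#' @return A list of class `ensemble_fit`: `member_refs` (global member
#'   indices into the concatenated pools), `pool_ids` (pool index per
#'   selected member), `weights` (implied by multiplicity, summing to 1
#'   over unique members), `pool_weights`, `chi2`, `scale`, `constant`,
#'   `generations_run`, `best_trace`, `seed`, `ga_params`.
#' @export
select_ensemble <- function(pools, experiment, ensemble_size = 20,
                            population = 50, generations = 500,
                            elitism_fraction = 0.1, mutation_rate = 0.1,
                            mass_scales = NULL, seed = 1,
                            fit_constant = TRUE) {
  if (inherits(pools, "conformer_pool")) pools <- list(pools)
  if (length(pools) == 0 || any(!vapply(pools, inherits, TRUE,
                                        "conformer_pool")))
    stop("pools must be conformer_pool objects")
  if (generations < 1) stop("generations must be >= 1")
  q0 <- pools[[1]]$q_grid
  for (p in pools) {
    if (is.null(p$curves)) stop("pools must carry precomputed curves")
    if (length(p$q_grid) != length(q0) || max(abs(p$q_grid - q0)) > 1e-9)
      stop("pools must share one q grid")
  }
  set.seed(seed)
  C <- do.call(cbind, lapply(pools, `[[`, "curves"))
  pool_of <- rep(seq_along(pools),
                 vapply(pools, function(p) ncol(p$curves), 1L))
  if (!is.null(mass_scales)) {
    stopifnot(length(mass_scales) == length(pools))
    f <- mass_scales[pool_of] / C[1, ]
    C <- sweep(C, 2, f, `*`)
  }
  # restrict to the experimental overlap once
  keep <- experiment$q >= min(q0) & experiment$q <= max(q0)
  qe <- experiment$q[keep]
  Ie <- experiment$intensity[keep]; se <- experiment$sigma[keep]
  if (any(se <= 0)) stop("experiment sigma must be positive")
  Ci <- apply(C, 2, function(y) stats::approx(q0, y, xout = qe)$y)
  w <- 1 / se^2
  nu <- if (fit_constant) 2L else 1L
  fitness <- function(idx) {
    It <- rowMeans(Ci[, idx, drop = FALSE])
    if (fit_constant) {
      X <- cbind(It, 1)
      cf <- solve(crossprod(X * sqrt(w)), crossprod(X, w * Ie))
      fit <- X %*% cf
    } else {
      cc <- sum(w * It * Ie) / sum(w * It^2)
      fit <- cc * It
    }
    sum(w * (Ie - fit)^2) / (length(qe) - nu)
  }

  n_mem <- ncol(C)
  pop <- matrix(sample.int(n_mem, ensemble_size * population, replace = TRUE),
                ensemble_size, population)
  fit_vals <- apply(pop, 2, fitness)
  n_elite <- max(1L, ceiling(elitism_fraction * population))
  best_trace <- numeric(generations)
  for (g in seq_len(generations)) {
    o <- order(fit_vals)
    pop <- pop[, o, drop = FALSE]; fit_vals <- fit_vals[o]
    best_trace[g] <- fit_vals[1]
    newpop <- matrix(0L, ensemble_size, population)
    newpop[, seq_len(n_elite)] <- pop[, seq_len(n_elite)]
    # rank-weighted parent selection
    pr <- (population:1); pr <- pr / sum(pr)
    for (k in (n_elite + 1):population) {
      par <- sample.int(population, 2, prob = pr)
      mask <- stats::runif(ensemble_size) < 0.5
      child <- ifelse(mask, pop[, par[1]], pop[, par[2]])
      mut <- stats::runif(ensemble_size) < mutation_rate
      if (any(mut))
        child[mut] <- sample.int(n_mem, sum(mut), replace = TRUE)
      newpop[, k] <- child
    }
    pop <- newpop
    fit_vals <- apply(pop, 2, fitness)
  }
  o <- order(fit_vals)
  best <- pop[, o[1]]
  # final fit details for the best individual
  It <- rowMeans(Ci[, best, drop = FALSE])
  th <- scattering_curve(qe, It, rep(0, length(qe)))
  ft <- fit_scale(th, scattering_curve(qe, Ie, se),
                  fit_constant = fit_constant)
  tab <- table(best)
  pw <- tapply(rep(1 / ensemble_size, ensemble_size), pool_of[best], sum)
  pool_weights <- stats::setNames(rep(0, length(pools)),
                                  vapply(pools, `[[`, "", "template_id"))
  pool_weights[as.integer(names(pw))] <- as.numeric(pw)
  structure(list(member_refs = best, pool_ids = pool_of[best],
                 weights = as.numeric(tab) / ensemble_size,
                 unique_members = as.integer(names(tab)),
                 pool_weights = pool_weights,
                 chi2 = min(fit_vals), scale = ft$scale,
                 constant = ft$constant,
                 generations_run = generations, best_trace = best_trace,
                 seed = seed,
                 ga_params = list(ensemble_size = ensemble_size,
                                  population = population,
                                  generations = generations,
                                  elitism_fraction = elitism_fraction,
                                  mutation_rate = mutation_rate,
                                  mass_scales = mass_scales)),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> chi2 = %.3f, %d members (%d unique), seed %d\n",
              x$chi2, length(x$member_refs), length(x$unique_members),
              x$seed))
  cat("  pool weights:",
      paste(sprintf("%s %.0f%%", names(x$pool_weights),
                    100 * x$pool_weights), collapse = ", "), "\n")
  invisible(x)
}

#' Radius-of-gyration distributions of a selected ensemble and its pools
#'
#' Histograms (normalized to unit sum) of the selected members (with
#' multiplicity) and of the full pools, on a common grid spanning the
#' pooled Rg range.
#'
#' @param fit an [select_ensemble()] result.
#' @param pools the pools the fit was run against.
#' @param bin_width histogram bin width, Angstrom (default 0.25).
#' @return A list of class `rg_distribution`: `bin_centers`,
#'   `selected_freq`, `pool_freq`, `bin_width`, `selected_rg`.
#' @export
rg_distribution <- function(fit, pools, bin_width = 0.25) {
  if (inherits(pools, "conformer_pool")) pools <- list(pools)
  stopifnot(inherits(fit, "ensemble_fit"))
  rg_all <- unlist(lapply(pools, `[[`, "rg_values"))
  if (any(fit$member_refs < 1 | fit$member_refs > length(rg_all)))
    stop("fit references members outside the supplied pools")
  rg_sel <- rg_all[fit$member_refs]
  lo <- floor(min(rg_all) / bin_width) * bin_width
  hi <- ceiling(max(rg_all) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  hs <- hist(rg_sel, breaks = breaks, plot = FALSE)
  hp <- hist(rg_all, breaks = breaks, plot = FALSE)
  structure(list(bin_centers = hs$mids,
                 selected_freq = hs$counts / sum(hs$counts),
                 pool_freq = hp$counts / sum(hp$counts),
                 bin_width = bin_width, selected_rg = rg_sel),
            class = "rg_distribution")
}
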