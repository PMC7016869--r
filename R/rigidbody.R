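#' SAXS-restrained rigid-body fit with flexible linkers
#'
#' Simulated-annealing search over the poses of the mobile bodies defined
#' by the flexible segments of `spec`, minimizing
#'   score = reduced chi2 (via [fit_scale()]) + clash penalty +
#'           chain-continuity penalty.
#' Moves: rotate a mobile body (<= `max_rot` degrees about its centroid),
#' translate it (<= `max_trans` Angstrom), or re-sample a flexible
#' segment.  After every body move the affected segment is re-bridged so
#' chain continuity (successive-residue gaps <= `max_gap`) holds by
#' construction; moves whose anchors become unreachable are rejected.  P2
#' specs search the monomer pose against the fixed two-fold axis and score
#' the generated dimer.
#'
#' @param spec an [assembly_spec()] with at least one `"swing"` segment.
#' @param template a [coordinate_model()] starting configuration.
#' @param experiment a [scattering_curve()] with positive sigma.
#' @param n_restarts independent annealing restarts (default 10).
#' @param seed integer seed.
#' @param n_steps annealing steps per restart (default 1500).
#' @param t_start,t_end geometric cooling schedule endpoints.
#' @param max_rot,max_trans move amplitudes (degrees, Angstrom).
#' @param clash_weight,max_gap penalty weight and continuity threshold.
#' @param fit_constant passed to [fit_scale()].
#' @param start_at_template start the first restart from the template
#'   configuration instead of a random one (default FALSE).
#' @return A list of class `rigid_body_fit`: `model` (best
#'   [coordinate_model()], dimerized for P2), `fit` (the [fit_scale()]
#'   result), `score`, `clash_count`, `continuity_penalty`, `restart_scores`.
#' @export
rigid_body_fit <- function(spec, template, experiment, n_restarts = 10,
                           seed = 1, n_steps = 1500, t_start = 2.0,
                           t_end = 0.01, max_rot = 15, max_trans = 5,
                           clash_weight = 0.5, max_gap = 4.2,
                           fit_constant = TRUE, start_at_template = FALSE) {
  stopifnot(inherits(spec, "assembly_spec"), is_coordinate_model(template),
            is_scattering_curve(experiment))
  set.seed(seed)
  n <- nrow(template$positions)
  segs <- spec$flexible_segments
  if (length(segs) == 0) stop("spec has no flexible segments to search")

  mobile_sets <- lapply(segs, function(fs) {
    seg <- span_idx(template, fs$span)
    lo <- min(seg); hi <- max(seg)
    mob <- if (identical(fs$mode, "bridge")) integer(0)
           else if (identical(fs$mobile, "downstream")) which(seq_len(n) > hi)
           else which(seq_len(n) < lo)
    list(seg = seg, lo = lo, hi = hi, mob = mob, fs = fs)
  })

  score_model <- function(pos) {
    m <- template; m$positions <- pos
    if (spec$symmetry == "P2")
      m <- apply_p2(m, spec$axis_point, spec$axis_dir,
                    clash_distance = spec$min_separation)
    th <- debye_curve(m, experiment$q, method = "auto")
    ft <- fit_scale(th, experiment, fit_constant = fit_constant)
    cl <- count_clashes(pos, spec$min_separation)
    if (spec$symmetry == "P2") cl <- cl + attr(m, "clash_count")
    cont <- continuity_penalty(pos, mobile_sets, max_gap)
    list(score = ft$chi2 + clash_weight * cl + 10 * cont, fit = ft,
         clash = cl, cont = cont, model = m)
  }

  rebridge <- function(pos, ms) {
    # re-sample the segment as a bridge between its (possibly moved) anchors
    fixed <- setdiff(seq_len(n), c(ms$seg, ms$mob))
    anc1 <- if (identical(ms$fs$mobile, "downstream")) pos[ms$lo - 1, ]
            else pos[ms$hi + 1, ]
    att <- if (identical(ms$fs$mobile, "downstream")) min(ms$mob)
           else max(ms$mob)
    anc2 <- pos[att, ]
    walk <- tryCatch(
      sample_linker(anc1, anc2, n_residues = length(ms$seg) + 1,
                    bond_length = spec$bond_length,
                    min_separation = spec$min_separation,
                    context = pos[c(fixed, setdiff(ms$mob, att)),
                                  , drop = FALSE],
                    max_retries = 30),
      error = function(e) NULL)
    if (is.null(walk)) return(NULL)
    w <- walk[seq_along(ms$seg), , drop = FALSE]
    if (identical(ms$fs$mobile, "downstream")) pos[ms$seg, ] <- w
    else pos[ms$seg, ] <- w[rev(seq_along(ms$seg)), , drop = FALSE]
    pos
  }

  propose <- function(pos) {
    ms <- mobile_sets[[sample.int(length(mobile_sets), 1)]]
    kind <- sample(c("rot", "trans", "resample"), 1)
    if (kind == "resample" || length(ms$mob) == 0) {
      ok <- tryCatch({
        tmp <- template; tmp$positions <- pos
        sample_conformer(tmp, spec, max_retries = 20)
      }, error = function(e) NULL)
      return(ok)
    }
    blk <- pos[ms$mob, , drop = FALSE]
    ctr <- colMeans(blk)
    if (kind == "rot") {
      R <- rotation_about_axis(random_unit_vector(),
                               stats::runif(1, -max_rot, max_rot) * pi / 180)
      blk <- sweep(sweep(blk, 2, ctr) %*% t(R), 2, ctr, `+`)
    } else {
      blk <- sweep(blk, 2, stats::runif(3, -max_trans, max_trans), `+`)
    }
    pos2 <- pos
    pos2[ms$mob, ] <- blk
    rebridge(pos2, ms)
  }

  best_overall <- NULL
  restart_scores <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    pos <- if (start_at_template && r == 1) template$positions
    else tryCatch(sample_conformer(template, spec, max_retries = 100),
                  error = function(e) NULL)
    if (is.null(pos))
      stop("initialization error: no clash-free starting configuration")
    cur <- score_model(pos)
    best <- list(pos = pos, sc = cur)
    temps <- t_start * (t_end / t_start)^((seq_len(n_steps) - 1) /
                                            max(n_steps - 1, 1))
    for (step in seq_len(n_steps)) {
      pos2 <- propose(pos)
      if (is.null(pos2)) next
      sc2 <- score_model(pos2)
      if (sc2$score <= cur$score ||
          stats::runif(1) < exp((cur$score - sc2$score) / temps[step])) {
        pos <- pos2; cur <- sc2
        if (cur$score < best$sc$score) best <- list(pos = pos, sc = cur)
      }
    }
    restart_scores[r] <- best$sc$score
    if (is.null(best_overall) || best$sc$score < best_overall$sc$score)
      best_overall <- best
  }
  sc <- best_overall$sc
  structure(list(model = sc$model, fit = sc$fit, score = sc$score,
                 clash_count = sc$clash, continuity_penalty = sc$cont,
                 restart_scores = restart_scores, seed = seed),
            class = "rigid_body_fit")
}

# number of non-bonded bead pairs closer than min_sep
count_clashes <- function(pos, min_sep) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  n <- nrow(pos)
  # successive beads are bonded: exempt
  idx <- cbind(seq_len(n - 1), 2:n)
  d[idx] <- Inf; d[idx[, 2:1]] <- Inf
  sum(d < min_sep) / 2
}

# number of junction bonds (flexible-segment boundaries and internal
# linker steps) exceeding max_gap; domain interiors are rigid bodies and
# carry no chain-continuity requirement at this resolution
continuity_penalty <- function(pos, mobile_sets, max_gap) {
  gaps <- 0L
  n <- nrow(pos)
  for (ms in mobile_sets) {
    idx <- ms$seg
    if (ms$lo > 1) idx <- c(ms$lo - 1L, idx)
    if (ms$hi < n) idx <- c(idx, ms$hi + 1L)
    d <- sqrt(rowSums((pos[idx[-1], , drop = FALSE] -
                         pos[idx[-length(idx)], , drop = FALSE])^2))
    gaps <- gaps + sum(d > max_gap)
  }
  gaps
}
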