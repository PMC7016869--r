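#' Assembly specification for flexible multi-domain models
#'
#' Describes how a template divides into rigid bodies and flexible
#' segments.  Each flexible segment is a residue span (inclusive, 1-based)
#' with a mode:
#' \itemize{
#'   \item `"swing"`: the segment is re-sampled as a tethered walk from the
#'     fixed side and the `mobile` block (`"upstream"` = all residues
#'     before the segment, `"downstream"` = all residues after it) is
#'     rigidly repositioned at the walk's end with a random orientation.
#'   \item `"bridge"`: both flanking bodies stay fixed and the segment is
#'     re-sampled as a closed self-avoiding bridge between them.
#' }
#'
#' @param domains named list of inclusive residue spans `c(start, end)`
#'   (e.g. `list(NTD = c(1, 79), DEP = c(95, 200), ...)`), used for
#'   bookkeeping and reports.
#' @param flexible_segments list of `list(span = c(start, end),
#'   mode = "swing"|"bridge", mobile = "upstream"|"downstream")`.
#' @param symmetry `"P1"` (default) or `"P2"`; P2 assemblies duplicate the
#'   generated monomer about `axis_point`/`axis_dir`.
#' @param axis_point,axis_dir the two-fold axis for P2 assemblies.
#' @param min_separation excluded-volume distance, Angstrom.
#' @param bond_length C-alpha virtual bond, Angstrom.
#' @return An object of class `assembly_spec`.
#' @export
assembly_spec <- function(domains = list(), flexible_segments = list(),
                          symmetry = c("P1", "P2"),
                          axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                          min_separation = 3.0, bond_length = 3.8) {
  symmetry <- match.arg(symmetry)
  for (fs in flexible_segments) {
    if (is.null(fs$span) || length(fs$span) != 2)
      stop("each flexible segment needs a length-2 span")
    if (is.null(fs$mode) || !fs$mode %in% c("swing", "bridge"))
      stop("flexible segment mode must be 'swing' or 'bridge'")
  }
  structure(list(domains = domains, flexible_segments = flexible_segments,
                 symmetry = symmetry, axis_point = axis_point,
                 axis_dir = axis_dir / sqrt(sum(axis_dir^2)),
                 min_separation = min_separation, bond_length = bond_length),
            class = "assembly_spec")
}

# indices of a residue span within a (single-chain) model
span_idx <- function(model, span) {
  which(model$residue_numbers >= span[1] & model$residue_numbers <= span[2])
}

# generate one conformer (positions matrix) from template + spec
sample_conformer <- function(template, spec, max_retries = 50) {
  pos <- template$positions
  n <- nrow(pos)
  b <- spec$bond_length; msep <- spec$min_separation
  for (fs in spec$flexible_segments) {
    seg <- span_idx(template, fs$span)
    if (length(seg) == 0) stop("flexible span ", fs$span[1], "-", fs$span[2],
                               " not found in template")
    lo <- min(seg); hi <- max(seg)
    mobile <- if (identical(fs$mode, "swing")) {
      if (identical(fs$mobile, "downstream")) seq_len(n) > hi
      else seq_len(n) < lo
    } else rep(FALSE, n)
    fixed_idx <- which(!mobile & !(seq_len(n) %in% seg))
    ctx <- pos[fixed_idx, , drop = FALSE]
    if (identical(fs$mode, "bridge")) {
      if (lo == 1 || hi == n) stop("bridge segment must be interior")
      # the closing walk targets bead hi+1, so that bead is not part of
      # the avoidance context
      ctx <- pos[setdiff(fixed_idx, hi + 1), , drop = FALSE]
      walk <- sample_linker(pos[lo - 1, ], pos[hi + 1, ],
                            n_residues = length(seg) + 1,
                            bond_length = b, min_separation = msep,
                            context = ctx, max_retries = max_retries)
      pos[seg, ] <- walk[seq_along(seg), , drop = FALSE]
    } else if (!any(mobile)) {
      # free tail: the segment re-samples as a tether with no body beyond
      anchor <- if (lo > 1) pos[lo - 1, ] else pos[hi + 1, ]
      walk <- sample_linker(anchor, NULL, n_residues = length(seg),
                            bond_length = b, min_separation = msep,
                            context = ctx, max_retries = max_retries)
      pos[seg, ] <- if (lo > 1) walk
                    else walk[rev(seq_along(seg)), , drop = FALSE]
    } else {
      # tether walk from the fixed-side anchor
      anchor <- if (identical(fs$mobile, "downstream")) pos[lo - 1, ]
                else pos[hi + 1, ]
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        walk <- sample_linker(anchor, NULL, n_residues = length(seg),
                              bond_length = b, min_separation = msep,
                              context = ctx, max_retries = max_retries)
        # reattach the mobile block at the walk end with random orientation
        mob <- which(mobile)
        att <- if (identical(fs$mobile, "downstream")) min(mob) else max(mob)
        Rr <- random_rotation()
        new_att <- walk[nrow(walk), ] + b * random_unit_vector()
        block <- sweep(pos[mob, , drop = FALSE], 2, pos[att, ])
        block <- sweep(block %*% t(Rr), 2, new_att, `+`)
        # clash check: block vs fixed context and vs the walk; the
        # attachment bead is bonded to the walk end, so that one contact
        # is exempt
        att_row <- match(att, mob)
        d2c <- if (nrow(ctx) == 0) Inf
               else do.call(pmin, as.data.frame(cross_dist2(block, ctx)))
        d2w <- cross_dist2(block, walk)
        d2w[att_row, nrow(walk)] <- Inf
        d2w <- do.call(pmin, as.data.frame(d2w))
        ok <- all(d2c >= msep^2) && all(d2w >= msep^2)
        if (ok) {
          if (identical(fs$mobile, "downstream")) {
            pos[seg, ] <- walk
            pos[mob, ] <- block
          } else {
            # walk was sampled from the downstream anchor: segment runs
            # hi..lo when walked upstream
            pos[seg, ] <- walk[rev(seq_along(seg)), , drop = FALSE]
            pos[mob, ] <- block
          }
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("sampling error: could not place mobile block")
    }
  }
  pos
}

#' Generate a conformer pool from a template
#'
#' Each member re-samples every flexible segment of `spec` (and
#' repositions the mobile bodies accordingly); members are clash-free at
#' the spec's `min_separation`.  P2 specs dimerize every member about the
#' spec's two-fold axis.  Per-member radii of gyration are always
#' computed; theory curves on `q_grid` are precomputed unless
#' `compute_curves = FALSE`.
#'
#' @param template a [coordinate_model()] (single chain).
#' @param spec an [assembly_spec()].
#' @param n_members pool size (classic EOM runs use 10000; scale down for
#'   quick studies).
#' @param seed integer seed for reproducibility.
#' @param q_grid q grid for precomputed member curves (default
#'   `seq(0.01, 0.3, length.out = 101)`).
#' @param compute_curves precompute member Debye curves (default TRUE).
#' @param bead_sigma Gaussian bead form-factor width passed to
#'   [debye_curve()] (default 0).
#' @param template_id label stored with the pool.
#' @return An object of class `conformer_pool`: `members` (list of
#'   position matrices), `rg_values`, `curves` (nq x n matrix or NULL),
#'   `q_grid`, `template`, `spec`, `seed`, `template_id`.
#' @export
build_pool <- function(template, spec, n_members = 10000, seed = 1,
                       q_grid = seq(0.01, 0.3, length.out = 101),
                       compute_curves = TRUE, bead_sigma = 0,
                       template_id = "pool") {
  stopifnot(is_coordinate_model(template), inherits(spec, "assembly_spec"))
  set.seed(seed)
  members <- vector("list", n_members)
  rg <- numeric(n_members)
  curves <- if (compute_curves)
    matrix(NA_real_, length(q_grid), n_members) else NULL
  n_mono <- nrow(template$positions)
  unit_w <- all(template$weights == 1)

  # only the flexible segments and their mobile blocks move between
  # members, so the rigid-part pair histogram is computed once and the
  # per-member cost is just the moving-internal and moving-vs-fixed pairs
  moving_mono <- sort(unique(unlist(lapply(spec$flexible_segments,
    function(fs) {
      seg <- span_idx(template, fs$span)
      if (identical(fs$mode, "swing")) {
        if (identical(fs$mobile, "downstream"))
          c(seg, which(seq_len(n_mono) > max(seg)))
        else c(seg, which(seq_len(n_mono) < min(seg)))
      } else seg
    }))))
  moving <- if (spec$symmetry == "P2")
    c(moving_mono, moving_mono + n_mono) else moving_mono
  n_tot <- if (spec$symmetry == "P2") 2L * n_mono else n_mono
  fixed <- setdiff(seq_len(n_tot), moving)
  use_fast <- compute_curves && unit_w && length(moving) > 0 &&
    length(fixed) > 1
  env <- if (bead_sigma > 0) exp(-(q_grid * bead_sigma)^2) else
    rep(1, length(q_grid))
  bw <- 0.5
  fix_stats <- NULL

  failures <- 0L
  for (i in seq_len(n_members)) {
    pos <- tryCatch(sample_conformer(template, spec),
                    error = function(e) NULL)
    if (is.null(pos)) {
      failures <- failures + 1L
      if (failures > max(20, n_members %/% 10))
        stop("partial-pool error: only ", i - 1, " of ", n_members,
             " members generated")
      pos <- sample_conformer(template, spec, max_retries = 200)
    }
    m <- template; m$positions <- pos
    if (spec$symmetry == "P2")
      m <- apply_p2(m, spec$axis_point, spec$axis_dir)
    members[[i]] <- m$positions
    if (use_fast) {
      if (is.null(fix_stats))
        fix_stats <- bin_pair_stats(
          as.numeric(stats::dist(m$positions[fixed, , drop = FALSE])), bw)
      dmv <- as.numeric(stats::dist(m$positions[moving, , drop = FALSE]))
      dcr <- sqrt(cross_dist2(m$positions[moving, , drop = FALSE],
                              m$positions[fixed, , drop = FALSE]))
      st <- merge_pair_stats(fix_stats, bin_pair_stats(dmv, bw),
                             bin_pair_stats(as.numeric(dcr), bw))
      curves[, i] <- env * debye_from_stats(q_grid, st, n_tot)
      # Rg^2 = sum over unordered pairs of d^2 / N^2 for unit weights
      rg[i] <- sqrt(sum(st$sumd2) / n_tot^2)
    } else {
      rg[i] <- radius_of_gyration(m)
      if (compute_curves)
        curves[, i] <- debye_curve(m, q_grid, method = "auto",
                                   bead_sigma = bead_sigma)$intensity
    }
  }
  structure(list(members = members, rg_values = rg, curves = curves,
                 q_grid = q_grid, template = template, spec = spec,
                 seed = seed, bead_sigma = bead_sigma,
                 template_id = template_id),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("<conformer_pool> '%s': %d members, Rg %.1f..%.1f A (seed %d)\n",
              x$template_id, length(x$members), min(x$rg_values),
              max(x$rg_values), x$seed))
  invisible(x)
}

#' Extract one pool member as a coordinate model
#'
#' @param pool a [build_pool()] result.
#' @param i member index.
#' @return A [coordinate_model()].
#' @export
pool_member <- function(pool, i) {
  stopifnot(inherits(pool, "conformer_pool"))
  tmpl <- pool$template
  pos <- pool$members[[i]]
  if (nrow(pos) == nrow(tmpl$positions)) {
    tmpl$positions <- pos
    tmpl
  } else {
    # P2 pools store dimer coordinates
    m <- tmpl; m$positions <- pos[seq_len(nrow(tmpl$positions)), , drop = FALSE]
    apply_p2(m, pool$spec$axis_point, pool$spec$axis_dir)
  }
}
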