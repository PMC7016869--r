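#' Generate a compact random globule of beads
#'
#' Grows a self-avoiding cluster at a target density: each bead is placed
#' one growth step from a random existing bead, rejecting placements
#' closer than `min_separation` to any bead or outside a spherical
#' envelope.  Both the step and the exclusion distance default to the
#' value that makes random sequential growth settle at
#' `volume_per_residue`, whose default (170 A^3 per residue, about 1.55
#' A^3/Da) matches the effective Porod volume protein SAXS reports rather
#' than the dry crystallographic density, so the Porod molecular-weight
#' chain is consistent on these toys.
#'
#' @param n_residues number of beads.
#' @param bond_length growth step, Angstrom (default: derived from the
#'   density).
#' @param min_separation excluded volume, Angstrom (default: derived).
#' @param volume_per_residue cubic Angstrom per residue (default 170).
#' @return n x 3 matrix centered on the origin.
#' @export
make_globule <- function(n_residues, bond_length = NULL,
                         min_separation = NULL, volume_per_residue = 170) {
  stopifnot(n_residues >= 1)
  if (n_residues == 1) return(matrix(0, 1, 3))
  # random sequential growth settles at ~0.55 * s^3 volume per bead for
  # exclusion distance s, so s is derived from the target density (the
  # field-typical effective Porod volume of ~1.55 A^3/Da at 110
  # Da/residue); the growth step equals s
  s <- (0.553 * volume_per_residue)^(1 / 3)
  if (is.null(min_separation)) min_separation <- s
  if (is.null(bond_length)) bond_length <- s
  rmax <- (3 * n_residues * volume_per_residue / (4 * pi))^(1 / 3) + s
  pos <- matrix(0, n_residues, 3)
  placed <- 1L
  guard <- 0L
  while (placed < n_residues) {
    guard <- guard + 1L
    if (guard > 400 * n_residues) {
      rmax <- rmax * 1.05  # relax the envelope rather than fail
      guard <- 0L
    }
    base <- pos[sample.int(placed, 1), ]
    p <- base + bond_length * random_unit_vector()
    if (sum(p^2) > rmax^2) next   # envelope centered on the seed bead
    d2 <- rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2, p)^2)
    if (min(d2) >= min_separation^2) {
      placed <- placed + 1L
      pos[placed, ] <- p
    }
  }
  sweep(pos, 2, colMeans(pos))
}

#' Build a toy multi-domain protein with flexible linkers
#'
#' Each domain is a compact random globule of the requested residue
#' count; consecutive domains are connected by sampled self-avoiding
#' linkers and packed into mutual contact (placements minimize the
#' assembly radius of gyration).  `"extended"` additionally opens the
#' designated hinge: the block downstream of the hinge linker is rotated
#' about the hinge pivot to a clash-free pose whose Rg exceeds the closed
#' conformer by `extend_delta_rg`, then the hinge linker is re-bridged —
#' emulating a compact-to-extended conformational change of a multidomain
#' regulator.
#'
#' @param domain_sizes integer vector of residues per domain (>= 2
#'   domains).
#' @param linker_lengths residues per inter-domain linker (recycled to
#'   `length(domain_sizes) - 1`).
#' @param packing `"closed"` or `"extended"`.
#' @param seed integer seed.
#' @param hinge_after_domain the linker index acting as the hinge for
#'   `"extended"` packing (default 1).
#' @param extend_delta_rg target Rg increase (Angstrom) of the extended
#'   conformer over the closed one (default 5.5, the scale of a
#'   hinge-opening intermediate); realized by rotating the post-hinge
#'   block about the hinge and re-bridging the hinge linker.
#' @param domain_names optional names (default D1, D2, ...; six domains
#'   get the EPAC-style names NTD, DEP, CNBD, REM, RA, GEF).
#' @return A list: `model` (a [coordinate_model()] with `domain_labels`),
#'   `domain_map` (named spans plus `flexible_segments` = linker spans).
#' @export
make_toy_multidomain <- function(domain_sizes, linker_lengths = 15,
                                 packing = c("closed", "extended"),
                                 seed = 1, hinge_after_domain = 1,
                                 extend_delta_rg = 5.5,
                                 domain_names = NULL) {
  packing <- match.arg(packing)
  nd <- length(domain_sizes)
  if (nd < 1) stop("need at least 1 domain")
  if (nd == 1) {
    set.seed(seed)
    g <- make_globule(domain_sizes)
    model <- coordinate_model(g, domain_labels = rep("D1", nrow(g)))
    return(list(model = model,
                domain_map = list(domains = list(D1 = c(1L, nrow(g))),
                                  flexible_segments = list(),
                                  packing = packing, seed = seed)))
  }
  linker_lengths <- rep(linker_lengths, length.out = nd - 1)
  if (is.null(domain_names)) {
    domain_names <- if (nd == 6) c("NTD", "DEP", "CNBD", "REM", "RA", "GEF")
                    else paste0("D", seq_len(nd))
  }
  set.seed(seed)
  b <- 3.8
  doms <- lapply(domain_sizes, make_globule)
  # reorder each globule so the chain enters and exits at surface beads on
  # roughly opposite sides (linkers must start from exposed positions)
  doms <- lapply(doms, function(d) {
    if (nrow(d) < 3) return(d)
    i_exit <- which.max(rowSums(d^2))
    u <- d[i_exit, ] / sqrt(sum(d[i_exit, ]^2))
    proj <- as.numeric(d %*% u)
    i_entry <- which.min(proj)
    mid <- setdiff(seq_len(nrow(d)), c(i_entry, i_exit))
    d[c(i_entry, mid, i_exit), , drop = FALSE]
  })

  # sequential build: domain 1 at the origin; each next domain is tethered
  # to the previous one by a sampled linker, its placement chosen from
  # candidate orientations to keep the assembly compact ("closed") or,
  # at the hinge linker, to swing the remaining block away ("extended")
  pos_list <- list(doms[[1]])
  labels <- rep(domain_names[1], domain_sizes[1])
  spans <- stats::setNames(list(c(1L, domain_sizes[1])), domain_names[1])
  flex <- list()
  next_res <- domain_sizes[1] + 1L
  assembled <- doms[[1]]
  for (k in 2:nd) {
    len <- linker_lengths[k - 1]
    a1 <- pos_list[[length(pos_list)]][nrow(pos_list[[length(pos_list)]]), ]
    placed <- NULL
    best_score <- Inf
    for (att in 1:250) {
      walk <- tryCatch(
        sample_linker(a1, NULL, n_residues = len, bond_length = b,
                      min_separation = 3.0, context = assembled,
                      max_retries = 30),
        error = function(e) NULL)
      if (is.null(walk)) next
      Rr <- random_rotation()
      dk <- doms[[k]] %*% t(Rr)
      # attach the domain's first bead one bond past the walk end
      u <- random_unit_vector()
      shift <- walk[nrow(walk), ] + b * u - dk[1, ]
      dk <- sweep(dk, 2, shift, `+`)
      # clash: domain beads vs assembly and walk (first bead exempt from
      # the walk-end contact)
      d2a <- min(cross_dist2(dk, assembled))
      d2w <- cross_dist2(dk, walk); d2w[1, nrow(walk)] <- Inf
      if (d2a < 3.0^2 || min(d2w) < 3.0^2) next
      # keep the anchors close enough that the linker stays re-bridgeable
      # (segment re-sampling is used by the conformer and hinge machinery)
      if (sum((a1 - dk[1, ])^2) > ((len - 1) * b - 0.5)^2) next
      # pack: minimize the radius of gyration of the grown assembly
      allp <- rbind(assembled, dk)
      ctr <- colMeans(allp)
      score <- sqrt(sum(sweep(allp, 2, ctr)^2) / nrow(allp))
      if (score < best_score) {
        best_score <- score
        placed <- list(walk = walk, dom = dk)
      }
    }
    if (is.null(placed))
      stop("infeasible packing: could not attach domain ", k)
    flex[[length(flex) + 1]] <- c(next_res, next_res + len - 1L)
    labels <- c(labels, rep(paste0("linker", k - 1), len),
                rep(domain_names[k], domain_sizes[k]))
    next_res <- next_res + len
    spans[[domain_names[k]]] <- c(next_res, next_res + domain_sizes[k] - 1L)
    next_res <- next_res + domain_sizes[k]
    pos_list[[length(pos_list) + 1]] <- placed$walk
    pos_list[[length(pos_list) + 1]] <- placed$dom
    assembled <- rbind(assembled, placed$walk, placed$dom)
  }
  pos <- do.call(rbind, pos_list)
  if (packing == "extended")
    pos <- open_hinge(pos, flex[[hinge_after_domain]], extend_delta_rg)
  model <- coordinate_model(pos, residue_numbers = seq_len(nrow(pos)),
                            domain_labels = labels)
  list(model = model,
       domain_map = list(domains = spans, flexible_segments = flex,
                         packing = packing, seed = seed))
}

# rotate the block downstream of the hinge linker about the hinge pivot,
# searching axes and angles for a clash-free pose whose Rg is closest to
# Rg(closed) + delta_rg, then re-bridge the hinge linker
open_hinge <- function(pos, hinge_span, delta_rg, min_sep = 3.0,
                       bond_length = 3.8) {
  n <- nrow(pos)
  segi <- hinge_span[1]:hinge_span[2]
  blk <- (hinge_span[2] + 1L):n
  fixed <- setdiff(seq_len(n), c(segi, blk))
  pivot <- pos[hinge_span[1] - 1L, ]
  rg_of <- function(p) {
    ctr <- colMeans(p); sqrt(sum(sweep(p, 2, ctr)^2) / nrow(p))
  }
  target <- rg_of(pos) + delta_rg
  best <- NULL
  for (att in 1:25) {
    ax <- random_unit_vector()
    for (th in seq(15, 180, by = 15) * pi / 180) {
      R <- rotation_about_axis(ax, th)
      nb <- sweep(sweep(pos[blk, , drop = FALSE], 2, pivot) %*% t(R),
                  2, pivot, `+`)
      if (min(cross_dist2(nb, pos[fixed, , drop = FALSE])) < min_sep^2)
        next
      p2 <- pos; p2[blk, ] <- nb
      sc <- abs(rg_of(p2[-segi, , drop = FALSE]) - target)
      if (is.null(best) || sc < best$sc) best <- list(pos = p2, sc = sc)
    }
  }
  if (is.null(best))
    stop("infeasible packing: no clash-free hinge rotation found")
  pos <- best$pos
  # re-bridge the hinge linker onto the rotated block
  a1 <- pos[hinge_span[1] - 1L, ]
  a2 <- pos[hinge_span[2] + 1L, ]
  ctx <- pos[setdiff(seq_len(n), c(segi, hinge_span[2] + 1L)), ,
             drop = FALSE]
  need <- (length(segi) + 1) * bond_length
  if (sqrt(sum((a1 - a2)^2)) >= need - 2 * bond_length)
    stop("hinge anchors unreachable after rotation")
  walk <- sample_linker(a1, a2, n_residues = length(segi) + 1,
                        bond_length = bond_length,
                        min_separation = min_sep, context = ctx,
                        max_retries = 400)
  pos[segi, ] <- walk[seq_along(segi), , drop = FALSE]
  pos
}

#' Ground truth for a simulated SAXS experiment
#'
#' @param components list of [coordinate_model()] mixture components.
#' @param fractions mass fractions summing to 1.
#' @param transmission buffer transmission factor planted in the sample.
#' @param scenario,params,seed provenance.
#' @param mass_da per-component molecular masses in Da (default 110 Da per
#'   bead).
#' @param bead_sigma Gaussian bead form-factor width used when simulating
#'   curves from the components (default 3 Angstrom, giving realistic
#'   high-q decay; see [debye_curve()]).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(components, fractions, transmission = 1.0,
                         scenario = "custom", params = list(), seed = NA,
                         mass_da = NULL, bead_sigma = 3) {
  stopifnot(length(components) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (is.null(mass_da))
    mass_da <- vapply(components, function(m) 110 * nrow(m$positions), 1)
  structure(list(components = components, fractions = fractions,
                 transmission = transmission, scenario = scenario,
                 params = params, seed = seed, mass_da = mass_da,
                 bead_sigma = bead_sigma),
            class = "ground_truth")
}

#' Simulate a sample/buffer SAXS curve pair from ground truth
#'
#' The ideal signal is the equal-mass-convention mixture of the component
#' Debye curves, each normalized so I(0) equals the component mass in Da
#' (the calibrated-I(0) convention).  The buffer is a smooth decaying
#' profile `b0 * exp(-q/qb) + b1`, scaled so signal/buffer is about 0.1
#' at q = 0.2 1/Angstrom (typical for dilute protein on a lab camera).
#' The recorded sample is signal + t * buffer with the ground-truth
#' transmission t, and independent Gaussian noise with
#' sigma(q) = noise_floor * sqrt(I_total(q) * exposure) / exposure
#' (counting statistics) is applied to the sample and buffer separately.
#'
#' @param truth a [ground_truth()].
#' @param q_grid q grid (default `seq(0.01, 0.3, length.out = 120)`).
#' @param noise_floor noise amplitude (default 1; counting units).
#' @param exposure_factor relative exposure (default 1; longer exposures
#'   reduce sigma as 1/sqrt).
#' @param buffer_profile list with `b0`, `qb`, `b1` shape parameters
#'   (amplitude is rescaled to the signal/buffer target) and
#'   `ratio_at_q2` (default 0.1).
#' @param seed integer seed.
#' @return list(sample =, buffer =) of [scattering_curve()] objects; the
#'   sample meta records the true transmission and scenario label.
#' @export
simulate_experiment <- function(truth, q_grid = seq(0.012, 0.6,
                                                    length.out = 240),
                                noise_floor = 1, exposure_factor = 1,
                                buffer_profile = list(b0 = 1, qb = 0.2,
                                                      b1 = 0.3,
                                                      ratio_at_q2 = 0.1),
                                seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (noise_floor < 0 || exposure_factor <= 0)
    stop("noise parameters must be positive")
  set.seed(seed)
  comp_curves <- lapply(truth$components, function(m)
    debye_curve(m, q_grid, method = "auto",
                bead_sigma = truth$bead_sigma %||% 0))
  signal <- mixture_curve(comp_curves, truth$fractions,
                          mass_scale = truth$mass_da)$intensity
  bp <- utils::modifyList(list(b0 = 1, qb = 0.2, b1 = 0.3,
                               ratio_at_q2 = 0.1), buffer_profile)
  shape <- bp$b0 * exp(-q_grid / bp$qb) + bp$b1
  s_at <- stats::approx(q_grid, signal, xout = 0.2, rule = 2)$y
  sh_at <- bp$b0 * exp(-0.2 / bp$qb) + bp$b1
  buffer_true <- shape * (s_at / bp$ratio_at_q2) / sh_at
  t <- truth$transmission
  sample_true <- signal + t * buffer_true
  sig_s <- noise_floor * sqrt(pmax(sample_true, 0) * exposure_factor) /
    exposure_factor
  sig_b <- noise_floor * sqrt(pmax(buffer_true, 0) * exposure_factor) /
    exposure_factor
  sig_s <- pmax(sig_s, 1e-12); sig_b <- pmax(sig_b, 1e-12)
  samp <- scattering_curve(
    q_grid, sample_true + stats::rnorm(length(q_grid), 0, sig_s), sig_s,
    meta = list(label = paste0(truth$scenario, " sample"),
                true_transmission = t, scenario = truth$scenario,
                seed = seed, calibrated = TRUE))
  buf <- scattering_curve(
    q_grid, buffer_true + stats::rnorm(length(q_grid), 0, sig_b), sig_b,
    meta = list(label = paste0(truth$scenario, " buffer"), seed = seed))
  list(sample = samp, buffer = buf, signal_true = signal)
}

# build a compact side-by-side P2 dimer: the two-fold axis runs parallel
# to z through a point offset from the monomer centroid along its
# thinnest principal direction, at the smallest clash-free separation
make_contact_dimer <- function(mono, clash_distance = 3.4) {
  ctr <- colMeans(mono$positions)
  pc <- eigen(stats::cov(mono$positions), symmetric = TRUE)$vectors[, 3]
  pc[3] <- 0                      # axis must be parallel to z
  nv <- sqrt(sum(pc^2))
  if (nv < 1e-6) pc <- c(1, 0, 0) else pc <- pc / nv
  for (r_off in seq(5, 100, by = 2.5)) {
    dimer <- apply_p2(mono, axis_point = ctr + r_off * pc,
                      axis_dir = c(0, 0, 1),
                      clash_distance = clash_distance)
    if (attr(dimer, "clash_count") == 0) return(dimer)
  }
  stop("could not place a clash-free two-fold axis")
}

#' Parameterized study scenarios with known ground truth
#'
#' \describe{
#'   \item{apo_two_state}{a compact (closed) and a hinge-extended
#'     conformer of the same multi-domain toy protein mixed at fraction
#'     `f` (compact) vs `1 - f`; emulates a closed/extended equilibrium.}
#'   \item{dimer_equilibrium}{a two-fold symmetric dimer of the extended
#'     conformer in equilibrium with `m` (mass fraction) of compact
#'     monomer.}
#'   \item{ternary}{a single rigid complex: the extended conformer bound
#'     to a partner globule (`partner_residues`, default 167).}
#' }
#'
#' @param name scenario name.
#' @param params list; `f` (default 0.85), `m` (default 0.10),
#'   `domain_sizes` (default `c(79, 110, 130, 130, 130, 300)`),
#'   `linker_lengths` (default `c(15, 4, 4, 4, 4)`), `transmission`
#'   (default 0.97), `partner_residues` (default 167).
#' @param seed integer seed.
#' @return A [ground_truth()].
#' @export
make_scenario <- function(name = c("apo_two_state", "dimer_equilibrium",
                                   "ternary"),
                          params = list(), seed = 1) {
  name <- match.arg(name)
  p <- utils::modifyList(
    list(f = 0.85, m = 0.10,
         domain_sizes = c(79, 110, 130, 130, 130, 300),
         linker_lengths = c(15, 4, 5, 4, 4),
         hinge_after_domain = 3,  # the hinge sits between CNBD and REM
         transmission = 0.97, partner_residues = 167), params)
  closed <- make_toy_multidomain(p$domain_sizes, p$linker_lengths,
                                 packing = "closed", seed = seed,
                                 hinge_after_domain = p$hinge_after_domain)
  extended <- make_toy_multidomain(p$domain_sizes, p$linker_lengths,
                                   packing = "extended", seed = seed,
                                   hinge_after_domain = p$hinge_after_domain)
  if (name == "apo_two_state") {
    ground_truth(list(closed = closed$model, extended = extended$model),
                 c(p$f, 1 - p$f), transmission = p$transmission,
                 scenario = name, params = p, seed = seed)
  } else if (name == "dimer_equilibrium") {
    mono <- extended$model
    dimer <- make_contact_dimer(mono)
    ground_truth(list(monomer = closed$model, dimer = dimer),
                 c(p$m, 1 - p$m), transmission = p$transmission,
                 scenario = name, params = p, seed = seed)
  } else {
    set.seed(seed + 1)
    partner <- make_globule(p$partner_residues)
    host <- extended$model
    # dock the partner in surface contact with the catalytic end
    ctr <- colMeans(host$positions)
    far <- host$positions[which.max(rowSums(sweep(host$positions, 2,
                                                  ctr)^2)), ]
    u <- (far - ctr) / sqrt(sum((far - ctr)^2))
    rp <- max(sqrt(rowSums(partner^2)))
    ppos <- sweep(partner, 2, far + (rp + 4) * u, `+`)
    complex <- coordinate_model(
      rbind(host$positions, ppos),
      chain_ids = c(host$chain_ids, rep("P", nrow(ppos))),
      residue_numbers = c(host$residue_numbers, seq_len(nrow(ppos))))
    ground_truth(list(ternary = complex), 1.0,
                 transmission = p$transmission, scenario = name,
                 params = p, seed = seed)
  }
}
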