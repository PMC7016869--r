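# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

# analytic sphere intensity: radius R, forward scattering i0
sphere_intensity <- function(q, R, i0 = 1e5) {
  x <- q * R
  i0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# closed-form sphere pair-distance distribution (unnormalized r^2 * gamma)
sphere_pr <- function(r, R) {
  u <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * u + 0.5 * u^3)
  p[r > 2 * R] <- 0
  p
}

fx_sphere_curve <- function(R = 30, qmax = 0.3, n = 180, rel_sigma = 1e-3) {
  q <- seq(0.005, qmax, length.out = n)
  I <- sphere_intensity(q, R)
  scattering_curve(q, I, pmax(I * rel_sigma, 1e-9))
}

# EPAC-like two-state scenario (the generator's default study conditions)
fx_scenario <- function() fx_cache("scenario", function() {
  make_scenario("apo_two_state", seed = 7)
})

# NTD-tether assembly spec for a multidomain toy model
ntd_tether_spec <- function(m, symmetry = "P1") {
  lk <- which(m$domain_labels == "linker1")
  sp <- assembly_spec(flexible_segments = list(list(
    span = c(min(m$residue_numbers[lk]), max(m$residue_numbers[lk])),
    mode = "swing", mobile = "upstream")))
  sp$symmetry <- symmetry
  sp
}

# small two-domain toy with known configuration, used by rigid-body tests
fx_toy2dom <- function() fx_cache("toy2dom", function() {
  toy <- make_toy_multidomain(c(60, 80), linker_lengths = 10,
                              packing = "closed", seed = 21)
  fs <- toy$domain_map$flexible_segments[[1]]
  spec <- assembly_spec(flexible_segments = list(list(
    span = fs, mode = "swing", mobile = "upstream")))
  list(model = toy$model, spec = spec,
       idx1 = which(toy$model$domain_labels == "D1"),
       idx2 = which(toy$model$domain_labels == "D2"))
})

# small module-test pools on the default scenario templates
fx_pools_small <- function() fx_cache("pools_small", function() {
  tr <- fx_scenario()
  q <- seq(0.012, 0.3, length.out = 110)
  ext <- tr$components$extended
  dimer_tmpl <- saxsens:::make_contact_dimer(ext)
  dspec <- ntd_tether_spec(ext, symmetry = "P2")
  dspec$axis_point <- attr(dimer_tmpl, "axis_point")
  dspec$axis_dir <- attr(dimer_tmpl, "axis_dir")
  list(
    q = q, truth = tr,
    closed = build_pool(tr$components$closed,
                        ntd_tether_spec(tr$components$closed),
                        n_members = 250, seed = 11, q_grid = q,
                        bead_sigma = 3, template_id = "closed"),
    extended = build_pool(ext, ntd_tether_spec(ext),
                          n_members = 250, seed = 12, q_grid = q,
                          bead_sigma = 3, template_id = "extended"),
    dimer = build_pool(ext, dspec, n_members = 80, seed = 13, q_grid = q,
                       bead_sigma = 3, template_id = "dimer"))
})

# plant a two-state mixture from pool members and simulate counting noise
plant_two_state <- function(pools, n_closed, n_extended, seed,
                            snr0 = 300) {
  set.seed(seed)
  ic <- sample(length(pools$closed$members), n_closed, replace = TRUE)
  ie <- sample(length(pools$extended$members), n_extended, replace = TRUE)
  sig <- rowMeans(cbind(pools$closed$curves[, ic, drop = FALSE],
                        pools$extended$curves[, ie, drop = FALSE]))
  sgm <- sqrt(pmax(sig, 0)) * sqrt(sig[1]) / snr0
  list(curve = scattering_curve(pools$q, sig + stats::rnorm(length(sig),
                                                            0, sgm), sgm),
       planted_rg_closed = pools$closed$rg_values[ic],
       planted_rg_extended = pools$extended$rg_values[ie])
}

# histogram container for direct decompose_peaks tests
mk_rg_dist <- function(x, freq) {
  structure(list(bin_centers = x, selected_freq = freq / sum(freq),
                 pool_freq = freq / sum(freq), bin_width = x[2] - x[1]),
            class = "rg_distribution")
}
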