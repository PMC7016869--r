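test_that("sample_linker tether mode places beads at the bond length", {
  set.seed(1)
  w <- sample_linker(c(0, 0, 0), NULL, n_residues = 1)
  expect_equal(sqrt(sum(w[1, ]^2)), 3.8, tolerance = 1e-9)

  w15 <- sample_linker(c(0, 0, 0), NULL, n_residues = 15)
  steps <- sqrt(rowSums(diff(rbind(c(0, 0, 0), w15))^2))
  expect_equal(steps, rep(3.8, 15), tolerance = 1e-9)
  # self-avoidance beyond bonded neighbours
  d <- as.matrix(dist(w15)); diag(d) <- Inf
  d[cbind(1:14, 2:15)] <- Inf; d[cbind(2:15, 1:14)] <- Inf
  expect_gte(min(d), 3.0)
})

test_that("bridging closes onto the far anchor in every seed", {
  closures <- vapply(1:100, function(s) {
    set.seed(s)
    w <- sample_linker(c(0, 0, 0), c(10, 0, 0), n_residues = 15)
    sqrt(sum((w[15, ] - c(10, 0, 0))^2))
  }, 1)
  expect_true(all(closures < 0.5))
  expect_error(sample_linker(c(0, 0, 0), c(60, 0, 0), n_residues = 15),
               "unreachable")
})

test_that("tethered walks scale like an excluded-volume chain", {
  set.seed(9)
  e2 <- replicate(1000, {
    w <- sample_linker(c(0, 0, 0), NULL, n_residues = 15)
    sum(w[15, ]^2)
  })
  ratio <- mean(e2) / (15 * 3.8^2)
  # excluded volume inflates the freely-jointed-chain value; the Flory
  # swelling n^(1/5) bounds it from above for a fully self-avoiding walk
  expect_gt(ratio, 1.0)
  expect_lt(ratio, 15^(1 / 5))
})

test_that("build_pool honours the spec: rigid, tethered and hinge pools", {
  tr <- fx_scenario()
  m <- tr$components$closed
  q <- seq(0.012, 0.3, length.out = 60)

  rigid <- build_pool(m, assembly_spec(), n_members = 5, seed = 1,
                      q_grid = q)
  expect_equal(length(unique(round(rigid$rg_values, 9))), 1L)
  expect_equal(rigid$members[[3]], m$positions)

  pools <- fx_pools_small()
  rgc <- pools$closed$rg_values
  expect_gt(sd(rgc), 0)
  expect_lt(sd(rgc), 6)
  # unimodal near the template Rg
  expect_lt(abs(median(rgc) - radius_of_gyration(m)), 6)

  # hinge-opened template extends the accessible Rg range upward
  expect_gt(max(pools$extended$rg_values),
            radius_of_gyration(m) + 5)
})

test_that("pools are reproducible and clash-free", {
  tr <- fx_scenario()
  m <- tr$components$closed
  spec <- ntd_tether_spec(m)
  q <- seq(0.012, 0.3, length.out = 40)
  p1 <- build_pool(m, spec, n_members = 12, seed = 99, q_grid = q)
  p2 <- build_pool(m, spec, n_members = 12, seed = 99, q_grid = q)
  expect_identical(p1$rg_values, p2$rg_values)
  expect_identical(p1$members[[7]], p2$members[[7]])

  # moving beads keep the exclusion distance from the fixed part
  lk <- which(m$domain_labels == "linker1")
  moving <- c(which(m$domain_labels == "NTD"), lk)
  fixed <- setdiff(seq_len(nrow(m$positions)), moving)
  for (i in c(1, 6, 12)) {
    pos <- p1$members[[i]]
    d2 <- saxsens:::cross_dist2(pos[setdiff(moving, max(lk)), ,
                                    drop = FALSE],
                                pos[fixed, , drop = FALSE])
    expect_gte(sqrt(min(d2)), 3.0 - 1e-9)
  }
})

test_that("rigid-body fit recovers a two-domain arrangement from its
           scattering", {
  toy <- fx_toy2dom()
  m <- toy$model
  q <- seq(0.012, 0.3, length.out = 70)
  th <- debye_curve(m, q)
  set.seed(5)
  sgm <- sqrt(pmax(th$intensity, 0)) * sqrt(th$intensity[1]) / 300
  dat <- scattering_curve(q, th$intensity + rnorm(length(q), 0, sgm), sgm)

  rb <- rigid_body_fit(toy$spec, m, dat, n_restarts = 3, n_steps = 400,
                       seed = 3)
  dtrue <- sqrt(sum((colMeans(m$positions[toy$idx1, ]) -
                       colMeans(m$positions[toy$idx2, ]))^2))
  dfit <- sqrt(sum((colMeans(rb$model$positions[toy$idx1, ]) -
                      colMeans(rb$model$positions[toy$idx2, ]))^2))
  expect_lt(abs(dfit - dtrue), 2)
  expect_lte(rb$fit$chi2, 1.2)
  expect_equal(rb$continuity_penalty, 0)
})

test_that("rigid-body fit is a fixed point at the truth on noise-free
           data", {
  toy <- fx_toy2dom()
  m <- toy$model
  q <- seq(0.012, 0.3, length.out = 70)
  th <- debye_curve(m, q)
  dat <- scattering_curve(q, th$intensity,
                          pmax(th$intensity * 1e-4, 1e-12))
  rb <- rigid_body_fit(toy$spec, m, dat, n_restarts = 1, n_steps = 50,
                       seed = 4, start_at_template = TRUE)
  expect_lt(rb$fit$chi2, 1e-6)
})

test_that("P2 rigid-body fit recovers the monomer offset and returns an
           exactly symmetric dimer", {
  # monomer = anchor globule near the axis + a tethered body whose pose
  # (and hence the dimer separation) is the search target
  set.seed(31)
  anchor_dom <- make_globule(50)
  toy <- make_toy_multidomain(c(50, 90), linker_lengths = 8,
                              packing = "closed", seed = 31)
  tmpl <- transform_model(toy$model, t = c(16, 0, 0))
  fs <- toy$domain_map$flexible_segments[[1]]
  spec <- assembly_spec(
    flexible_segments = list(list(span = fs, mode = "swing",
                                  mobile = "downstream")),
    symmetry = "P2")
  truth_dimer <- apply_p2(tmpl, c(0, 0, 0), c(0, 0, 1))
  q <- seq(0.012, 0.25, length.out = 60)
  th <- debye_curve(truth_dimer, q)
  set.seed(32)
  sgm <- sqrt(pmax(th$intensity, 0)) * sqrt(th$intensity[1]) / 300
  dat <- scattering_curve(q, th$intensity + rnorm(length(q), 0, sgm), sgm)

  rb <- rigid_body_fit(spec, tmpl, dat, n_restarts = 2, n_steps = 250,
                       seed = 33, start_at_template = TRUE)
  n <- nrow(tmpl$positions)
  fit_pos <- rb$model$positions
  # exact two-fold: rotating by 180 degrees permutes the chains
  rot <- saxsens:::transform_positions(
    fit_pos, saxsens:::rotation_about_axis(c(0, 0, 1), pi))
  expect_lt(max(abs(rot[1:n, ] - fit_pos[n + 1:n, ])), 1e-9)
  # monomer-centroid separation recovered within 2 A
  sep_true <- 2 * sqrt(sum(colMeans(truth_dimer$positions[1:n, ])[1:2]^2))
  sep_fit <- 2 * sqrt(sum(colMeans(fit_pos[1:n, ])[1:2]^2))
  expect_lt(abs(sep_fit - sep_true), 2)
})
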