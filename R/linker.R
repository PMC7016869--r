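#' Sample a self-avoiding C-alpha linker chain
#'
#' Generates a random chain of `n_residues` beads with fixed successive
#' bead distance `bond_length`, starting `bond_length` away from
#' `anchor_start`.  Every bead must stay at least `min_separation` from
#' the beads of `context` and from non-adjacent beads of the chain itself.
#' In bridging mode (`anchor_end` given) the walk is direction-biased
#' toward the target and then closed by cyclic-coordinate-descent (CCD)
#' pivot rotations until the final bead lies within `closure_tol` of
#' `anchor_end`; bond lengths are preserved exactly by the pivots.
#'
#' @param anchor_start length-3 start anchor (the bead preceding the
#'   segment), Angstrom.
#' @param anchor_end optional length-3 end anchor for bridging mode.
#' @param n_residues number of beads to place.
#' @param bond_length successive bead distance (default 3.8 Angstrom, the
#'   C-alpha virtual bond).
#' @param min_separation excluded-volume distance (default 3.0 Angstrom).
#' @param context optional [coordinate_model()] or N x 3 matrix of beads
#'   to avoid.
#' @param closure_tol bridging closure tolerance (default 0.5 Angstrom).
#' @param max_retries chain-level retry cap (default 200).
#' @return n_residues x 3 matrix of bead coordinates.
#' @export
sample_linker <- function(anchor_start, anchor_end = NULL, n_residues,
                          bond_length = 3.8, min_separation = 3.0,
                          context = NULL, closure_tol = 0.5,
                          max_retries = 200) {
  anchor_start <- as.numeric(anchor_start)
  stopifnot(length(anchor_start) == 3, n_residues >= 1)
  ctx <- if (is.null(context)) NULL
         else if (is_coordinate_model(context)) context$positions
         else as.matrix(context)
  if (!is.null(ctx) && nrow(ctx) == 0) ctx <- NULL
  bridging <- !is.null(anchor_end)
  if (bridging) {
    anchor_end <- as.numeric(anchor_end)
    D <- sqrt(sum((anchor_end - anchor_start)^2))
    if (D >= n_residues * bond_length - 2 * bond_length)
      stop("geometry error: anchors ", round(D, 1),
           " A apart unreachable with ", n_residues, " residues")
  }
  clash <- function(p, chain_prev) {
    if (!is.null(ctx) &&
        min(rowSums(sweep(ctx, 2, p)^2)) < min_separation^2) return(TRUE)
    if (!is.null(chain_prev) && nrow(chain_prev) > 1) {
      # exclude the immediately preceding bead (bonded neighbour)
      prior <- chain_prev[-nrow(chain_prev), , drop = FALSE]
      if (min(rowSums(sweep(prior, 2, p)^2)) < min_separation^2) return(TRUE)
    }
    FALSE
  }
  for (try in seq_len(max_retries)) {
    chain <- matrix(NA_real_, n_residues, 3)
    prev <- anchor_start
    ok <- TRUE
    for (k in seq_len(n_residues)) {
      placed <- FALSE
      for (att in 1:50) {
        u <- random_unit_vector()
        if (bridging) {
          remaining <- n_residues - k + 1  # links left incl. this one
          v <- anchor_end - prev
          dv <- sqrt(sum(v^2))
          lam <- if (dv < 1e-9) 0
                 else min(1, (dv / (remaining * bond_length))^2)
          u <- (1 - lam) * u + lam * v / max(dv, 1e-9)
          u <- u / sqrt(sum(u^2))
        }
        p <- prev + bond_length * u
        if (!clash(p, chain[seq_len(k - 1), , drop = FALSE])) {
          chain[k, ] <- p; prev <- p; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    if (bridging) {
      chain2 <- ccd_close(chain, anchor_start, anchor_end, closure_tol)
      if (is.null(chain2)) next
      # closure moves may introduce clashes: verify
      bad <- FALSE
      for (k in seq_len(n_residues)) {
        if (clash(chain2[k, ], chain2[seq_len(k - 1), , drop = FALSE])) {
          bad <- TRUE; break
        }
      }
      if (bad) next
      chain <- chain2
    }
    return(chain)
  }
  stop("sampling error: could not place a clash-free ", n_residues,
       "-residue linker in ", max_retries, " attempts")
}

# cyclic coordinate descent: rotate chain tails about internal pivots so
# the final bead converges onto the target; returns NULL on failure
ccd_close <- function(chain, anchor_start, target, tol, max_sweeps = 60) {
  n <- nrow(chain)
  nodes <- rbind(anchor_start, chain)  # node 1 is fixed
  for (sweep_i in seq_len(max_sweeps)) {
    err <- sqrt(sum((nodes[n + 1, ] - target)^2))
    if (err <= tol) return(nodes[-1, , drop = FALSE])
    for (j in seq_len(n)) {           # pivot at node j (can't move node 1)
      piv <- nodes[j, ]
      a <- nodes[n + 1, ] - piv
      b <- target - piv
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na < 1e-9 || nb < 1e-9) next
      axis <- c(a[2] * b[3] - a[3] * b[2],
                a[3] * b[1] - a[1] * b[3],
                a[1] * b[2] - a[2] * b[1])
      nx <- sqrt(sum(axis^2))
      if (nx < 1e-12) next
      ang <- acos(max(-1, min(1, sum(a * b) / (na * nb))))
      R <- rotation_about_axis(axis / nx, ang)
      idx <- (j + 1):(n + 1)
      nodes[idx, ] <- sweep(sweep(nodes[idx, , drop = FALSE], 2, piv) %*%
                              t(R), 2, piv, `+`)
    }
  }
  err <- sqrt(sum((nodes[n + 1, ] - target)^2))
  if (err <= tol) nodes[-1, , drop = FALSE] else NULL
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-9) return(v / nv)
  }
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
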