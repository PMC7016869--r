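#' Coarse-grained coordinate model
#'
#' A residue-level (C-alpha bead) point model: positions with per-point
#' scattering weights, chain ids, residue numbers and optional domain
#' labels.  All scattering operators in the package consume this type.
#'
#' @param positions N x 3 numeric matrix, Angstrom.
#' @param weights per-point scattering weight (default 1 per bead).
#' @param chain_ids character vector (default "A").
#' @param residue_numbers integer vector, 1-based, unique within a chain.
#' @param domain_labels optional character vector of domain names.
#' @return An object of class `coordinate_model`.
#' @export
coordinate_model <- function(positions, weights = NULL, chain_ids = NULL,
                             residue_numbers = NULL, domain_labels = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 1)
    stop("positions must be an N x 3 matrix with N >= 1")
  if (any(!is.finite(positions))) stop("positions must be finite")
  n <- nrow(positions)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(chain_ids)) chain_ids <- rep("A", n)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  if (length(weights) != n || length(chain_ids) != n ||
      length(residue_numbers) != n)
    stop("weights, chain_ids and residue_numbers must match positions")
  if (anyDuplicated(paste(chain_ids, residue_numbers)))
    stop("residue numbers must be unique within a chain")
  if (!is.null(domain_labels) && length(domain_labels) != n)
    stop("domain_labels must match positions")
  structure(list(positions = unname(positions), weights = as.numeric(weights),
                 chain_ids = as.character(chain_ids),
                 residue_numbers = as.integer(residue_numbers),
                 domain_labels = domain_labels),
            class = "coordinate_model")
}

#' @export
print.coordinate_model <- function(x, ...) {
  cat(sprintf("<coordinate_model> %d beads, %d chain(s), Rg = %.2f A\n",
              nrow(x$positions), length(unique(x$chain_ids)),
              radius_of_gyration(x)))
  invisible(x)
}

is_coordinate_model <- function(x) inherits(x, "coordinate_model")

#' Read a coarse-grained model from a PDB file
#'
#' Extracts C-alpha atoms by default (alternate locations resolved to the
#' highest occupancy); `coarse_grain = "all"` keeps every atom as a bead.
#' Weights are set to 1 per bead.
#'
#' @param path PDB file path.
#' @param coarse_grain `"CA"` (default) or `"all"`.
#' @return A [coordinate_model()].
#' @export
read_model <- function(path, coarse_grain = c("CA", "all")) {
  coarse_grain <- match.arg(coarse_grain)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (coarse_grain == "CA") at <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) stop("extraction error: no C-alpha atoms in ", path)
  # resolve altloc to highest occupancy
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key),
                          function(i) i[which.max(occ[i])]))
    at <- at[sort(keep), , drop = FALSE]
  }
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  coordinate_model(cbind(at$x, at$y, at$z),
                   chain_ids = chain,
                   residue_numbers = at$resno)
}

#' Write a coarse-grained model as a PDB file
#'
#' Beads are written as C-alpha records (pseudo-atoms for bead models),
#' one residue per bead, coordinates at PDB precision (3 decimals).
#'
#' @param model a [coordinate_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(is_coordinate_model(model))
  n <- nrow(model$positions)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000, substr(model$chain_ids, 1, 1),
    model$residue_numbers %% 10000,
    model$positions[, 1], model$positions[, 2], model$positions[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Radius of gyration of a coordinate model
#'
#' Weight-weighted root-mean-square distance of the beads from their
#' weighted centroid.
#'
#' @param model a [coordinate_model()].
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(model) {
  stopifnot(is_coordinate_model(model))
  w <- model$weights
  W <- sum(w)
  if (W <= 0) stop("zero total weight")
  ctr <- colSums(model$positions * w) / W
  d2 <- rowSums(sweep(model$positions, 2, ctr)^2)
  sqrt(sum(w * d2) / W)
}

# ---- rigid-transform helpers -------------------------------------------

# rotation matrix about unit axis u by angle theta (Rodrigues)
rotation_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

transform_positions <- function(pos, R = diag(3), t = c(0, 0, 0)) {
  sweep(pos %*% t(R), 2, t, `+`)
}

#' Apply a rigid transform to a model
#'
#' @param model a [coordinate_model()].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector, Angstrom.
#' @return The transformed [coordinate_model()].
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is_coordinate_model(model))
  model$positions <- transform_positions(model$positions, R, t)
  model
}

#' Build a two-fold (P2) symmetric dimer from a monomer
#'
#' The dimer is the union of the monomer and its copy rotated 180 degrees
#' about the given axis.  Chains of the copy get a "2" suffix.  Inter-copy
#' bead pairs closer than `clash_distance` are counted and reported in the
#' `clash_count` attribute (clashes are not fatal).
#'
#' @param monomer a [coordinate_model()].
#' @param axis_point a point on the two-fold axis (length 3, Angstrom).
#' @param axis_dir direction of the axis (length 3, normalized internally).
#' @param clash_distance clash threshold, Angstrom (default 3.0).
#' @return A [coordinate_model()] dimer with attribute `clash_count`.
#' @export
apply_p2 <- function(monomer, axis_point = c(0, 0, 0),
                     axis_dir = c(0, 0, 1), clash_distance = 3.0) {
  stopifnot(is_coordinate_model(monomer))
  R <- rotation_about_axis(axis_dir, pi)
  pos2 <- transform_positions(
    sweep(monomer$positions, 2, axis_point), R, axis_point)
  # nearest original bead for each rotated bead
  d2 <- cross_dist2(pos2, monomer$positions)
  dmin <- sqrt(do.call(pmin, as.data.frame(d2)))
  clash_count <- sum(dmin < clash_distance)
  dimer <- coordinate_model(
    rbind(monomer$positions, pos2),
    weights = rep(monomer$weights, 2),
    chain_ids = c(monomer$chain_ids, paste0(monomer$chain_ids, "2")),
    residue_numbers = c(monomer$residue_numbers,
                        monomer$residue_numbers + max(monomer$residue_numbers)),
    domain_labels = if (is.null(monomer$domain_labels)) NULL
                    else rep(monomer$domain_labels, 2))
  attr(dimer, "clash_count") <- clash_count
  attr(dimer, "axis_point") <- axis_point
  attr(dimer, "axis_dir") <- axis_dir / sqrt(sum(axis_dir^2))
  dimer
}
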