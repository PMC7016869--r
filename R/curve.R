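#' One-dimensional scattering curve
#'
#' Container for a reduced 1D SAXS profile: intensity I(q) with 1-sigma
#' uncertainties on a strictly increasing momentum-transfer grid
#' (q = 4*pi*sin(theta)/lambda, in 1/Angstrom).  Intensities are in
#' arbitrary units until [calibrate_intensity()] rescales them so that the
#' extrapolated I(0) reads as molecular weight in Da.
#'
#' @param q numeric vector of momentum transfer values (1/Angstrom),
#'   strictly increasing and positive.
#' @param intensity numeric vector of intensities, same length as `q`.
#' @param sigma numeric vector of 1-sigma uncertainties, positive, same
#'   length as `q`.  For theoretical curves a vector of zeros is allowed.
#' @param meta named list of metadata (e.g. `concentration` in mg/mL,
#'   `exposure_h`, `label`, header comments).
#' @return An object of class `scattering_curve`: a list with elements
#'   `q`, `intensity`, `sigma`, `meta`.
#' @export
scattering_curve <- function(q, intensity, sigma = rep(0, length(q)),
                             meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  if (length(q) != length(intensity) || length(q) != length(sigma))
    stop("q, intensity and sigma must have equal length")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q values must be finite and positive")
  if (is.unsorted(q, strictly = TRUE))
    stop("q must be strictly increasing")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 meta = as.list(meta)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q = %.4g..%.4g 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  if (!is.null(x$meta$label)) cat("  label:", x$meta$label, "\n")
  if (!is.null(x$meta$concentration))
    cat("  concentration:", x$meta$concentration, "mg/mL\n")
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

is_scattering_curve <- function(x) inherits(x, "scattering_curve")

#' Read a 3-column SAXS curve from text
#'
#' Parses the de-facto exchange format used by SASBDB deposits: whitespace
#' separated columns q, I, sigma, with `#` comment lines.  Rows with
#' non-positive q or sigma are dropped (and counted in
#' `meta$n_dropped`); header comment lines are preserved in `meta$header`.
#'
#' @param path path to the file.
#' @param format currently only `"dat3col"`.
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path, format = "dat3col") {
  format <- match.arg(format, "dat3col")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- grepl("^\\s*#", lines)
  header <- sub("^\\s*#\\s?", "", lines[is_comment])
  data_lines <- lines[!is_comment]
  if (length(data_lines) < 5)
    stop("insufficient data: fewer than 5 non-comment rows in ", path)
  fields <- strsplit(trimws(data_lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) < 3)
  if (length(bad))
    stop(sprintf("format error in %s: line %d does not have 3 numeric columns",
                 path, bad[1]))
  m <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(fields, `[`, 1:3)))), ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("format error in %s: non-numeric value on data line %d",
                 path, bad))
  }
  keep <- m[, 1] > 0 & m[, 3] > 0
  n_dropped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 5)
    stop("insufficient data: fewer than 5 valid rows in ", path)
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  scattering_curve(m[, 1], m[, 2], m[, 3],
                   meta = list(header = header, n_dropped = n_dropped,
                               source = path))
}

#' Write a scattering curve as 3-column text
#'
#' Writes q, I, sigma columns preceded by `#` comment lines recording the
#' metadata, re-readable by [read_curve()].
#'
#' @param curve a [scattering_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(is_scattering_curve(curve))
  hdr <- c("# q(1/A) I sigma")
  for (nm in names(curve$meta)) {
    val <- curve$meta[[nm]]
    if (is.atomic(val) && length(val) > 0 && nm != "header")
      hdr <- c(hdr, sprintf("# %s: %s", nm,
                            paste(format(val, digits = 10), collapse = " ")))
  }
  body <- sprintf("%.8g %.8g %.8g", curve$q, curve$intensity, curve$sigma)
  ok <- tryCatch({
    writeLines(c(hdr, body), path); TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

#' Interpolate a curve onto a new q grid
#'
#' Linear interpolation in q, restricted to the overlap of the two grids
#' (no extrapolation).  Sigma is interpolated the same way.
#'
#' @param curve a [scattering_curve()].
#' @param q target q grid; values outside the curve's range are dropped.
#' @return A [scattering_curve()] on the (possibly trimmed) target grid.
#' @export
interpolate_curve <- function(curve, q) {
  stopifnot(is_scattering_curve(curve))
  q <- q[q >= min(curve$q) & q <= max(curve$q)]
  if (length(q) < 2) stop("no overlap between curve range and target grid")
  i <- stats::approx(curve$q, curve$intensity, xout = q)$y
  s <- stats::approx(curve$q, curve$sigma, xout = q)$y
  scattering_curve(q, i, s, meta = curve$meta)
}

# restrict a curve to [qmin, qmax]
trim_curve <- function(curve, qmin = -Inf, qmax = Inf) {
  keep <- curve$q >= qmin & curve$q <= qmax
  if (sum(keep) < 2) stop("q window outside data range")
  scattering_curve(curve$q[keep], curve$intensity[keep], curve$sigma[keep],
                   meta = curve$meta)
}
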