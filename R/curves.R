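# ScatteringCurve and PairDistanceDistribution containers.

#' Construct a scattering curve
#'
#' A SANS curve is a set of `(Q, I, sigma)` triplets with strictly
#' increasing, positive momentum transfer `Q` (in inverse Angstrom).
#' Intensities are in cm^-1 on absolute scale, or arbitrary units when
#' `absolute = FALSE`.
#'
#' @param Q momentum transfer grid, A^-1, strictly increasing, > 0.
#' @param I intensities, same length as `Q`.
#' @param sigma optional 1-sigma uncertainties, same length, all > 0.
#' @param meta free-text provenance.
#' @param absolute logical; `TRUE` when `I` is on absolute (cm^-1) scale.
#' @return an object of class `sans_curve`.
#' @export
scattering_curve <- function(Q, I, sigma = NULL, meta = "", absolute = FALSE) {
  Q <- as.numeric(Q); I <- as.numeric(I)
  if (length(Q) == 0L || length(Q) != length(I)) {
    stop("Q and I must be non-empty and of equal length")
  }
  if (any(!is.finite(Q)) || any(Q <= 0)) stop("Q must be finite and > 0")
  if (any(diff(Q) <= 0)) stop("Q must be strictly increasing")
  if (any(!is.finite(I))) stop("I must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(I)) stop("sigma must match I in length")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  }
  structure(
    list(Q = Q, I = I, sigma = sigma,
         meta = as.character(meta), absolute = isTRUE(absolute)),
    class = "sans_curve"
  )
}

#' @export
print.sans_curve <- function(x, ...) {
  cat(sprintf(
    "SANS curve: %d points, Q in [%.4g, %.4g] A^-1, %s%s\n",
    length(x$Q), min(x$Q), max(x$Q),
    if (is.null(x$sigma)) "no uncertainties" else "with uncertainties",
    if (x$absolute) ", absolute scale (cm^-1)" else ""
  ))
  if (nzchar(x$meta)) cat(" meta: ", x$meta, "\n", sep = "")
  invisible(x)
}

#' @export
length.sans_curve <- function(x) length(x$Q)

#' @export
as.data.frame.sans_curve <- function(x, ...) {
  d <- data.frame(Q = x$Q, I = x$I)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' Read a three-column scattering curve from text
#'
#' Expects whitespace-separated columns Q, I and (optionally) sigma;
#' lines starting with `#` are treated as header/comment lines and kept
#' as metadata. This covers the common SASBDB-style `.dat` layout.
#'
#' @param path file path.
#' @param absolute logical, passed through to [scattering_curve()].
#' @return a `sans_curve`.
#' @export
read_curve <- function(path, absolute = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- lines[grepl("^\\s*#", lines)]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("format error: no data rows in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !(ncol %in% c(2L, 3L))) {
    stop("format error: expected 2 or 3 whitespace-separated columns in ", path)
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = ncol,
                               byrow = TRUE))
  if (anyNA(m)) stop("format error: non-numeric data in ", path)
  scattering_curve(
    Q = m[, 1], I = m[, 2],
    sigma = if (ncol == 3L) m[, 3] else NULL,
    meta = paste(sub("^\\s*#\\s?", "", header), collapse = "\n"),
    absolute = absolute
  )
}

#' Write a scattering curve as three-column text
#'
#' @param curve a `sans_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sans_curve"))
  hdr <- c("# Q[1/A]  I  sigma",
           if (nzchar(curve$meta)) paste0("# ", strsplit(curve$meta, "\n")[[1]]))
  d <- as.data.frame(curve)
  rows <- do.call(sprintf, c(
    list(paste(rep("%.8e", ncol(d)), collapse = "  ")),
    unname(as.list(d))
  ))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Construct a pair-distance distribution
#'
#' `p(r)` is stored on a uniform grid starting at r = 0 and is
#' normalised so that its trapezoidal integral is 1; it vanishes at
#' r = 0 and beyond `d_max`.
#'
#' @param r distance grid from 0, Angstrom, uniform spacing.
#' @param p nonnegative density values.
#' @param d_max maximum intramolecular distance, Angstrom.
#' @return an object of class `pair_distribution`.
#' @export
pair_distribution <- function(r, p, d_max = max(r)) {
  r <- as.numeric(r); p <- as.numeric(p)
  stopifnot(length(r) == length(p), length(r) >= 3L)
  if (r[1] != 0) stop("r grid must start at 0")
  if (any(p < -1e-12 * max(abs(p)))) stop("p(r) must be nonnegative")
  p[p < 0] <- 0
  p[1] <- 0
  # p vanishes beyond d_max, within one grid step (histogram bins may
  # straddle the longest distance)
  dr <- stats::median(diff(r))
  p[r > d_max + dr] <- 0
  area <- .trapz(r, p)
  if (area <= 0) stop("p(r) integrates to zero")
  structure(list(r = r, p = p / area, d_max = d_max),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("p(r): %d grid points, d_max = %.1f A, peak at r = %.1f A\n",
              length(x$r), x$d_max, x$r[which.max(x$p)]))
  invisible(x)
}

# trapezoidal integral on a (possibly non-uniform) grid
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# numerically safe sin(x)/x
.sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-8
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# second derivative of sinc, stable near 0 (series: -1/3 + x^2/10)
.sinc_dd <- function(x) {
  out <- -1 / 3 + x^2 / 10
  nz <- abs(x) > 1e-3
  xz <- x[nz]
  out[nz] <- -sin(xz) / xz - 2 * cos(xz) / xz^2 + 2 * sin(xz) / xz^3
  out
}

#' Transform a pair-distance distribution to a scattering curve
#'
#' Implements `I(Q) = const * integral p(r) sinc(Q r) dr`, the shape
#' relation between the distance distribution and the intensity (the
#' self-scattering constant is absorbed into the normalisation, so the
#' result is scaled to `I(0) = 1`).
#'
#' @param pr a `pair_distribution`.
#' @param Q_grid momentum transfer grid, A^-1.
#' @return a `sans_curve` with `I(0)` extrapolating to 1.
#' @export
pr_to_curve <- function(pr, Q_grid) {
  stopifnot(inherits(pr, "pair_distribution"))
  if (any(Q_grid <= 0)) stop("Q must be > 0")
  I <- vapply(Q_grid, function(q) .trapz(pr$r, pr$p * .sinc(q * pr$r)),
              numeric(1))
  scattering_curve(Q_grid, I, meta = "from p(r)")
}
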