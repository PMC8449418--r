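# Principal-component landscapes of aligned C-alpha coordinates:
# Kabsch superposition, iterative mean alignment, eigendecomposition,
# projection, and correlation of goodness of fit with landscape
# coordinates.

# accept an atomic_model or a bare n x 3 matrix
.as_conf <- function(x) {
  if (inherits(x, "atomic_model")) .calpha_coords(x)$xyz else as.matrix(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` with a
#' proper rotation (det = +1; mirror solutions are rejected, so a true
#' mirror image retains a nonzero RMSD). Degenerate (e.g. collinear)
#' point sets produce a warning but still return a result.
#'
#' @param mobile,reference n x 3 coordinate matrices (or
#'   `atomic_model`s, whose C-alpha coordinates are used), matched
#'   row-for-row, n >= 3.
#' @return list with `coords` (rotated+translated mobile), `rmsd`,
#'   `rotation` (3 x 3), `translation`.
#' @export
superpose <- function(mobile, reference) {
  A <- .as_conf(mobile); B <- .as_conf(reference)
  if (nrow(A) != nrow(B)) stop("correspondence mismatch: point counts differ")
  if (nrow(A) < 3L) stop("need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  if (min(sv$d) < 1e-10 * max(sv$d)) {
    warning("degenerate point set: superposition may be ill-determined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rot <- A0 %*% t(R)
  out <- sweep(rot, 2, cb, `+`)
  list(coords = out, rmsd = .rmsd(out, B), rotation = R,
       translation = cb - as.vector(R %*% ca))
}

#' Build a principal-component landscape
#'
#' Aligns all structures to their running mean (iterated Kabsch
#' superposition until the mean moves by less than `tol` RMSD), then
#' eigendecomposes the covariance of the aligned Cartesian
#' coordinates. Components are sorted by explained variance, and each
#' is oriented so that the structure with the largest absolute
#' projection projects positively (a reproducible sign convention).
#'
#' @param structures list of n x 3 conformations (or `atomic_model`s)
#'   with matched correspondence; at least 2.
#' @param n_components number of components to keep (must be smaller
#'   than the number of structures).
#' @param labels optional structure labels.
#' @param tol mean-convergence tolerance, Angstrom RMSD.
#' @return an object of class `pca_landscape`: `mean` (n x 3),
#'   `components` (3n x k, orthonormal columns), `variance`
#'   (explained variance per component), `total_variance`,
#'   `projections` (m x k, zero mean per column), `labels`.
#' @export
build_landscape <- function(structures, n_components = 2, labels = NULL,
                            tol = 1e-6) {
  m <- length(structures)
  if (m < 2L) stop("need at least 2 structures")
  if (n_components >= m) stop("n_components must be < number of structures")
  confs <- lapply(structures, .as_conf)
  n <- nrow(confs[[1]])
  if (any(vapply(confs, nrow, integer(1)) != n)) {
    stop("correspondence mismatch: structures differ in size")
  }
  if (is.null(labels)) labels <- sprintf("structure_%02d", seq_len(m))
  # iterative alignment to the running mean
  aligned <- lapply(confs, function(x) superpose(x, confs[[1]])$coords)
  mean_c <- Reduce(`+`, aligned) / m
  for (it in 1:50) {
    aligned <- lapply(aligned, function(x) superpose(x, mean_c)$coords)
    new_mean <- Reduce(`+`, aligned) / m
    delta <- .rmsd(new_mean, mean_c)
    mean_c <- new_mean
    if (delta < tol) break
  }
  X <- t(vapply(aligned, function(x) as.vector(t(x)), numeric(3 * n)))
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = 0, nv = min(m - 1L, 3L * n))
  eigvals <- sv$d^2 / (m - 1L)
  k <- n_components
  comps <- sv$v[, seq_len(k), drop = FALSE]
  proj <- X %*% comps
  # sign convention
  for (j in seq_len(k)) {
    i_max <- which.max(abs(proj[, j]))
    if (proj[i_max, j] < 0) {
      comps[, j] <- -comps[, j]
      proj[, j] <- -proj[, j]
    }
  }
  structure(
    list(mean = mean_c, components = comps, variance = eigvals[seq_len(k)],
         total_variance = sum(eigvals), projections = proj,
         labels = labels),
    class = "pca_landscape"
  )
}

#' @export
print.pca_landscape <- function(x, ...) {
  pct <- 100 * x$variance / x$total_variance
  cat(sprintf(
    "PCA landscape: %d structures, %d components (%s%% of variance)\n",
    nrow(x$projections), ncol(x$components),
    paste(sprintf("%.1f", pct), collapse = " + ")))
  invisible(x)
}

#' Project a conformation onto a landscape
#'
#' Superposes the conformation onto the landscape mean, subtracts the
#' mean, and takes inner products with the component vectors.
#'
#' @param landscape a `pca_landscape`.
#' @param conformation n x 3 matrix or `atomic_model` with matched
#'   correspondence.
#' @return numeric vector of coordinates, one per component.
#' @export
project_landscape <- function(landscape, conformation) {
  stopifnot(inherits(landscape, "pca_landscape"))
  conf <- .as_conf(conformation)
  if (nrow(conf) != nrow(landscape$mean)) {
    stop("correspondence mismatch with the landscape mean")
  }
  al <- superpose(conf, landscape$mean)$coords
  dx <- as.vector(t(al)) - as.vector(t(landscape$mean))
  drop(crossprod(landscape$components, dx))
}

#' Correlate goodness of fit with a landscape coordinate
#'
#' Bins the chosen projection coordinate into equal-width bins, giving
#' the mean chi-square per bin, the location of the minimum-chi-square
#' bin, and the Spearman rank correlation between coordinate and
#' chi-square. This is the one-dimensional summary used to read off
#' where along a collective motion the best-fitting conformations lie.
#'
#' @param projections m x k matrix of landscape coordinates (or vector).
#' @param chi2 length-m chi-square values.
#' @param component which column of `projections` to use.
#' @param n_bins number of equal-width bins (default 20).
#' @return list with `bin_centers`, `bin_mean_chi2` (NA for empty
#'   bins), `min_bin_center`, `best_coordinate` (coordinate of the
#'   single best structure), `spearman`.
#' @export
correlate_fit <- function(projections, chi2, component = 1, n_bins = 20) {
  x <- if (is.matrix(projections)) projections[, component] else projections
  if (length(x) != length(chi2)) stop("projections and chi2 lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate coordinate: zero range")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  means <- rep(NA_real_, n_bins)
  agg <- tapply(chi2, idx, mean)
  means[as.integer(names(agg))] <- agg
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(
    bin_centers = centers,
    bin_mean_chi2 = means,
    min_bin_center = centers[which.min(means)],
    best_coordinate = x[which.min(chi2)],
    spearman = suppressWarnings(stats::cor(x, chi2, method = "spearman"))
  )
}
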