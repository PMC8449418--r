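# Fitting theoretical curves to data: scale + constant background by
# weighted least squares, reduced chi-square with dof approximated by
# the number of points, two-state mixture scans, and ensemble ranking.

#' Fit a theoretical curve to data
#'
#' Finds scale `a >= 0` and constant background `b` minimising
#' `sum ((I_data - a I_theory - b) / sigma)^2` in closed form (2x2
#' normal equations). The reduced chi-square divides by the number of
#' points, approximating the degrees of freedom by N. If the
#' unconstrained solution has negative scale it is re-fit with
#' `a = 0`, signalling a pathological model.
#'
#' @param theory `sans_curve` evaluated on (or interpolated to) the
#'   data's Q grid; see [interpolate_theory()].
#' @param data `sans_curve` with uncertainties.
#' @param background if `FALSE`, fit the scale only (b = 0).
#' @param model_label label stored in the result.
#' @return an object of class `fit_result`: `scale`, `background`,
#'   `chi2_reduced`, `n_points`, `model_label`.
#' @export
fit_model <- function(theory, data, background = TRUE, model_label = "") {
  stopifnot(inherits(theory, "sans_curve"), inherits(data, "sans_curve"))
  if (is.null(data$sigma)) stop("data must have uncertainties")
  if (length(theory$Q) != length(data$Q) ||
      max(abs(theory$Q - data$Q)) > 1e-9 * max(data$Q)) {
    stop("theory must be on the data's Q grid (use interpolate_theory)")
  }
  w <- 1 / data$sigma^2
  t_ <- theory$I; y <- data$I
  n <- length(y)
  if (stats::sd(t_) == 0) stop("degenerate-fit error: constant theory curve")
  if (background) {
    s_tt <- sum(w * t_^2); s_t <- sum(w * t_); s_1 <- sum(w)
    s_ty <- sum(w * t_ * y); s_y <- sum(w * y)
    det <- s_tt * s_1 - s_t^2
    if (abs(det) < 1e-300) stop("degenerate-fit error: singular normal equations")
    a <- (s_ty * s_1 - s_t * s_y) / det
    b <- (s_tt * s_y - s_t * s_ty) / det
    if (a < 0) { # pathological model: constrain scale to zero
      a <- 0
      b <- s_y / s_1
    }
  } else {
    a <- sum(w * t_ * y) / sum(w * t_^2)
    if (a < 0) a <- 0
    b <- 0
  }
  chi2 <- sum(w * (y - a * t_ - b)^2) / n
  structure(
    list(scale = a, background = b, chi2_reduced = chi2, n_points = n,
         model_label = as.character(model_label)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit%s: chi2_red = %.4g (N = %d), scale = %.4g, bkg = %.4g\n",
              if (nzchar(x$model_label)) paste0(" [", x$model_label, "]") else "",
              x$chi2_reduced, x$n_points, x$scale, x$background))
  invisible(x)
}

#' Evaluate chi-square at fixed scale and background
#'
#' Recomputes the reduced chi-square of a fit without refitting; used
#' to verify that a stored `fit_result` reproduces its chi-square.
#'
#' @inheritParams fit_model
#' @param scale,background fixed fit parameters.
#' @return reduced chi-square.
#' @export
chi2_at <- function(theory, data, scale, background = 0) {
  w <- 1 / data$sigma^2
  sum(w * (data$I - scale * theory$I - background)^2) / length(data$I)
}

#' Interpolate a theoretical curve onto a target Q grid
#'
#' Cubic-spline interpolation of `log I` against `log Q` where the
#' curve is strictly positive (power-law segments are then exactly
#' linear), falling back to linear interpolation of I otherwise.
#' Extrapolation is refused.
#'
#' @param theory a `sans_curve`.
#' @param q_target target grid, must lie within the theory's Q span.
#' @return a `sans_curve` on `q_target`.
#' @export
interpolate_theory <- function(theory, q_target) {
  stopifnot(inherits(theory, "sans_curve"))
  if (min(q_target) < min(theory$Q) - 1e-12 ||
      max(q_target) > max(theory$Q) + 1e-12) {
    stop("extrapolation error: q_target outside the theory's Q span")
  }
  I <- if (all(theory$I > 0)) {
    exp(stats::spline(log(theory$Q), log(theory$I), xout = log(q_target),
                      method = "fmm")$y)
  } else {
    stats::approx(theory$Q, theory$I, xout = q_target)$y
  }
  scattering_curve(q_target, I, meta = theory$meta, absolute = theory$absolute)
}

#' Scan a two-state linear combination against data
#'
#' For each mixing fraction `k` on a grid, forms
#' `I(k) = k I_A + (1 - k) I_B`, fits scale and background, and records
#' the reduced chi-square. Reports the best `k` and the largest `k`
#' whose chi-square does not exceed chi-square at `k = 0` (the
#' tolerated contribution of state A), refined by linear interpolation
#' between grid points.
#'
#' @param theory_a,theory_b `sans_curve`s of the two states on the
#'   data's Q grid (state A is the one whose fraction is `k`).
#' @param data `sans_curve` with uncertainties.
#' @param step grid spacing for `k`, in (0, 0.5].
#' @param background passed to [fit_model()].
#' @return an object of class `mixture_result`: `k_grid`, `chi2`,
#'   `k_best`, `k_max_tolerated`.
#' @export
mixture_scan <- function(theory_a, theory_b, data, step = 0.01,
                         background = TRUE) {
  stopifnot(step > 0, step <= 0.5)
  k_grid <- seq(0, 1, by = step)
  if (k_grid[length(k_grid)] < 1) k_grid <- c(k_grid, 1)
  chi2 <- vapply(k_grid, function(k) {
    mix <- scattering_curve(data$Q, k * theory_a$I + (1 - k) * theory_b$I)
    fit_model(mix, data, background = background)$chi2_reduced
  }, numeric(1))
  k_best <- k_grid[which.min(chi2)]
  # largest k with chi2(k) <= chi2(0), sub-step by linear interpolation
  ref <- chi2[1]
  ok <- chi2 <= ref + 1e-12 * max(1, ref)
  j <- max(which(ok))
  k_max <- k_grid[j]
  if (j < length(k_grid)) {
    dk <- k_grid[j + 1] - k_grid[j]
    dchi <- chi2[j + 1] - chi2[j]
    if (dchi > 0) k_max <- k_grid[j] + dk * (ref - chi2[j]) / dchi
  }
  structure(
    list(k_grid = k_grid, chi2 = chi2, k_best = k_best,
         k_max_tolerated = min(k_max, 1)),
    class = "mixture_result"
  )
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf(
    "Mixture scan: k_best = %.3f (chi2 = %.4g), chi2(k=0) = %.4g, k_max_tolerated = %.3f\n",
    x$k_best, min(x$chi2), x$chi2[1], x$k_max_tolerated))
  invisible(x)
}

#' Fit and rank an ensemble of theoretical curves
#'
#' Fits every member against the data and returns the results sorted by
#' ascending reduced chi-square (stable: ties keep input order).
#'
#' @param theories non-empty list of `sans_curve`s on the data grid.
#' @param data `sans_curve` with uncertainties.
#' @param labels optional labels, recycled to the list length.
#' @param background passed to [fit_model()].
#' @return list of `fit_result`, best first, each with an `index`
#'   field giving its position in the input list.
#' @export
rank_ensemble <- function(theories, data, labels = NULL, background = TRUE) {
  if (length(theories) == 0L) stop("empty model list")
  if (is.null(labels)) labels <- sprintf("model_%02d", seq_along(theories))
  fits <- mapply(function(th, lb, i) {
    f <- fit_model(th, data, background = background, model_label = lb)
    f$index <- i
    f
  }, theories, labels, seq_along(theories), SIMPLIFY = FALSE)
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2_reduced")
  fits[order(chi2)] # order() is a stable sort
}
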