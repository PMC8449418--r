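# Experimental-curve operations: detector-distance merging, constant
# background, concentration normalisation, Guinier analysis, the I(0)
# molecular-weight relation, and regularised indirect Fourier
# transformation of p(r).

#' Merge two detector-distance curves
#'
#' The low-Q curve is kept up to the crossover and the high-Q curve
#' above it. Unless `scale` is given, a multiplicative factor for the
#' high-Q segment is fitted by (sigma-weighted) least squares on the
#' overlap region, enforcing continuity; real instruments typically
#' have the two distances on a common absolute scale, so `scale = 1`
#' may be forced.
#'
#' @param low_q,high_q `sans_curve`s covering the low- and high-Q
#'   windows; they must overlap around `crossover`.
#' @param crossover merge point, A^-1 (e.g. 0.070 for long-distance
#'   data used up to that Q, 0.095 for a paused-flow configuration).
#' @param scale optional fixed scale applied to `high_q` (skips the fit).
#' @return merged `sans_curve`.
#' @export
merge_curves <- function(low_q, high_q, crossover, scale = NULL) {
  stopifnot(inherits(low_q, "sans_curve"), inherits(high_q, "sans_curve"))
  lo <- max(min(high_q$Q), min(low_q$Q))
  hi <- min(max(low_q$Q), max(high_q$Q))
  if (lo >= hi) stop("merge error: curves do not overlap")
  if (is.null(scale)) {
    sel_l <- low_q$Q >= lo & low_q$Q <= hi
    if (sum(sel_l) < 2L) stop("merge error: fewer than 2 overlap points")
    ih <- stats::approx(high_q$Q, high_q$I, xout = low_q$Q[sel_l])$y
    w <- if (!is.null(low_q$sigma)) 1 / low_q$sigma[sel_l]^2 else
      rep(1, sum(sel_l))
    scale <- sum(w * low_q$I[sel_l] * ih) / sum(w * ih^2)
  }
  keep_l <- low_q$Q <= crossover
  keep_h <- high_q$Q > crossover
  if (!any(keep_l) || !any(keep_h)) {
    stop("merge error: crossover leaves one segment empty")
  }
  Q <- c(low_q$Q[keep_l], high_q$Q[keep_h])
  I <- c(low_q$I[keep_l], scale * high_q$I[keep_h])
  s <- if (!is.null(low_q$sigma) && !is.null(high_q$sigma)) {
    c(low_q$sigma[keep_l], scale * high_q$sigma[keep_h])
  } else NULL
  out <- scattering_curve(Q, I, sigma = s,
                          meta = sprintf("merged at %.4g A^-1, scale %.6g",
                                         crossover, scale),
                          absolute = low_q$absolute)
  attr(out, "merge_scale") <- scale
  out
}

#' Subtract a constant background
#'
#' The constant is either given explicitly or estimated as the mean
#' intensity over a high-Q window where the signal has decayed into
#' the flat background.
#'
#' @param curve a `sans_curve`.
#' @param high_q_window length-2 numeric `(Q_lo, Q_hi)` window, A^-1.
#' @param value explicit constant (overrides the window).
#' @return background-subtracted `sans_curve`.
#' @export
subtract_constant <- function(curve, high_q_window = NULL, value = NULL) {
  stopifnot(inherits(curve, "sans_curve"))
  if (is.null(value)) {
    if (is.null(high_q_window) || length(high_q_window) != 2L) {
      stop("provide either a high-Q window or an explicit value")
    }
    sel <- curve$Q >= high_q_window[1] & curve$Q <= high_q_window[2]
    if (!any(sel)) stop("empty window: no points in [",
                        high_q_window[1], ", ", high_q_window[2], "]")
    value <- mean(curve$I[sel])
  }
  scattering_curve(curve$Q, curve$I - value, sigma = curve$sigma,
                   meta = sprintf("%s; background %.4g subtracted",
                                  curve$meta, value),
                   absolute = curve$absolute)
}

#' Normalise a curve by protein concentration
#'
#' Concentration from 280 nm absorbance:
#' `c = A280 * mass / (eps280 * path)` in g/L, converted to g/cm^3;
#' intensities and uncertainties are divided by it, yielding the
#' concentration-normalised absolute scale used in the I(0)
#' molecular-weight relation.
#'
#' @param curve a `sans_curve` in cm^-1.
#' @param a280 absorbance at 280 nm (dimensionless).
#' @param eps280 molar extinction coefficient, M^-1 cm^-1.
#' @param path_cm optical path length, cm.
#' @param mass molar mass, g/mol.
#' @return list with `curve` (I/c, units cm^-1 per g/cm^3 = cm^2/g) and
#'   `c_g_cm3` the concentration used.
#' @export
normalize_by_concentration <- function(curve, a280, eps280, path_cm, mass) {
  stopifnot(inherits(curve, "sans_curve"))
  if (any(c(a280, eps280, path_cm, mass) <= 0)) {
    stop("a280, eps280, path_cm and mass must all be positive")
  }
  c_g_l <- a280 * mass / (eps280 * path_cm)
  c_g_cm3 <- c_g_l * 1e-3
  out <- scattering_curve(curve$Q, curve$I / c_g_cm3,
                          sigma = if (!is.null(curve$sigma)) curve$sigma / c_g_cm3,
                          meta = sprintf("%s; / c = %.4g g/cm^3",
                                         curve$meta, c_g_cm3),
                          absolute = curve$absolute)
  list(curve = out, c_g_cm3 = c_g_cm3)
}

#' Guinier analysis
#'
#' Weighted linear least squares of `ln I` against `Q^2` over the given
#' Q range; the Guinier law `I = I(0) exp(-Q^2 Rg^2 / 3)` then gives
#' `Rg = sqrt(-3 slope)` and `I(0) = exp(intercept)`. Weights follow
#' from error propagation, `var(ln I) = (sigma/I)^2`. A warning is
#' emitted when `Q_max * Rg` exceeds `qrg_warn` (conventional validity
#' is ~1.3; fits out to QRg of about 3 are sometimes used for globular
#' particles and are flagged, not refused).
#'
#' @param curve a `sans_curve` with positive intensities in the range.
#' @param q_range length-2 numeric, fit window in Q (default the
#'   0.010-0.046 A^-1 window typical of a ~180 kDa pentamer).
#' @param qrg_warn threshold for the QRg warning (default 1.5).
#' @return an object of class `guinier_result`: fields `I0`, `Rg`,
#'   `I0_se`, `Rg_se`, `q_range`, `n_points`, `qmax_rg`,
#'   `qrg_exceeded`.
#' @export
guinier_fit <- function(curve, q_range = c(0.010, 0.046), qrg_warn = 1.5) {
  stopifnot(inherits(curve, "sans_curve"), length(q_range) == 2L)
  sel <- curve$Q >= q_range[1] & curve$Q <= q_range[2]
  if (sum(sel) < 3L) stop("need at least 3 points in the Guinier range")
  I <- curve$I[sel]; Q <- curve$Q[sel]
  if (any(I <= 0)) stop("nonpositive intensity in the Guinier range")
  x <- Q^2; y <- log(I)
  w <- if (!is.null(curve$sigma)) (I / curve$sigma[sel])^2 else rep(1, length(I))
  # explicit weighted least squares (an ideal Guinier curve fits
  # perfectly; lm's summary machinery warns on zero residuals)
  sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  slope <- sum(w * (x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  if (slope >= 0) stop("no-Guinier-region error: nonnegative slope of ln I vs Q^2")
  resid <- y - intercept - slope * x
  s2 <- sum(w * resid^2) / max(length(y) - 2L, 1L)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / sw + mx^2 / sxx))
  rg <- sqrt(-3 * slope)
  rg_se <- 3 * se_slope / (2 * rg)
  i0 <- exp(intercept)
  qmax_rg <- max(Q) * rg
  if (qmax_rg > qrg_warn) {
    warning(sprintf("Guinier fit extends to QRg = %.2f (> %.2f)",
                    qmax_rg, qrg_warn))
  }
  structure(
    list(I0 = i0, Rg = rg, I0_se = i0 * se_int, Rg_se = rg_se,
         q_range = q_range, n_points = sum(sel), qmax_rg = qmax_rg,
         qrg_exceeded = qmax_rg > 3.0),
    class = "guinier_result"
  )
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "Guinier: Rg = %.2f +/- %.2f A, I(0) = %.4g +/- %.2g, %d pts, Qmax*Rg = %.2f%s\n",
    x$Rg, x$Rg_se, x$I0, x$I0_se, x$n_points, x$qmax_rg,
    if (x$qrg_exceeded) " [exceeds 3.0]" else ""))
  invisible(x)
}

#' Molecular weight from forward scattering
#'
#' `Mw = N_A I(0) / (c (delta_rho nu_bar)^2)` with I(0) in cm^-1 on
#' absolute scale, concentration in g/cm^3, excess scattering length
#' density in cm^-2 and partial specific volume in cm^3/g.
#'
#' @param I0 forward scattering, cm^-1.
#' @param c concentration, g/cm^3.
#' @param delta_rho excess scattering length density, cm^-2.
#' @param nu_bar partial specific volume, cm^3/g.
#' @return molecular weight, g/mol.
#' @export
mw_from_i0 <- function(I0, c, delta_rho, nu_bar) {
  if (any(c(I0, c, delta_rho, nu_bar) <= 0)) {
    stop("all arguments must be positive")
  }
  .NA_AVOGADRO * I0 / (c * (delta_rho * nu_bar)^2)
}

#' Forward scattering expected for a molecular weight (inverse of
#' [mw_from_i0()])
#'
#' @inheritParams mw_from_i0
#' @param Mw molecular weight, g/mol.
#' @return I(0) in cm^-1.
#' @export
mw_to_i0 <- function(Mw, c, delta_rho, nu_bar) {
  if (any(c(Mw, c, delta_rho, nu_bar) <= 0)) {
    stop("all arguments must be positive")
  }
  Mw * c * (delta_rho * nu_bar)^2 / .NA_AVOGADRO
}

#' Excess scattering length density of a model in a solvent
#'
#' `delta_rho = |rho_protein - rho_solvent|` where the protein's
#' scattering length density counts exchanged labile hydrogens as D.
#'
#' @param model an annotated `atomic_model`.
#' @param solvent a `solvent_spec`.
#' @return excess scattering length density, cm^-2.
#' @export
excess_sld <- function(model, solvent = solvent_spec()) {
  # b without the displaced-solvent term
  vac <- solvent_spec(d2o_fraction = solvent$d2o_fraction,
                      exchanged_fraction_soluble = solvent$exchanged_fraction_soluble,
                      exchanged_fraction_tm = solvent$exchanged_fraction_tm,
                      rho_solvent = 0)
  b_total <- sum(effective_scattering_lengths(model, vac))
  v_cm3 <- estimate_molecular_volume(model) * 1e-24
  abs(b_total / v_cm3 - solvent$rho_solvent)
}

#' Indirect Fourier transform to p(r)
#'
#' Estimates the pair-distance distribution from a measured curve by
#' minimising `chi^2 + alpha * integral p''(r)^2 dr` over nonnegative
#' p(r) on a uniform grid with p(0) = p(d_max) = 0 (second-derivative
#' smoothness regularisation; the bound-constrained quadratic problem
#' is solved by L-BFGS-B with analytic gradients). When `alpha` is not
#' given it is chosen on a log-spaced grid by an L-curve corner
#' heuristic (maximum curvature of log chi^2 vs log roughness). A
#' constant offset is co-fitted by default, absorbing self-scattering
#' and residual flat background that the sinc basis cannot represent.
#'
#' @param curve a `sans_curve` with uncertainties.
#' @param d_max assumed maximum dimension, Angstrom.
#' @param n_r number of r grid points (default 60).
#' @param alpha regularisation weight; `NULL` selects it automatically.
#' @param fit_const co-fit a constant intensity offset.
#' @return a `pair_distribution` with attributes `chi2_reduced`,
#'   `alpha`, `const` and `fit` (the back-calculated curve).
#' @export
ift_pr <- function(curve, d_max, n_r = 60, alpha = NULL, fit_const = TRUE) {
  stopifnot(inherits(curve, "sans_curve"))
  if (is.null(curve$sigma)) stop("ift_pr requires uncertainties")
  if (d_max <= 0) stop("d_max must be > 0")
  r <- seq(0, d_max, length.out = n_r)
  dr <- r[2] - r[1]
  # free coefficients are interior grid values; end points pinned at 0
  free <- 2:(n_r - 1L)
  A_full <- outer(curve$Q, r, function(q, rr) .sinc(q * rr)) * dr
  n_f <- length(free)
  A <- A_full[, free, drop = FALSE] / curve$sigma
  if (fit_const) A <- cbind(A, 1 / curve$sigma)
  n_par <- ncol(A)
  y <- curve$I / curve$sigma
  # second-difference operator on the full grid (zero-padded ends);
  # the constant-offset column is not penalised
  D <- matrix(0, n_f, n_par)
  for (j in seq_len(n_f)) {
    D[j, j] <- -2
    if (j > 1) D[j, j - 1] <- 1
    if (j < n_f) D[j, j + 1] <- 1
  }
  D <- D / dr^2
  lower <- c(rep(0, n_f), if (fit_const) -Inf)
  AtA <- crossprod(A); Aty <- crossprod(A, y)
  DtD <- crossprod(D)
  solve_alpha <- function(a) {
    H <- AtA + a * DtD
    fn <- function(p) {
      drop(crossprod(p, H %*% p)) / 2 - drop(crossprod(p, Aty))
    }
    gr <- function(p) drop(H %*% p - Aty)
    p0 <- tryCatch(solve(H + 1e-10 * mean(diag(H)) * diag(n_par), Aty),
                   error = function(e) NULL)
    if (is.null(p0)) {
      stop("regularization error: ill-conditioned system; increase alpha")
    }
    p0 <- drop(p0)
    p0[seq_len(n_f)] <- pmax(p0[seq_len(n_f)], 0)
    opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                        lower = lower,
                        control = list(maxit = 500, factr = 1e7))
    p <- opt$par
    resid <- y - drop(A %*% p)
    list(p = p, chi2 = sum(resid^2), rough = drop(crossprod(D %*% p)))
  }
  if (is.null(alpha)) {
    # scale candidate alphas relative to the data term's magnitude
    a0 <- sum(diag(AtA)) / max(sum(diag(DtD)), .Machine$double.eps)
    alphas <- a0 * 10^seq(-4, 3, length.out = 12)
    sols <- lapply(alphas, solve_alpha)
    lx <- log10(vapply(sols, `[[`, numeric(1), "rough") + 1e-300)
    ly <- log10(vapply(sols, `[[`, numeric(1), "chi2") + 1e-300)
    # discrete curvature of the L-curve; fall back to mid-grid
    k <- length(alphas)
    curv <- rep(-Inf, k)
    for (j in 2:(k - 1L)) {
      v1 <- c(lx[j] - lx[j - 1], ly[j] - ly[j - 1])
      v2 <- c(lx[j + 1] - lx[j], ly[j + 1] - ly[j])
      cross <- v1[1] * v2[2] - v1[2] * v2[1]
      curv[j] <- cross / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)) + 1e-300)
    }
    jbest <- if (all(!is.finite(curv))) ceiling(k / 2) else which.max(curv)
    alpha <- alphas[jbest]
    sol <- sols[[jbest]]
  } else {
    sol <- solve_alpha(alpha)
  }
  p_full <- numeric(n_r)
  p_full[free] <- sol$p[seq_len(n_f)]
  const <- if (fit_const) sol$p[n_par] else 0
  out <- pair_distribution(r, p_full, d_max = d_max)
  attr(out, "chi2_reduced") <- sol$chi2 / length(curve$Q)
  attr(out, "alpha") <- alpha
  attr(out, "const") <- const
  attr(out, "fit") <- scattering_curve(
    curve$Q, drop(A_full[, free] %*% sol$p[seq_len(n_f)]) + const,
    meta = "IFT back-calculated")
  out
}
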