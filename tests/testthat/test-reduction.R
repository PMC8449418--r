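# Curve reduction: merging, background, normalisation, Guinier,
# molecular weight, and the indirect Fourier transform.

test_that("merging keeps low-Q below and rescaled high-Q above the crossover", {
  Q <- seq(0.01, 0.3, length.out = 120)
  I <- exp(-Q^2 * 400)
  lo <- scattering_curve(Q[Q <= 0.12], I[Q <= 0.12],
                         sigma = rep(0.01, sum(Q <= 0.12)))
  hi <- scattering_curve(Q[Q >= 0.08], I[Q >= 0.08],
                         sigma = rep(0.01, sum(Q >= 0.08)))
  # identical curves: merged output equals the input, scale 1
  m <- merge_curves(lo, hi, crossover = 0.10)
  expect_equal(attr(m, "merge_scale"), 1, tolerance = 1e-12)
  expect_equal(m$I, I[Q <= 0.10 | Q > 0.10], tolerance = 1e-12)
  expect_true(all(diff(m$Q) > 0))

  # high-Q segment pre-multiplied by 2 is scaled back by 0.5
  hi2 <- scattering_curve(hi$Q, 2 * hi$I, sigma = hi$sigma)
  m2 <- merge_curves(lo, hi2, crossover = 0.10)
  expect_equal(attr(m2, "merge_scale"), 0.5, tolerance = 1e-12)
  expect_equal(m2$I, m$I, tolerance = 1e-12)

  # explicit scale override skips the fit
  m3 <- merge_curves(lo, hi2, crossover = 0.10, scale = 1)
  expect_gt(max(abs(m3$I - m$I)), 0.01)

  # disjoint curves refuse to merge
  lo_d <- scattering_curve(Q[Q <= 0.05], I[Q <= 0.05])
  hi_d <- scattering_curve(Q[Q >= 0.2], I[Q >= 0.2])
  expect_error(merge_curves(lo_d, hi_d, 0.1), "merge error")
})

test_that("simulated two-distance experiment merges back to the truth", {
  truth <- debye_curve(toy_closed, unit_solvent(),
                       seq(0.01, 0.25, length.out = 200), method = "exact")
  # vanishing noise: the merge recovers the generator exactly
  seg0 <- simulate_experiment(truth, noise_spec(rel_sigma = 1e-12,
                                                floor_sigma = 1e-12,
                                                seed = 1))
  m0 <- merge_curves(seg0$low_q, seg0$high_q, crossover = 0.095)
  expect_equal(m0$I, truth$I, tolerance = 1e-6)
  # 1% noise: merged curve stays within a few sigma everywhere
  seg <- simulate_experiment(truth, noise_spec(seed = 8))
  m1 <- merge_curves(seg$low_q, seg$high_q, crossover = 0.095)
  t_on_grid <- stats::approx(truth$Q, truth$I, xout = m1$Q)$y
  expect_lt(max(abs(m1$I - t_on_grid) / m1$sigma), 5)
})

test_that("constant background subtraction recovers known offsets", {
  Q <- seq(0.01, 0.5, length.out = 100)
  flat <- scattering_curve(Q, rep(0.02, 100))
  out <- subtract_constant(flat, value = 0.02)
  expect_equal(out$I, rep(0, 100))

  cur <- scattering_curve(Q, exp(-Q^2 * 900) + 0.01)
  rec <- subtract_constant(cur, high_q_window = c(0.4, 0.5))
  expect_equal(mean(rec$I[Q >= 0.4]), 0, tolerance = 1e-6)
  expect_error(subtract_constant(cur, high_q_window = c(0.6, 0.7)),
               "empty window")

  # sphere curve plus constant: window past the first minimum
  # recovers the constant to 10%
  sph <- analytic_sphere_curve(30, seq(0.01, 0.4, length.out = 300))
  plus <- scattering_curve(sph$Q, sph$I + 1e-3)
  est <- mean(plus$I[plus$Q >= 0.25]) -
    mean(subtract_constant(plus, high_q_window = c(0.25, 0.4))$I[plus$Q >= 0.25])
  expect_equal(est, 1e-3, tolerance = 0.1)
})

test_that("concentration normalisation implements c = A280 M / (eps l)", {
  Q <- seq(0.01, 0.1, length.out = 20)
  cur <- scattering_curve(Q, rep(1, 20), sigma = rep(0.1, 20))
  # a280 = 0.5, eps = 1e5, path 1 cm, M = 182700 -> c = 913.5 mg/L
  out <- normalize_by_concentration(cur, a280 = 0.5, eps280 = 1e5,
                                    path_cm = 1, mass = 182700)
  expect_equal(out$c_g_cm3, 9.135e-4, tolerance = 1e-12)
  expect_equal(out$curve$I, rep(1 / 9.135e-4, 20))
  expect_equal(out$curve$sigma, rep(0.1 / 9.135e-4, 20))
  # doubling A280 halves the output intensity
  out2 <- normalize_by_concentration(cur, 1.0, 1e5, 1, 182700)
  expect_equal(out2$curve$I, out$curve$I / 2)
  expect_error(normalize_by_concentration(cur, -1, 1e5, 1, 182700),
               "positive")
})

test_that("Guinier fit is exact on an ideal Guinier curve", {
  Rg <- 38; I0 <- 0.17
  Q <- seq(0.005, 1.2 / Rg, length.out = 60)
  cur <- scattering_curve(Q, I0 * exp(-Q^2 * Rg^2 / 3))
  g <- guinier_fit(cur, q_range = range(Q), qrg_warn = 2)
  expect_equal(g$Rg, Rg, tolerance = 1e-6)
  expect_equal(g$I0, I0, tolerance = 1e-6)
  expect_false(g$qrg_exceeded)

  # sphere of R = 49 recovers Rg = sqrt(3/5) * 49 in the asymptotic window
  R <- 49; rg_true <- sqrt(3 / 5) * R
  Qs <- seq(0.002, 0.7 / rg_true, length.out = 80)
  gs <- guinier_fit(analytic_sphere_curve(R, Qs), q_range = range(Qs),
                    qrg_warn = 2)
  expect_equal(gs$Rg, rg_true, tolerance = 0.01)

  # wide-window fits warn; rising curves refuse
  expect_warning(
    guinier_fit(analytic_sphere_curve(R, seq(0.002, 3 / rg_true, 1e-3)),
                q_range = c(0, 1), qrg_warn = 1.5), "QRg")
  rising <- scattering_curve(Q, exp(Q^2 * 100))
  expect_error(guinier_fit(rising, q_range = range(Q)), "no-Guinier-region")
})

test_that("molecular weight relation evaluates and inverts exactly", {
  # forward-evaluated example: these inputs give ~182.7 kDa
  mw <- mw_from_i0(I0 = 0.1748, c = 1e-3, delta_rho = 3.0e10, nu_bar = 0.8)
  expect_equal(mw, 182700, tolerance = 0.001)
  # linearity and round trip
  expect_equal(mw_from_i0(0.1748, 2e-3, 3.0e10, 0.8), mw / 2)
  set.seed(3)
  for (i in 1:20) {
    M <- runif(1, 1e4, 1e6); cc <- runif(1, 1e-4, 1e-2)
    dr <- runif(1, 1e10, 6e10); nb <- runif(1, 0.6, 0.9)
    expect_equal(mw_from_i0(mw_to_i0(M, cc, dr, nb), cc, dr, nb), M,
                 tolerance = 1e-10)
  }
  expect_error(mw_from_i0(-1, 1, 1, 1), "positive")
})

test_that("a noiseless absolute-scale synthetic curve returns the generator mass", {
  # protein-like chain with real contrast in D2O
  pep <- annotate_hydrogens(fake_protein(rep(names(FORMULA_H), 2)))
  solv <- solvent_spec()
  mass <- sequence_mass_and_extinction(pep)$mass
  rg <- model_rg(pep, solv)
  Q <- seq(0.002, 0.6 / rg, length.out = 40)
  cur <- debye_curve(pep, solv, Q, method = "exact")
  c_g_cm3 <- 2e-3 # 2 mg/mL
  abs_cur <- scale_to_absolute(cur, c_mg_ml = 2, mass = mass)
  g <- guinier_fit(abs_cur, q_range = range(Q), qrg_warn = 2)
  mw <- mw_from_i0(g$I0, c_g_cm3, excess_sld(pep, solv),
                   partial_specific_volume(pep))
  expect_equal(mw, mass, tolerance = 0.05)
})

test_that("reduction pipeline commutes with a global intensity rescale", {
  truth <- debye_curve(toy_closed, unit_solvent(),
                       seq(0.01, 0.25, length.out = 150), method = "exact")
  seg <- simulate_experiment(truth, noise_spec(seed = 13))
  k <- 7.3
  scale_up <- function(cv) scattering_curve(cv$Q, k * cv$I,
                                            sigma = k * cv$sigma)
  pipe <- function(lo, hi) {
    m <- merge_curves(lo, hi, crossover = 0.095)
    m <- subtract_constant(m, value = mean(m$I[m$Q > 0.2]))
    normalize_by_concentration(m, 0.4, 9e4, 1, 1.8e5)$curve
  }
  a <- pipe(scale_up(seg$low_q), scale_up(seg$high_q))
  b <- pipe(seg$low_q, seg$high_q)
  expect_equal(a$I, k * b$I, tolerance = 1e-9)
})

test_that("IFT recovers sphere and two-point distance distributions", {
  R <- 30
  Q <- seq(0.008, 0.25, length.out = 120)
  truth <- analytic_sphere_curve(R, Q)
  cur <- scattering_curve(Q, truth$I, sigma = 0.01 * truth$I + 1e-4)
  pr <- ift_pr(cur, d_max = 2 * R, n_r = 61)
  ref <- analytic_sphere_pr(R, n_r = 61)
  expect_lt(pentasans:::.trapz(pr$r, abs(pr$p - ref$p)), 0.03)

  # two scatterers 10 A apart: p(r) peaks at the separation
  m2 <- atomic_model(data.frame(
    element = "C", x = c(0, 10), y = 0, z = 0, resname = "GLY",
    resno = 1:2, chain = "A", atom_name = "CA", occupancy = 1),
    implicit_h = c(0L, 0L), labile_h = c(0L, 0L))
  d2 <- debye_curve(m2, unit_solvent(), seq(0.02, 1.2, length.out = 200),
                    method = "exact")
  c2 <- scattering_curve(d2$Q, d2$I, sigma = rep(0.01 * max(d2$I), 200))
  p2 <- ift_pr(c2, d_max = 15, n_r = 40)
  expect_equal(p2$r[which.max(p2$p)], 10, tolerance = 0.5)

  expect_error(ift_pr(scattering_curve(Q, truth$I), d_max = 2 * R),
               "uncertainties")
})

test_that("IFT d_max estimate from a noisy pentamer curve is close to truth", {
  truth <- debye_curve(toy_closed, unit_solvent(),
                       seq(0.008, 0.30, length.out = 250), method = "exact")
  sim <- simulate_curve(truth, noise_spec(rel_sigma = 0.01,
                                          floor_sigma = 0.005, seed = 5))
  pr <- ift_pr(sim, d_max = 115, n_r = 66)
  d_true <- model_pr(toy_closed, unit_solvent(), bin = 2)$d_max
  d_est <- max(pr$r[pr$p > 0.01 * max(pr$p)])
  expect_lt(abs(d_est - d_true) / d_true, 0.10)
})
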