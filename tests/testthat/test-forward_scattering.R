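# Debye forward model, effective scattering lengths, Rg and p(r).

bead <- function(x, y, z, element = "C") {
  n <- length(x)
  atomic_model(data.frame(
    element = element, x = x, y = y, z = z, resname = "GLY",
    resno = seq_len(n), chain = "A", atom_name = "CA", occupancy = 1),
    implicit_h = rep(0L, n), labile_h = rep(0L, n))
}

test_that("effective scattering lengths combine tabulated b, H/D exchange and excluded volume", {
  vac <- unit_solvent()
  # bare carbon, no hydrogens
  expect_equal(effective_scattering_lengths(bead(0, 0, 0), vac),
               6.6460 * FM)
  # backbone-N-like atom with one labile H, fully exchanged
  m <- atomic_model(data.frame(
    element = "N", x = 0, y = 0, z = 0, resname = "GLY", resno = 1,
    chain = "A", atom_name = "N", occupancy = 1),
    implicit_h = 1L, labile_h = 1L)
  s_full <- solvent_spec(exchanged_fraction_soluble = 1, rho_solvent = 0)
  expect_equal(effective_scattering_lengths(m, s_full),
               (9.36 + 6.671) * FM, tolerance = 1e-6)
  # f = 0 keeps the hydrogen as 1H
  s_none <- solvent_spec(exchanged_fraction_soluble = 0, rho_solvent = 0)
  expect_equal(effective_scattering_lengths(m, s_none),
               (9.36 - 3.7390) * FM, tolerance = 1e-6)
  # linearity: sum b changes by n_labile (b_D - b_H)
  pep <- annotate_hydrogens(fake_protein(c("SER", "LYS", "THR")))
  b0 <- sum(effective_scattering_lengths(pep, s_none))
  b1 <- sum(effective_scattering_lengths(pep, s_full))
  expect_equal(b1 - b0, sum(pep$labile_h) * (6.671 + 3.7390) * FM,
               tolerance = 1e-9)
  # transmembrane atoms use the shielded fraction
  pep_tm <- assign_membrane_slab(pep, -1e6, 1e6) # everything "in membrane"
  s_mix <- solvent_spec(exchanged_fraction_soluble = 1,
                        exchanged_fraction_tm = 0, rho_solvent = 0)
  expect_equal(sum(effective_scattering_lengths(pep_tm, s_mix)), b0,
               tolerance = 1e-9)
  # excluded volume reduces b by rho * V
  s_rho <- solvent_spec(d2o_fraction = 1)
  b_c <- effective_scattering_lengths(bead(0, 0, 0), s_rho)
  expect_equal(b_c, 6.6460 * FM - s_rho$rho_solvent * atom_volume("C") * 1e-24)
})

test_that("raising the exchanged fraction monotonically increases total b", {
  pep <- annotate_hydrogens(fake_protein(c("ARG", "TYR", "ASN", "GLY")))
  f <- seq(0, 1, by = 0.25)
  tot <- vapply(f, function(fi) {
    sum(effective_scattering_lengths(
      pep, solvent_spec(exchanged_fraction_soluble = fi, rho_solvent = 0)))
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("Debye curve matches the two-point closed form and the forward limit", {
  m <- bead(c(0, 10), c(0, 0), c(0, 0))
  Q <- seq(0.01, 1, length.out = 80)
  cur <- debye_curve(m, unit_solvent(), Q, method = "exact")
  b <- 6.6460 * FM
  expect_equal(cur$I / (4 * b^2), (1 + sin(Q * 10) / (Q * 10)) / 2,
               tolerance = 1e-12)
  # I(Q) -> (sum b)^2 as Q -> 0
  lowq <- debye_curve(m, unit_solvent(), 1e-5, method = "exact")
  expect_equal(lowq$I, (2 * b)^2, tolerance = 1e-8)
  expect_error(debye_curve(m, unit_solvent(), c(-0.1, 0.1)), "positive")
})

test_that("histogram Debye agrees with the exact sum to 0.5% below Q = 0.5", {
  Q <- seq(0.01, 0.5, length.out = 60)
  ex <- debye_curve(toy_closed, unit_solvent(), Q, method = "exact")
  hi <- debye_curve(toy_closed, unit_solvent(), Q, method = "histogram",
                    bin = 0.5)
  expect_lt(max(abs(hi$I - ex$I) / abs(ex$I)), 0.005)
})

test_that("sphere bead model reproduces the analytic form factor", {
  # moderate-size oracle; the acceptance suite runs the full-size one
  R <- 25
  mdl <- sphere_bead_model(R, spacing = 2)
  Q <- seq(0.01, 3 / R, length.out = 30)
  cur <- debye_curve(mdl, unit_solvent(), Q, method = "exact")
  I0 <- sum(effective_scattering_lengths(mdl, unit_solvent()))^2
  ana <- analytic_sphere_curve(R, Q)
  expect_lt(max(abs(cur$I / I0 - ana$I) / ana$I), 0.01)
})

test_that("model_rg: closed forms, degenerate cases and weighting variants", {
  expect_equal(model_rg(bead(0, 0, 0), unit_solvent()), 0)
  R <- 30
  sph <- sphere_bead_model(R, spacing = 1.5)
  expect_equal(model_rg(sph, unit_solvent()), sqrt(3 / 5) * R,
               tolerance = 5e-3)
  # geometric and contrast weighting agree for uniform beads
  expect_equal(model_rg(sph, unit_solvent()),
               model_rg(sph, weighting = "geometric"), tolerance = 1e-12)
  # uniformly negative contrast is fine (protein in pure D2O)
  m_neg <- bead(c(0, 5), c(0, 0), c(0, 0), element = "H")
  expect_gt(model_rg(m_neg, unit_solvent()), 0)
  # a contrast-matched mixture (16 H + 9 C, net b ~ 0) is degenerate
  m_match <- bead(seq_len(25), rep(0, 25), rep(0, 25),
                  element = rep(c("H", "C"), c(16, 9)))
  expect_error(model_rg(m_match, unit_solvent()), "degenerate-contrast")
})

test_that("Guinier fit of a noiseless model curve reproduces model Rg", {
  rg <- model_rg(toy_closed, unit_solvent())
  # asymptotic window (QRg <= 0.7): truncation bias below ~0.5%
  Q <- seq(0.003, 0.7 / rg, length.out = 50)
  cur <- debye_curve(toy_closed, unit_solvent(), Q, method = "exact")
  g <- guinier_fit(cur, q_range = range(Q), qrg_warn = 2)
  expect_equal(g$Rg, rg, tolerance = 0.01)
  # the conventional noise-robust window (QRg <= 1.3) agrees to 2%
  Q2 <- seq(0.003, 1.3 / rg, length.out = 50)
  g2 <- guinier_fit(debye_curve(toy_closed, unit_solvent(), Q2,
                                method = "exact"),
                    q_range = range(Q2), qrg_warn = 2)
  expect_equal(g2$Rg, rg, tolerance = 0.02)
})

test_that("model p(r): single-separation peak, sphere shape and toy d_max", {
  m <- bead(c(0, 10), c(0, 0), c(0, 0))
  pr <- model_pr(m, unit_solvent(), bin = 1)
  expect_equal(pr$r[which.max(pr$p)], 10, tolerance = 0.5)
  expect_equal(pr$d_max, 10)
  expect_equal(pr$p[1], 0)

  # rejection-sampled uniform sphere: its p(r) is smooth, unlike the
  # shell-quantised lattice spectrum
  set.seed(42)
  xyz <- matrix(runif(3 * 12000, -30, 30), ncol = 3)
  xyz <- xyz[rowSums(xyz^2) <= 30^2, ][1:3000, ]
  cloud <- bead(xyz[, 1], xyz[, 2], xyz[, 3])
  pr_s <- model_pr(cloud, unit_solvent(), bin = 2)
  ref <- analytic_sphere_pr(30, n_r = 301)
  p_ref <- stats::approx(ref$r, ref$p, xout = pr_s$r, rule = 2)$y
  # L1 distance between normalised distributions (Monte-Carlo limited)
  expect_lt(pentasans:::.trapz(pr_s$r, abs(pr_s$p - p_ref)), 0.05)

  # the toy channel is built to GLIC-like dimensions, d_max ~ 110 A
  pr_t <- model_pr(toy_closed, unit_solvent(), bin = 2)
  expect_gt(pr_t$d_max, 100)
  expect_lt(pr_t$d_max, 120)
  expect_error(model_pr(toy_closed, unit_solvent(), bin = -1), "bin")
})

test_that("p(r) and I(Q) are mutually consistent transforms", {
  Q <- seq(0.01, 0.3, length.out = 40)
  direct <- debye_curve(toy_closed, unit_solvent(), Q, method = "exact")
  pr <- model_pr(toy_closed, unit_solvent(), bin = 0.05)
  via_pr <- pr_to_curve(pr, Q)
  # p(r) encodes the pair correlations; remove the flat self-term
  # from the direct sum before comparing shapes
  b <- effective_scattering_lengths(toy_closed, unit_solvent())
  pair_I <- direct$I - sum(b^2)
  r1 <- pair_I / pair_I[1]
  r2 <- via_pr$I / via_pr$I[1]
  expect_lt(max(abs(r1 - r2) / abs(r1)), 0.01)
})

test_that("I(Q), Rg and p(r) are invariant under rigid-body motion", {
  th <- 0.7; ax <- c(0.36, 0.48, 0.8)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  Rot <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  m2 <- toy_closed
  xyz <- coords(toy_closed) %*% t(Rot)
  m2$atoms$x <- xyz[, 1] + 5; m2$atoms$y <- xyz[, 2] - 3
  m2$atoms$z <- xyz[, 3] + 11
  Q <- seq(0.02, 0.3, length.out = 20)
  i1 <- debye_curve(toy_closed, unit_solvent(), Q, method = "exact")$I
  i2 <- debye_curve(m2, unit_solvent(), Q, method = "exact")$I
  expect_lt(max(abs(i2 - i1) / i1), 1e-6)
  expect_equal(model_rg(m2, unit_solvent()),
               model_rg(toy_closed, unit_solvent()), tolerance = 1e-6)
  p1 <- model_pr(toy_closed, unit_solvent(), bin = 1)
  p2 <- model_pr(m2, unit_solvent(), bin = 1)
  expect_equal(p2$d_max, p1$d_max, tolerance = 1e-6)
  expect_lt(max(abs(p2$p - p1$p)), 1e-6 * max(p1$p))
})

test_that("absolute-scale conversion applies the molecule number density", {
  Q <- seq(0.01, 0.1, length.out = 10)
  cur <- debye_curve(toy_closed, unit_solvent(), Q, method = "exact")
  abs_cur <- scale_to_absolute(cur, c_mg_ml = 2, mass = 180000)
  expect_true(abs_cur$absolute)
  expect_equal(abs_cur$I / cur$I,
               rep(2e-3 * 6.02214076e23 / 180000, length(Q)))
})
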