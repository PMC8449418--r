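# Synthetic ground truth: toy pentameric channels, analytic sphere
# oracles, and simulated two-detector-distance experiments with
# Q-dependent Gaussian noise.

# evaluate expr with a local RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a toy pentameric channel
#'
#' A deterministic C5-symmetric bead model standing in for a pentameric
#' ligand-gated ion channel: an extracellular domain (ECD) of bead
#' columns on a wide ring sitting on a transmembrane domain (TMD) of
#' four helix-like columns around a central pore. The conformational
#' parameter `u` interpolates the two gating motions: at `u = 0`
#' (closed-like) the ECD ring is expanded and the pore contracted; at
#' `u = 1` (open-like) the ECD contracts toward the pore axis while the
#' pore-lining column tilts outward. Default dimensions give a ~110 A
#' maximum extent, mimicking a ~180 kDa channel, and make the closed
#' and open curves differ measurably around Q of 0.10-0.12 A^-1.
#'
#' @param n_subunits number of subunits (default 5).
#' @param ecd_radius ECD ring radius at `u = 0`, Angstrom.
#' @param tmd_radius TMD pore radius at `u = 0`, Angstrom.
#' @param ecd_height,tmd_height domain heights, Angstrom.
#' @param spacing bead spacing along each column, Angstrom.
#' @param ecd_contraction fractional ECD radius decrease from u=0 to u=1.
#' @param pore_expansion fractional TMD pore radius increase from u=0 to u=1.
#' @param u conformation parameter in \[0, 1\].
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(n_subunits = 5, ecd_radius = 31, tmd_radius = 9,
                     ecd_height = 62, tmd_height = 30, spacing = 3.8,
                     ecd_contraction = 0.18, pore_expansion = 0.45, u = 0) {
  stopifnot(n_subunits >= 1, ecd_radius > 0, tmd_radius > 0,
            ecd_height > 0, tmd_height > 0, spacing > 0,
            u >= 0, u <= 1)
  structure(
    list(n_subunits = n_subunits, ecd_radius = ecd_radius,
         tmd_radius = tmd_radius, ecd_height = ecd_height,
         tmd_height = tmd_height, spacing = spacing,
         ecd_contraction = ecd_contraction,
         pore_expansion = pore_expansion, u = u),
    class = "toy_spec"
  )
}

#' Build a toy pentameric bead model
#'
#' Beads are pseudo-C-alpha carbons (atom name CA, zero implicit
#' hydrogens) so the model can be fed both to the forward-scattering
#' layer (uniform contrast) and to the elastic-network layer. The
#' membrane slab corresponds to the TMD z-extent.
#'
#' @param spec a `toy_spec`.
#' @return an annotated `atomic_model` with `tm_mask` set on TMD beads;
#'   attribute `n_tmd_beads` records the constructed TMD bead count.
#' @export
make_toy_pentamer <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  u <- spec$u
  r_ecd <- spec$ecd_radius * (1 - spec$ecd_contraction * u)
  r_pore <- spec$tmd_radius * (1 + spec$pore_expansion * u)
  z_tmd <- seq(-spec$tmd_height / 2, spec$tmd_height / 2, by = spec$spacing)
  z_ecd <- seq(spec$tmd_height / 2 + spec$spacing,
               spec$tmd_height / 2 + spec$ecd_height, by = spec$spacing)
  pts <- list()
  col_id <- 0L
  # each column is a tight helix (radius 1.5 A, 100 deg/bead) around
  # its own vertical axis, with a small deterministic radial/vertical
  # jitter: protein-like irregularity that avoids the collinear chains
  # and coplanar column ends that would give an elastic network
  # spurious zero modes. Helix phase and jitter are expressed in the
  # subunit's local frame, so C5 symmetry stays exact.
  col_at <- function(radius, angle_deg, z) {
    a <- angle_deg * pi / 180
    k <- seq_along(z)
    th <- a + (k - 1L) * 100 * pi / 180
    dr <- 0.6 * cos(2.3 * k + 1.3 * col_id)
    dz <- 0.7 * sin(1.7 * k + 0.9 * col_id)
    cbind((radius + dr) * cos(a) + 1.5 * cos(th),
          (radius + dr) * sin(a) + 1.5 * sin(th), z + dz)
  }
  add_col <- function(radius, angle_deg, z) {
    col_id <<- (col_id %% 9L) + 1L
    pts[[length(pts) + 1L]] <<- col_at(radius, angle_deg, z)
  }
  for (s in seq_len(spec$n_subunits) - 1L) {
    phi <- 360 / spec$n_subunits * s
    # ECD: a contiguous beta-sandwich wall (four columns spanning the
    # subunit arc so neighbouring subunits stay in Calpha contact)
    # plus an inner column toward the vestibule
    col_id <- 0L
    for (dphi in c(-27, -9, 9, 27)) {
      add_col(r_ecd, phi + dphi, z_ecd)
    }
    add_col(r_ecd - 8, phi, z_ecd)
    # TMD: pore-lining column, two peripheral helices bridging to the
    # neighbouring subunits, and an outer lipid-facing helix
    add_col(r_pore, phi, z_tmd)
    add_col(r_pore + 7, phi - 18, z_tmd)
    add_col(r_pore + 7, phi + 18, z_tmd)
    add_col(r_pore + 10, phi, z_tmd)
  }
  per_sub <- c(rep("ECD", 5L * length(z_ecd)), rep("TMD", 4L * length(z_tmd)))
  xyz <- do.call(rbind, pts)
  n <- nrow(xyz)
  domain <- rep(per_sub, spec$n_subunits)
  chain <- rep(LETTERS[seq_len(spec$n_subunits)],
               each = n / spec$n_subunits)
  model <- atomic_model(
    atoms = data.frame(
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      resname = "GLY",
      resno = stats::ave(seq_len(n), chain, FUN = seq_along),
      chain = chain, atom_name = "CA", occupancy = 1,
      stringsAsFactors = FALSE
    ),
    implicit_h = rep(0L, n), labile_h = rep(0L, n),
    label = sprintf("toy pentamer u=%.2f", u)
  )
  # slab spans the actual TMD bead extent (columns carry a small
  # vertical jitter, so use the realised coordinates)
  z_tm <- range(xyz[domain == "TMD", 3])
  model <- assign_membrane_slab(model, z_tm[1], z_tm[2])
  attr(model, "n_tmd_beads") <- sum(domain == "TMD")
  attr(model, "domain") <- domain
  model
}

#' Analytic sphere form factor curve
#'
#' `I(Q) = [3 (sin(QR) - QR cos(QR)) / (QR)^3]^2`, normalised to
#' `I(0) = 1`. Serves as a closed-form oracle for the Debye machinery.
#'
#' @param R sphere radius, Angstrom.
#' @param Q_grid momentum transfer grid, A^-1.
#' @return a `sans_curve`.
#' @export
analytic_sphere_curve <- function(R, Q_grid) {
  stopifnot(R > 0)
  if (any(Q_grid <= 0)) stop("Q must be > 0")
  x <- Q_grid * R
  amp <- 3 * (sin(x) - x * cos(x)) / x^3
  # series for small x, where the closed form cancels catastrophically
  small <- x < 0.01
  amp[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  scattering_curve(Q_grid, amp^2, meta = sprintf("analytic sphere R=%g", R))
}

#' Analytic sphere pair-distance distribution
#'
#' Closed form for a homogeneous sphere of radius R:
#' `p(r) = c r^2 (1 - 3r/(4R) + r^3/(16 R^3))` for `r <= 2R`,
#' normalised to unit integral.
#'
#' @param R sphere radius, Angstrom.
#' @param n_r grid size.
#' @return a `pair_distribution` with `d_max = 2R`.
#' @export
analytic_sphere_pr <- function(R, n_r = 201) {
  r <- seq(0, 2 * R, length.out = n_r)
  x <- r / R
  p <- r^2 * (1 - 0.75 * x + x^3 / 16)
  p[p < 0] <- 0
  pair_distribution(r, p, d_max = 2 * R)
}

#' Uniform-sphere bead model
#'
#' Cubic-lattice point cloud filling a sphere, as a unit-contrast
#' `atomic_model`; the standard numerical stand-in for the homogeneous
#' sphere when exercising the Debye machinery against the closed form.
#'
#' @param R radius, Angstrom.
#' @param spacing lattice constant, Angstrom.
#' @return an annotated `atomic_model` (carbon beads, no hydrogens).
#' @export
sphere_bead_model <- function(R, spacing = 2) {
  g <- seq(-R, R, by = spacing)
  xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
  xyz <- xyz[rowSums(xyz^2) <= R^2, , drop = FALSE]
  n <- nrow(xyz)
  atomic_model(
    atoms = data.frame(
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      resname = "GLY", resno = seq_len(n), chain = "A",
      atom_name = "CA", occupancy = 1, stringsAsFactors = FALSE
    ),
    implicit_h = rep(0L, n), labile_h = rep(0L, n),
    label = sprintf("sphere beads R=%g", R)
  )
}

#' Noise and acquisition specification for simulated experiments
#'
#' Q-dependent Gaussian noise emulating a two-detector-distance SANS
#' acquisition: `sigma(Q) = a I(Q) + b (Q/Q_max)^p max(I)`, so low-Q
#' points are signal-limited and high-Q points noise-limited.
#'
#' @param rel_sigma relative noise level `a` (default 0.01).
#' @param floor_sigma high-Q noise-floor coefficient `b` (default 0.02).
#' @param growth exponent `p` of the noise floor (default 1).
#' @param crossover Q splitting the two simulated detector distances,
#'   A^-1 (default 0.095, a paused-flow-style merge point).
#' @param overlap half-width of the simulated overlap window, A^-1.
#' @param seed RNG seed, recorded in outputs.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(rel_sigma = 0.01, floor_sigma = 0.02, growth = 1,
                       crossover = 0.095, overlap = 0.01, seed = 1L) {
  stopifnot(rel_sigma > 0, floor_sigma >= 0, growth > 0, crossover > 0,
            overlap >= 0)
  structure(
    list(rel_sigma = rel_sigma, floor_sigma = floor_sigma, growth = growth,
         crossover = crossover, overlap = overlap, seed = as.integer(seed)),
    class = "noise_spec"
  )
}

# sigma(Q) model shared by simulate_experiment
.noise_sigma <- function(truth, noise) {
  noise$rel_sigma * abs(truth$I) +
    noise$floor_sigma * (truth$Q / max(truth$Q))^noise$growth * max(abs(truth$I))
}

#' Simulate a two-detector-distance experiment
#'
#' Splits a noiseless truth curve into overlapping low-Q and high-Q
#' segments around the crossover, adds seeded Gaussian noise with the
#' sigma model of [noise_spec()], and returns both segments; the
#' reported sigma arrays are the generating ones. The global RNG state
#' is left untouched.
#'
#' @param truth a noiseless `sans_curve` covering both windows.
#' @param noise a `noise_spec`.
#' @return list with `low_q` and `high_q` `sans_curve`s.
#' @export
simulate_experiment <- function(truth, noise = noise_spec()) {
  stopifnot(inherits(truth, "sans_curve"), inherits(noise, "noise_spec"))
  if (min(truth$Q) >= noise$crossover || max(truth$Q) <= noise$crossover) {
    stop("truth curve does not cover both detector windows")
  }
  sig <- .noise_sigma(truth, noise)
  I_noisy <- .with_seed(noise$seed, truth$I + stats::rnorm(length(sig), 0, sig))
  lo <- truth$Q <= noise$crossover + noise$overlap
  hi <- truth$Q >= noise$crossover - noise$overlap
  if (sum(lo) < 2L || sum(hi) < 2L) {
    stop("truth curve does not cover both detector windows")
  }
  mk <- function(sel, tag) scattering_curve(
    truth$Q[sel], I_noisy[sel], sigma = sig[sel],
    meta = sprintf("simulated %s segment, seed %d", tag, noise$seed),
    absolute = truth$absolute)
  list(low_q = mk(lo, "low-Q"), high_q = mk(hi, "high-Q"))
}

#' Simulate a single merged noisy curve
#'
#' Convenience wrapper: noise on the full grid without the
#' detector split.
#'
#' @inheritParams simulate_experiment
#' @return a `sans_curve` with uncertainties.
#' @export
simulate_curve <- function(truth, noise = noise_spec()) {
  sig <- .noise_sigma(truth, noise)
  I_noisy <- .with_seed(noise$seed, truth$I + stats::rnorm(length(sig), 0, sig))
  scattering_curve(truth$Q, I_noisy, sigma = sig,
                   meta = sprintf("simulated, seed %d", noise$seed),
                   absolute = truth$absolute)
}

#' Linear combination of two curves
#'
#' `I = k I_A + (1 - k) I_B` on a common Q grid: the two-state mixture
#' model used to bound the open-state contribution.
#'
#' @param curve_a,curve_b `sans_curve`s on identical Q grids.
#' @param k fraction of state A, in \[0, 1\].
#' @return a `sans_curve`.
#' @export
mixture_curve <- function(curve_a, curve_b, k) {
  stopifnot(inherits(curve_a, "sans_curve"), inherits(curve_b, "sans_curve"),
            k >= 0, k <= 1)
  if (length(curve_a$Q) != length(curve_b$Q) ||
      max(abs(curve_a$Q - curve_b$Q)) > 1e-9 * max(curve_a$Q)) {
    stop("grid mismatch: curves must share a Q grid")
  }
  scattering_curve(curve_a$Q, k * curve_a$I + (1 - k) * curve_b$I,
                   meta = sprintf("mixture k=%.3f", k))
}
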