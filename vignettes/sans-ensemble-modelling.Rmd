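---
title: "Modelling SANS curves of a pentameric ion channel: forward model, ensemble fitting and landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SANS curves of a pentameric ion channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentasans)
```

## The problem

Small-angle neutron scattering (SANS) measures the orientationally
averaged intensity $I(Q)$ of a particle in solution as a function of
momentum transfer $Q = (4\pi/\lambda)\sin\theta$. For a membrane
protein measured in D$_2$O with match-out deuterated detergent, the
detergent belt is invisible and the signal comes from the protein
alone. The curves of two conformations of a pentameric ligand-gated
ion channel — a closed-like state with an expanded extracellular
domain (ECD) and a contracted pore, and an open-like state with the
opposite geometry — differ only subtly, in a window around
$Q \in [0.10, 0.12]$ Å$^{-1}$ corresponding to internal distances of
50–60 Å. Deciding which conformation, or which mixture of
conformations, a measured curve supports therefore needs a careful
forward model, error-weighted fitting, and an ensemble of candidate
intermediates rather than two crystal structures alone.

This package implements that entire chain: a Debye-equation forward
model with hydrogen–deuterium exchange bookkeeping, experimental-curve
reduction and Guinier/molecular-weight analysis, regularised indirect
Fourier transformation, single-structure and two-state mixture fitting
by reduced $\chi^2$, elastic-network interpolation of transition
pathways, and principal-component landscapes that correlate goodness
of fit with collective motions. A synthetic-data module generates toy
pentamers and simulated experiments with known ground truth, so every
stage is testable offline.

## The forward model

The scattered intensity of an atomic model is the Debye sum

$$I(Q) \;=\; \sum_{i}\sum_{j} b_i\,b_j\,
\frac{\sin(Q r_{ij})}{Q r_{ij}},$$

with per-atom effective scattering lengths

$$b_i = b_{\mathrm{heavy},i}
      + (n_{H,i}-n_{L,i})\,b_H
      + n_{L,i}\bigl[(1-f_i)\,b_H + f_i\,b_D\bigr]
      - \rho_s V_i .$$

Here $n_{H,i}$ is the number of hydrogens implicitly attached to heavy
atom $i$ (crystal structures carry none, so they are assigned from
per-residue templates at standard protonation), $n_{L,i}$ of which are
labile (bonded to N/O/S and hence exchangeable in D$_2$O);
$b_H = -3.739$ fm and $b_D = +6.671$ fm; $\rho_s$ is the solvent
scattering length density (computed from the D$_2$O fraction; pure
D$_2$O gives $6.36\times10^{10}$ cm$^{-2}$); and $V_i$ is the
displaced atomic volume (Fraser–MacRae–Suzuki values), giving the
excluded-volume term with an optional global scale factor.

### Exchange model

The exchanged fraction $f_i$ takes one of two values: a soluble-domain
fraction (default 0.90, reflecting incomplete exchange on the
~100-minute timescale of a chromatography-coupled measurement) and a
transmembrane fraction (default 0.0: hydrogens buried in the membrane
region are shielded from solvent and stay $^1$H). The membrane region
is a user-set z-slab, default thickness 30 Å, with the model oriented
membrane-normal along z; this replaces an external membrane-placement
service with a reproducible offline convention. Exchange kinetics are
deliberately reduced to these two scalars; per-residue kinetic
modelling is out of scope, and the two fractions are configurable per
pH condition. Low-pH protonation of selected acidic residues is
supported as a hydrogen-count override (`annotate_hydrogens(...,
protonate = c("E35", "H277"))`); it changes contrast bookkeeping only,
as no electrostatics enter the model.

### What is deliberately omitted

No hydration-shell term is added: with the detergent matched out and
the solvent pure D$_2$O, the protein-only approximation is the
baseline, and a constant-density shell would add a parameter the
synthetic tests cannot constrain. Instrumental resolution smearing and
X-ray form factors are likewise out of scope.

### Numerical evaluation

The exact Debye sum is $O(N^2)$ per $Q$ point and is used up to 5000
atoms. Above that a distance-histogram variant bins all pair
distances (default bin 0.5 Å). Two refinements keep the histogram
accurate: each bin is evaluated at its contrast-weighted mean distance
rather than its centre (exact for the discrete, shell-like distance
spectra of bead models), and a second-order term using the within-bin
variance corrects the residual curvature of $\sin(Qr)/Qr$. With these,
the histogram agrees with the exact sum to well under 0.5% for
$Q \le 0.5$ Å$^{-1}$, and a 14,000-bead sphere reproduces the analytic
sphere form factor to better than 1% out to $QR = 4$.

## Curve reduction and size analysis

`merge_curves` joins two detector-distance segments at a crossover
(e.g. 0.095 Å$^{-1}$ for a paused-flow configuration), fitting a
multiplicative factor on the overlap unless told to keep the absolute
scales; `subtract_constant` removes a flat background estimated from a
high-$Q$ window; `normalize_by_concentration` divides by the
concentration inferred from $A_{280}$ and a sequence-computed
extinction coefficient ($\varepsilon_{280} = 5500\,n_W + 1490\,n_Y +
125\,n_{SS}$).

Guinier analysis fits $\ln I$ against $Q^2$ by weighted least squares.
Two windows matter. The conventional experimental window extends to
$Q_{\max} R_g \approx 1.3$ (and published work on globular pentamers
has used ranges reaching $QR_g \approx 3$, which this package permits
but flags). For *noiseless model curves*, however, the truncation bias
of the Guinier approximation is measurable: for an ideal sphere the
quartic term of the form factor inflates the fitted $R_g$ by ~1.9% at
$Q_{\max}R_g = 1.3$. Oracle checks therefore evaluate the low-$Q$
expansion in its asymptotic regime, $Q_{\max}R_g \le 0.7$, where the
bias is below 0.5%. Fits beyond $Q_{\max}R_g = 1.5$ warn by default.

The molecular weight follows from the forward-scattering relation

$$M_w = \frac{N_A\, I(0)}{c\,(\Delta\rho\,\bar\nu)^2},$$

with $I(0)$ in cm$^{-1}$, concentration $c$ in g/cm$^3$, excess
scattering length density $\Delta\rho$ in cm$^{-2}$ and partial
specific volume $\bar\nu$ in cm$^3$/g, the latter computed by dividing
the model's displaced volume by its sequence mass (typical proteins
land at 0.70–0.80 cm$^3$/g).

The indirect Fourier transform (`ift_pr`) estimates $p(r)$ on
$[0, d_{\max}]$ by minimising $\chi^2 + \alpha \int p''(r)^2\,dr$
subject to $p \ge 0$ and $p(0) = p(d_{\max}) = 0$, solved as a
bound-constrained quadratic programme (L-BFGS-B with analytic
gradients). A constant intensity offset is co-fitted, absorbing
self-scattering and residual background that the $\mathrm{sinc}$ basis
cannot represent. When $\alpha$ is not supplied it is picked on a
log-spaced grid by the corner (maximum discrete curvature) of the
L-curve of $\log\chi^2$ against log roughness — a deterministic
stand-in for evidence-based selection.

## Fitting and mixtures

`fit_model` fits scale and constant background in closed form and
reports reduced $\chi^2$ with the degrees of freedom approximated by
the number of points — the convention used when comparing against
published goodness-of-fit values for this system; note it makes
$\chi^2$ slightly smaller than an $N-p$ convention. Negative fitted
scales are clamped to zero and signal a pathological model. Theory
curves are interpolated onto the data grid by cubic splines in
$\log I$ vs $\log Q$ (power-law segments are exactly linear there);
extrapolation is refused.

Two-state analysis scans $I_k = k I_A + (1-k) I_B$ over a $k$ grid
(default step 0.01), fitting each combination. Besides the best $k$ it
reports the *largest tolerated* fraction of state A: the largest $k$
whose $\chi^2$ does not exceed $\chi^2(k=0)$, refined by linear
interpolation between grid points. This is the quantity that bounds
how much open-state contribution a resting-condition curve admits.

## Transition pathways

Candidate intermediates are generated by elastic-network-driven
interpolation between two end states. A union network (springs present
within a 10 Å C$\alpha$ cutoff in either end state) carries
equilibrium lengths scheduled linearly in *distance space* from source
to target; after each schedule step the coordinates are relaxed by
stress majorisation (SMACOF). The Guttman-transform update was chosen
over explicit Brownian or gradient dynamics because it decreases the
stress monotonically with no step-size parameter, which makes the
pathway deterministic and robust; optional seeded thermal noise can be
added per step. Interpolating distances rather than Cartesian
coordinates keeps intermediates locally rigid (no linear-morph bond
compression), and running the scheme in both directions yields two
distinct pathways, 25 frames each by default, with the final frame
within 1 Å RMSD of the target. Full-atom models are rebuilt by
carrying each atom rigidly with its residue's C$\alpha$ — adequate at
SANS resolution, where side-chain detail is invisible.

Thermal-like diversity around each frame comes from
`nm_perturb_sample`: random excitation of the lowest normal modes of
the frame's anisotropic network model, with amplitudes
$\propto 1/\sqrt{\lambda_k}$ rescaled to a requested RMSD. A connected
network has exactly six zero modes; underbraced bead geometries can
have additional floppy mechanisms, which `enm_modes` detects and
skips rather than letting their vanishing eigenvalues dominate the
sampling. The bundled bead toys are coarser than real C$\alpha$
traces, so their mode analyses use a 12 Å cutoff; 10 Å remains the
default for protein models.

## The PC landscape

`build_landscape` performs PCA on C$\alpha$ Cartesian coordinates
(C$\alpha$ was chosen as the atom set; heavy-atom PCA differs only in
weighting and would not change the picture at this resolution). All
structures are aligned to their running mean by Kabsch superposition
until the mean converges, then the coordinate covariance is
eigendecomposed. Each component is oriented so that the structure with
the largest absolute projection projects positively — an arbitrary but
reproducible sign convention. `correlate_fit` summarises $\chi^2$
along a component with 20 equal-width bins (empty bins reported
missing), the minimum-$\chi^2$ bin, and a Spearman rank correlation.

When a reference set of experimental structures is unavailable
offline, the landscape is built from the pathway frames themselves;
the mathematics is identical and the first component then captures the
closed-to-open transition by construction.

## The synthetic twin system

`make_toy_pentamer` builds a deterministic C5-symmetric bead channel:
five subunits, each an ECD wall of bead columns on a wide ring over a
TMD of four helix-like columns around a central pore, ~110 Å tall to
match the real channel's $d_{\max}$. The gating parameter $u$ moves
the geometry between closed-like ($u=0$: ECD ring expanded, pore
contracted) and open-like ($u=1$: ECD contracted by 18%, pore expanded
by 45%); these amplitudes were set so that the two endpoint curves
differ measurably in the $Q \in [0.10, 0.12]$ Å$^{-1}$ window while
their radii of gyration differ by only ~2 Å, mirroring the real
system's subtlety at low $Q$. Columns carry a small helical twist and
a deterministic, C5-co-rotating jitter — protein-like irregularity
that also keeps the contact graph rigid (collinear bead chains would
give the elastic network spurious zero modes).

`simulate_experiment` emulates a two-detector-distance acquisition:
the noiseless truth is split into overlapping segments at a crossover
(default 0.095 Å$^{-1}$) and Gaussian noise is added with
$\sigma(Q) = a\,I(Q) + b\,(Q/Q_{\max})^p \max I$, defaults $a = 0.01$,
$b = 0.02$, $p = 1$, so low-$Q$ points are signal-limited and high-$Q$
points noise-limited as in real SANS. The reported uncertainties are
the generating ones, which is what makes $\chi^2$ calibration checks
exact. All generators are pure functions of their spec and seed and
leave the global RNG state untouched.

What the toys do *not* emulate: real secondary-structure packing,
side-chain-level contrast variation, detergent residues, aggregation
tails, instrument smearing, or inter-particle structure factors.
Passing tests on the toys therefore demonstrates the correctness of
the algorithms under the stated noise model, not the fidelity of any
particular biological conclusion.

## Problem sizes and runtime choices

The test and acceptance runs use: a 14,147-bead sphere (spacing 2 Å)
for the form-factor oracle; 560-bead toy pentamers; 400-point curves
for $\chi^2$ calibration; 200-point curves for mixture scans; 25
frames per pathway direction; and ensemble workflows of 50
conformations fitted with the histogram Debye method. These sizes keep
each full analysis in the minutes range on a single CPU while leaving
all tolerances comfortably met.

## A worked twin experiment

```{r example, eval = FALSE}
us <- solvent_spec(rho_solvent = 0)      # unit-contrast beads
closed <- make_toy_pentamer(toy_spec(u = 0))
open <- make_toy_pentamer(toy_spec(u = 1))

# simulate a paused-flow-style measurement of the closed state
Q <- seq(0.012, 0.3, length.out = 200)
truth <- debye_curve(closed, us, Q)
segs <- simulate_experiment(truth, noise_spec(seed = 1))
data <- merge_curves(segs$low_q, segs$high_q, crossover = 0.095)

# size analysis, candidate ranking, mixture bound
guinier_fit(data, q_range = c(0.012, 0.035))
run_single_fit(list(closed, open), data, us,
               labels = c("closed", "open"))$table
mixture_scan(debye_curve(open, us, data$Q),
             debye_curve(closed, us, data$Q), data)
```

## Known limitations

The excluded-volume treatment uses one global displaced-volume scale
rather than atom-type-specific fitting; absolute-scale comparisons to
real instruments additionally depend on calibration conventions not
modelled here. The exchange model's two fractions cannot reproduce
residue-level exchange kinetics. The pathway generator produces
plausible, locally rigid intermediates, not a thermodynamic ensemble —
its frames are seeds for fitting, and their $\chi^2$ ranking carries
no free-energy meaning. Mixtures beyond two states and Bayesian
ensemble reweighting are out of scope.
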