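---
title: "Methods and design notes for acdfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for acdfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdfret)
```

This vignette is the package's own account of the models it implements,
the tunable parameters that matter, the numerical choices made where the
literature protocol leaves the design open, and what the synthetic-data
tests do and do not establish.

## 1. Spectral FRET: the Ratio A model

A protein carrying intrinsic Trp/Tyr donors and a single genetically
encoded Acd acceptor is measured three times: emission under 280 nm
excitation (`F280`: donor emission + acceptor emission from both FRET and
direct excitation), emission under 370 nm excitation (`F370`: acceptor
only), and a donor-only control without the acceptor (`F280,NoTAG`). The
control is scaled onto the sample's donor band and subtracted; the
residual, divided pointwise by `F370` and averaged over the acceptor
band, is

$$\mathrm{Ratio\,A} = \frac{F_{280}}{F_{370}}
 = \frac{F_{280}^{direct}}{F_{370}} + \frac{F_{280}^{FRET}}{F_{370}},$$

and subtracting the free-acceptor value $\mathrm{Ratio\,A_0}$ (no donor,
hence direct excitation only) isolates the FRET-sensitized term, which is
proportional to the FRET efficiency. The method's assumptions: the
donor-only control has the same donor spectral shape as the sample; the
acceptor's emission shape is excitation-independent (so the ratio trace is
flat in wavelength); and direct excitation per acceptor is sample-independent
(so the free-acceptor Ratio A0 transfers). The per-wavelength ratio's
coefficient of variation is reported as `flatness`; a non-flat trace
signals contaminating fluorescence or detector nonlinearity.

Key parameters:

* **Averaging window** — 410–480 nm inclusive on the native 1 nm grid,
  the acceptor emission band. Configurable per call.
* **Donor scaling window and rule** — the protocol literature says only
  that the control is "scaled"/"normalized by the Trp/Tyr fluorescence";
  the rule is not printed. We default to matching trapezoidal *integrals*
  over 300–360 nm, which averages noise over ~60 points instead of
  trusting a single peak value; peak matching is available via
  `rule = "peak"`. This was a genuinely open design point.
* **Condition comparison test** — the significance marks in the
  literature do not state the test. Replicates here are paired by design
  (the same preparation measured apo and with Zn²⁺), so
  `compare_conditions()` defaults to a two-sided paired t-test with no
  multiple-testing correction (annotations are per construct); Welch and
  `p.adjust` methods are exposed. Identical apo/treated replicates give a
  zero-variance t statistic; that degenerate case is reported as p = 1
  (no evidence of change) rather than an error.
* **Reversibility** — with a chelator arm,
  `1 − |mean(rev) − mean(apo)| / |mean(treated) − mean(apo)|`, 1 meaning
  fully reversed.

## 2. Structure-based FRET prediction

Predictions start from a dimeric structural model (PDB or mmCIF). For a
fixed donor–acceptor distance $r$ the Förster relation gives
$E(r) = 1/(1 + (r/R_0)^6)$ with $R_0 = 23.5$ Å (Trp→Acd) and
$20.9$ Å (Tyr→Acd); the orientation factor $\kappa^2 = 2/3$ is absorbed
into these scalar radii, appropriate for mobile fluorophores.

**Rotamer ensembles.** Fluorophore position uncertainty is represented by
a weighted point cloud per site. Candidate conformers are built on an
idealized side-chain scaffold grown from the site's backbone (N, CA, C):
CB by ideal L-amino-acid geometry, then two rotatable bonds whose
dihedrals are sampled from $\{-60°, +60°, 180°\}$ (9 candidates). The
fluorophore reference point is the ring-system centroid — indole for Trp,
phenol for Tyr, the acridone tricycle for Acd — placed at a
label-specific distance from CG (2.4, 2.1 and 3.8 Å respectively).
Candidates whose reference point lies within 2.5 Å of any heavy atom
outside the site's own residue are rejected; survivors get uniform
weights (a Boltzmann-style soft weighting by worst overlap is available).
This is a deliberate desk-scale simplification of full rotamer-library
approaches: it is frame-covariant (predictions are invariant to
rigid-body motion of the model), fully auditable (the candidate set and
clash verdicts are returned, and the test suite checks them against a
brute-force oracle), and honest about not reproducing any particular
library's populations. An all-clash site raises an error suggesting a
looser cutoff rather than silently returning nothing.

**Multi-acceptor combination.** A dimer carries the acceptor in both
subunits. For one donor and independent acceptors in a fixed joint
conformer state, rate additivity gives
$E = \sum_a k_a / (1 + \sum_a k_a)$, $k_a = (R_0/r_a)^6$ — the standard
kinetic treatment of parallel transfer channels. The reported efficiency
is the expectation of $E$ over joint rotamer states (donor rotamer and
one rotamer per acceptor drawn independently by their weights), computed
by exhaustive enumeration when the joint state count is ≤ 10⁴ and by
seeded Monte Carlo otherwise; the two paths agree within Monte Carlo
error by construction and by test. Averaging $\langle E(r)\rangle$ rather
than evaluating $E(\langle r\rangle)$ is the physically correct choice
for a static ensemble and the default; the shortcut is exposed as
`average = "distance"` because which convention a given study used is
often unstated.

**Donor aggregation.** Per-construct efficiency is the weighted mean of
per-donor efficiencies with equal Trp/Tyr weights by default
(`donor_weights`), because relative donor contributions (quantum yields,
absorption at 280 nm) vary between systems and no universal weighting is
defensible; the weights are a single named argument. A native Trp/Tyr at
the substituted position is removed from the donor list — the acceptor
physically replaces it. `intrasubunit` mode restricts each donor to the
acceptor copy in its own chain; since removing acceptors can only lower
$\sum k$, `all_donors ≥ intrasubunit` holds identically, and the package
tests it as an invariant. Known limitation: donor ensembles are filtered
against the model *including* the native residue at the acceptor site, a
second-order inconsistency for donors adjacent to that site.

**Comparison with measurement.** Relative FRET is proportional to, not
equal to, efficiency, so `correlate_and_fit()` reports the sample Pearson
correlation plus the least-squares slope through the origin,
$m = \sum xy / \sum x^2$.

## 3. TCSPC reconvolution

The fit model is background plus the discrete convolution of the
(normalized, optionally time-shifted) IRF with
$\sum_k \alpha_k e^{-t/\tau_k}$. The default objective is weighted least
squares with Poisson weights $1/\max(c_i, 1)$ — standard, adequate at the
photon counts where lifetimes are quantitative, and directly
interpretable through the reduced chi-square, which the fit reports; a
Poisson deviance objective is available (`objective = "mle"`). The
optimization uses variable projection: only lifetimes (and optionally an
IRF shift) are handled by the nonlinear optimizer, while component
amplitudes and any free background are solved at each step by weighted
linear least squares with an active-set nonnegativity clamp. This removes
the classic amplitude/lifetime collinearity from the nonlinear search.
When pre-pulse bins exist (IRF mass < 1e-9 of peak), the background is
fixed to their mean instead of fitted. Reported amplitudes are fractional
photon contributions ($a_k = \alpha_k\tau_k / \sum\alpha\tau$), so the
mean lifetime $\sum a_k \tau_k$ is the intensity-weighted mean and
matches the photon-fraction convention of the simulator. A two-component
fit of one-component data is flagged `degenerate` (vanishing amplitude or
collapsing lifetimes) rather than hidden. Pile-up, afterpulsing, and
polarization are not modeled: the intended acquisition regime is
magic-angle detection at < 1% of the excitation rate, where these
corrections are negligible.

## 4. Flux traces

Traces are normalized as $(F(t) - F_{min})/(F_{max} - F_{min})$, which is
exactly invariant to instrument gain and offset. $F_{max}$ defaults to the
mean over the recorded baseline (trace start to the valinomycin event —
the protocol's 3 min baseline); $F_{min}$ to the mean over the last 30 s
of the trace, after CCCP. The protocol names these phases but not
averaging windows, so both windows are arguments. Quench extent is
1 minus the mean normalized value over the last 30 s before CCCP; the
rate comes from a single-exponential fit of the post-valinomycin segment,
with a log-linear fallback, and rates faster than twice the sampling rate
are reported at that resolution bound with `rate_censored = TRUE` (a step
quench has no resolvable rate at 5 s sampling).

## 5. The synthetic world

Generators emit exactly the file formats the pipeline reads and return
their ground truth; recovery tests compare only against that record.
Stated-world defaults: spectra on a 300–500 nm grid at 1 nm (matching
1 nm acquisition increments), donor band 335/25 nm, acceptor band
420/35 nm (broad enough that `F370` stays well above zero across the
whole averaging window, as a real acridone emission does), Ratio A0 0.5
and proportionality m = 0.8 (mid-range of plausibly observed ratios);
flux traces at 5 s sampling with a 3 min baseline; TCSPC histograms of
10⁶ photons on 0.04 ns bins with a 0.2 ns Gaussian IRF centered at 5 ns.
The donor-quench fraction defaults to the true efficiency so donor loss
and acceptor gain move together, as they must for a real FRET change.

Two deliberate idealizations:

* **Band truncation.** The donor band is zeroed above 405 nm and the
  acceptor band below 365 nm. Untruncated Gaussian tails leak ~10⁻⁶ of
  intensity across the analysis windows, which would break the exact
  noise-free identity `relative_fret = m·E` that the recovery criteria
  assert at 10⁻⁹. Real spectra overlap; the noise-robustness of the
  pipeline under that overlap is probed by the noisy scenarios, not by
  the exactness test.
* **Noiseless IRF.** The simulated IRF histogram is the analytic Gaussian
  profile rather than a Poisson draw: a measured IRF is acquired at high
  counts, and a noiseless reference keeps the decay fit's reduced
  chi-square interpretable as a test statistic.

Gaussian band shapes, a single exponential quench phase, and
translation/rotation-generated toy dimers emulate the *arithmetic* of the
pipeline, not photophysics: a green recovery test establishes that the
implementation computes its stated quantities correctly on data whose
truth is known, not that the model captures solvatochromism, rotamer
thermodynamics, or liposome heterogeneity.

## 6. Error handling conventions

All domain errors are classed conditions (`format_error`, `grid_error`,
`range_error`, `degenerate_spectrum_error`, `division_error`,
`pairing_error`, `statistics_error`, `site_error`,
`empty_ensemble_error`, `degenerate_distance_error`, `precision_error`,
`fit_error`, `annotation_error`, `degenerate_trace_error`,
`argument_error`), so callers and the CLI can distinguish input problems
(exit 1) from computation failures (exit 2). Argmax ties break toward the
smallest abscissa; negative intensities after blank subtraction are kept
to preserve noise statistics in downstream ratios; pointwise arithmetic
on mismatched grids resamples onto the coarser grid of the overlap only
when explicitly allowed, and extrapolation is always refused.

## 7. Known limitations

* The rotamer scaffold uses idealized geometry and a 3×3 chi grid; its
  distance distributions are coarser than library-based ensembles, so
  absolute predicted efficiencies carry systematic error even when the
  measured-vs-predicted correlation is informative.
* Donor–donor homotransfer and donor competition are ignored (donors are
  treated independently).
* No absolute FRET efficiencies from quantum yields or donor lifetimes;
  the spectral pipeline yields relative FRET only.
* Chromatogram support is peak location and trace arithmetic only — no
  peak deconvolution or area integration.
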