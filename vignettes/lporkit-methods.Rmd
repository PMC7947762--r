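---
title: "Methods and design notes for lporkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for lporkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lporkit)
```

Light-dependent protochlorophyllide oxidoreductases (LPORs) are
single-subunit NADPH-dependent enzymes that reduce the C17=C18 bond of
protochlorophyllide (Pchlide) to chlorophyllide (Chlide) only under
illumination. Their characterization combines several quantitative
measurements — spectral binding titrations, pulsed-light activity
assays, thermal unfolding, genome marker screens and tree-support
counts — and `lporkit` implements each of them as a tested, reusable
stage. This vignette explains the models behind each stage, the
parameters that matter, and the numerical choices made where the
methods literature leaves the details open.

## Spectral titration and the dissociation constant

The affinity of the ternary LPOR·NADPH·Pchlide complex is measured by
titrating a fixed pigment concentration $B$ (default 2 µM) with
increasing apo-protein $A$ (0–200 µM) at saturating NADPH, so protein
and cofactor act as a single binding partner. Binding red-shifts the
pigment's Q~y~ band (free ≈ 630 nm, bound several nm to the red), and
each measured spectrum is a mixture of the two species plus a turbidity
baseline

$$f(\lambda) = a\,\lambda^{-n} + y_0, \qquad n = 2,$$

which grows with protein concentration. `unmix_spectrum()` decomposes
one spectrum into nonnegative contributions of the free and bound
reference spectra plus this baseline, solved as a nonnegative least
squares problem (the sign-free offset is split into two nonnegative
columns). Because the references are spectra of the full pigment
concentration, the coefficients read directly as mole fractions.

Since pigment and protein concentrations are comparable, the free
ligand is depleted and the bound fraction follows the mass-action
quadratic ("tight-binding" form),

$$x_{AB}(A) = S_0 + (S_\mathrm{max}-S_0)\,
  \frac{K_d + B + A - \sqrt{(K_d + B + A)^2 - 4AB}}{2B},$$

implemented in `bound_fraction()` with the discriminant clamped at zero
so the stoichiometric limit is safe. `fit_kd()` fits the free and bound
mole-fraction profiles of a whole series jointly to this model with a
shared $K_d$, $S_0$, $S_\mathrm{max}$ by Levenberg–Marquardt
(`minpack.lm`), starting $K_d$ at the concentration of half-maximal
signal.

**Bound-reference refinement.** The pure bound spectrum is unknown a
priori and is initialized from the highest-concentration spectrum with
its fitted scatter removed. That initial reference still contains a
free-pigment admixture of $1-f_\mathrm{max}$, where $f_\mathrm{max}$ is
the true bound fraction at the top of the titration. The admixture is
exposed by the fitted plateau: writing the initial reference as
$(1-\varphi)\,S_\mathrm{bound} + \varphi\,S_\mathrm{free}$, the bound
coefficient of each mixture becomes $f/(1-\varphi')$-scaled and the
extrapolated plateau fits to $S_\mathrm{max} = 1/(1-\varphi) > 1$, so

$$\varphi = 1 - 1/S_\mathrm{max}.$$

`fit_kd()` subtracts $\varphi$ of the free reference, renormalizes, and
repeats unmixing and global fitting until the $K_d$ estimate is
stationary (relative tolerance `1e-4`, at most 10 rounds). After
convergence the mole fractions span 0 to 1 and the refined bound
spectrum is returned. This is the unique linear correction with that
property: a reference contaminated by a known 20% free admixture yields
$S_\mathrm{max} = 1.25$ and a recovered $\varphi = 0.200$ exactly (see
`tests/testthat/test-binding.R`). Note that the plateau is *greater*
than 1 for a contaminated reference — a plateau below 1 would instead
indicate an over-corrected reference, which the same formula handles
with $\varphi < 0$.

The standard error on $K_d$ is the asymptotic (Jacobian-based) error of
the Levenberg–Marquardt fit. Published "±" values on binding constants
are often replicate standard deviations instead; the two are not
comparable and `lporkit` makes no claim to reproduce published error
bars. Scatter parameters are per-spectrum (each sample has its own
turbidity), not shared.

```{r}
ser <- sim_titration(40, cfg = sim_config(seed = 1, noise_sd = 0.002))
fit_kd(ser)
```

## Pulsed-illumination kinetics

Activity assays illuminate the sample in cycles (default 1 s light /
11 s dark; 6 s/12 s for weak enzymes) while product absorbance at
672 nm is recorded. Frames recorded during a pulse carry broadband
stray-light artifacts; `filter_illumination_events()` removes frames
flagged by the acquisition mask or deviating from a 5-point running
median by more than 0.1 AU (configurable). A running median is used
because a spike must not drag its clean neighbours over the threshold.

`initial_rate()` regresses A672 against cumulative illumination time —
the natural abscissa for a strictly light-driven enzyme — over the
longest initial window that is still linear: the longest prefix with
$R^2 \ge 0.99$ (minimum 4 points), further trimmed from the tail while
the last point's residual exceeds 3× the RMSE of the remaining window.
The trim matters on traces that saturate from substrate depletion:
without it, the longest high-$R^2$ prefix swallows part of the plateau
and biases the slope by a few percent; with it, the noiseless bias is
below 0.1%. Traces where no prefix is acceptably linear fall back to
the first 4 points with an explicit flag.

Specific activity follows Beer–Lambert with
$\varepsilon_{672} = 69{,}950\ \mathrm{M^{-1}cm^{-1}}$: 1 µM/min of
product over a 1 cm path is 0.06995 AU/min, and one unit (U) converts
1 µmol substrate per minute. pH and temperature optima are summarized
by `optimum_and_range()`: the optimum is the argmax (ties resolve to
the midpoint of the tied set) and the reported range is the total width
where the piecewise-linear interpolant stays at or above 80% of the
maximum; profiles still above threshold at a boundary are flagged
truncated. Substrate preference between monovinyl and divinyl pigment
forms (`mv_dv_preference()`) is the larger-over-smaller activity ratio
rounded half-up to one decimal, with a preference called only above
1.5-fold.

## Thermal unfolding

Nano-DSF reports intrinsic tryptophan fluorescence at 350 and 330 nm
along a thermal ramp; the unfolding readout is the ratio F350/F330 and
the melting temperature is the peak of its first derivative.
`melting_temperature()` smooths the ratio with a Savitzky–Golay filter
(local quadratic, default 9 points), differentiates by central
differences, smooths the derivative once more, and refines the peak
with a parabola fitted over the contiguous top of the peak (points at
or above 60% of the maximum). The two-state derivative peak is broad
and nearly flat near its top, so a three-point parabola at the argmax
inherits the full grid-level noise (errors above 1 °C at realistic
noise), while the peak-top fit averages it away: over 50 simulated
ramps at default noise the maximum error is below 0.3 °C, and a
noiseless sigmoid is recovered to 0.01 °C. A transition is only
reported when the smoothed ratio changes by at least `min_delta`
(default 0.01) and the derivative peak stands at least 3× above the
ramp-average slope — a purely linear drift has zero prominence by
construction and is rejected. Non-uniform temperature grids are
handled by explicit local quadratic fits.

## Genome markers and the AAPB rule

Aerobic anoxygenic phototrophic bacteria (AAPBs) are diagnosed from
marker presence/absence: the three dark-operative oxidoreductase
subunits (BchB, BchL, BchN) and a type II reaction center (PufL, PufM)
indicate anoxygenic phototrophy, at least one oxidative cyclase (AcsF
or BchE) indicates an (semi)aerobic chlorophototroph, and possession of
*both* Calvin-cycle markers (RuBisCO large chain and
phosphoribulokinase) disqualifies. `call_aapb()` evaluates

`(BchB & BchL & BchN) & (PufL & PufM) & (AcsF | BchE) & (!RuBisCO | !PRK)`

and records each clause outcome so a call can be audited. The
Calvin-cycle clause reads "lacks RuBisCO and/or PRK" as a disjunction
(only both-present disqualifies); the strict both-absent reading is
available via `rubisco_mode = "both_absent"`. Presence itself comes
from profile-HMM search hits (`read_hmm_tblout()`,
`presence_matrix()`): a marker is present when at least one hit reaches
its model's curated trusted bit-score cutoff, with an e-value ≤ 1e-5
fallback for models without one. Curated trusted cutoffs are bit
scores, not e-values; both gates are explicit and configurable.

## Tree support and consensus

Support statements of the form "the clade clusters in 83 out of 100
trees" are counts of unrooted monophyly over a tree collection. All
trees are unrooted on load; a taxon set is monophyletic when its split
against the remaining taxa corresponds to an edge
(`is_clade_monophyletic()`), with splits canonicalized on the side not
containing the alphabetically first taxon. `majority_rule_consensus()`
tallies splits over the collection and keeps exactly those occurring in
more than the threshold fraction (strict majority, ties excluded);
for thresholds ≥ 0.5 the retained splits are pairwise compatible and
assemble into a unique, generally multifurcating tree annotated with
split frequencies. The construction is cross-checked in the test suite
against an edge-removal oracle on every unrooted topology with up to 7
leaves and against `ape::consensus()`.

## SAXS and sequence utilities

Molecular masses from small-angle scattering use the standard rules of
thumb: Porod volume (Å³) / 1.7 → Da, and the excluded volume of a
filtered dummy-atom model / 2 → Da. `guinier_rg()` estimates the radius
of gyration by iteratively fitting $\ln I = \ln I_0 - R_g^2 q^2/3$ on
the largest low-q window with $qR_g \le 1.3$, then shrinks the window
while a statistically significant $q^4$ term biases the fitted slope by
more than 1% — compact globular form factors (e.g. a hard sphere)
deviate from the Guinier law inside $qR_g \le 1.3$, and without the
guard the sphere $R_g$ is overestimated by ~1.8%; with it the error is
below 0.5% while ideal Guinier data remain exact to machine precision.
Aggregation is flagged when the low-q half of the final window fits a
distinctly (>15%) larger $R_g$ than the high-q half. Composition-based
parameters (`protein_params()`) use 5,500/1,490/125 M⁻¹cm⁻¹ for
Trp/Tyr/cystine at 280 nm; the default cysteine convention is
all-reduced (reducing assay buffers), switchable to all-cystine.

## The synthetic-data module

The raw study inputs (spectra, traces, scans) are not deposited, so
every generator produces the corresponding input class with known
ground truth:

* `sim_titration()` — Gaussian Q~y~ bands (free at 630 nm, bound
  red-shifted by +8 nm, σ = 9 nm, 0.03 AU/µM), exact mass-action bound
  fractions from an equilibrium root-finder that is independent of the
  closed-form model it is used to test, λ⁻² scatter scaling linearly
  with protein concentration (up to 10⁴ AU·nm² ≈ 0.025 AU at 630 nm),
  grid 620–720 nm / 1 nm, Gaussian noise 0.002 AU.
* `sim_photoconversion()` — product growing linearly with cumulative
  light time, hard saturation after a configurable converted fraction
  (default 50% of 3.5 µM substrate), +0.5 AU broadband artifacts on
  illuminated frames, 1 Hz sampling.
* `sim_dsf()` — logistic two-state ratio curve with its inflection
  exactly at $T_m$ (steepness 2.5 °C, baselines 0.80/1.10), grid
  15–85 °C in 0.25 °C steps (the instrument ramp is finer, ~0.03 °C;
  0.25 °C keeps simulated traces light and is still far below the
  transition width), ratio noise 0.002.
* `sim_marker_table()` — AAPB, oxygenic and non-phototroph archetype
  rows with retained labels; AAPB rows draw their cyclase and
  (incomplete) Calvin patterns randomly so the rule's disjunctions are
  exercised.
* `sim_tree_set()` — exactly `round(frequency × n)` trees containing
  the clade; the rest break it by a verified leaf swap.

All generators consume a `sim_config(seed, noise_sd, grid)` and draw
from R's default Mersenne-Twister stream seeded per call, restoring the
caller's RNG state, so a seed fully determines a data set. Noise
levels are plausible bench values chosen once (instrument noise is not
published); they are parameters, not fitted quantities.

**What the generators do not emulate:** correlated (pink) instrument
noise, wavelength calibration drift, non-Gaussian lineshapes,
temperature-dependent baselines in DSF beyond a linear channel drift,
fragmentary genomes (markers are noiseless presence/absence), and
branch-length heterogeneity (topologies only). Passing recovery tests
on this synthetic data therefore demonstrates correctness of the
estimators under the stated models, not robustness to every real-world
artifact.

## Problem sizes and degenerate inputs

The test suite and the acceptance script use 41-point titrations
(0–200 µM in 5 µM steps, 101 wavelengths), 100 noisy titration
replicates across $K_d \in \{2, 7, 40, 105\}$ µM, 50-ramp DSF
recovery at two midpoints, the full 2⁹ marker truth table, 1,000
simulated genomes, every unrooted topology with ≤ 7 leaves (945 at
n = 7) and 100-tree support sets. These sizes make every property
exhaustive or statistically stable while keeping a full run in well
under a minute per stage.

Degenerate inputs are first-class: titrations without curvature raise
an identifiability error rather than returning a meaningless $K_d$;
flat or linear DSF traces raise a no-transition error; an all-flagged
time course, disjoint wavelength ranges, empty tree sets and
non-positive Guinier slopes are all explicit errors; boundary-truncated
optimum ranges and collinear unmixing references are flagged rather
than silently accepted.
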