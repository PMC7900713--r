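---
title: "Models and methods behind glucoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glucoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glucoscope analyzes single-cell glucose metabolism read out by a ratiometric
FRET biosensor: per-cell acceptor/donor emission ratios from two-channel
time-lapse microscopy, their kinetic decomposition into consumption and
uptake rates, heritability of metabolic state across divisions, single-cell
dose-response classification, spatial profiling of wounds and tumors, TCSPC
fluorescence-lifetime maps, and ¹³C label-incorporation from GC-MS
mass-isotopomer distributions. Because no imaging data are deposited for this
class of experiment, every stage is validated by parameter recovery on a
synthetic-data generator whose ground truth is recorded; this vignette
explains the models, the tunable parameters, and the design choices, and is
explicit about what the synthetic validation does and does not show.

## The biosensor model

The sensor maps intracellular glucose G (mM) to an emitted acceptor/donor
ratio through a Hill curve

$$R(G) = R_{\min} + (R_{\max} - R_{\min})\,\frac{G^h}{K_d^h + G^h},$$

with defaults $R_{\min} = 1$, $R_{\max} = 3$, $K_d = 0.6$ mM, $h = 1$.
A hyperbolic (h = 1) form is the standard behavior of periplasmic
binding-protein sensors, and a Kd in the high-micromolar range matches the
sensors used for intracellular glucose; a sensor's effective Kd and dynamic
range in ratio units are construct- and instrument-specific, so these
defaults are placeholders that every generator and analysis accepts as
configuration (`biosensor_model()`). None of the analyses depend on their absolute values:
the quantification stage is ratio-based, the kinetics are slopes in ratio
units, and the classification stages are rank- or threshold-based on
normalized shifts.

## Glucose balance and the wash-out/wash-in decomposition

Intracellular glucose follows

$$\frac{dG}{dt} = V_{up}\,\frac{G_{ext}(t)}{K_{up}+G_{ext}(t)}
  \;-\; V_{con}\,\frac{G}{K_m + G},$$

i.e. media-dependent saturable transport minus Michaelis–Menten consumption.
$K_{up} = 1.7$ mM is the canonical GLUT1 transport constant; $K_m = 2$ mM is
deliberately set above the operating glucose range (≈0.1–1.2 mM here) so that
wash-out decays are close to single-exponential — the experimentally observed
shape, and the reason a one-phase decay fit is the right summary. The
wash-out/wash-in schedule is the classic one: 25 mM from 0, 0 mM at 10 min,
25 mM at 40 min, imaged every 30 s.

The kinetics stage is purely operational and mirrors how such data are
analyzed:

* **consumption** = −(OLS slope of ratio vs time) over the 3 minutes
  following wash-out (the "initial slope" window; length and estimator are
  configurable, and a two-point difference mode exists for exact-replication
  studies);
* **refill slope** = OLS slope over the 3 minutes following wash-in;
* **uptake** = consumption + refill slope, exactly — the cell keeps consuming
  while it refills, so the refill slope understates transport by the
  consumption rate. This identity holds to machine precision for every cell
  by construction.
* **one-phase decay fit** $y = \mathrm{plateau} + \mathrm{span}\,
  e^{-k(t-t_0)}$ with $t_{1/2} = \ln 2 / k$, Levenberg–Marquardt from
  endpoint/log-slope initial guesses, parameter tolerance 1e-8. The plateau
  is free, not pinned to the 0 mM floor.

The generator records, per cell, the model-implied instantaneous signal
rates at the two media switches (the sensor-gain-weighted fluxes), which is
what the window estimators target. Recovery on the synthetic cohort is
asserted two ways: the fitted k agrees with an independent fixed-step RK4
integration (100× finer step) to ~1e-8 noise-free and ~2% (median) at noise
SD 0.02; and the estimated rates rank-correlate with the generating truth at
ρ ≥ 0.9. Cells at steady state necessarily have consumption flux equal to
uptake flux, so the generator's high-state cells — parameterized to sit at
higher steady ratios — also consume and import faster, reproducing the
empirical coupling between steady-state signal and flux.

## Heritability and lineage statistics

The lineage generator gives every founder a standardized latent glycolytic
state drawn from a bimodal high/low mixture (standardized to unit variance so
inheritance stays stationary). At division the track ends and two daughters
begin, each with

$$s_{child} = \rho\, s_{parent} + \sqrt{1-\rho^2}\,\varepsilon,
 \qquad \varepsilon \sim N(0,1),$$

so parent–daughter correlation is ρ and grandparent–granddaughter ρ² — an
AR(1) across generations, which reproduces a *declining* correlation with
generational distance — the qualitative signature such experiments show —
without claiming a mechanism. The
emitted ratio is a linear map of the state (mean 1.8, SD 0.25 ratio units)
plus a slow Ornstein–Uhlenbeck within-cell fluctuation (SD 0.03, τ = 60 min)
and frame noise (SD 0.02); the lineage scenario runs at constant 25 mM, so
the ODE above is not involved. Cell cycles are Gamma(shape 40) with mean
1/division_rate (default 18 h, CV ≈ 16%), and division events are snapped to
the 5-min imaging grid because mitoses are observed at frames.

Analysis mirrors the experimental procedure: traces are relabeled so each
founder's first mitosis is T = 0 (`synchronize_to_mitosis()`, with
sample-count conservation), founders are binned by their ratio at mitosis
and each bin's mean/variance trace pools all progeny
(`binned_cohort_traces()`), and ancestor–descendant Pearson correlations use
a per-cell summary ratio (mean over the 2 h before division; the choice of
summary statistic is genuinely open, so it is configurable).
Both daughters contribute pairs, as lineage plots include all progeny; an
`one_per_family` option subsamples independent pairs. Sibling sharing of the
parent inflates the Monte-Carlo variance of pooled correlations by roughly
√2, so the recovery analysis runs 500 founders (~3,900 parent–daughter and
~2,900 grandparent pairs), which puts the Monte-Carlo error of r near 0.02 —
comfortably inside the ±0.05 / ±0.07 recovery bands for ρ and ρ².

Sorted-population relaxation (`return_to_mean()`) takes daily population
medians of a sorted subpopulation, subtracts the global reference, and fits
an exponential convergence; the generator uses an OU state with configurable
relaxation time, and asymmetric high-vs-low relaxation enters the synthetic
study as two different time constants.

## Dose–response classification and refractory cells

The stepped-dose schedule is 0, 0.05, 0.1, 0.5 µM at 0, 1, 2, 3 h; each
step's ratio is the mean of frames within ±5 min of the step's assay time
(just before the next step), and shifts are baseline-normalized,
$(R_i - R_0)/R_0$ (an absolute mode exists). Classification: **strong** if
the shift at the lowest non-zero dose is already ≤ −0.2; **non** if the final
shift stays above −0.05; **weak** otherwise. Class boundaries are inherently
study-specific; these defaults separate the generated classes cleanly and
are exposed in the interface.

A cell is **refractory** when its ratio at the maximal dose is strictly above
the median of the untreated control population. This is an operational,
median-referenced definition, and the generator records ground truth in the
same operational sense: the per-cell flag is whether the *noise-free* final
ratio exceeds the analytic control median. The `refractory_fraction`
parameter controls a constitutively high subpopulation (baseline drawn from
the upper 30% tail, no dose response) that always satisfies it; in addition,
a non-responder whose baseline happens to lie above the control median
genuinely "remains above the median" and is part of the truth. Any
median-referenced definition has this property — two samples from the same
distribution split ~50/50 (the package asserts 40–60% at n = 500) — so a
truth channel that ignored it could never match the measured fraction.

## Spatial profiling

The re-slice-along-outline procedure used for tumor quantification (circle
the region, straighten, sum-project, divide acceptor by donor) is
implemented as an equivalent distance-transform banding: every region pixel
gets its Euclidean distance to the outline (inward positive), distances are
binned every 100 µm (50 µm mode for stain profiles), and each band's FRET is
the **ratio of sums** — channel intensities summed over the band first, then
divided — exactly the statistic the sum-projection produces. A brute-force
pixel-loop oracle enforces the equivalence in the tests, and the banding is
invariant under image rotation for circular regions. Regions that fill the
whole frame take the image border as their outline. Microns-per-pixel is a
required argument with no default.

Scratch kymographs locate the wound edge per frame (first cell-occupied
column; the wound is the cell-free region of the occupancy mask), bin cell
pixels by distance from the current edge, and average the ratio per
(distance band, time bin). A static field yields a time-constant kymograph
to machine precision. Wound closure is
$100\,(A_{0h} - A_{24h})/A_{0h}$ on the cell-free area; negative closure is
reported but flagged. The scratch generator produces an exponential
edge gradient (default length scale 200 µm, the typical width of the
high-glucose border layer that forms at a fresh wound edge), which the
profile fit recovers within 10% under Poisson noise.

## FLIM

TCSPC decays (256 bins over a 12.5 ns window, matching an 80–90 MHz
excitation period) are modeled per pixel as

$$m(t) = \mathrm{scale}\cdot\big[\mathrm{IRF} \circledast
 (a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2})\big] + \mathrm{background},$$

fitted by Poisson-weighted (Neyman, counts+1) least squares. The pipeline is
smooth (3×3 spatial averaging with edge renormalization) → strict mask
(integrated counts **> 100** photons; exactly 100 is excluded) → per-pixel
fit. Initial guesses are deterministic and data-driven: background from the
dimmest 5% of bins, the long lifetime from the late-tail log-slope, the
short lifetime from the early post-peak slope; lifetimes are reported sorted
with the amplitude-weighted mean $\bar\tau = a_1\tau_1 + a_2\tau_2$. A
degenerate fit (τ₁ ≈ τ₂ within 5%) is flagged as effectively
mono-exponential. An IRF time-shift parameter is implemented for misaligned
measured IRFs but defaults to off: when the IRF is acquired under the same
conditions as the decay (as with a scatterer reference) it is already
aligned, and a free shift only inflates the variance of $\bar\tau$ — at 10⁴
photons the per-pixel spread of $\bar\tau$ is intrinsically a few percent
(bias < 2% over repeated draws at 10⁵ photons), which is why maps are read
through medians and the 3×3 binning.

The convolution is an explicit O(n²) causal discrete convolution (n = 256 is
small); an independent double-loop oracle checks it to 1e-10.

## Isotope correction

For an n-carbon skeleton at natural ¹³C abundance q (default 0.0107, the
standard isotopic constant), column j of the correction matrix is the
binomial mass distribution of the n−j remaining ¹²C positions; observed =
M · true. Correction solves the system by non-negative least squares and
renormalizes (negative components are impossible by construction of NNLS;
pre-clip values are returned). Percent labeled is 100·(1 − M+0) of the
corrected distribution, refusing uncorrected input unless overridden. Only
the carbon skeleton is corrected; derivatization-atom corrections are out of
scope. The generator labels each tracer-accessible carbon independently with
probability p and applies natural abundance to the remaining positions, so
percent labeled has the closed form 100·(1 − (1−p)ⁿ) used in recovery tests.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes simulate → quantify → kinetics inside a run
directory, writes a manifest with MD5 checksums, and derives per-stage seeds
as `seed + 1000 * stage_index` so stages can be rerun independently;
identical config + seed reproduces identical checksums. Image stacks are
written as multi-page TIFF: 16-bit for label masks (bit-exact round trip)
and 32-bit fixed point scaled by 2⁻¹⁶ for intensities (round-trip error
below one part in 2³¹ of full scale — the TIFF writer stores 32-bit samples
as integers in [0, 1]).

Problem sizes used throughout the validation are chosen to make Monte-Carlo
error small relative to each tolerance while keeping a full run on a laptop
in a few minutes: 200-cell wash-out cohorts at 30-s sampling, 500-founder
lineage cohorts over 3,000 min at 5-min intervals for the heritability
recovery (170 founders in the narrative driver), 600-cell dose cohorts with
a 300-cell control, 2,000 null simulations for the KS type-I check, and
small (≤ 20×20) lifetime maps — a full 256×256 map is a production-scale run
(hours), not a validation run.

## What the synthetic validation shows — and what it does not

Passing recovery tests demonstrates that each estimator recovers the
quantity it defines, under the generator's assumptions: disk-shaped,
well-separated, slowly moving cells; Gaussian or Poisson noise; exponential
gradients; AR(1) inheritance; binomial labeling. Real data violate several
of these — irregular morphology and touching cells (practitioners often
fall back to manual segmentation), bleed-through and photobleaching
(explicit non-goals),
non-exponential wash-out kinetics under transporter regulation, cell-cycle
correlated states, and detector pile-up in TCSPC. Results on real images
therefore depend on segmentation and background quality in ways these tests
cannot certify; the tests certify the computational chain, not the optics.

Known limitations: tracking is nearest-centroid with one-to-two division
handling and is validated only on well-separated cells; the refractory truth
is median-referenced by definition (see above); the bi-exponential fit at
low photon counts has intrinsic variance near the information limit, so
single-pixel lifetimes should be read through the map's median statistics.
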