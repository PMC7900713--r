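# glucoscope

Single-cell analysis of glucose metabolism imaged with a ratiometric FRET
biosensor. Cancer cell populations are metabolically heterogeneous even under
uniform culture: some cells run high glycolytic flux with high intracellular
glucose, others lean on mitochondrial metabolism — and the state is heritable
across divisions, spatially patterned in wounds and tumors, and unevenly
responsive to pathway inhibitors. glucoscope implements the full
computational chain for studying this with a glucose FRET sensor, for
imaging labs and computational biologists who need the quantification steps
as tested, reusable functions rather than ad hoc scripts:

* **FRET quantification** — per-cell acceptor/donor ratios (ratio of
  background-subtracted channel means) from two-channel stacks and label
  masks; Otsu segmentation; nearest-centroid tracking with division
  detection; quartile state calls; two-sample Kolmogorov–Smirnov comparison
  of ratio distributions.
* **Kinetics** — wash-out/wash-in decomposition: consumption = −initial
  slope after the switch to 0 mM glucose, uptake = consumption + refill
  slope after return to 25 mM (exact identity), plus the one-phase decay fit
  `y = plateau + span·e^(−k t)` with `t½ = ln 2 / k`, and 10-h trace
  stability statistics.
* **Lineage heritability** — traces relabeled to each founder's first
  mitosis at T = 0, cohort bins by the ratio at mitosis, and
  ancestor–descendant Pearson correlations; under AR(1) inheritance with
  correlation ρ, parent–daughter r ≈ ρ and grandparent r ≈ ρ².
* **Dose–response** — per-step normalized FRET shifts under stepped
  inhibitor doses (0, 0.05, 0.1, 0.5 µM at hourly steps), non/weak/strong
  responder classes, and refractory cells (final ratio above the untreated
  control median).
* **Spatial** — wound-edge kymographs, percent wound closure, and tumor
  center–periphery profiles: distance-to-outline bands every 100 µm with
  ratio-of-sums FRET and nuclei density.
* **FLIM** — per-pixel bi-exponential TCSPC fits with a measured IRF
  (`irf ⊛ (a₁e^(−t/τ₁) + a₂e^(−t/τ₂))`, Poisson-weighted), 3×3 spatial
  binning, strict >100-photon masking, amplitude-weighted mean lifetime
  maps (FRET shortens the donor lifetime).
* **Isotopes** — binomial natural-abundance correction of mass-isotopomer
  distributions (NNLS) and percent of the pool carrying ≥1 ¹³C.
* **Synthetic data** — generators for every input above with recorded ground
  truth, so the whole chain is validated by parameter recovery.

The repository is organized as an analysis workflow: all computation lives in
the package (`R/`), and the numbered scripts under `analysis/` are thin
narrative drivers that write tables under `results/`.

## Worked example

Simulate a 200-cell wash-out/wash-in experiment (25 mM → 0 mM at 10 min →
25 mM at 40 min, imaged every 30 s, ratio noise SD 0.02) and decompose each
cell's kinetics:

```r
library(glucoscope)

cfg <- scenario_config(
  n_cells = 200, duration = 70, frame_interval = 0.5,
  glucose_schedule = data.frame(time = c(0, 10, 40), glucose_mM = c(25, 0, 25)),
  noise_sd = 0.02, seed = 1)
sim <- simulate_washout_cohort(cfg)
kin <- cohort_kinetics(sim$traces, washout_time = 10, washin_time = 40)
m <- merge(kin, sim$truth[, c("cell_id", "state")], by = "cell_id")
aggregate(cbind(consumption, uptake) ~ state, m, median)
```

Running `Rscript analysis/02_kinetics.R` prints:

```
n = 200 cells; median t1/2 of the glucose drop: 5.2 min
rank correlation with generating truth: consumption 0.914, uptake 0.986
uptake = consumption + refill holds to 5.6e-17
  state consumption    uptake
1  high  0.09078745 0.3344614
2   low  0.05341392 0.1257517
```

Half the signal decays in ~5 min after glucose removal; the estimated rates
rank-match the generating truth, and high-glucose cells consume (0.091 vs
0.053 ratio-units/min) and import glucose faster than low-glucose cells —
high steady-state glucose reflects fast turnover, not slow use. The other
drivers follow the same pattern: `03_heritability.R` recovers ρ from lineage
correlations (r declining to ≈ρ² across two generations), `04_dose_response.R`
classifies 600 dosed cells at 100% agreement with truth and estimates the
refractory fraction (23.2%, 95% CI 19.8–26.8%, against a generating 24.0%),
`05_spatial.R` fits a 201 µm length scale to a generated 200 µm wound-edge
gradient, and `06_flim.R` maps a two-region lifetime field (2.50 vs 1.47 ns
fitted against 2.52/1.49 ns truth).

## Layout

```
R/                  package code: one file per stage (simulate_*, fret_quant,
                    kinetics, lineage, dose_response, spatial, flim, isotopes,
                    io, pipeline)
analysis/01..07_*.R narrative drivers writing results/ tables
scripts/acceptance.R  end-to-end recomputation of the headline numbers
tests/testthat/     unit + property + oracle + acceptance tests
vignettes/methods.Rmd  the models, parameters and design choices in full
```
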