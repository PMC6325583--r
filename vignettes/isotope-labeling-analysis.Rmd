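---
title: "Mass-isotopomer deconvolution and turnover rates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-isotopomer deconvolution and turnover rates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midtrace)
```

This vignette is the package's account of the science it implements: the
isotopomer mixture model, the two deconvolution estimators, the
steady-state rate model, the synthetic-data generator, and the numerical
and design choices made where the design was genuinely open.

## The labeling experiments being modeled

Isolated plastids (or intact cells) of a red alga are incubated for 1 h
with either ¹³C-bicarbonate or [2-¹³C]acetate at 99% isotopic enrichment.
Bicarbonate enters through photosynthesis and can label *every* carbon of
newly synthesized sugar and glycerol moieties; acetate enters fatty acid
synthesis as intact C2 units and can label only one carbon per unit — the
even-numbered acyl carbons — so an 18-carbon chain has at most 9 labelable
positions. After lipid extraction and hydrolysis, each fragment (methyl
galactoside, glycerol, FAMEs) is measured by GC-MS, giving a
mass-isotopomer distribution (MID): the relative abundances M0..MK of
molecules carrying 0..K heavy isotopes. Parallel ¹⁴C incubations give
absolute incorporation (pmol ¹⁴C·mg⁻¹ chlorophyll·h⁻¹) per lipid class or
fatty acid.

## The isotopomer mixture model

A `fragment_spec` records the backbone carbon count N, the labelable
count L, and D derivatization carbons (FAME methyl, TMS groups), which
are chemically added after the labeling and therefore always at natural
abundance. A *population* is a subpool of molecules sharing one isotopic
abundance p: every labelable position is ¹³C with probability p,
independently. Its MID is

  Binomial(L, p) ⊛ Binomial(N − L + D, p_nat),

where ⊛ is discrete convolution (mass shifts add) and p_nat is the
natural ¹³C abundance. The observed MID of a pool is a fraction-weighted
mixture over populations, Σⱼ fⱼ·MIDⱼ, with Σfⱼ = 1; the unlabeled
population is the j with p = p_nat, which collapses to the plain
whole-fragment natural-abundance binomial. Two exact invariants are
enforced by tests: every MID is nonnegative and sums to 1 within 1e−9,
and the mean mass shift of any mixture equals Σⱼ fⱼ·L·pⱼ + (N−L+D)·p_nat
exactly (first-moment conservation).

Truncation needs no special handling: a fragment with K total carbons has
MIDs of length K+1 by construction, so there is no infinite tail to cut.

## Deconvolution: two estimators

The "newly synthesized" readout of the experiments is the *highly
labeled* fraction — material with p > 0.5 (strict inequality; a shift
exactly at p = 0.5 does not count). Because the algorithm of the original
spectral-processing program is not published, the package provides two
estimators and treats neither as canonical.

**Per-isotopomer stripping** (default). Find the largest α such that
`observed − α·natural` stays elementwise above −tol, clip the remainder
at zero, and renormalize. Each residual shift k is read as a nominal
population with p = k/L (capped at 1); shift-0 residual mass has p = 0
and is folded back into the unlabeled fraction. This mirrors the
figure-level presentation of isotopomer distributions: each bar beyond
natural abundance is an isotopomer, judged by its own k/L.

**Grid mixture fit.** Build one candidate population MID per p on a grid
(default 0.05 steps from 0.05 to 1) plus the natural population, solve
nonnegative least squares for the weights (Lawson–Hanson, via
`pracma::lsqnonneg`), renormalize to sum to 1, and drop components below
1e−4. The highly-labeled criterion is then applied to each *fitted
population's* p. Duplicate grid entries are deduplicated with a warning.

The estimators differ in principle: stripping classifies shift by shift,
the fit classifies population by population. For a single population at
high enrichment (p ≥ 0.9, the regime of material newly made from 99%
substrate) the two agree to well under one percentage point, because a
Binomial(L, p≥0.9) puts almost no mass at shifts with k/L ≤ 0.5. At
moderate enrichment they genuinely diverge — a p = 0.7 population on a
six-carbon fragment carries ~26% of its mass at shifts with k/L ≤ 0.5,
which stripping assigns to the less-densely-labeled class. This is a
property of the criteria, not an implementation artifact; the tests
assert agreement of the *total* labeled mass at all enrichments and of
the highly labeled mass in the high-enrichment regime only.

A related identifiability caveat: a length-(K+1) MID determines only K
moments of the mixing distribution over p, so with a dense grid the
nonnegative-weight representation is not unique in general. For the
sparse, well-separated mixtures the experiments produce (natural
population plus one or two enriched populations on the grid), the
active-set solver recovers the generating fractions to 1e−6 in the
noiseless tests; recovery claims are always made under that condition.

## Rates under the steady-state model

A pool of constant size with equal input and output fluxes replaces its
material at rate k; the labeled fraction after time t is
f(t) = 1 − exp(−kt). Inverting at the single 1-h timepoint gives the
turnover rate k = −ln(1 − B/100)/t from the highly labeled percentage B.
Because −ln(1−x) ≥ x, the turnover rate always dominates the plain
fractional rate B/100, and for B < 1% the two agree within 1% relative —
both properties are tested. The incorporation rate is A·B/100 for pool
content A, and the degradation rate follows the identity
turnover = growth + degradation with growth μ = ln 2 / doubling time
(12 h → 0.0578 h⁻¹, printed as 0.058). In isolated plastids turnover can
fall below μ (downstream consumption of the pool is arrested in vitro);
the difference is floored at zero and flagged rather than rejected.
Fractions of exactly 100% are a domain error: under this model a pool
cannot be fully replaced in finite time, so B = 100 indicates a
measurement inconsistent with the model rather than a fast pool.

Specific radioactivity is the proportion of labeled carbon,
¹⁴C/(¹⁴C+¹²C), on the ×10⁻⁶ scale: pmol ¹⁴C incorporation divided by
pool carbon, with pool carbon computed as carbon number × content / 1000
(lipid classes, μmol C) or as C2 units × content (fatty acids, nmol C2,
with a factor 1000 restoring the scale). The dpm-to-pmol conversion uses
1 Ci = 2.22×10¹² dpm, so pmol = dpm / (2.22 × specific activity in
mCi·mmol⁻¹); it is provided as plumbing and not asserted to be the
original workflow's exact path.

## Reproducing the published tables

Four reference tables ship as plain-text fixtures, split into *input*
columns (pool contents, labeled fractions, ¹⁴C incorporations — the
measured quantities) and *printed* derived cells with their decimal
precision. `reproduce_table()` recomputes the derived columns, rounds
half-to-even at the printed precision, and diffs cell by cell.
"Not detected" entries are missing values throughout and never enter the
diff. Four printed cells do not recompute from their own printed inputs:

```{r anomalies}
tabs <- reproduce_all_tables()
do.call(rbind, lapply(tabs, function(r)
  r$diff[r$diff$anomaly, c("pool", "column", "printed", "rounded")]))
```

In each case the recomputed value differs in the last digit or two
(e.g. printed 5.25 vs recomputed 5.28), consistent with the source having
applied the formula to unrounded labeled fractions before printing the
rounded ones. These cells are flagged `anomaly = TRUE` in the fixtures;
the diff reports them every time and `ok` tolerates exactly these, never
a silent mismatch elsewhere.

## The synthetic-data generator

`simulation_scenario()` ties each fragment to a true turnover rate k and
a labeled-population enrichment (default p = 0.99, the substrate
enrichment of the experiments; newly synthesized material is assumed
drawn entirely from the labeled substrate). At each timepoint the true
labeled fraction is 1 − exp(−kt); the observed MID is the corresponding
two-population mixture, either exact (`n_ions = 0`) or a multinomial draw
of `n_ions` ions — ion-counting statistics are the only simulated noise
source. Chromatographic baselines, spectral overlap and detector effects
are *not* emulated, so a passing recovery test demonstrates correctness
of the deconvolution and rate arithmetic under counting noise, not
robustness to every artifact of real spectra. The bundled calibration
scenario uses the intact-cell turnover rates (galactose 0.092, glycerol
0.063, 16:0 0.073 h⁻¹) at the experiment's 1-h timepoint. No ion counts
are reported for the original measurements, so the noisy-scenario budget
(10⁵ ions) was chosen once as a typical well-integrated GC-MS peak; the
recovery error shrinks monotonically with the ion budget (a tested
property), with the median relative error at 10⁵ ions well under 1%,
and the calibration script writes the full error-versus-ions table.

Reproducibility: each fragment × timepoint draw uses a substream seed
derived by a stable polynomial hash of the fragment name folded with the
master seed, so adding a fragment to a scenario does not perturb the
draws of the others, and identical scenarios are byte-identical.

## Numerical choices and degenerate inputs

- p_nat defaults to 0.0107 (representative terrestrial ¹³C abundance);
  it is a parameter everywhere because the original constant is unstated.
- Only carbon isotopes are modeled. Derivatization carbons default to 0
  (backbone-only analysis); fragment definitions with FAME/TMS carbon
  counts are bundled for the corrected mode, since whether the original
  processing corrected for them is unknowable. H/O/Si isotopes are out of
  scope.
- Stripping tolerance: 1e−9 for noiseless data. Under counting noise the
  feasibility constraint must not bind on near-empty high-mass bins, so
  the pipeline default widens it to 1/sqrt(n_ions), the counting-noise
  scale; negative residual entries are clipped, the clipped mass is
  carried into the reconstruction residual norm, and fractions are
  renormalized.
- The stripping estimator's highly-labeled readout carries a small
  deterministic bias for small fragments even noiselessly: a p = 0.99
  population on glycerol (L = 3) has 3·0.99·0.01² ≈ 3×10⁻⁴ of its mass at
  shift 1 (k/L ≤ 0.5), which is classified less-densely labeled. The
  model-based estimator has no such truncation, which is why the exact
  noiseless recovery claims use it (with the true p on the grid), while
  the stripping estimator is validated to its documented bias scale
  (~1e−3 relative).
- Degenerate mixtures (all populations at p = p_nat) collapse exactly to
  the natural-abundance MID; a fragment with L = 0 but labeled mass in
  its residual is an inconsistency error; empty measurement tables yield
  empty rate tables.
- Rounding for printed-precision comparison is round-half-even (base
  `round()`), matching the fixtures' per-cell decimal places.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data and
the bundled printed fixtures: fragments up to 18 carbons, grids of ≤ 21
candidate populations, 100–200 seeded replicates at 10³–10⁷ ions. These
sizes exercise every code path at comfortably interactive runtimes while
keeping Monte-Carlo summaries (medians over ≥ 100 replicates) stable to
well inside the tolerances they are tested against.

## Known limitations

- Positional isotopomers (which specific carbons are labeled) are not
  resolved; only mass shifts are modeled.
- The steady-state inversion uses a single timepoint; multi-timepoint
  curve fitting of labeling kinetics is out of scope.
- The acetate tracer model assumes label lands only on even acyl
  carbons; exchange through the TCA cycle or carboxylation that could
  scramble label is not modeled.
- The mixture fit's grid resolution (0.05) bounds how finely distinct
  enrichments can be separated; populations off the grid project onto
  neighboring candidates.
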