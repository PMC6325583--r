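# midtrace

Stable-isotope and radiotracer labeling analysis for plastid lipid
metabolism. The package targets experiments of the kind performed on the
unicellular red alga *Cyanidioschyzon merolae*: intact cells or isolated
plastids are fed ¹³C-bicarbonate (labels every carbon of newly made sugar
and glycerol moieties) or [2-¹³C]acetate (labels one carbon per acetate-
derived C2 unit of a fatty acid, i.e. the even-numbered acyl carbons), the
lipids are hydrolyzed into polar-group and fatty-acid fragments, and each
fragment's mass-isotopomer distribution (MID) is measured by GC-MS.
Parallel ¹⁴C incubations give absolute incorporation in pmol per mg
chlorophyll per hour. From these, the analysis derives pool turnover
rates, incorporation rates, specific radioactivities and degradation
rates. It is written for lipid biochemists and metabolic-flux analysts
who need those derivations to be explicit, tested and reproducible.

## The model

**MID mixture model.** A fragment with N backbone carbons, of which L are
reachable by the tracer, is modeled as a mixture of isotopomer
*populations*. Each population j shares one isotopic abundance pⱼ — the
probability that any labelable position carries ¹³C — so its MID is
Binomial(L, pⱼ) convolved with Binomial(N − L + D, p_nat) for the
non-labelable backbone and D derivatization carbons at natural abundance
p_nat = 0.0107. The observed MID is Σⱼ fⱼ · MIDⱼ with mixture fractions
fⱼ. Two deconvolution estimators recover (pⱼ, fⱼ): per-isotopomer
stripping (remove the largest feasible natural-abundance multiple, read
each remaining mass shift k as nominal p = k/L), and a nonnegative
least-squares fit over a grid of candidate p values. Material with
p > 0.5 counts as *highly labeled*, i.e. newly synthesized.

**Rates.** For a pool of content A (nmol·mg⁻¹ chl) with highly labeled
fraction B (%) after t = 1 h of labeling, assuming a steady-state pool
with balanced input and output:

- incorporation rate `[C] = A × B/100` (nmol·mg⁻¹ chl·h⁻¹)
- turnover rate `k = −ln(1 − B/100)/t` (h⁻¹), the inverse of
  `f(t) = 1 − exp(−kt)`
- specific radioactivity = ¹⁴C incorporation / pool carbon (×10⁻⁶),
  with pool carbon as carbon number × content (lipids) or C2 units ×
  content (fatty acids)
- degradation rate = turnover − specific growth rate (μ = ln 2 / doubling
  time), floored at zero and flagged when in-vitro turnover falls below μ.

A seeded generator simulates the whole forward process (binomial
mixtures, first-order labeling time courses, multinomial ion-counting
noise) so every stage is testable end to end without instrument data.

## Worked example

Deconvolve a synthetic galactose MID (6 labelable carbons, 7% of the pool
newly synthesized at p = 0.9) and convert the fraction into rates:

```r
library(midtrace)
frag <- fragment_spec("galactose", 6, 6)
obs  <- mixture_mid(frag, label_populations(c(0.0107, 0.9), c(0.93, 0.07)))
dec  <- deconvolve_mid(obs, frag)
dec$total_labeled_fraction
#> [1] 6.999993
turnover_rate(dec$highly_labeled_fraction)   # h^-1, 1-h labeling
#> [1] 0.07137839
```

Reproduce a published reference table from its input columns:

```r
reproduce_table("acetate_fa")
#> <table_reproduction> acetate_fa: all cells match (documented anomalies excepted)
```

which recomputes, per fatty acid, the C2-unit contents (43.3, 8624,
2637 nmol C2·mg⁻¹ chl for 14:0, 16:0, 18:0) and specific radioactivities
(16.2, 0.669, 1.396 ×10⁻⁶) and diffs them cell by cell against the
bundled printed values at printed precision. Four cells across the four
bundled tables are flagged as documented rounding anomalies: the source
evidently computed them from unrounded fractions, and the diff reports
both the printed and the recomputed value (e.g. 5.25 printed vs 5.28
recomputed for the 16:0 acetate incorporation rate).

The numbered scripts under `analysis/` run the full workflow — table
reproduction, noiseless turnover recovery, and ion-count noise
calibration — and write their outputs under `results/`.

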