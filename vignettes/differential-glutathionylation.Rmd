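---
title: "Quantifying differential protein S-glutathionylation from ICAT ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential protein S-glutathionylation from ICAT ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutaquant)
```

## The measurement model

S-glutathionylation is a reversible disulfide between a protein cysteine
thiol and glutathione. In the cleavable-ICAT labeling scheme this package
analyses, the two redox states of each cysteine are tagged with the two
isotopic forms of one reagent: reduced (free) thiols receive the light
(^12^C) tag, then glutathionylated thiols are selectively released by
glutaredoxin and receive the heavy (^13^C) tag. After tryptic digestion
and avidin enrichment of tagged peptides, the heavy:light intensity ratio
of a peptide,

$$ r = \mathrm{H{:}L} = \frac{[\mathrm{SG}]}{[\mathrm{SH}]}, $$

directly measures its glutathionylated-to-free thiol ratio. The site
occupancy (stoichiometry) follows as $\theta = r/(1+r)$, and conversely
$r = \theta/(1-\theta)$ (`occupancy_from_ratio()`,
`ratio_from_occupancy()`). Because each peptide carries one H:L value, a
peptide with several labeled cysteines reports one shared ratio for all
of them; the site tables propagate that shared value and flag peptides
that map ambiguously (multiple exact occurrences in their protein).

## The differential procedure

Given a peptide-level table of per-sample measurements for a case group
and a control group, `quantify_peptides()` proceeds in fixed stages:

1. **Filter** (`filter_peptides()`): keep rows with identification
   confidence ≥ 95% and H:L ≥ 0.01. Both floors are inclusive ("at
   least"); a strict-confidence variant is available by configuration.
   The H:L floor is a quantification floor: ratios below it are
   indistinguishable from noise in the light channel.
2. **Collapse technical replicates**
   (`collapse_technical_replicates()`): repeated injections of one
   subject's sample are averaged first, so subjects — not injections —
   are the statistical units. Treating duplicates as independent would
   pseudo-replicate and overstate significance.
3. **Group means**: the per-group average of per-subject H:L values,
   arithmetic by default. A geometric option exists because ratio data
   are log-distributed; the arithmetic default matches the convention of
   averaging H:L values directly.
4. **Ratio-of-ratios**: the differential statistic per peptide is
   $\mathrm{RoR} = \overline{\mathrm{H{:}L}}_{case} /
   \overline{\mathrm{H{:}L}}_{control}$. It is dimensionless and
   invariant to any common rescaling of intensities.
5. **Mann–Whitney test** (`mann_whitney_p()`): two-sided, on the
   per-subject values of the two groups. With a tie-free pooled sample
   of at most `exact_test_max_n` (default 12) observations the exact U
   null distribution is used (two-sided p as twice the smaller tail,
   capped at 1 — identical to enumerating all group labelings);
   otherwise the midrank normal approximation with tie and continuity
   corrections. A pooled sample with zero rank variance returns p = 1.
6. **Call** (`call_differential()`): a peptide is significant when its
   RoR *strictly exceeds* the 1.5-fold cutoff **and** p < 0.05. Only
   increases are called by default (the biology of oxidative stress
   motivates a one-sided fold gate); `two_sided_fold` also calls
   decreases below 1/1.5. No multiplicity correction is applied by
   default; Benjamini–Hochberg is available (`mtc = "BH"`), in which
   case alpha applies to q-values.
7. **Rollup** (`rollup_to_proteins()`): a protein is significant when at
   least one of its peptides is. The any-peptide rule is deliberately
   permissive: site-level modifications are local events, and requiring
   agreement across peptides would conflate distinct cysteines.

Peptides observed in fewer than `min_subjects_per_group` (default 3)
subjects in either group are excluded and logged — too few subjects make
the rank test uninformative (the smallest achievable two-sided exact p
with 3 vs 2 subjects is 0.2).

## The synthetic-data generator

Real raw data for this kind of study are rarely redeposited in reusable
form, so the package ships a generative stand-in
(`simulate_experiment()`) that produces a proteome (FASTA), a planted
ground truth, and a pipeline-ready measurement table. It emulates:

* **Design**: 11 case vs 7 control subjects, each in technical
  duplicate — a realistic fibroblast case/control cohort size.
* **Scale**: 300 random proteins (200–600 residues) at human-like
  amino-acid composition with 2.3% cysteine yield ≈ 2,100 detectable
  cysteine peptides (length 6–40 after in-silico tryptic digestion,
  cleaving after K/R except before P). This matches the peptide count
  of a proteome-wide ICAT study; the protein count is lower than such a
  study reports because the simulator observes every digestible
  cysteine peptide, whereas LC-MS/MS samples a subset per protein.
* **Baseline occupancy**: Beta(1.5, 10) — mean ≈ 12%, right-skewed,
  consistent with reported basal thiol-oxidation levels — truncated
  below `occupancy_floor = 0.01`. The truncation is a population
  statement, not a convenience: a quantified ICAT peptide by definition
  passed the H:L ≥ 0.01 floor, so sites whose noise-free ratio falls
  under the floor are not part of the population the generator
  emulates.
* **Effects**: a fraction (default 10%) of cysteine peptides receives a
  case-group effect by multiplying the occupancy odds:
  $\theta_{case} = e\rho/(1+e\rho)$ with
  $\rho = \theta_{control}/(1-\theta_{control})$ and effect size
  $e$ (default 2), so the expected ratio-of-ratios at a planted peptide
  is exactly $e$. Effects are planted **per peptide**, shared by all of
  a peptide's cysteines: because only one H:L exists per peptide,
  independently perturbed co-measured sites would form mixtures that no
  method could resolve, and the ground truth would not correspond to
  any measurable quantity.
* **Noise**: multiplicative lognormal error on each isotope channel,
  parameterised by a per-channel coefficient of variation (default
  0.20), entering the ratio as $\exp(\varepsilon_H - \varepsilon_L)$.
  MS intensity error is multiplicative, and the difference-of-logs form
  keeps the ratio unbiased on the log scale.
* **Missingness**: per-observation dropout, missing-completely-at-random
  (default 5%), plus a small fraction (5%) of low-confidence
  identifications that the 95% filter removes. No empirical noise or
  missingness magnitudes are available for this assay; these defaults
  are stated assumptions, and every benchmark reports them.

What the generator does **not** emulate: spectra (no m/z, retention
time, chimeric interference), intensity-dependent missingness,
between-protein abundance structure, shared-peptide ambiguity across
proteins, or the enzymology of the glutaredoxin exchange. Passing
recovery benchmarks on this generator therefore demonstrates that the
statistical pipeline is correct and well calibrated under its stated
model, not that the assay itself is unbiased.

## Numerical and design choices

* Coordinates are 1-based and inclusive throughout, the proteomics
  convention (sites are reported like "Cys160"); offset arithmetic is
  confined to `map_peptide_to_protein()`.
* Isoleucine and leucine are distinct; the upstream search engine has
  already committed to an identification.
* Exact vs approximate Mann–Whitney switches at a pooled n of 12
  (configurable); at the default 11-vs-7 design the approximation is
  used, and its true type-I level at alpha 0.05 is 0.044 (computed from
  the exact U distribution), i.e. slightly conservative.
* p-values are clipped to (0, 1]; ratio-of-ratios requires a positive,
  present control mean and errors otherwise rather than emitting Inf.
* Ambiguous peptides (multiple occurrences in a protein) keep all site
  coordinates and a flag; dropping them would silently bias site
  counts.
* Deterministic outputs: result tables are sorted (accession, position,
  peptide) and written with shortest-round-trip number formatting, so
  identical inputs give byte-identical files; all simulation draws flow
  from one seed through fixed per-stage substreams.
* Enrichment (`hypergeometric_enrichment()`) uses the hypergeometric
  upper tail with the universe defaulting, by convention, to all
  *quantified* features — conditioning on detectability avoids
  abundance bias. The joint protein+metabolite test pools the two
  universes with kind tags and runs a single hypergeometric per
  pathway; topology-weighted impact scores of dedicated pathway tools
  are deliberately out of scope, as transparent and testable behaviour
  is the goal here.

## Benchmarks and their problem sizes

`run_recovery_benchmark()` closes the loop: simulate, quantify, join
calls to ground truth by site, and report sensitivity = TP/(TP+FN) over
planted sites and empirical false-discovery proportion = FP/(FP+TP) over
calls. The package's own checks use: the full 300-protein design
(≈ 2,000 tested peptides) for null calibration; a 60-protein design
(≈ 450 cysteine peptides, ≈ 45 planted) for the noiseless-exactness
check and for a 10-seed power sweep over effect ratios 1.5/2/3; and
25–40 protein designs for determinism and orchestration tests. At the
default noise level, sensitivity at a 2-fold effect is ≈ 0.98 with FDP
below 1%, the null type-I rate sits at the expected 0.044, and no null
peptide jointly passes both gates.

## Limitations

* The Mann–Whitney unit is the peptide; protein significance inherits
  the most significant peptide without combining evidence across
  peptides. With very many peptides per protein the any-peptide rule
  inflates protein-level findings unless `mtc = "BH"` is enabled.
* Arithmetic averaging of ratios is right-skew-sensitive; at high noise
  the ratio-of-ratios is biased slightly above 1 under the null (Jensen
  effect). The rank test is unaffected; the geometric option removes
  the bias at the cost of departing from the conventional statistic.
* One-sided fold calling means decreased glutathionylation is invisible
  by default.
* The generator's independence of peptides (no shared-subject
  correlation beyond design structure) makes Monte-Carlo standard
  errors on calibration estimates straightforward but slightly
  optimistic relative to real correlated proteomes.

## A minimal run

```{r example, eval = FALSE}
library(glutaquant)

sim <- simulate_experiment(sim_config(seed = 1))
res <- quantify_peptides(sim$table, quant_config(), proteome = sim$proteome)
res

bench <- run_recovery_benchmark(sim_config(seed = 1))
bench
```
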