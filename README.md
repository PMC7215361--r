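# glutaquant

Differential protein S-glutathionylation analysis from cleavable-ICAT
heavy:light peptide ratio tables.

## The problem

S-glutathionylation — a reversible mixed disulfide between a protein
cysteine and glutathione — is a marker and effector of oxidative stress,
notably in mitochondrial disease. In the cleavable-ICAT redox workflow,
reduced thiols are labeled with the light (^12C) reagent, glutathionylated
thiols are released by glutaredoxin and labeled with the heavy (^13C)
reagent, and each peptide's heavy:light intensity ratio measures its
glutathionylated-to-free thiol ratio:

```
H:L = [SG] / [SH],      occupancy θ = H:L / (1 + H:L)
```

`glutaquant` takes the peptide-level H:L export of such an experiment
(case vs control cohorts, technical replicates) and produces differential
glutathionylation calls. It is aimed at redox-proteomics analysts who
want a transparent, fully tested implementation of the standard
ratio-of-ratios workflow, plus a synthetic-data generator for assessing
its power and calibration.

## The method

Per peptide (protein accession + sequence + labeled cysteine positions):

1. filter rows at ≥ 95% identification confidence and H:L ≥ 0.01;
2. average technical replicates within each subject;
3. average per-subject H:L within each group;
4. form the **ratio-of-ratios** `RoR = mean(H:L)_case / mean(H:L)_control`;
5. test the per-subject values with the two-sided **Mann–Whitney** test
   (exact for small tie-free samples, midrank normal approximation with
   tie/continuity corrections otherwise);
6. call a peptide significant when `RoR > 1.5` **and** `p < 0.05`;
7. roll up to proteins (significant iff ≥ 1 significant peptide) and map
   labeled cysteines to 1-based protein coordinates.

Downstream helpers compute cross-condition overlaps of significant
protein sets and hypergeometric over-representation against
user-supplied GMT annotation sets, including a pooled-universe joint
protein + metabolite pathway test.

## Worked example

```r
library(glutaquant)

# a full synthetic experiment: 300-protein proteome, 11 cases vs 7
# controls in duplicate, 10% of cysteine peptides carrying a 2-fold
# planted increase, 20% channel noise, 5% dropout
sim <- simulate_experiment(sim_config(seed = 1))
res <- quantify_peptides(sim$table, quant_config(), proteome = sim$proteome)
res
#> Differential S-glutathionylation result
#>   rows read 65751 | rejected conf 3325, ratio 290 | retained 62152
#>   peptides tested 1922 (excluded 0) | significant 192
#>   proteins quantified 298 | significant 137
```

65,751 table rows (peptide × subject × replicate) survive as 1,922
tested peptides; 192 peptides on 137 proteins pass both the 1.5-fold and
p < 0.05 gates. The top calls show ratios near the planted 2-fold
effect:

```r
head(dplyr::arrange(res$calls, p_value)[, c("accession", "peptide",
     "ratio_of_ratios", "p_value", "significant")], 3)
#>   accession peptide           ratio_of_ratios  p_value significant
#> 1 SYNP0008  HNTMAAVGCAAQGK               1.93  5.78e-4  TRUE
#> 2 SYNP0009  AQMLLYGMVSTFVYDAQ...         1.92  5.78e-4  TRUE
#> 3 SYNP0010  SWPLYFDIFHCALR               1.99  5.78e-4  TRUE
```

Because the data are simulated, recovery can be scored against the
planted truth:

```r
run_recovery_benchmark(sim_config(seed = 1))
#> Recovery benchmark
#>   planted sites 232 | called 230 | true positives 228
#>   sensitivity 0.9828 | empirical FDP 0.0087
```

At the default design and noise level the pipeline recovers 98% of
planted 2-fold sites with under 1% false discoveries.

See the vignette (`vignettes/differential-glutathionylation.Rmd`) for
the measurement model, generator assumptions, and design rationale.

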