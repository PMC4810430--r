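# spheroseq

Early-stage multicellular tumor spheroids (MTS, ≤ ~200 µm, pre-hypoxic) mimic
the avascular growth of primary tumors and micrometastases. Comparing their
bulk transcriptome against matched monolayer cultures raises a recurring set
of analysis steps: a detection filter on read counts and relative expression,
regulation calls that must accommodate *binary* behavior (transcripts
synthesized de novo in the spheroid, or switched off completely), a signed
fold-change convention, mapping regulated lncRNAs to their nearest
protein-coding neighbors to screen for cis co-regulation, chromosome-level
distribution statistics, and the oxygraph arithmetic used to demonstrate
OxPhos hyperactivation in the same model. `spheroseq` implements this
pipeline as composable, tibble-in/tibble-out R functions, together with a
seeded negative-binomial simulator that plants known effects so every stage
can be validated against ground truth.

## The method

For each transcript with reads \(r\) and relative expression
\(RPKM = r \cdot 10^9 / (L \cdot N)\) (length \(L\) nt, library size \(N\)),
detection in a condition fails only when both cutoffs fail
(\(RPKM < 0.2\) **and** \(r < 10\)). Each transcript then receives exactly one
status:

| status | rule |
|---|---|
| `filtered` | undetected in both conditions |
| `de_novo` | detected only in MTS |
| `switched_off` | detected only in monolayer |
| `up` / `down` | detected in both, signed fold change \(\ge\) +2 / \(\le\) −2 |
| `unchanged` | detected, below threshold |

The signed fold change reports the ratio \(x_{MTS}/x_{mono}\) as \(r\) when
\(r \ge 1\) and as \(-1/r\) otherwise (a 15-fold decrease is −15). Summaries
count de-novo transcripts inside the positive class and switched-off inside
the negative class, with percentages over regulated transcripts rounded
half-up.

Downstream, regulated lncRNAs are paired with their nearest protein-coding
gene on each genomic side (gene-body gap distance, 0 on overlap; ties kept;
default within 1 Mb) and each pair is classified `concordant`, `discordant`
or `none` from the two members' regulation classes. Window-chained runs of
dysregulated features (consecutive gap ≤ 100 kb, ≥ 3 members) are reported
as chromosomal clusters — the pattern histone-gene clusters show in this
model. Chromosome statistics comprise Pearson correlations of regulated
counts against chromosome length and against gene density, and a 1-df
chi-square goodness-of-fit of the regulated strand split against the
annotated background. Respirometry helpers implement OxPhos flux
(basal − oligomycin-resistant rate), the coupling ratio U/B.R., and the
spheroid geometric-mean diameter \(D_G = \sqrt{ab}\).

## Worked example

```r
library(spheroseq)

cfg <- sim_config(seed = 42)            # 2000 transcripts, dispersion 0.05,
sim <- simulate_mts_experiment(cfg)     # planted effects + truth table
report <- run_pipeline(sim$annotation, sim$expression)
report
#> <mts_report>
#>   transcripts: 2000 (459 regulated: 142 up, 217 down, 50 de novo, 50 switched off)
#>   lncRNA-coding neighbor pairs: 447 (80 concordant, 46 discordant)
#>   clusters: 1; chromosomes: 10
#>   strand bias: chi2 = 2.7160, p = 0.09934

score_against_truth(report, sim$truth)
#> # A tibble: 5 × 6
#>   status       n_planted n_called n_correct recall precision
#>   <chr>            <int>    <int>     <int>  <dbl>     <dbl>
#> 1 up                 135      142       131  0.970     0.923
#> 2 de_novo             50       50        50  1         1
#> 3 down               122      217       122  1         0.562
#> 4 switched_off        50       50        50  1         1
#> 5 pairs               16      126        16  1         0.738
```

All 50 planted binary transcripts are recovered exactly (they are
definition-forced once detection is set), fold-change calls recover planted
effects with high recall at this noise level, and the planted 25-member
cluster is the single cluster reported. At `dispersion = 0` every recall and
precision is exactly 1. The respirometry arithmetic on the published rate
table:

```r
oxphos_flux(c(5.2, 10.3), c(1.7, 3))   # 3.5 7.3  (monolayer, MTS)
round(uncoupling_ratio(17.2, 10.3), 1) # 1.7
geometric_mean_diameter(190, 210)      # 199.7 µm
```

`write_report(report, "out/")` exports the calls, pairs, cluster BED,
chromosome summary and JSON stats; `plot_regulation_summary()`,
`plot_length_histogram()` and `plot_chromosome_distribution()` draw the
standard figures.

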