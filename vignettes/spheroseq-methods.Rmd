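---
title: "Methods: regulation calling and cis co-regulation in early-stage spheroid transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulation calling and cis co-regulation in early-stage spheroid transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroseq)
```

## The analysis model

`spheroseq` analyzes a two-condition bulk RNA-seq contrast — monolayer
culture versus early-stage (pre-hypoxic, ≤ ~200 µm) multicellular tumor
spheroids — in which a large fraction of the regulated long non-coding RNAs
behave *binarily*: they appear de novo in the spheroid or cease to be
expressed entirely. A classification scheme built only on fold changes
mishandles these transcripts (their ratios are undefined or infinite), so
the package treats detection and effect size as two separate decisions.

**Detection.** A transcript is detected in a condition unless it fails both
cutoffs: relative expression below `min_relexpr` (default 0.2) *and* fewer
than `min_reads` reads (default 10). Relative expression is RPKM,
$r \cdot 10^9 / (L \cdot N)$. Two deliberate choices sit here:

- *Metric.* The upstream workbench this kind of data comes from reports a
  "relative expression level" without defining it; RPKM is the standard
  reads-per-kilobase-per-million proxy at that scale and is what the 0.2
  cutoff is applied to. Callers with a different normalization can supply
  their own `relexpr_*` columns.
- *Filter semantics.* The filtering rule as usually stated ("relative
  expression lower than 0.2 and less than 10 reads") reads literally as a
  conjunction, so `semantics = "and"` (a transcript survives if *either*
  criterion passes) is the default; `semantics = "or"` is available because
  closed-source implementations of such filters are not verifiable.

**Classification.** Undetected in both conditions → `filtered`; detected
only in MTS → `de_novo`; only in monolayer → `switched_off`. Otherwise the
signed fold change $f$ — the expression ratio reported as $r$ when $r \ge 1$
and $-1/r$ when $r < 1$ — decides `up` ($f \ge$ `fc_threshold`), `down`
($f \le -$`fc_threshold`) or `unchanged`. Defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_relexpr` | 0.2 | RPKM | the detection cutoff of the source protocol |
| `min_reads` | 10 | reads | idem |
| `fc_threshold` | 2.0 | fold | the conventional 2-fold screening threshold; whether the original RNA-seq classification used exactly this value is not documented, so it is exposed |
| `fc_on` | `"relexpr"` | — | RPKM ratios normalize the two library depths; `"reads"` gives raw-count ratios |
| `require_significance` | `FALSE` | — | an external test column (e.g. edgeR) can gate up/down calls; the package does not re-derive differential-expression statistics |

Binary statuses carry `NA` rather than ±∞ fold changes: they are a separate
class, not an extreme of the continuous one. Summaries tally de-novo inside
the positive class and switched-off inside the negative class, and class
percentages are computed over regulated transcripts only, rounded half-up to
integers — `round()`'s banker's rounding would not reproduce conventionally
printed tallies.

## Neighbor pairs, clusters, chromosome statistics

**Coordinates** are 0-based half-open internally; GTF I/O (1-based
inclusive) converts at the boundary. The convention is stated explicitly
because interval conventions are where nearest-neighbor code silently
disagrees.

**Nearest coding neighbors.** For each regulated lncRNA the package returns
up to `k_per_side = 1` nearest protein-coding genes on each genomic side
plus all overlapping genes, within `max_distance = 1 Mb`. Distance is the
gap between gene bodies (closed-interval projections), 0 on overlap;
book-ended features (gap 0 without overlap) are labelled `overlapping` so
that `distance == 0 ⇔ side == "overlapping"` holds exactly. Equal-distance
ties are all returned as separate pairs — lncRNAs genuinely co-regulated
with two or three neighbors are a finding of interest, not a tie to break.
Strand affects only the reported orientation. `max_distance` bounds
"nearby" because cis effects at megabase range are indistinguishable from
coincidence in this design; both knobs are exposed since the original
analyses do not state whether "nearest" meant the single closest gene or any
adjacent regulated gene.

**Clusters** are the package's own formalization of what chromosome-view
plots show: maximal runs of dysregulated features in which each member lies
within `window = 100 kb` of the nearest preceding member, reported when the
run has ≥ `min_members = 3` members. Interleaved unchanged features do not
break a run. Maximality is guaranteed by construction (runs split exactly
where a gap exceeds the window).

**Chromosome statistics.** "Density" is the total annotated transcripts of
the biotype per chromosome (the quantity chromosome-distribution figures
plot), not transcripts-per-Mb; the summary table carries both columns so the
alternative is one `mutate()` away. The strand-bias test is a 1-df
chi-square goodness-of-fit of the regulated strand split against the
background strand proportions, no continuity correction; a 2×2 independence
variant (with optional Yates correction) is provided as a sensitivity check.
On the published strand counts (767/735 regulated vs 58271/53339 background)
every standard 1-df formulation gives a statistic near 0.79 with p ≈ 0.37 —
comfortably non-significant, agreeing with the qualitative conclusion of no
strand preference. A sometimes-quoted statistic of 0.0011 for this table
cannot be reproduced from these counts under any standard 1-df formulation
and is not treated as ground truth here.

## Respirometry and morphometry

`oxphos_flux = basal − oligomycin` exactly (conservation
`flux + oligomycin = basal` is a tested invariant); `uncoupling_ratio =
U / basal`; `geometric_mean_diameter` is $\sqrt{ab}$. Group summaries report
the *mean of per-replicate ratios* ± SD: published coupling-ratio tables are
consistent with per-replicate averaging rather than ratios of means
(7.1/5.2 = 1.37 printed as 1.3 ± 0.1). Non-mitochondrial correction
(subtracting the NaCN-resistant rate before deriving quantities) is off by
default because published flux values are consistent with uncorrected basal
rates; `nonmito_correction = TRUE` enables it. Paired t-tests between
conditions delegate to `stats::t.test`; with a constant measure (e.g. NaCN
set to zero throughout) the p-value is reported as `NA`, not fabricated.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the reference synthetic experiment: 2,000
transcripts (1,000 coding, 1,000 lncRNA) on 10 chromosomes of 60 Mb;
negative-binomial counts (mean 200, log-normal baseline spread
`sdlog = 0.5`, dispersion 0.05 — a typical bulk RNA-seq biological-replicate
scale); 100 planted up and 100 down at |FC| = 4; 50 de-novo and 50
switched-off; 10 concordant and 6 discordant lncRNA–coding pairs within
50 kb; one 25-member alternating-biotype cluster (the size of the
histone-gene cluster such data show on chromosome 6). lncRNA lengths come
from a three-bin mixture (< 1000 / 1000–2499 / ≥ 2500 nt) with proportions
0.61/0.27/0.12 — the observed bin proportions of regulated lncRNAs in this
model, adjusted by one percentage point so they sum to one. At
`dispersion = 0` counts equal rounded means, making planted effects exactly
recoverable; de-novo transcripts have monolayer counts exactly zero by
construction.

Placement uses inter-feature gaps of 120–300 kb, above the cluster window
and the pair gap, so planted structures are unambiguous by construction:
the nearest coding gene of a planted pair's lncRNA is its partner, and no
accidental window-chain forms. One seed drives everything; the experiment
wrapper seeds once, and the stage generators derive their stream from the
same configured seed so each is independently reproducible.

The simulator does **not** emulate read-level artifacts (no FASTQ, GC or
length bias), splicing isoforms, batch effects, or correlated
expression between neighbors beyond the planted pairs. Consequently,
passing recovery tests demonstrates the *pipeline logic* — filtering,
classification, interval search, scoring — under a realistic noise model,
not robustness to alignment or library-preparation pathologies. One
realistic artifact it does reproduce: planted asymmetric effects shift the
library composition, which biases RPKM-based fold changes of unchanged
transcripts slightly toward `down` as dispersion grows. This is the
real-data argument for TMM-style normalization, which is intentionally out
of scope (an externally normalized `relexpr` column slots straight in).

Scoring separates two questions. *Recall* of planted pairs asks whether
every planted pair is recovered with its planted class. *Precision* asks
whether reported co-regulated pairs are consistent with the planted statuses
of both members — independently planted singletons that happen to be
neighbors genuinely co-vary, so they count as correct detections; at zero
noise precision is exactly 1 and it degrades as dispersion corrupts calls.

## Numerical and degenerate-input choices

- Empty annotation → GTF with header only; empty call set → error for
  summaries (an empty summary is more likely a pipeline bug than a result).
- All-unchanged inputs: class percentages reported as 0 with a
  `no_regulated` attribute flag rather than NaN.
- Correlations require ≥ 3 chromosomes and non-constant vectors; inside
  `run_pipeline()` a degenerate correlation yields `r = NA` instead of
  aborting the run.
- Zero expected cells make the strand test abort with a degenerate-table
  error; statistic 0 and p = 1 are returned exactly on proportion-matched
  tables.
- Negative OxPhos flux (oligomycin rate above basal) is returned with a
  warning, not clamped.

## Problem sizes

The test suite validates the interval algorithms against brute-force
enumeration on 100+ random instances of up to 200 features, planted-truth
recovery on the 2,000-transcript reference simulation at dispersion 0 and
0.05 (ten seeds pooled for the noisy case), and the statistics on
hand-evaluated fixed tables; the full suite runs in well under a minute per
module. These sizes were chosen to exercise every code path — multiple
chromosomes, ties, overlaps, empty sides — while keeping the suite quick to
iterate on.

## Known limitations

- Differential-expression significance is accepted, never computed;
  classification on fold change alone will over-call at low counts unless
  detection thresholds are raised or a significance column is supplied.
- The nearest-gene screen is a cis *candidate* generator; it cannot
  distinguish co-regulation from shared regulatory environment, and
  trans-acting effects are invisible to it.
- Dataset-scale results (counts of regulated transcripts, specific
  correlation coefficients) depend on the raw reads of a particular
  experiment and cannot be validated in their absence; the package therefore
  validates against planted synthetic truth, hand-evaluated statistics and
  exact arithmetic instead.
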