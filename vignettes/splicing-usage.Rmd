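---
title: "Exon/junction usage, clinical grouping and survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon/junction usage, clinical grouping and survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceusage)
```

# The problem

Bulk RNA-seq consortia distribute *level-3* quantifications: per-sample
RSEM-style normalized counts for genes, transcript isoforms, exons and
exon–exon junctions, alongside raw clinical tables. Comparing exon signal
across samples directly confounds two things: how much the *gene* is
expressed, and which *isoforms* the gene's transcription is split into.
`spliceusage` implements a normalization that removes the first so the
second is visible, plus the supporting steps a complete analysis needs:
mapping quantified features to transcript models, turning messy clinical
fields into a few well-defined categories, and relating isoform expression
to overall survival.

# The usage model

For one gene with $n$ exon (or junction) features and $m$ samples, let
$x_{ij} \ge 0$ be the quantification of feature $i$ in sample $j$.

1. **Gene expression.** $e_j = \frac{1}{n}\sum_{i=1}^{n} x_{ij}$. The gene's
   expression is estimated from the very features being normalized; exon
   and junction matrices are normalized independently, each with its own
   $n$, rather than pooled.
2. **Splicing index.** $r_{ij} = x_{ij}/e_j$. A constitutive exon has
   $r \approx 1$ in every sample regardless of expression level; a cassette
   exon's $r$ tracks its inclusion.
3. **Scale.** $Q_{95,i}$ is the 95th percentile of $\{r_{ij}\}_{j=1..m}$.
   Scaling by a high quantile rather than the maximum keeps one outlier
   sample from compressing the whole row.
4. **Usage.**
   $$y_{ij} = \begin{cases}
     \min(r_{ij}/Q_{95,i},\, 1) & Q_{95,i} > 0.05\\[2pt]
     \min(r_{ij}/0.05,\, 1)    & Q_{95,i} \le 0.05
   \end{cases}$$
   The floor handles features that are small *relative to their gene* in
   nearly all samples: without it, dividing by a minuscule $Q_{95,i}$ would
   saturate the row and manufacture signal out of noise.

Consequences that the test suite asserts: every defined $y_{ij} \in [0,1]$;
usage is invariant to rescaling all of one sample's values by $c>0$
(library-size invariance — $e_j$ absorbs $c$); for any feature with
$Q_{95,i} > 0.05$ and enough samples, the $\ge$95th-percentile samples
clamp at exactly 1; and when every ratio of a feature is $\le 0.05$ the
definition reduces exactly to $\min(r_{ij}/0.05, 1)$.

## Numerical choices

* **Quantile convention.** $Q_{95,i}$ uses linear interpolation between
  closest order statistics (`stats::quantile` type 7). The definition of
  the estimator does not pin this down; type 7 is the default of the
  mainstream numeric stacks, and the test oracle implements the same rule
  by explicit sort-and-interpolate so the convention is pinned by a test,
  not by folklore.
* **What $Q_{95}$ is a quantile of.** The ratios $r_{ij}$, not the raw
  $x_{ij}$: the usage formula divides $r$ by it, and the 0.05 floor is a
  statement about a feature's size *relative to the gene*, which only makes
  sense on the ratio scale. The two conventions differ only by per-sample
  weighting, but the choice is explicit and tested.
* **Zero gene expression.** If $e_j = 0$ (every feature of the gene is zero
  in sample $j$), the formula is undefined. We emit $y_{ij} = 0$ and record
  the sample in `zero_expression_samples` rather than propagating NaN into
  downstream plots; a zero column is also what an empty sample looks like
  visually.
* **Missing values at load.** A quantification TSV cell may be empty; the
  loader either imputes 0 (default, counted in the load report) or drops
  the row, by flag. Missingness never reaches the normalization.

# Feature-to-transcript annotation

Exon and junction row names encode loci
(`chrom:start-end:strand`, `chrom:pos:strand,chrom:pos:strand`, 1-based
inclusive). Internally all coordinates are 0-based half-open; conversions
happen only at I/O boundaries (GTF in/out, feature-ID parsing), which keeps
off-by-one reasoning in exactly two small functions.

An exon feature is assigned to every transcript whose *genomic span*
(first-exon start to last-exon end) it overlaps by at least 1 bp — span
overlap, not exon-level intersection, so intronic signal of an isoform
still annotates to it. A junction is assigned to transcripts whose span
contains **both** anchors; requiring one anchor only would annotate
read-through junctions to transcripts they cannot belong to. This
both-anchor rule is a design decision, not an externally fixed convention.
Features with unknown strand match transcripts on either strand; a
known-vs-known mismatch excludes the match. Annotation is always performed
against one queried gene, so a feature overlapping two genes is simply
assigned to whichever gene the user asked about. The overlap engine is
`GenomicRanges::findOverlaps`; an all-pairs brute-force loop serves as the
oracle in the property tests.

# Clinical harmonization

Raw TCGA-style fields become small categorical vocabularies; every rule is
total, and anything unknown, missing or literally "Indeterminate"
(case-insensitive) becomes the literal category `UNDEFINED`:

* **Pack-years smoked**: cutoffs 10 and 100 give "less than 10" /
  "less than 100" / "greater than 100". The labels force half-open bins
  $[0,10)$, $[10,100)$, $[100,\infty)$; boundary values go up.
* **Overall survival**: event = death (1) iff `day_to_death` is present and
  non-zero — a recorded 0 is treated as no death, following the non-zero
  wording literally; time = the larger of `day_to_death` and
  `days_to_last_follow-up`; both absent gives a missing pair. The rules
  guarantee event = 1 never co-occurs with missing time.
* **Stage**: pathology/clinical/Masaoka stage strings collapse to
  I/II/III/IV/X. Parsing is case-insensitive, strips an optional "Stage "
  prefix and a single trailing substage letter A–C ("IS" is *not* "I");
  everything else is `UNDEFINED`.
* **Liver-cancer risk factors**: "Alpha-1 antitrypsin deficiency",
  "hemochromatosis" and "other" merge into "others"; "Alcohol consumption",
  "hepatitis b", "hepatitis c" keep their own class.
* **Alcohol per day**: "0" vs ">0".
* **Pregnancies**: "1".."5" and ">5". A recorded 0 falls outside the
  declared vocabulary; we map it to `UNDEFINED` rather than invent a
  seventh class (verified by exhaustive application over 0..12).

Rules are data, not code: the shipped `inst/extdata/clinical_rules.json`
can be replaced per cohort, and generic `numeric-binned` and `merge-map`
rule kinds cover new variables without code changes. `harmonize()` attaches
a per-variable report (category counts, `UNDEFINED` counts) so silent
vocabulary drift is visible.

# Survival grouping and estimation

Samples joined to an isoform's expression are split at a cutoff; the
default is the midpoint of the expression range, $(\min + \max)/2$ — note
this is *not* the median, so skewed expression gives unequal groups by
design. Expression exactly at the cutoff goes to the **high** group
(deterministic tie rule). The start-time control is a plain filter —
samples with `time >= start_time` are kept and re-zeroed — not a
delayed-entry (left-truncation) adjustment of risk sets; the distinction
matters statistically and is deliberately documented rather than hidden.
Curves come from the product-limit estimator (`survival::survfit` under the
hood), re-shaped to start at $(t=0, S=1)$ with one point per distinct event
time; censoring times are kept for tick marks. A log-rank wrapper
(`km_logrank`) is provided as an extra beyond the rendered display.

One estimator subtlety encoded in the tests: appending a censored
observation later than all event times adds no step, but it *does* enlarge
every risk set and therefore changes the survival values — that is the
definition, not a bug.

# Rendering

All three figure types are written as SVG text with fixed 3-decimal
coordinate formatting, stable element ordering and no timestamps, so
identical inputs give byte-identical files — an explicit design goal, since
reproducibility of figures is checked by hashing. Provenance data
attributes (`data-y`, `data-times`, `data-survival`, box-plot quartiles)
carry values at `%.12g` so documents can be parsed back and compared to the
matrices that produced them (the tests do this with `xml2` at 1e-9).

* **Main plot**: a top band of group colors, per-sample gene-expression
  bars, then one row per feature where each sample's usage is a vertical
  mark of height proportional to $y_{ij}$; samples are ordered within each
  group by ascending gene expression (ties broken by sample ID, stable),
  groups concatenated in given order. The left panel draws each transcript
  as exon boxes joined by an intron line under a linear genomic-to-pixel
  scale over the gene span.
* **Box plots**: Tukey convention — box at the quartiles (type-7), whiskers
  to the most extreme point within 1.5 IQR, outliers as dots. The
  convention is a choice; nothing upstream fixes it.
* **KM plots**: step paths (`H`/`V` commands, one vertical per event time),
  censor ticks, a legend carrying each group's size and the cutoff.
* Category-to-color assignment is deterministic by sorted label order from
  a fixed palette.

Interactivity (hover, knobs, genome-browser links) is out of scope; the
cutoff and start time are function arguments / CLI flags instead.

# The synthetic cohort generator

The generator exists so every step above is testable against known ground
truth without downloading anything. Defaults define the canonical study
condition used throughout the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 200 | cohort size (two groups of 100) |
| `group_fractions` | 0.5 / 0.5 | normal-like vs tumor-like |
| `exons_per_transcript` | 7 | full isoform's exon count |
| `cassette_index` | 4 | the skipped exon |
| `inclusion` | 0.9 vs 0.1 | cassette-isoform fraction per group |
| `noise` | 0.15 (sdlog) | multiplicative log-normal noise |
| `survival$baseline` | 8e-4 /day | exponential hazard at lowest expression |
| `survival$effect` | 1.2 | log hazard ratio across the expression range |
| `survival$censor_max` | 2500 days | uniform follow-up upper bound |

Within a gene, the first transcript carries all exons and later transcripts
each skip one internal exon — the classic cassette/skipped-exon pattern in
which one isoform's presence is read directly off one exon's usage. Per
sample, a log-normal gene abundance is split across isoforms by the
group-dependent inclusion level; exon values are sums of the abundances of
the isoforms containing the exon, junction values sums over isoforms
realizing that exon adjacency, each multiplied by independent log-normal
noise. Survival times are exponential with a rate increasing in the
designated isoform's (0–1 scaled) expression; censoring is an independent
uniform follow-up. Clinical categories are drawn *category-first* from
fixed tables and only then converted to raw strings, so the manifest's
expected category counts are ground truth by construction, independent of
the harmonization code they verify.

On the noise default: the parameter models *residual exon-to-gene ratio*
noise — expression noise shared by all of a sample's features cancels in
$r_{ij}$ — and for a decently expressed exon in RSEM-style data a 10–20%
coefficient of variation is the realistic "moderate" range; we use
sdlog 0.15. The choice matters because the 95th-percentile scale sits in
the noise tail: heavier independent per-exon noise inflates $Q_{95,i}$ and
shrinks everyone's usage toward the interior, attenuating group contrasts.

What the generator does **not** emulate: read-level sampling, length or GC
bias, batch effects, correlated noise across exons, more than one splicing
event per gene, informative censoring, or TCGA barcode semantics. Passing
tests on this cohort therefore demonstrate that the implementation computes
what it claims on data with a known signal — not that the statistic is
robust to every artifact of real cohorts.

# Problem sizes and determinism

The test suite runs cohorts of 200 samples for end-to-end checks and
4–60 samples elsewhere; the formula-equivalence property uses 1,000 random
matrices up to 10×50 (the acceptance script re-runs 200 of them plus the
full cohort). These sizes were chosen as the smallest at which the studied
contrasts are stable across seeds. All generators take a mandatory seed;
identical seed and configuration reproduce every output file byte for byte
(values are written with fixed formatting, and the manifest stores
file names relative to its own directory).

# Known limitations

* Gene expression is estimated from the features being normalized, so a
  gene quantified by very few features has a noisy $e_j$ and correlated
  usage rows.
* No differential-splicing statistic is computed — the package quantifies
  and displays; inference beyond the optional log-rank test is out of
  scope, as are PSI-from-reads, splicing-event classification, Cox models
  and confidence bands.
* The default KM cutoff (range midpoint) is sensitive to single extreme
  samples; the cutoff argument exists precisely because of that.
* Start-time filtering conditions on surviving to the start time without
  adjusting risk sets (no delayed entry).
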