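---
title: "Models and methods behind lncscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscreen)
```

`lncscreen` implements the downstream analysis workflow of a bulk RNA-seq
lncRNA study: novel-lncRNA discovery and positional classification,
threshold-based differential expression, a knockout-versus-wildtype
double-ratio screen with expression-profile clustering, and ceRNA
(miRNA-sponge) candidate discovery. This vignette records the models, the
parameters that matter, the numerical conventions, and the design decisions
that were genuinely open — so that results can be interpreted, and the
choices revisited, without reading the source.

## The genomic data model

All annotation work happens on a tidy exon table: one row per exon, 1-based
inclusive coordinates (the GTF convention), strand restricted to `+`/`-`.
Two derived per-transcript quantities anchor the coordinate conventions:

* `genome_span = max(end) - min(start) + 1` — the genomic footprint in bp;
* `transcript_length = sum(end - start + 1)` — the spliced length in nt.

Span is always at least the spliced length, with equality exactly for
single-exon transcripts; this invariant is property-tested. Transcripts with
`.` strand are rejected at parse time rather than silently kept, because the
positional lncRNA classes are strand-defined and an unstranded transcript
has no well-defined class. Interval overlap queries are delegated to
`GenomicRanges`/`IRanges` and are verified against a brute-force scan in the
test suite.

## Novel lncRNA discovery

A novel transcript becomes a lncRNA candidate when its spliced length is
**strictly** greater than `min_length` (default 200 nt — the conventional
lncRNA length floor) and it has at least `min_exons` exons. The exon
criterion is the one genuinely ambiguous filter in this workflow: the field's
standard multi-exon filter keeps transcripts with two or more exons, while a
literal "more than two exons" reading requires three. We default to
`min_exons = 2` (the community convention, and the weaker assumption) and
expose the literal reading as `min_exons = 3`; a three-exon transcript of
1925 nt passes either way.

Coding potential is decided by unanimity across four predictor verdicts
(CPC-like, CNCI-like, CPAT-like, and a protein-domain search where
"noncoding" means no domain hit). Unanimity is the strictest monotone rule:
flipping any verdict to "coding" can only remove candidates, never add them
(property-tested). Missing verdicts are a hard error rather than a silent
drop; `discover_lncrnas()` reports unscored transcripts separately. When no
external predictor table exists, `orf_verdicts()` fills the table from the
built-in three-frame ORF screen: the longest AUG-to-stop ORF (stop included)
per forward frame, with a coding-suspect flag at 300 nt (a 100-codon ORF,
the classical heuristic cutoff). The ORF screen is a transparent stand-in,
not a reimplementation of any trained predictor, and its output is labelled
as such (`attr(*, "source") == "orf_heuristic"`).

Positional classification applies four mutually exclusive rules with a fixed
precedence — sense (same-strand exon overlap), then intronic (extent
contained in a single intron of a same-strand transcript), then antisense
(opposite-strand overlap with a gene extent), then lincRNA. The precedence
order is our own: upstream tools do not publish their rules, so we rank by
the specificity of the evidence (exonic same-strand overlap is the strongest
statement, intergenic the weakest). Classification is invariant under exon
permutation and coordinate translation, and recovers planted classes exactly
on synthetic annotations.

Composition percentages are reported to one decimal using round-half-up
(base R's `round()` rounds half to even, which would print 56.25% as 56.2%
rather than the conventional 56.3%).

## Differential expression

FPKM follows the standard definition
`counts / (length_kb * totals / 1e6)`, and the computation inverts exactly
(re-multiplying recovers counts), which is tested.

The DE test is a two-group negative-binomial Wald test: size-factor
normalization (median-of-ratios over genes with no zero counts), group means
with a 0.5-count pseudocount, and a z-statistic on the log-mean difference
with variance `(mu + alpha * mu^2) / (n * mu^2)` per group (delta method).
`log2FC` is treated-over-control. Genes that are all-zero in both groups get
`log2FC = 0`, `p = 1`.

Dispersion estimation is the one place where we deviated from the most
literal design. Raw per-gene method-of-moments dispersion at n = 3 has only
four degrees of freedom; plugging it into a normal-referenced Wald statistic
produces a strongly anticonservative test, because underestimated dispersions
simultaneously shrink the SE and inflate the statistic. The package therefore
moderates dispersion with a mean–dispersion trend: per-gene MoM estimates are
pooled (untrimmed means) over 20 quantile bins of the gene mean and linearly
interpolated, with constant extrapolation beyond the outer bins and a floor
of 1e-8. This is the same information-sharing idea that mature DE tools use,
in its simplest form. The raw estimate remains available as
`dispersion = "per-gene"` for users who want it, with the calibration caveat
in its documentation. The test suite verifies that the default test rejects
at close to the nominal 5% rate under the null and detects planted 8-fold
changes with high sensitivity at the study thresholds.

The test is deliberately a *stand-in*, isolated behind `nb_test()`: the
pipeline accepts externally computed DE tables (any table with `log2FC` and
`p`) in `call_de()`, so a dedicated DE package's output can replace the
built-in test without touching anything else.

"Adjusted p-value" is interpreted as Benjamini–Hochberg — the default of the
ecosystem's standard DE tool — and implemented via `stats::p.adjust`, with an
independent hand-written step-up implementation serving as the test oracle.
Significance uses **strict** inequalities on both axes (`|log2FC| >`
threshold, `p_adj <` alpha), matching how thresholds of the form "> 2" and
"< 0.05" are printed; a gene at exactly the threshold is not called.
Thresholds are 2.0 (lncRNA calling) and 1.0 (mRNA DEG calling) at
alpha = 0.05.

The clustering/heatmap transform is `log10(FPKM + 1e-6)` followed by per-row
z-scoring. The 1e-6 pseudocount is fixed by the convention that zero FPKM
maps to −6 before standardization. "Normalized" in heatmap legends is read as
per-row z-scoring — the heatmap-package default — and constant rows map to
all-zeros rather than NaN.

## The knockout double-ratio screen

The screen works on per-gene group summaries of a WT/KO × 0h/4h design:
group-mean FPKM (means over replicates are taken *before* ratios, since the
screen's formulas are written on group values) and group-total read counts.

* **Low-count removal.** A gene is removed when its total reads are below
  `min_reads = 5` in *every* one of the four groups — the literal reading of
  "fewer than five total reads in each group". The stricter any-group variant
  is a config switch (`low_count_rule = "any"`).
* **Induction difference ratio** `r_diff = (KO4h − KO0h)/(WT4h − WT0h)`.
  A pseudocount added to each term cancels in the differences, so none is
  applied. A zero denominator yields a signed-infinity sentinel: `+Inf`
  counts as "> 2", `-Inf` (and any negative ratio) counts as "< 0.5", and
  0/0 is defined as 1 (no induction anywhere is a neutral ratio).
* **Relative fold-change ratio** `r_fc = (KO4h/KO0h)/(WT4h/WT0h)` with a
  pseudocount `eps = 0.01` FPKM added to every term; with `eps = 0` a zero
  in a denominator position is a hard error. 0.01 FPKM is negligible against
  typically expressed genes but regularizes the ratio at the detection floor.
* **Selection** requires *both* ratios extreme (`> 2` or `< 0.5`, strict) —
  the criteria are conjunctive. Selection is scale-invariant and (for finite
  positive ratios) invariant under exchanging the WT and KO roles, since
  `r -> 1/r` maps the acceptance region onto itself; both are
  property-tested.

Selected genes are clustered on their transformed group-mean profiles:
Euclidean distance, complete linkage — the defaults of the heatmap package
this workflow's figures conventionally use — and the tree is cut at `k = 3`,
the number of profile classes the screen is designed to report. Class labels
I/II/III are assigned by descending cluster size with ties broken by the
lexicographically smallest member gene id, making labels deterministic. If
every profile is identical the clustering is degenerate: the package warns
and assigns a single class rather than fabricating structure.

## ceRNA candidate discovery

Seed matching is canonical and fully transparent: the seed is miRNA positions
2–7 (core) or 2–8, 1-based from the 5′ end; target sites are perfect
Watson–Crick reverse-complement matches of the core, classified as 8mer
(match of seed 2–8 plus a 3′ `A` anchor), 7mer-m8 (seed 2–8), 7mer-A1
(seed 2–7 plus `A`), or 6mer, in that priority. Sites are anchored at the
core locus: at one core position only the highest-priority class is
reported, while distinct (possibly overlapping) core positions are all
reported. G:U wobble pairing is **not** allowed — the conservative default;
allowing wobble only adds candidate sites, and a rule-based scanner should
err toward precision. Matching happens in RNA space; DNA input is converted
losslessly.

This scanner deliberately replaces trained target-prediction models (which
are out of scope and not reproducible from rules): consequently the package's
dual-binder Venn counts describe what canonical seed matching supports, not
what any trained predictor would score. The scanner is verified
site-by-site against a brute-force every-window oracle on randomized
sequences.

Sponge candidates are panel miRNAs with at least `min_sites` sites on both
the lncRNA and the 3′UTR (default 1; raising it tightens candidacy
monotonically — tested). `delete_sites()` excises non-overlapping site spans
and returns a coordinate map; `rescan_mutant()` re-scans the mutant, maps
sites back, and flags (with a warning) any site whose mapped-back span is
non-contiguous, i.e. created across an excision junction.

## What the synthetic data emulate — and what they do not

The generators produce every input the pipeline reads, each with a truth
table, under one `generator_config()`. Defaults encode the study conditions
the package is designed around: a 0/2/8/24 h time course with n = 3 and a
featured transcript peaking 16-fold at 2 h; planted DE counts of 81/433/83
per timepoint; a WT/KO × 0h/4h screen with 53 regulated genes among 5000
background genes plus a 200-gene low-count stratum; a 10-miRNA panel with 6
dual binders whose featured member has two 8mer sites on each target. The
default seed is 20369; any integer works.

Key generator choices:

* **Screen margins.** Background genes are constructed with both ratios in
  [0.85, 1.2]; regulated genes follow three archetypes (knockout
  hyper-induction; concordant down-regulation, stronger in the knockout;
  wildtype induction reversed in the knockout) whose ratios exceed 4 or fall
  below 0.25 — a factor of ~2 beyond the selection thresholds on either
  side. At `noise_cv = 0` recovery is therefore exact by construction; the
  default replicate noise (`noise_cv = 0.1`, a typical replicate coefficient
  of variation for well-expressed genes) leaves several standard errors of
  margin, and the suite checks sensitivity ≥ 0.9 there.
* **Clean seed-site truth.** Random sequences of realistic length would
  contain accidental 6-nt seed matches with high probability (expected
  ~0.7 accidental sites per miRNA over ~2.7 kb of target). Rather than
  recording accidents into truth — which would make "exactly k dual binders"
  depend on the seed — the generator rejection-samples panel miRNAs whose
  seed-core complement is absent from both targets, plants sites
  explicitly, and then audits the finished instance with the scanner,
  requiring found == planned. The recorded truth is therefore exact for
  every seed. The cost is a small unrealism: synthetic panels have no
  background sites at all, so the screen's false-positive behaviour on
  *sequence* background is not exercised by these data (the scanner itself
  is instead validated against the brute-force oracle on fully random
  pairs, where accidental matches abound).
* **Counts/FPKM consistency.** Screen counts are derived from the FPKM
  values at a fixed transcript length (1 kb) and depth (2 × 10⁷ fragments),
  so the low-count stratum is low in reads *because* it is low in FPKM, as
  in real data.
* **NB parameterization** is (mean, dispersion) with variance
  `mu + dispersion * mu^2` throughout (dispersion 0.05 by default, a typical
  bulk RNA-seq value for moderately expressed genes; 0 gives deterministic
  rounded means).

What passing tests on these data show: the pipeline's logic — filters,
rules, ratios, clustering, scanning — is correct against planted truth, and
the DE test is calibrated under its own model. What they do not show:
robustness to mapping artefacts, 3′ bias, batch effects, overdispersion
heterogeneity beyond the mean trend, isoform ambiguity, or non-canonical
miRNA binding. Real-data conclusions still require the real upstream inputs.

## Problem sizes and determinism

The test suite and the acceptance script run the stages at the scales the
methods are designed for where that is cheap (the full 53-among-5000 screen,
1000-pair scanner oracle, 10,000-gene null calibration, 100 classification
replicates) and at reduced scale where only the logic is under test. All
randomness is seeded; generators are deterministic functions of
`generator_config()$seed`, and two pipeline runs with the same config
produce byte-identical tables (tested).

## Known limitations

* The NB Wald stand-in does not implement shrinkage of fold changes or
  outlier handling; very low counts at n = 3 remain hard, and users with
  real data should prefer a dedicated DE package and inject its table.
* Positional classification assumes a gene's transcripts share a strand and
  uses gene *extents* for the antisense rule; unusual loci (bidirectional
  or nested genes) inherit the precedence order's judgement.
* The seed scanner ignores binding context (site accessibility, pairing
  energy, conservation); it enumerates candidate sites, it does not rank
  them.
* `cluster_classes()` with `k = 3` imposes three classes; it does not test
  whether three is the right number.
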