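---
title: "lncwhiten: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncwhiten: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lncwhiten)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It is written for someone who wants to audit or
extend the pipeline, not just run it.

## The problem

Interscapular brown adipose tissue whitens with age: thermogenic,
UCP1-rich brown tissue converts to a white-like, lipid-storing phenotype.
A staged bulk RNA-seq design over that conversion (here four stages,
newborn through aged, three biological replicates each) lets one catalogue
the long non-coding RNAs active in the depot and nominate candidate
regulators. The raw materials are upstream outputs — a reference
annotation, a merged transcript assembly, count and TPM matrices, and
coding-potential calls from CPC2, CPAT, CNCI and Pfam — and the analysis
is a chain of filters, classifications and tests. `lncwhiten` implements
that chain with explicit contracts at every step.

## Coordinates and containers

All intervals are 1-based and closed, the native GRanges convention, so
GTF input and output need no coordinate shifts. Transcripts live in a
`transcript_set` (exon `GRanges` plus a per-transcript table); the
reference is compiled into an `annotation_index` holding gene bodies
(union span of each gene's transcripts — the common convention where an
annotation does not define gene extents itself), exons, derived introns
and intron-chain keys. Expression lives in an `expr_matrix` whose stages
form an ordered factor; raw counts must be exactly integral (a count of
3.5 is an input error, not something to round), TPM any non-negative real.

## Identification

The structural filter keeps transcripts with length $\ge$ 200 nt (a 200-nt
transcript is kept: only strictly shorter ones are discarded), $\ge$ 2
exons, and TPM strictly above 0.1 in at least one sample. The same TPM
rule is applied to reference-annotated lncRNAs before they are merged into
the catalogue — the expression filter describes what is *expressed*, and
there is no reason to exempt annotated models from it.

Positional classification follows a fixed precedence, mirroring the
o/x/i/u class codes of assembly-comparison tools:

1. same-strand exonic overlap **and** an exact intron-chain match with a
   reference transcript → `rejected_known`;
2. same-strand exonic overlap otherwise → `sense_overlapping`;
3. opposite-strand exonic overlap → `antisense`;
4. containment in a single intron of a single reference transcript
   (either strand) → `intronic`;
5. no gene-body overlap at all → `lincRNA`;
6. everything else (gene-body overlap without exonic overlap, spans
   crossing exon/intron boundaries) → `rejected_known`.

Two deliberate refinements: single-exon transcripts never match an intron
chain (they have none), and "intronic" requires containment in one intron
of one transcript, either strand — strandedness of intronic assignment is
recorded in the output for audit. The classifier is verified in the test
suite against an independent brute-force oracle on random annotations, and
is invariant under chromosome renaming and coordinate translation.

The coding-potential consensus is an intersection: a transcript is a
credible lncRNA only if all four predictors call it non-coding. A missing
call fails the consensus (conservative) and is warned about. `longest_orf`
is shipped only as a deterministic stand-in predictor (non-coding iff the
longest forward-frame ATG..stop ORF is under 100 codons) so end-to-end
tests need no external tools; it requires a terminating stop codon to
count an ORF.

## Cis-targets and the correlation screen

Genic lncRNAs (AS, intronic, SO) target the protein-coding genes whose
locus overlaps them (`host`, distance 0). lincRNAs target every
protein-coding gene within 100 kb, measured as the gap between closest
boundaries (not midpoints), boundary inclusive. Correlations are Pearson
on raw TPM across all samples (a `log2p1` flag switches to log2(TPM+1));
p-values use the t approximation on $n-2$ degrees of freedom. No
multiple-testing correction is applied in this screen — it is reported at
nominal p < 0.05, as such screens conventionally are — so its hit rate
should be read as descriptive, and shared library-size fluctuations will
inflate it on real data. Per-category summaries count lncRNAs, not pairs:
an lncRNA with several targets counts once if any partner is significant.

## Transcriptional complexity

For a stage (replicate-mean TPM; a per-sample mode exists), features are
sorted descending and the cumulative share of total expression is
computed; `top_k_fraction(x, k)` is the curve at rank `k` (capped at the
feature count). The statistic is invariant under permutation and positive
scaling; ties are broken by feature id purely for determinism (ties cannot
change the curve's values). Curves are computed over the *retained* lncRNA
set — features that failed the expression filter are not part of the
denominator.

## Differential expression

The paper-grade tool for this job is DESeq2; this package instead ships a
small, fully documented NB Wald test so that every number is reproducible
from first principles, and keeps DESeq2 only as a cross-check oracle in
the tests (for size factors). The pieces:

- **Normalization**: median-of-ratios size factors (the median, per
  sample, of count ratios to per-feature geometric means).
- **Dispersion**: per-feature method of moments pooled across the two
  groups, $\hat\alpha = \max(0, (s^2-\bar\mu)/\bar\mu^2)$. With three
  replicates this estimate has ~4 degrees of freedom and is far too noisy
  to plug into a normal-reference Wald test: doing so yields an empirical
  type-I error of ~0.13 at a nominal 0.05. We therefore floor each
  feature's $\hat\alpha$ at the across-feature median — borrowing strength
  across features in the spirit of DESeq2's dispersion moderation — which
  restores the nominal level (measured 0.049–0.052 across NB scenarios
  with $\mu$ 20–200 and $\alpha$ 0.02–0.2 at $n=3$) while keeping full
  power for strong effects. The cost is mild conservatism for features
  whose true dispersion is far below the population median.
- **Test**: log2 fold change on pseudocounted (0.5) normalized group
  means; delta-method SE with $\mathrm{Var}(m) = (m + \alpha m^2)/n$;
  two-sided normal p; BH adjustment within each comparison.
- **Calling**: DELs at |log2FC| > 1.5 and FDR < 0.01, strict inequalities.
  Up means higher in the later stage of the comparison (B vs A); the
  conventional sign is used throughout.

Not implemented, deliberately: fold-change shrinkage, outlier handling,
independent filtering, GLM designs beyond two groups. Users comparing
against DESeq2 output should expect agreement in direction and rough
magnitude, not numerically identical statistics.

## Patterns and enrichment

The DEL union is clustered with k-means (k = 8 by default, matching the
eight recurring stage patterns of the whitening course) on row-z-scored
stage-mean TPM; z-scoring (population SD) makes the clustering about
*shape*, not level — a raw-TPM mode would let abundance dominate.
`stats::kmeans` (Hartigan–Wong, 25 restarts) does the optimization;
labels are renumbered canonically (by each cluster's first feature id) so
identical fits compare equal across runs, and the fit is deterministic
given the seed. Enrichment is the standard upper-tail hypergeometric test
of each cluster's cis-target genes against a user-supplied GMT file, with
the universe defaulting to all genes in the pathway map, and no
multiple-testing correction (raw p < 0.05), as in the screen above.

Candidate ranking is filter-then-sort: DEL in at least one comparison,
at least one significant cis correlation, ordered by peak stage-mean TPM.
The criteria (abundance, differential expression, correlation) have no
published weighting; a fixed, reproducible rule was chosen over an
arbitrary composite score.

## The synthetic world

`generate_dataset()` emulates the study design rather than any particular
dataset: 2 chromosomes, 200 non-overlapping multi-exon protein-coding
genes with alternating strands and 20–80 kb intergenic gaps, 30 annotated
lncRNAs, and 120 planted novel transcripts — 50 lincRNA, 25 antisense, 25
intronic, 15 sense-overlapping, 5 exact copies of reference structures —
each built to satisfy its category's defining predicate under the
classifier's documented precedence, all ≥ 200 nt with ≥ 2 exons. Counts
are negative binomial (dispersion 0.05, a typical bulk-RNA-seq biological
value) around per-stage means: a log-normal base level times one of eight
stage-pattern archetypes (early peak, biphasic, monotone rise/fall, late
burst) for 40% of novel lncRNAs, flat otherwise. TPM is derived from the
sampled counts by length normalization and per-sample scaling to 10⁶.

Three calibration choices are part of the stated world and were fixed
before the tests were frozen:

- lncRNA base means are well below gene base means (log-normal meanlog
  2.5 vs 6), mirroring the observation that lncRNAs are much less
  expressed than coding genes; this also keeps lncRNA output a small share
  of the TPM denominator, so the dominance construction below does not
  compositionally distort other features' TPM.
- Archetyped features get a base-mean floor of 30 expected counts, so the
  generator's contract — planted differential expression is recoverable
  end-to-end at default depth — holds.
- Planted correlation pairs share their stage profile (inverted for
  negative pairs) plus a mild 15% log-normal per-sample co-fluctuation;
  the profile sharing carries the signal, and the latent keeps within-stage
  correlation without drowning the planted fold changes in replicate noise.

Dominance is planted by rescaling the classical-BAT-stage means of the ten
strongest (non-pair) lncRNAs so they carry exactly 80% of
length-normalized lncRNA output at that stage — the share the top-10 curve
then reproduces within Monte-Carlo noise (measured 0.79–0.80 across
seeds).

What the generator does **not** emulate: read-level artifacts, alignment
and assembly errors, batch effects, GC bias, annotation incompleteness,
and isoform-level ambiguity. A green end-to-end test therefore establishes
that the pipeline's logic and statistics behave as specified on data that
satisfy its assumptions — not that any upstream tool chain was run
correctly.

The truth ledger records every planted fact (categories, per-stage means
and per-comparison true log2 fold changes, pair signs, dominant ids,
flipped coding calls, the designated enriched pathway). The end-to-end
test asserts exact recovery of categories and planted DELs, and tolerates
up to five unplanted DEL calls — which is not slack: at FDR < 0.01 with
~300 discovery events over six comparisons, a few false discoveries are
exactly what the error rate licenses.

## Numerical conventions and degenerate inputs

- Zero-variance vectors: correlations are flagged `ns` with a warning;
  z-scoring drops constant rows with a warning; complexity curves error on
  all-zero input (the fractions are undefined).
- Features with zero counts in both groups get log2FC 0 and p 1.
- Size factors require at least one feature with nonzero counts in every
  sample; the error message points to a pseudo-reference fallback as the
  remedy rather than silently switching to one.
- BH adjustment validates p ∈ [0, 1] and never returns a value below the
  raw p.
- All randomness — generator, k-means restarts — flows through explicit
  seeds; generator outputs are pure functions of (spec, seed).

## Interfaces

This is a library-first package: the exported functions, the synthetic
generator and `run_pipeline()` (bundle in, report + tables out, optional
TSV output directory) are the interface, with `scripts/acceptance.R` as a
worked headless entry point. File formats are the field's: GTF for
transcript models, TSV for matrices and metadata and per-predictor call
tables, GMT for pathways.

## Known limitations

- The NB test is two-group only; time-course trends are captured through
  the six pairwise comparisons, not a spline or LRT model.
- The correlation screen is associational; "cis-target" means positional
  proximity plus co-expression, not a regulatory claim.
- Classification trusts the reference: genes absent from the annotation
  make their antisense/intronic partners look intergenic.
- The hypergeometric universe defaults to the pathway map's gene set;
  with sparse maps this can overstate enrichment and should be set
  explicitly when it matters.
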