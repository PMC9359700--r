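---
title: "Models and methods behind polycage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polycage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycage)
```

polycage analyses strand-specific CAGE transcription start site (CTSS)
count tracks from total RNA and polysome fractions of two biological
conditions (a healthy control, `WT`, and a disease condition, `TCL1`).
This vignette explains the models, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
choices made where several reasonable options existed.

## From CTSS tracks to promoters

Each sample is a strand-specific map of genomic base to tag count — the
number of capped 5' ends observed at that exact position. Counts are
scaled to tags per million (TPM) per sample, and the pooled TPM signal
over all total-RNA samples is clustered with the slice-reduce approach:
positions at or above `slice_threshold` (default 0.1 TPM) are kept, and
kept positions within `merge_dist` (default 20 bp) on the same strand
are merged into one tag cluster. The pooled signal names the approach's
parameters as configuration because the approach itself is conventional;
the defaults here follow the widely used CAGE tooling the field settled
on. The cluster peak is the leftmost position of maximal pooled signal —
a deterministic tie-break.

Promoter width is measured as the span holding the central 10–90% of
each cluster's cumulative pooled signal, which trims straggler tags that
stretch a cluster without contributing expression. Widths of 1–10 bases
define sharp promoters, 11–100 bases broad promoters; wider clusters are
kept but excluded from shape-based analyses. Clusters are retained only
if at least one condition has all replicates at or above 1 TPM. The
quoted filter ("less than 1 TPM in the two libraries of either
condition") is ambiguous about quantifier order; the reading implemented
keeps condition-specific promoters, which the downstream
condition-specific TSS analyses require. Whether the pooled signal
should combine all samples or each condition separately is likewise
unstated upstream; pooling all samples is the default and per-condition
pooling is available by subsetting the track list.

## Enhancer candidates

Active enhancers transcribe short capped eRNAs divergently and in a
balanced way. A candidate is a minus-strand cluster paired with the
nearest plus-strand cluster downstream of it within a 400 bp
peak-to-peak window (the window size is a documented choice; the
upstream literature does not fix one). With arm sums \(D\) (minus, the
upstream arm) and \(U\) (plus, downstream) and fractions
\(d = D/(D+U)\), \(u = U/(D+U)\), the balance score is the Bhattacharyya
coefficient against a perfectly balanced split:

\[B = \sqrt{d/2} + \sqrt{u/2} \in [\sqrt{1/2},\, 1],\]

maximal exactly at \(d=u=1/2\). Candidates with \(B \ge 0.95\) are
called enhancers; their constituent clusters are removed from the TSS
cluster set so that one locus is never typed both ways. Enhancer–TSS
links require genomic distance at most 50 kbp, positive Pearson
correlation of log2(TPM+1) expression across total-RNA samples, and a
two-sided correlation p below 0.05. Arm expression is summed for the
correlation — a documented choice, since the upstream method leaves it
open.

## Gene structure and alternative promoters

Each cluster's peak is tested against same-strand transcript features
with precedence promoter > 5' UTR > CDS > exon > intron (promoter =
annotated TSS ± 100 bp), then opposite-strand overlap (antisense), else
intergenic. The precedence order is the field's convention for CAGE
annotation; ties across transcripts break by distance to the annotated
TSS and then gene identifier, so the calls never depend on input order.

Within a gene, clusters are converted to shares of the gene's pooled
expression; clusters under 10% are dropped from the multi-TSS analysis.
The canonical TSS is the retained cluster at the annotated promoter if
one exists, otherwise the highest-expressed retained cluster
(expression ties break to the transcript-5'-most peak). This hybrid
annotation/expression rule is a documented decision — the source
analyses do not state which convention they used — and it behaves
sensibly at both extremes: a gene whose annotated promoter is silent
still gets a canonical TSS, and an annotated promoter is never demoted
by a marginally stronger intra-genic cluster.

An alternative TSS at or upstream of the annotated start codon
(promoter, 5' UTR) retains the ORF; one downstream of it (CDS, intron)
truncates or modifies the N terminus. The boundary base — a peak exactly
at the first base of the start codon — is classified truncating, since
the complete codon is no longer upstream of the transcript body. For
ORF-retaining TSSs the 5' UTR is read along the spliced exonic path and
upstream AUGs are counted in all frames with overlaps allowed.

## Differential expression and TSS usage

Counts are modelled as negative binomial. Size factors are
median-of-ratios (total-count fallback). Dispersions are per-unit
method-of-moments estimates on normalized counts, shrunk toward the
common dispersion (default weight 0.8) and floored at 1e-8. The common
dispersion is the *mean* of the per-unit moment estimates over expressed
units: at two replicates per condition each per-unit estimate has about
two degrees of freedom, and a median of such estimates sits roughly 30%
low, which makes the downstream test anticonservative.

The Wald test evaluates the log2 fold change of `TCL1` vs `WT` against
a standard error computed at the pooled mean (the score-test
convention) and inflated by 5% as a finite-replicate correction. Both
choices were fixed by calibration simulations at the study's design of
two replicates per condition: with them, the null rejection rate at
nominal 0.05 sits near 0.05 across dispersion regimes (the acceptance
suite pins it to [0.03, 0.07] over 2000 units), while 4-fold effects at
moderate counts are detected with essentially full power. Multiple
testing is Benjamini–Hochberg; up/down status is called at FDR < 0.05.

Differential TSS usage (promoter shifting) is tested per retained
cluster of each multi-TSS gene. The reported effect is the cluster's
condition log2 fold change minus the gene's (counts summed over its
retained clusters): invariant to any shared condition factor on the
whole gene. The p-value contrasts the cluster against the *rest* of the
gene rather than the gene total, because cluster and rest are
independent under the NB model while cluster and gene total are not;
the two effect definitions are proportional, so direction and ranking
agree. Gene-level aggregation of per-TSS p-values is deliberately left
out of the default output.

Sample QC uses pairwise Pearson correlation and PCA of centered
log2(TPM+1) via SVD. The log transform stands in for the
package-internal variance-stabilizing transform of the upstream
tooling; it is documented output, not a claim of equivalence.

## Translation efficiency

For the profiled disease condition, per-unit TPM is computed within
each polysome fraction (Free, Light, Heavy) separately, so fraction
sequencing depths cancel, and

\[\mathrm{TE} = \frac{\mathrm{TPM}_{\mathrm{Light}} +
\mathrm{TPM}_{\mathrm{Heavy}} + \varepsilon}{\mathrm{TPM}_{\mathrm{Free}}
+ \varepsilon}, \qquad \varepsilon = 1\ \mathrm{TPM}.\]

The pseudocount is exposed in configuration and reported with the
output; no value is stated by the source analyses. Within each
multi-TSS gene the canonical TSS is paired with each retained
alternative; the alternative is Differential High-TE if its TE is at
least twofold the canonical's, Differential Low-TE if at most half, and
the classification is mirror-symmetric in the pair. ORF-truncating
alternatives are additionally scored by their polysome-fraction signal
relative to the canonical TSS: a ratio of at least 50% marks a
substantial truncation impact (a zero canonical polysome signal yields
an infinite ratio, labelled substantial and flagged). The inclusive
log2 fold change of a shift adds the alternative TSS's condition fold
change and the log2 alternative/canonical ratio within the disease
condition. The source describes this score only verbally; the additive
definition is a documented decision and both addends are reported so
any other combination can be recomputed.

## Cap-proximal sequence effects

The first transcribed bases are read off the genome strand-aware: on
the minus strand the k-mer is the reverse complement of the window
ending at the CTSS. TE at single-CTSS resolution (replicate-pooled
Polysomes vs Free, same pseudocount, minimum 1 TPM in both pooled
tracks) is grouped by start k-mer; groups under 50 CTSSs are dropped as
their medians are unstable. The per-CTSS (rather than per-cluster)
resolution matters because neighbouring CTSSs within one promoter can
differ sharply in TE. The analysis covers CTSSs inside TSS clusters
only: enhancer-arm CTSSs sit overwhelmingly in the Free fraction
regardless of their first bases and would dilute any start-nucleotide
contrast. CNY starts are trinucleotides with C first and a pyrimidine
third. Start-nucleotide frequencies are TPM-weighted by default, since
the quantity of interest is transcripts, not distinct positions.

## Motif analysis

JASPAR-format position frequency matrices are converted to log2-odds
with a pseudocount of 0.8 distributed by the background frequencies.
Windows of −1000..+100 around cluster peaks are scanned on both
strands; a motif is present when its best relative score
\((s - s_{\min})/(s_{\max} - s_{\min})\) reaches 0.85. A relative-score
threshold is reproducible without a background model, which is why it
replaces the upstream matcher's unstated p-value cutoff. Enrichment of
upregulated alternative-TSS promoters against all upregulated promoters
uses a one-sided Fisher exact test per motif with BH correction; odds
ratios are Haldane-corrected when a cell is zero.

## The synthetic-data generator

The generator builds a single-chromosome random genome with one
transcript per gene (5' UTR, spliced CDS with two introns, annotated
start codon), places alternative promoters in multi-TSS genes (in the
5' UTR, retaining; or in the first intron, truncating), and puts
balanced divergent enhancer pairs, arms 180 bp apart, into dedicated
intergenic space. Counts are negative binomial (dispersion 0.05) around
per-condition means shared across replicates; two replicates per
condition mirror the study design, and Free/Light/Heavy fractions are
generated for the disease condition only, which is the condition that
was polysome-profiled. Planted condition effects are log2 fold changes
of 1.5 on alternative TSSs (60% upward) and on a quarter of single-TSS
genes.

Polysome partitioning follows a logit model per CTSS: baseline
log-odds \(b_0 = \log 250 + 2 + \log 2\) (a typical transcript with a
~250 base UTR and ~4 upstream AUGs in random sequence is about
two-thirds polysomal; a lower baseline would push repressed starts
under the 1-TPM per-CTSS filter, censoring the very positions the
cap-proximal analysis needs), shifted by \(-\log(\mathrm{UTR\ length})\), \(-0.5\) per upstream AUG,
and \(+\log(0.25)\) for CNY starts; Light and Heavy split the polysome
probability equally, and the three fraction expectations sum exactly to
the total-transcript expectation. Start trinucleotides are not planted:
they are read off the simulated genome, so extraction and recovery
round-trip exactly, and CNY occurs at its natural random-sequence rate
(~12.5%). Enhancer CTSSs are 90% polysome-free. Per-cluster depth
averages ~3000 tags so that 1 TPM corresponds to several tags, matching
the depth-to-promoter-count relationship of real CAGE libraries; at toy
depths the 1-TPM per-CTSS filter degenerates into a zero-count censor
and distorts TE medians.

What the generator does not emulate: mapping artifacts and the
CAGE-specific G-bias (the simulation starts at CTSS level), splice
isoform diversity beyond one transcript per gene, chromatin context,
correlated noise between fractions, and sequence composition biases of
real promoters (CpG islands, TATA boxes). Tests passing on this
generator therefore validate the pipeline's inference machinery and its
bookkeeping, not the biology of any real dataset.

Problem sizes used in the shipped checks are a deliberate compromise:
the default configuration (80 genes) exercises every stage end-to-end
in seconds, while parameter-recovery checks use 500 genes with 180
multi-TSS genes, which yields well over 200 CNY and 200 non-CNY CTSSs
and enough clusters that the median-of-heavy-tailed-odds ratio
estimator is stable.

## Degenerate inputs and numerical conventions

Internally all coordinates are 0-based half-open; GTF is converted on
read and write. Zero-signal clusters, empty tracks, all-zero count
units, zero-variance samples and constant matrices raise explicit
errors or flagged values rather than silent zeros. Minus-strand CTSS
positions are the 5'-most transcribed base, so k-mer extraction
reverse-complements. A documented inconsistency in the source material
(the Light fraction described as 2–4 ribosomes in one place and 2–5 in
another) is irrelevant at CTSS level, where fraction identity comes
from the sample sheet.

## Known limitations

The NB Wald test with moment dispersions is a transparent,
property-tested stand-in for the heavier shrinkage machinery of the
established DE packages; at two replicates its power profile is
similar but not identical. The per-TSS DTU test does not aggregate to
gene-level p-values. Enhancer calling uses CAGE signal geometry only —
no chromatin marks. Motif presence is binary at a fixed relative score;
no positional prior within the window is used.
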