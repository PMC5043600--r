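---
title: "Detecting A-to-I RNA editing in single cells: model, filters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA, and
sequencers read inosine as guanosine, so true editing events surface as
A-to-G mismatches between RNA reads and the genomic reference. In
single-cell RNA-seq the signal competes with sequencing errors, germline
SNPs, and alignment artifacts, all at low per-cell coverage. `editomics`
implements a complete detection-and-analysis chain for this setting: a
per-transcriptome binomial error model, a cascade of eight orthogonal
filters, an A-to-I retention rule anchored on Alu elements and a
known-editing-site catalogue, and cohort-level analytics (editing level,
frequency-matrix clustering, expression associations, stage-specificity
tests). A synthetic-data generator with full ground truth exercises every
step.

## Detection model

For each cell, the background mismatch rate `p` is the fraction of
quality-passing aligned bases (base quality >= 20) that disagree with the
reference — a per-transcriptome quantity, since library quality differs
between cells. At a site with `n` mapped reads of which `k` support a
variant, the probability that all `k` mismatches are sequencing errors is
the upper binomial tail P(X >= k), X ~ Binomial(n, p), computed through
the regularised incomplete-beta identity (`pbinom`), which is stable for
the tiny tails involved. The test is one-sided: errors can only inflate
`k`, so only an excess of mismatches is evidence against the error model.
P values are Benjamini–Hochberg adjusted within each cell by default (the
error model is per-transcriptome, so the natural multiple-testing family
is the cell's mismatch sites; `bh_family = "global"` pools instead).
Candidates must then clear hard gates: adjusted P < 0.01, depth >= 4,
variant support >= 3, and mismatch frequency k/n >= 0.1.

Multi-allelic columns are tested per alternate allele against the same
`n`, and only the majority alternate is carried forward (logged). The
strand of a base is the alignment strand of its read — the libraries this
chain targets are not strand-specific, which also drives the T-to-C
handling below.

## The filter cascade

Every post-threshold detection receives an independent verdict from each
filter; the retained set is the conjunction, so filter order cannot
change the result (the attrition table reports survivors in a canonical
order purely for bookkeeping). Thresholds are `pipeline_config()` keys;
defaults below.

* **Strand bias** (Fisher alpha 0.005): two-tailed Fisher's exact test on
  variant/reference x sense/antisense supporting reads. With variant
  strand frequency `v` and reference strand frequency `r`, a site fails
  iff (P < 0.005 and |v − 0.5| > |r − 0.5|) or v > 0.9 or v < 0.1. When
  zero reference reads make `r` undefined, it is taken as 0.5 — the FET
  branch then cannot fire (a zero margin gives P = 1) and only the
  absolute v bounds apply.
* **Position bias** (Fisher alpha 0.05): same construction on
  variant/reference x read-end/read-middle bases, where a read end is the
  last 10 bases toward the 3' end or the first 5 toward the 5' end of the
  biological read (measured after trimming; for minus-strand alignments
  the stored sequence is reversed, so end status is computed on the
  original read orientation). Fails iff (P < 0.05 and end frequency >
  middle frequency) or end frequency > 0.9. The published table layout is
  only printed for the strand filter; the position table mirrors it.
* **Realignment support** (>= 90 %): each variant-supporting read is
  re-placed by local alignment (match +1, mismatch −3, gap open −5, gap
  extend −2) against a combined genome+transcript reference; the site
  survives if at least 90 % of its variant reads have a best placement
  covering it. Tied best placements count as covering if any tie covers
  the site; a `strict` switch requires all ties to. The aligner is a
  pluggable contract (read, reference) -> placements, defaulting to
  `Biostrings::pairwiseAlignment`. Pileup-only input carries no read
  sequences, so the verdict is then `not_applied`.
* **Region masks**: simple-repeat intervals; reference same-base runs of
  length >= 5 that contain or directly abut the site (measured on the
  reference strand); and, for non-Alu sites only, positions within 5 bp
  of an annotated exon–intron boundary (inclusive, genomic distance).
* **Known SNPs**: membership in the union of supplied DNA SNP lists,
  allele-aware when the list carries an alternate allele.
* **Recurrence**: sites detected in cells of exactly one embryo are
  removed — rare private SNPs masquerade as editing, while true editing
  recurs across individuals.
* **Frequency cap**: mismatch frequency > 0.95 (strict) indicates a
  homozygous genomic difference rather than editing.

## A-to-I retention and annotation

Among surviving mismatches, the editome keeps Alu A-to-G unconditionally
and non-Alu A-to-G only when present in the known-editing catalogue
(most genuine human editing is Alu-borne; outside Alu the false-positive
risk warrants the whitelist). Because the libraries are unstranded, a
genomic T-to-C over a minus-strand gene is the same biochemical A-to-G
event read from the other strand; the default `transcript_sense` mode
retains such sites under the same Alu/catalogue rule, while `strict`
drops all T-to-C — both are tested. Everything else stays in the
mismatch spectrum but not the editome.

Genic features are assigned by precedence CDS > 5'UTR > 3'UTR > ncRNA >
intronic > intergenic across all overlapping transcripts (the upstream
annotator's behaviour is not published; the precedence is explicit and
configurable here). Coding effects rebuild the codon in transcript
orientation and translate with the standard code; initiator-codon
semantics apply only to the first codon. miRNA-target overlap requires
both a seed-match interval hit and a 3'UTR feature. Neighbour preference
reports G fractions at −1/+1 of the edited adenosine, reading the
reverse complement for T-to-C sites.

## Cohort analytics

The editing level is edited bases per million uniquely mapped bases.
"Edited bases" sums a cell's variant-supporting reads over the *cohort*
union of retained sites: the editome is a cohort-level object, and
counting only a cell's own re-detections would couple the statistic to
sequencing depth through detection power at marginal frequencies. A
per-site variant (counting sites, not bases) sits behind `per_site`.

The editing matrix stores frequency where detected, 0 where covered
(depth >= 4) but unedited, and −1 where depth < 4; cells are clustered on
Euclidean row distances with complete linkage (the stated clustering
routine's default). Stage summaries report mean ± sample sd of per-cell
site counts and editing levels, with two-sided Wilcoxon rank-sum tests
between sequential stages (exact when the smaller group has <= 10 cells
and no ties force the normal approximation; identical constant samples
return P = 1). Expression uses RPKM = 1e9 · count/(gene length · total
mapped reads). Expression–frequency associations are per-site Spearman
correlations across cells with usable entries (>= 3), BH-adjusted over
all tested sites, flagged at adjusted P < 0.1. Stage-specificity of
miRNA-target editing uses two-tailed Fisher tests on edited/unedited
cell counts inside one stage (or two sequential stages) versus the rest;
a flag additionally requires the in-stage edited fraction to exceed the
out-stage fraction, since the claim is enrichment. Stages with fewer
than 4 cells are excluded (the analogous published analysis excluded its
smallest stage; the exact floor was not stated, so 4 is a configurable
default). Rank-sum tests on RPKM stand in for differential expression;
the upstream study used a count-model test there, which is out of scope,
and the difference is confined to that comparison.

## The synthetic cohort

`sim_config()` defaults define the study conditions: a 1 Mb single-contig
genome carrying 30 multi-exon gene loci on both strands (one in five
ncRNA), 40 Alu intervals of 300 bp (one inside each coding gene's 3'UTR,
the rest intergenic), 20 simple repeats, 30 homopolymer runs; 24 cells —
2 embryos x 2 cells at each of six stages (oocyte, zygote, 2-cell,
4-cell, 8-cell, morula; the pronucleus stage is omitted by default as
the stage with too few cells for stage-wise testing); 500 planted edits
(80 % in Alu) with base frequencies uniform in [0.1, 0.95]; 200
embryo-private SNPs, all A-to-G (the adversarial case), half at
frequency 0.5 and half at 1.0, half listed in the SNP catalogue; 50
strand-confined and 50 read-end-confined artifact sites at frequencies
0.3–0.6, planted as Alu A-to-G so only the bias filters can stop them;
per-base errors at 1e-3; Poisson coverage with mean depth 20. The
catalogue lists 90 % of non-Alu edits plus decoys. Sequence context at
planted edits carries the ADAR motif: G at +1 with probability 0.7, G at
−1 with probability 0.1 (transcript sense). Edits inside minus-strand
genes are planted as genomic T-to-C, exercising the transcript-sense
retention path.

Editing activity per cell is the stage multiplier (1.0 through 4-cell,
0.3 at 8-cell, 0.18 at morula — the published trajectory's shape) times
lognormal noise (sd 0.15); a simulated ADAR RPKM equals 30 x activity
times its own lognormal noise. Four genes carry miRNA-target edits
confined to one stage and two to a pair of sequential stages (3 sites
each at base frequency 0.8); one gene's editing frequency is planted to
fall as its expression rises across stages, for the association
analysis. Seed-match intervals on stage-restricted loci cover only their
dedicated sites so the gene-level editing indicator carries the planted
pattern.

What the generator does not emulate: transcript-level expression
variation within a gene, splice isoform effects on coverage, realistic
quality-score distributions (SAM emission uses constant Q40),
PCR-duplicate structure, and genuinely multi-allelic sites. Passing
tests therefore demonstrate the statistical machinery and the filter
logic, not robustness to every artefact of real single-cell libraries.

## Validation design and problem sizes

Three cohorts cover the validation analyses. The default 24-cell cohort
drives detection accuracy (precision/recall against truth, artifact and
SNP removal), clustering, motif recovery, and stage-specificity. A
36-cell variant (3 embryos x 2 cells per stage) is used for the
editing-level trajectory: with 4 cells per stage the exact rank-sum
test's two-sided floor is 2/70 ≈ 0.029, so a P < 0.01 claim needs at
least 6 cells per stage — within the published per-stage range. A
30-cell depth-titration cohort (three flat-activity stages, depth
factors 1–4x, activity noise set to zero) isolates the editing-level
statistic's depth sensitivity: with biological activity noise left on,
the Pearson correlation against mapped bases at n = 30 is dominated by
chance correlation between activity and depth (null sd of r ≈ 0.19), so
the controlled design varies depth alone.

The QC gate of 0.5 Gb uniquely mapped bases presumes a full-size
transcriptome; `sim_pipeline_config()` scales it to a quarter of the
nominal per-cell coverage of the simulated genome, preserving its role
(dropping poorly covered cells) at toy scale.

## Numerical and degenerate-input choices

Fisher tests on tables with a zero margin return P = 1 (single
admissible table). BH ties use the standard step-up cummin; no mid-P.
Binomial tails come from `pbinom` rather than naive summation.
Correlations refuse constant vectors. Site coordinates are 1-based
fully-closed internally and in TSVs; BED input/output converts at the
boundary. Dendrogram tie-breaks follow the deterministic input cell
order. Cells with a single member report sd 0 with a flag. Empty
detection yields precision NA rather than a silent zero.

## Known limitations

The realignment filter runs only on alignment-level input (SAM), not on
pre-computed pileups, and its default aligner is exhaustive local
alignment — appropriate for the toy genome, slow for a real one. The
position-bias table pools all non-reference bases at a column rather
than only the carried alternate (a conservative approximation that
matters only at multi-allelic columns). Catalogue strand-awareness
assumes A-to-G entries are recorded on "+" and T-to-C on "−". The
expression module consumes an RPKM table as given; gene quantification
itself is upstream.
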