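# editomics

Detection and analysis of A-to-I RNA editing in single-cell RNA-seq.

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so editing surfaces as A→G
mismatches between RNA reads and the genomic reference. In single cells
that signal is buried under sequencing errors, germline SNPs and
alignment artifacts at low coverage. `editomics` is for researchers who
want a transparent, fully tested implementation of a single-cell editome
pipeline: per-site error-model testing, an eight-filter artifact
cascade, Alu/catalogue-anchored A-to-I retention, and cohort analytics
(editing level, frequency-matrix clustering, expression associations,
stage-specificity tests), with a synthetic-data generator that provides
ground truth for every claim.

## The model

For each cell (transcriptome) the background mismatch rate is

&nbsp;&nbsp;&nbsp;&nbsp;p = (quality-passing non-reference bases) / (quality-passing aligned bases).

At a site with *n* mapped reads and *k* variant-supporting reads, the
probability that all *k* mismatches are sequencing errors is the upper
binomial tail

&nbsp;&nbsp;&nbsp;&nbsp;P(X ≥ k),&nbsp; X ~ Binomial(n, p),

BH-adjusted per cell. Candidates need adjusted P < 0.01, n ≥ 4, k ≥ 3
and frequency k/n ≥ 0.1, then must survive eight filters: strand bias
(two-tailed Fisher at 0.005 plus strand-frequency bounds 0.1/0.9),
read-position bias (Fisher at 0.05; read end = last 10 bases at 3', first
5 at 5'), ≥ 90 % realignment support against a genome+transcript
reference, simple-repeat / homopolymer-run (≥ 5 bp) / splice-proximity
(± 5 bp, non-Alu only) masks, known-SNP lists, cross-embryo recurrence
(sites private to one embryo are rare SNPs, not editing), and a 0.95
frequency cap. The editome keeps Alu A→G plus catalogued non-Alu A→G;
genomic T→C over minus-strand genes is retained as transcript-sense A→G
(libraries are unstranded). Per-cell editing level is edited bases per
million uniquely mapped bases.

See `vignettes/editomics-methods.Rmd` for the full model description,
parameter table and validation design.

## Worked example

The package ships a hand-built four-cell, twelve-site cohort with one
clean Alu A→G edit and one site per failure mode:

```r
library(editomics)
demo <- demo_cascade_cohort()
res  <- run_pipeline(demo$pileup, demo$meta, demo$ann, demo$config)
res$attrition
#>                        stage sites_out
#>  1: candidate_mismatch_sites        46
#>  2:                 detected        38
#>  3:           strand_verdict        34
#>  4:              pos_verdict        30
#>  5:          realign_verdict        30
#>  6:             mask_verdict        22
#>  7:              snp_verdict        18
#>  8:       recurrence_verdict        16
#>  9:          freqcap_verdict        12
#> 10:            a2i_retention         4
```

46 mismatch-bearing columns enter; the hard thresholds drop the depth-3
and frequency-0.09 sites (38 cell-level detections remain), each filter
then removes exactly its intended site across the four cells, and the
A-to-I retention rule drops the uncatalogued non-Alu A→G and the Alu
C→T, leaving the single planted edit in all four cells:

```r
res$editome[, .(cell_id, pos, ref, alt, n, k, freq, region_class)]
#>    cell_id  pos ref alt  n  k freq region_class
#> 1:      a1  121   A   G 20 10  0.5          Alu
#> 2:      a2  121   A   G 20 10  0.5          Alu
#> 3:      b1  121   A   G 20 10  0.5          Alu
#> 4:      b2  121   A   G 20 10  0.5          Alu
```

Every removed site records which gate stopped it, e.g. the
strand-confined site shows `strand_verdict = "fail"` with variant strand
frequency 1.0, the dbSNP-listed site fails `snp_verdict`, and the
single-embryo site fails `recurrence_verdict` with `n_embryos = 1`.

The full simulated study is the `analysis/` workflow:

```sh
Rscript analysis/01_simulate.R          # 24-cell cohort, 1 Mb genome, truth
Rscript analysis/02_detect_editome.R    # pipeline + scoring against truth
Rscript analysis/03_editing_levels.R    # spectrum, motif, levels, clustering
Rscript analysis/04_stage_specificity.R # Fisher stage tests, expression links
```

On the default seed this recovers the planted editome with precision
1.00 and recall 0.97, removes 100 % of the planted strand/read-end
artifacts and embryo-private SNPs, reproduces the +1 G motif enrichment
(0.70) and the sharp editing-level drop at the 8-cell stage (−65 % on
the default cohort), clusters ≤4-cell cells apart from 8-cell/morula
cells, and flags exactly the genes whose miRNA-target editing was
planted as stage-restricted.

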