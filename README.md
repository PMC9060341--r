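# pairwiseMosaic

Selecting mosaic mutations from comprehensive all-vs-all pairwise
single-cell (clone-to-clone) comparisons, without a matched bulk.

## The problem

Somatic callers run on pairs of single-cell (or clonally expanded)
genomes from one individual emit a mixture of true mosaic mutations,
germline variants leaking through lost or dropped alleles in the
control cell, and false positives. Cell-vs-bulk designs subtract
high-frequency mosaic mutations together with the germline — precisely
the early-embryonic lineage markers one often wants. This package
consolidates the calls of **all N(N−1) ordered pairwise comparisons**
of N cells and classifies every non-redundant variant as mosaic,
germline, high-frequency mosaic, or noise. It is written for
genomicists doing mosaic-variant discovery and retrospective cell
lineage tracing from cloned or amplified single cells (WGS or exome).

## The method

Each variant becomes an N×N binary **call matrix**: entry (i, j) is 1
iff the variant was called with cell i as case and cell j as control.
A mosaic mutation carried by a cell set C shows up as the **rows** of
C; a germline variant lost in a set L as the **columns** of L; noise is
sporadic. With a carrier fraction f of N cells, the expected call count
is

    n = f (1 − f) N²,

inverted as f = 0.5 − √(0.25 − n/N²) ∈ [0, 0.5] and N′ ≈ fN estimated
carriers. The two scores are normalized subset maxima

    MosaicScore   = max(n_m) / n   (best size-N′ row subset)
    GermlineScore = max(n_g) / n   (best size-N′ column subset)

computed exactly by summing the N′ largest row/column sums (an
exhaustive-subset oracle, `bruteForceScores()`, is kept in the package
and tested for exact agreement). Two cut-offs (default 0.75/0.75)
partition the score plane into the four categories.

An **allele-dropout analysis (ADA) mode** handles MDA-amplified single
cells: 5-kb bins whose heterozygous-SNP VAFs contain an extreme value
(< 0.01 or > 0.99) *and* whose folded maximum-likelihood VAF deviates
from 0.5 by more than 0.1 are flagged (plus one neighbouring bin each
side), and cells without a confident call at a flagged locus are
excluded from that variant's score. The same mechanism restricts exome
designs to per-cell capture regions. **Structural variants** are
clustered by ≥ 50% reciprocal overlap (same chromosome and type;
insertions within ±50 bp) and scored identically.

A seeded **synthetic cohort generator** (`simulateCohort()`) emits the
manifest, pairwise VCFs, per-cell SNP tables, dropout BEDs and a truth
table, so the whole pipeline is testable end to end without external
data. See the methods vignette (`vignettes/pairwise-mosaic-methods.Rmd`)
for the model, parameter rationale and limitations.

## Worked example

```r
library(pairwiseMosaic)

# a mosaic mutation carried by clones 2 and 5 of a 5-clone cohort:
# calls appear exactly where a carrier (row) meets a non-carrier (column)
m <- matrix(0L, 5, 5); m[c(2, 5), c(1, 3, 4)] <- 1L
cm <- CallMatrix("chr1:15000:G:A", paste0("clone", 1:5), m,
                 chrom = "chr1", pos = 15000, ref = "G", alt = "A")
computeScores(cm)
#>              key chrom   pos ref alt n N_active   f N_prime mosaic_score
#> 1 chr1:15000:G:A  chr1 15000   G   A 6        5 0.4       2            1
#>   germline_score carrier_cells
#> 1      0.6666667 clone2,clone5
```

Six calls in 25 comparisons give f = 0.4, i.e. N′ = 2 carriers; the
two best rows contain all six calls (mosaic score 1.0) while the two
best columns contain only four (germline score 0.67), so at the default
0.75/0.75 cut-offs the variant classifies as **mosaic**, carried by
clones 2 and 5.

The same pipeline end to end on a simulated 6-cell cohort:

```r
cfg <- cohortConfig(nCells = 6, nGermline = 30, nMosaic = 15,
                    nNoise = 20, seed = 11)
sim <- simulateCohort(cfg, "cohort_dir")
res <- scoreCohort(sim$manifest, "out")          # writes out/scores.tsv
cls <- callCohort(res$scoresPath, "out", matrices = res$matrices)
table(cls$classified$category)
#>              germline high_frequency_mosaic                mosaic
#>                    30                     1                    14
#>                 noise
#>                    20
```

(The high-frequency call is a simulated mosaic carried by 3 of 6 cells,
whose perfect pattern is row- and column-like at once.) The same stages
are exposed as a command line:

```sh
Rscript inst/cli/pairwise-mosaic.R score --manifest cohort_dir/manifest.tsv --out out/
Rscript inst/cli/pairwise-mosaic.R call  --out out/ --mosaic-cut 0.75 --germline-cut 0.75
Rscript inst/cli/pairwise-mosaic.R matrix --manifest cohort_dir/manifest.tsv \
        --out out/ --variant chr1:175452:G:C
```

with `score_sv` / `call_sv` / `matrix_sv` twins for structural
variants, and `simulate` for synthetic cohorts. Outputs are TSV tables
(scores, per-cell annotated calls) plus plots — score-plane density,
per-category and per-cell counts, VAF histogram, six-class mutation
spectrum, and per-variant matrix renderings — each with a TSV side-file
carrying the plotted numbers.

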