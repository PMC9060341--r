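---
title: "Selecting mosaic mutations from all-vs-all pairwise cell comparisons"
author: "pairwiseMosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting mosaic mutations from all-vs-all pairwise cell comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairwiseMosaic)
```

## The problem

When single cells (or clonal lines expanded from single cells) of one
individual are sequenced and compared pairwise with a somatic caller,
every call is one of three things: a **mosaic mutation** (post-zygotic,
carried by a subset of cells), a **germline variant** leaking into the
somatic output because the control cell lost or failed to amplify it, or
a **false positive**. The usual cell-vs-bulk design misses exactly the
interesting high-frequency mosaic mutations -- those present in a large
fraction of cells are also present in the bulk and are subtracted as
"germline". Comparing every cell against every other cell removes the
need for a bulk and, crucially, retains those high-frequency mutations;
the price is that each variant's evidence is scattered over N(N-1)
ordered comparisons and must be consolidated. This package performs that
consolidation.

## The call matrix and the two scores

For N cells, each non-redundant variant is summarised by an N x N binary
matrix M with `M[i, j] = 1` when the variant was called with cell i as
case and cell j as control (`buildCallMatrices()`). A somatic caller
calls a variant only when the case carries it and the control does not,
so:

* a **mosaic mutation** carried by a set C of cells produces calls in
  the **rows** of C (each carrier against each non-carrier);
* a **germline variant** lost in a set L of cells produces calls in the
  **columns** of L (every intact cell against each losing cell);
* **noise** is sporadic, respecting neither arrangement.

If a fraction $f$ of cells carries a variant, the expected number of
calls across all $N^2$ ordered comparisons is

$$n = f\,(1-f)\,N^2 .$$

Solving for $f$ gives two roots, $f_m = 0.5 - \sqrt{0.25 - n/N^2}$ and
its mirror $f_g = 1 - f_m$. Because a mosaic mutation is carried by the
minority and a germline variant is missing from the minority, the two
interpretations share the single parameter $f = f_m \in [0, 0.5]$: the
fraction of carriers (mosaic reading) or of losers (germline reading).
`estimateCellFraction()` returns the smaller root, clamped to 0.5 when
$n/N^2 > 0.25$ (more calls than any single-variant pattern can explain;
treated as a maximal-frequency candidate rather than an error). The
estimated carrier count is $N' = \mathrm{round}(fN)$
(`carrierCount()`).

With row sums $nr_i$ and column sums $nc_i$ of the (active part of the)
matrix, the best estimates of the in-pattern call counts are maxima over
all size-$N'$ subsets of cells, and the scores are

$$\mathrm{MosaicScore} = \frac{\max n_m}{n}, \qquad
  \mathrm{GermlineScore} = \frac{\max n_g}{n},$$

where $n_m$ ($n_g$) sums the row (column) counts over the subset. The
subset maximum of a sum of fixed per-cell contributions is attained by
the $N'$ largest contributions, so `computeScores()` simply sums the
top-$N'$ row (column) sums; `bruteForceScores()` is the literal
exhaustive-enumeration oracle kept in the package (guarded to N <= 12)
and the test suite verifies exact agreement on 1000 random matrices.

```{r archetypes}
# mosaic carried by cells 2 and 5 of 5
computeScores(local({
    m <- matrix(0L, 5, 5); m[c(2, 5), c(1, 3, 4)] <- 1L
    CallMatrix("demo", paste0("c", 1:5), m)
}))[, c("n", "f", "N_prime", "mosaic_score", "germline_score")]
```

### Classification

The (mosaic, germline) score plane is split into four regions
(`classifyScores()`): mosaic (high/low), germline (low/high),
high-frequency mosaic (high/high, typical of early-embryonic mutations
present in most but not all cells) and noise (low/low). Defaults put
both cut-offs at 0.75 with the cut-off value itself inside the high
region, so a perfect score of 1 always classifies. The value 0.75 is a
package default, not a canonical constant: it keeps perfect patterns
in-region under up to 25% smearing from missed calls, and both cut-offs
are exposed as function arguments, CLI flags and a `key = value` config
file. Note an intrinsic boundary fact: a perfect row pattern with $k$
carriers has germline score $k/(N-k)$, so patterns with
$k \gtrsim 3N/7$ -- and always at $k = N/2$, where rows and columns are
equally strong -- legitimately classify as high-frequency mosaic rather
than plain mosaic. That is the method's definition at work, not a
failure mode.

$N'$ rounds to the nearest integer with ties up; rounding to 0 is
allowed and makes an isolated sporadic call score (0, 0), i.e. noise,
instead of trivially scoring 1. Ties among equal row sums resolve to the
lowest cell index so carrier sets are deterministic; under cell
relabeling the scores are invariant while tied carrier choices may
permute.

### Per-call confidence filters

`postFilterCalls()` implements the conventional post-filters for
clone-derived calls: VAF >= 0.35 (culture- and amplification-induced
artifacts sit lower), indels shorter than 10 bp, depth > 10 reads,
>= 2 alternate reads. They are off by default in `callCohort()`, off in
SV mode, and a missing annotation never triggers its filter (invertible
with `dropMissing`).

## Allele dropout analysis (ADA) mode

Whole-genome amplification (MDA in particular) can fail to amplify one
haplotype over an interval. A germline heterozygous variant on the
dropped haplotype then reads as homozygous reference in that cell, every
other cell is called against it, and a spurious perfect-column (germline
region) variant enters the output. ADA mode removes such artifacts in
two steps.

**Detection** (`detectDropoutBins()`): the genome is walked in 5000-bp
bins; a bin is dropout iff (i) at least one heterozygous SNP in the bin
has VAF < 0.01 or > 0.99 **and** (ii) the bin's maximum-likelihood VAF
deviates from 0.5 by more than 0.1. The likelihood is a symmetric
binomial mixture folded to [0, 0.5],
$\ell(f) = \sum_i \log[0.5\,B(a_i; d_i, f) + 0.5\,B(a_i; d_i, 1-f)]$,
maximised on a 0.01 grid (`maxLikelihoodVaf()`); the folded form is
used because the dropped haplotype is unknown and SNPs are unphased.
The immediately neighbouring bin on each side is co-flagged (a regional
phenomenon rarely respects bin boundaries; one bin per side is the
minimal reading of "neighbouring"). Ties on the grid resolve to the
smaller $f$; with no usable depths the mean folded VAF is the fallback.
Requiring both conditions makes the rule robust: a single low-depth SNP
at VAF 0 fails (ii) in an otherwise balanced bin, while genuine dropout
satisfies both.

**Exclusion** (`applyAdaExclusion()`): for each variant, a cell is
dropped from the active set iff it has no confident call for that
variant (no call, or only calls with case VAF < 0.5, or calls lacking a
VAF -- missing VAF is treated as unsupportive, the conservative choice
that permits exclusion) *and* the locus is covered by that cell's
dropout map. Cells with a confident call are never excluded: the call
itself shows the allele amplified. All quantities ($n$, $N$, $f$, $N'$,
both scores) are recomputed on the reduced matrix -- always from the
current active set, also when exclusions cascade from precomputed maps
-- and a variant with no surviving call is removed as an artifact.
Exome designs reuse the identical contract with
`type = "capture"`, where "covered" becomes "outside the capture
regions"; the same no-confident-call clause is applied for symmetry.

## Structural variants

SV calls (MANTA-style `SVTYPE`/`END` annotations) cannot be keyed by
exact coordinates; two calls are the same SV iff they are on the same
chromosome, have the same type, and overlap reciprocally by at least
50% (boundary inclusive). Insertions are point-like and match within
±50 bp instead. Requiring the type to match is a package decision: a
DEL and a DUP over the same span are different events.
`clusterSvCalls()` extends the pairwise predicate to call sets by
single linkage -- the minimal extension -- so chains such as [0,100),
[40,140), [80,180) merge into one cluster even though the extremes
overlap by only 20%; the cluster takes its first-seen member's span as
the representative label. After clustering, scoring and classification
are byte-for-byte the SNV path.

## The synthetic cohort generator

`simulateCohort()` writes exactly the artefacts the pipeline consumes
(manifest, per-pair VCFs with `AD`/`DP`/`AF` genotype fields, per-cell
heterozygous-SNP tables, per-cell dropout BEDs, plus a ground-truth
table). Its generative assumptions mirror the analysis model:

* calls are emitted per ordered pair with probability `sensitivity`
  exactly when the case (apparently) carries the variant and the
  control does not;
* heterozygous and clonal-mosaic VAFs are drawn from a symmetric
  Beta(s, s) around 0.5 (default s = 20, sd ~0.08, a well-behaved
  clone; lower s mimics MDA allelic imbalance), with read counts
  binomial at Poisson depths (mean 30x);
* germline loss is per-cell Bernoulli (default 5%), conditioned on at
  least one loss because a germline variant lost nowhere emits no
  pairwise call and can never enter the analysis -- recovery metrics
  are therefore defined over variants with at least one emitted call;
* dropout is a per-cell set of intervals (disjoint across cells, i.e.
  the single-cell-artifact regime): backbone SNPs inside them read
  homozygous, and germline variants planted inside them flip to an
  apparent one-column pattern. All other variant loci keep a margin of
  one detection bin beyond the intervals, so neighbour-bin flagging
  cannot entangle dropout-free variants;
* a truth-table mosaic with carrier count exactly N/2 is labelled
  `high_frequency_mosaic`, because its perfect pattern scores (1, 1) by
  construction -- row and column interpretations coincide.

The defaults (10 cells, 200 germline / 50 mosaic / 100 noise variants,
sensitivity 0.95, one 5-Mb chromosome, SNP backbone every 1 kb) are the
reference conditions used by the test suite; the end-to-end tests run
within seconds at these sizes. What the generator deliberately does
**not** model: read-level errors and mapping artifacts, caller-specific
FILTER behaviour, multi-chromosome structure, CNVs, partial allelic
imbalance (dropout is all-or-nothing per interval), and correlated
caller errors across pairs. Passing tests therefore demonstrate the
correctness of the consolidation logic under its own generative model,
not the error profile of any particular caller on real data.

A property worth knowing when reading results: with imperfect
sensitivity, missed calls deflate $n$, $f$ is biased low, and $N'$ can
round below the true carrier count; a k-carrier mosaic then keeps only
the top $N' < k$ rows and can fall under the mosaic cut-off. At the
reference conditions this affects a few percent of three-carrier
mosaics (those losing 3+ of their 21 expected calls) -- visible as
mosaic recovery slightly below 100% for some seeds -- and is inherent
to the estimator, not a defect of the implementation.

## Numerical and interface decisions

* Coordinates: VCF positions are 1-based inclusive; all BED input and
  output is 0-based half-open (conversion via `rtracklayer`); SV spans
  are stored 0-based half-open. A BED line `chr1 100 200` therefore
  covers 1-based 101..200 and excludes a variant at position 100.
* Variant normalisation is limited to splitting multi-allelic records
  (one call per alternate allele); indel left-alignment is a documented
  upstream requirement.
* VAF extraction precedence: per-allele `AF` FORMAT field, else
  alt/total from `AD`, else missing. Per-cell VAF on the matrix is
  taken from the case side only (the maximum over that cell's calls);
  control-side evidence is not mined.
* Records failing their caller's FILTER are dropped by default
  (`PASS` and `.` pass); `keepFiltered` retains them.
* Both matrix entries of a doubly-called variant (i vs j and j vs i)
  are kept as-is; no symmetrisation is applied.
* Incomplete all-to-all designs are scored with a warning rather than
  an error -- real cohorts lose pairs -- but the scores assume $N^2$
  comparisons, so completeness is reported.
* The CLI is two-stage (`score` writes, `call` reads) so cut-offs can
  be retuned without re-reading VCFs.

## Limitations

The scores are pattern-geometric, not inferential: no read-count
likelihood, no FDR control, no per-cell error model beyond the ADA
rule. Variants not sampled by the analysed cells are invisible by
construction. Fraction estimates assume a complete all-to-all design
and degrade gracefully but untracked with missing pairs. The ADA rule
is the binned-VAF rule only; it does not segment CNVs and will flag
genuinely CN-altered regions as dropout (which is, for scoring
purposes, usually the desired behaviour).
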