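#' Configuration for a synthetic clone cohort
#'
#' Describes the generative model behind the pairwise-comparison design:
#' a cohort of N clonally expanded cells from one individual, with hidden
#' germline variants (present in every cell, visible to a pairwise
#' somatic caller only where a cell lost or dropped the variant), hidden
#' mosaic mutations (carried by a fraction of at most half the cells,
#' clonal within each carrier, so heterozygous-like VAF around 0.5), and
#' sporadic false-positive calls. A call for a true variant is emitted
#' for ordered pair (i, j) with probability \code{sensitivity} exactly
#' when cell i (apparently) carries it and cell j (apparently) does not.
#'
#' Allele dropout is modelled per cell as a set of genomic intervals in
#' which one haplotype failed to amplify: heterozygous SNPs inside them
#' read as homozygous (VAF 0 or 1), and germline variants placed inside
#' them flip to an apparent column pattern (every other cell called
#' against the dropout cell). \code{nMaskedGermline} germline variants
#' are planted inside dropout intervals, one affected cell each; all
#' other variant loci avoid dropout intervals.
#'
#' @param nCells number of cells N (>= 2).
#' @param nGermline number of germline variants subject to sporadic
#'   per-cell loss.
#' @param nMosaic number of mosaic mutations.
#' @param nNoise number of sporadic false-positive calls (one random
#'   ordered pair each, at a distinct locus).
#' @param sensitivity per-true-pair call emission probability.
#' @param germlineLossRate per-cell probability that a germline variant
#'   is lost/undetected in that cell; loss sets are conditioned on being
#'   non-empty, since a germline variant lost nowhere produces no
#'   pairwise call and cannot enter the analysis.
#' @param mosaicFractions carrier fractions to draw from (each <= 0.5).
#' @param nMaskedGermline germline variants masked by allele dropout in
#'   exactly one cell each (requires \code{dropoutPerCell > 0}).
#' @param dropoutPerCell number of dropout intervals per cell.
#' @param dropoutLength length (bp) of each dropout interval.
#' @param vafShape shape parameter of the symmetric Beta(s, s) drawn
#'   around 0.5 for heterozygous/clonal allele fractions (s = 20 gives
#'   sd ~ 0.078, a well-behaved clone; lower it to mimic MDA noise).
#' @param meanDepth mean sequencing depth (Poisson).
#' @param genomeLength length of the single simulated chromosome
#'   ("chr1").
#' @param snpSpacing spacing (bp) of the heterozygous-SNP backbone used
#'   for dropout detection.
#' @param seed integer seed fixing all randomness.
#' @return Named list of validated settings (class
#'   \code{"cohortConfig"}).
#' @export
cohortConfig <- function(nCells = 10, nGermline = 200, nMosaic = 50,
                         nNoise = 100, sensitivity = 0.95,
                         germlineLossRate = 0.05,
                         mosaicFractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                         nMaskedGermline = 0, dropoutPerCell = 0,
                         dropoutLength = 50000, vafShape = 20,
                         meanDepth = 30, genomeLength = 5e6,
                         snpSpacing = 1000, seed = 1L) {
    stopifnot(nCells >= 2, nGermline >= 0, nMosaic >= 0, nNoise >= 0,
              sensitivity >= 0, sensitivity <= 1,
              germlineLossRate >= 0, germlineLossRate <= 1,
              nMaskedGermline >= 0, dropoutPerCell >= 0,
              vafShape > 0, meanDepth > 0)
    if (any(mosaicFractions <= 0 | mosaicFractions > 0.5))
        stop("mosaic carrier fractions must lie in (0, 0.5]")
    if (nMaskedGermline > 0 && dropoutPerCell == 0)
        stop("masked germline variants require dropout intervals")
    structure(list(nCells = nCells, nGermline = nGermline,
                   nMosaic = nMosaic, nNoise = nNoise,
                   sensitivity = sensitivity,
                   germlineLossRate = germlineLossRate,
                   mosaicFractions = mosaicFractions,
                   nMaskedGermline = nMaskedGermline,
                   dropoutPerCell = dropoutPerCell,
                   dropoutLength = dropoutLength, vafShape = vafShape,
                   meanDepth = meanDepth, genomeLength = genomeLength,
                   snpSpacing = snpSpacing, seed = as.integer(seed)),
              class = "cohortConfig")
}

sim_bases <- c("A", "C", "G", "T")

sim_write_vcf <- function(path, records, genomeLength) {
    header <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=chr1,length=%d>", as.integer(genomeLength)),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "CASE", sep = "\t"))
    body <- character(0)
    if (nrow(records)) {
        records <- records[order(records$pos), , drop = FALSE]
        alt_reads <- records$alt_reads
        depth <- records$depth
        body <- sprintf(
            "chr1\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP:AF\t0/1:%d,%d:%d:%s",
            records$pos, records$ref, records$alt, depth - alt_reads,
            alt_reads, depth, sprintf("%.4f", records$vaf))
    }
    writeLines(c(header, body), path)
}

#' Simulate a synthetic clone cohort on disk
#'
#' Writes, under \code{dir}: one VCF per ordered cell pair
#' (\code{pair_<case>_vs_<control>.vcf}), a manifest TSV referencing
#' them, per-cell heterozygous-SNP tables
#' (\code{snps_<cell>.tsv}), per-cell dropout BEDs when dropout is
#' simulated (\code{dropout_<cell>.bed}, also linked from the manifest),
#' and a ground-truth table \code{truth.tsv} with one row per variant:
#' \code{key, chrom, pos, ref, alt, category, carrier_cells,
#' true_fraction, dropout_affected, n_calls}.
#'
#' Truth categories: mosaic mutations with carrier count k < N/2 are
#' \code{"mosaic"}; at k = N/2 the row and column patterns are equally
#' strong and the variant is genuinely a \code{"high_frequency_mosaic"};
#' germline variants (lost or dropout-masked) are \code{"germline"};
#' sporadic calls are \code{"noise"}. \code{n_calls} is the number of
#' pairwise calls actually emitted, so recovery can be assessed over the
#' variants that are observable at all (a germline variant lost nowhere
#' never reaches the caller output).
#'
#' All randomness derives from \code{config$seed}; two runs with the
#' same config produce byte-identical files.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, a list with \code{dir}, \code{manifest} (path),
#'   \code{truth} (data.frame), \code{cells}, \code{snpTables} and
#'   \code{dropoutBeds} (named paths), and \code{dropoutRegions}
#'   (named list of \code{GRanges}).
#' @export
simulateCohort <- function(config, dir = tempfile("cohort")) {
    stopifnot(inherits(config, "cohortConfig"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    set.seed(config$seed)
    N <- config$nCells
    cells <- sprintf("cell%02d", seq_len(N))
    L <- config$genomeLength

    ## per-cell dropout intervals: disjoint across cells, drawn inside
    ## cell-specific slices of the genome so a locus is dropped in at
    ## most one cell (the single-cell-artifact regime being emulated)
    dropout <- stats::setNames(vector("list", N), cells)
    if (config$dropoutPerCell > 0) {
        slice <- floor(L / N)
        for (i in seq_len(N)) {
            lo <- (i - 1) * slice + 1
            starts <- sort(sample(seq(lo, lo + slice - config$dropoutLength - 1),
                                  config$dropoutPerCell))
            gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
                "chr1", IRanges::IRanges(starts,
                                         starts + config$dropoutLength - 1)))
            dropout[[i]] <- gr
        }
    } else {
        for (i in seq_len(N)) dropout[[i]] <- GenomicRanges::GRanges()
    }
    in_dropout <- function(pos, gr) {
        if (!length(gr)) return(rep(FALSE, length(pos)))
        GenomicRanges::countOverlaps(
            GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos)),
            gr) > 0L
    }
    ## dropout-free loci keep a >1-bin margin from any dropout interval,
    ## so neighbour-bin marking during detection cannot touch them
    all_iv <- do.call(c, unname(dropout))
    any_dropout <- if (length(all_iv))
        GenomicRanges::GRanges("chr1", IRanges::IRanges(
            pmax(1, GenomicRanges::start(all_iv) - 10000),
            GenomicRanges::end(all_iv) + 10000))
    else GenomicRanges::GRanges()

    ## distinct variant loci; non-masked variants avoid all dropout
    n_free <- config$nGermline + config$nMosaic + config$nNoise
    cand <- sample(L, min(L, (n_free + config$nMaskedGermline) * 3 + 100))
    cand <- cand[cand %% config$snpSpacing != 0]  # keep off the SNP backbone
    free_pos <- cand[!in_dropout(cand, any_dropout)][seq_len(n_free)]
    if (anyNA(free_pos)) stop("genome too small for requested variant count")

    draw_alleles <- function(k) {
        ref <- sample(sim_bases, k, replace = TRUE)
        shift <- sample(3, k, replace = TRUE)
        alt <- sim_bases[(match(ref, sim_bases) - 1 + shift) %% 4 + 1]
        list(ref = ref, alt = alt)
    }

    truth <- list()
    calls <- list()  # per variant: data.frame(case, control)
    het_vaf <- function(n) stats::rbeta(n, config$vafShape, config$vafShape)
    emit <- function(case_idx, ctrl_idx, pos, ref, alt) {
        keep <- stats::runif(length(case_idx)) <= config$sensitivity
        if (!any(keep)) return(NULL)
        ci <- case_idx[keep]; cj <- ctrl_idx[keep]
        vaf_by_cell <- stats::setNames(het_vaf(N), cells)
        depth <- pmax(stats::rpois(length(ci), config$meanDepth), 8L)
        vaf <- vaf_by_cell[cells[ci]]
        alt_reads <- pmin(depth, pmax(1L, round(vaf * depth)))
        data.frame(case = cells[ci], control = cells[cj], pos = pos,
                   ref = ref, alt = alt, vaf = round(alt_reads / depth, 4),
                   depth = depth, alt_reads = alt_reads,
                   stringsAsFactors = FALSE)
    }
    add_truth <- function(pos, ref, alt, category, carrier_idx, frac,
                          dropout_affected, df) {
        truth[[length(truth) + 1L]] <<- data.frame(
            key = sprintf("chr1:%d:%s:%s", pos, ref, alt), chrom = "chr1",
            pos = pos, ref = ref, alt = alt, category = category,
            carrier_cells = paste(cells[sort(carrier_idx)], collapse = ","),
            true_fraction = frac, dropout_affected = dropout_affected,
            n_calls = if (is.null(df)) 0L else nrow(df),
            stringsAsFactors = FALSE)
        if (!is.null(df)) calls[[length(calls) + 1L]] <<- df
    }

    pos_i <- 0L
    next_pos <- function() {
        pos_i <<- pos_i + 1L
        free_pos[pos_i]
    }

    ## germline variants with sporadic loss (loss set conditioned non-empty)
    if (config$nGermline > 0) {
        al <- draw_alleles(config$nGermline)
        for (v in seq_len(config$nGermline)) {
            loss <- which(stats::runif(N) < config$germlineLossRate)
            if (!length(loss)) loss <- sample(N, 1L)
            pos <- next_pos()
            pairs <- expand.grid(case = setdiff(seq_len(N), loss),
                                 control = loss)
            df <- emit(pairs$case, pairs$control, pos, al$ref[v], al$alt[v])
            add_truth(pos, al$ref[v], al$alt[v], "germline",
                      setdiff(seq_len(N), loss), (N - length(loss)) / N,
                      FALSE, df)
        }
    }

    ## mosaic mutations
    if (config$nMosaic > 0) {
        al <- draw_alleles(config$nMosaic)
        fr <- sample(config$mosaicFractions, config$nMosaic, replace = TRUE)
        for (v in seq_len(config$nMosaic)) {
            k <- max(1L, round(fr[v] * N))
            carriers <- sample(N, k)
            pos <- next_pos()
            pairs <- expand.grid(case = carriers,
                                 control = setdiff(seq_len(N), carriers))
            df <- emit(pairs$case, pairs$control, pos, al$ref[v], al$alt[v])
            category <- if (k >= N / 2) "high_frequency_mosaic" else "mosaic"
            add_truth(pos, al$ref[v], al$alt[v], category, carriers, k / N,
                      FALSE, df)
        }
    }

    ## sporadic false positives: one call on one random ordered pair each
    if (config$nNoise > 0) {
        al <- draw_alleles(config$nNoise)
        for (v in seq_len(config$nNoise)) {
            i <- sample(N, 1L)
            j <- sample(setdiff(seq_len(N), i), 1L)
            pos <- next_pos()
            depth <- max(stats::rpois(1, config$meanDepth), 8L)
            vaf <- stats::runif(1, 0.1, 0.9)
            alt_reads <- pmin(depth, pmax(1L, round(vaf * depth)))
            df <- data.frame(case = cells[i], control = cells[j], pos = pos,
                             ref = al$ref[v], alt = al$alt[v],
                             vaf = round(alt_reads / depth, 4),
                             depth = depth, alt_reads = alt_reads,
                             stringsAsFactors = FALSE)
            add_truth(pos, al$ref[v], al$alt[v], "noise", i, 1 / N,
                      FALSE, df)
        }
    }

    ## germline variants masked by dropout in exactly one cell: present
    ## in every cell, but the dropout cell reads homozygous reference,
    ## so every other cell is called against it (apparent column)
    if (config$nMaskedGermline > 0) {
        al <- draw_alleles(config$nMaskedGermline)
        cell_cycle <- rep(seq_len(N), length.out = config$nMaskedGermline)
        for (v in seq_len(config$nMaskedGermline)) {
            c_drop <- cell_cycle[v]
            iv <- dropout[[c_drop]][1 + (v %% length(dropout[[c_drop]]))]
            pos <- GenomicRanges::start(iv) +
                sample(GenomicRanges::width(iv) - 2L, 1L)
            pairs <- expand.grid(case = setdiff(seq_len(N), c_drop),
                                 control = c_drop)
            df <- emit(pairs$case, pairs$control, pos, al$ref[v], al$alt[v])
            add_truth(pos, al$ref[v], al$alt[v], "germline", seq_len(N),
                      1, TRUE, df)
        }
    }

    truth <- do.call(rbind, truth)
    all_calls <- do.call(rbind, calls)

    ## pairwise VCFs + manifest (all-to-all ordered pairs)
    pairs_all <- expand.grid(control = cells, case = cells,
                             stringsAsFactors = FALSE)[, c("case", "control")]
    pairs_all <- pairs_all[pairs_all$case != pairs_all$control, ]
    pairs_all <- pairs_all[order(pairs_all$case, pairs_all$control), ]
    vcf_names <- sprintf("pair_%s_vs_%s.vcf", pairs_all$case,
                         pairs_all$control)
    for (r in seq_len(nrow(pairs_all))) {
        sel <- all_calls[all_calls$case == pairs_all$case[r] &
                         all_calls$control == pairs_all$control[r], ,
                         drop = FALSE]
        sim_write_vcf(file.path(dir, vcf_names[r]), sel, L)
    }
    manifest_df <- data.frame(case = pairs_all$case,
                              control = pairs_all$control,
                              vcf = vcf_names, stringsAsFactors = FALSE)

    ## per-cell SNP tables (heterozygous backbone; dropout flips to hom)
    snp_pos <- seq(config$snpSpacing, L - 1, by = config$snpSpacing)
    snp_paths <- stats::setNames(file.path(dir, sprintf("snps_%s.tsv", cells)),
                                 cells)
    for (i in seq_len(N)) {
        depth <- pmax(stats::rpois(length(snp_pos), config$meanDepth), 1L)
        a <- stats::rbinom(length(snp_pos), depth, 0.5)
        dropped <- in_dropout(snp_pos, dropout[[i]])
        if (any(dropped)) {
            hap <- stats::runif(sum(dropped)) < 0.5  # which allele survived
            a[dropped] <- ifelse(hap, depth[dropped], 0L)
        }
        utils::write.table(
            data.frame(chrom = "chr1", pos = snp_pos, alt_reads = a,
                       depth = depth),
            snp_paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
    }

    bed_paths <- character(0)
    if (config$dropoutPerCell > 0) {
        bed_paths <- stats::setNames(
            file.path(dir, sprintf("dropout_%s.bed", cells)), cells)
        for (i in seq_len(N)) writeDropoutBed(dropout[[i]], bed_paths[i])
        manifest_df$dropout_bed <-
            basename(bed_paths[manifest_df$case])
    }

    manifest_path <- file.path(dir, "manifest.tsv")
    utils::write.table(manifest_df, manifest_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth_path <- file.path(dir, "truth.tsv")
    truth_out <- truth
    truth_out$true_fraction <- sprintf("%.6f", truth_out$true_fraction)
    utils::write.table(truth_out, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    invisible(list(dir = dir, manifest = manifest_path,
                   truthPath = truth_path, truth = truth, cells = cells,
                   snpTables = snp_paths, dropoutBeds = bed_paths,
                   dropoutRegions = dropout))
}
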