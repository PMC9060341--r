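# Fixture builders shared across tests; everything is generated in code.

cells5 <- paste0("c", 1:5)

# perfect mosaic pattern: carriers' rows set at every non-carrier column
row_pattern_matrix <- function(N, carriers, key = "rowpat") {
    m <- matrix(0L, N, N)
    m[carriers, setdiff(seq_len(N), carriers)] <- 1L
    CallMatrix(key, sprintf("c%02d", seq_len(N)), m,
               chrom = "chr1", pos = 1000, ref = "A", alt = "T")
}

# perfect germline-loss pattern: columns of the losing cells
col_pattern_matrix <- function(N, lost, key = "colpat") {
    m <- matrix(0L, N, N)
    m[setdiff(seq_len(N), lost), lost] <- 1L
    CallMatrix(key, sprintf("c%02d", seq_len(N)), m,
               chrom = "chr1", pos = 1000, ref = "A", alt = "T")
}

random_call_matrix <- function(N, p = 0.3, key = "rand") {
    repeat {
        m <- matrix(rbinom(N * N, 1L, p), N, N)
        diag(m) <- 0L
        if (sum(m) >= 1L) break
    }
    CallMatrix(key, sprintf("c%02d", seq_len(N)), m,
               chrom = "chr1", pos = 1000, ref = "A", alt = "T")
}

# minimal VCFv4.2 writer for io tests: records is a data.frame with
# chrom, pos, ref, alt and optional filter, gt (raw FORMAT string)
write_test_vcf <- function(path, records,
                           format = "GT:AD:DP:AF") {
    header <- c("##fileformat=VCFv4.2",
                "##contig=<ID=chr1,length=1000000>",
                "##contig=<ID=chr2,length=1000000>",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
                "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
                "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
                "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"f\">",
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", "CASE", sep = "\t"))
    filt <- if (is.null(records$filter)) rep("PASS", nrow(records))
            else records$filter
    gt <- if (is.null(records$gt)) rep("0/1:15,15:30:0.5", nrow(records))
          else records$gt
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\t%s\t%s",
                    records$chrom, records$pos, records$ref, records$alt,
                    filt, format, gt)
    writeLines(c(header, body), path)
    path
}

write_test_manifest <- function(path, case, control, vcf, ...) {
    df <- data.frame(case = case, control = control, vcf = vcf, ...,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# SV VCF with SVTYPE/END INFO annotations
write_test_sv_vcf <- function(path, records) {
    header <- c("##fileformat=VCFv4.2",
                "##contig=<ID=chr1,length=10000000>",
                "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
                "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", "CASE", sep = "\t"))
    body <- sprintf("%s\t%d\t.\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d\tGT\t0/1",
                    records$chrom, records$pos, records$svtype,
                    records$svtype, records$end)
    writeLines(c(header, body), path)
    path
}
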