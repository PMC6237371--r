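# Small fixtures built in code.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(SummarizedExperiment)
})

tiny_layout <- function(len = 1e6, n = 1, sex = FALSE) {
    chrom <- sprintf("chr%d", seq_len(n))
    lens <- rep(len, n)
    auto <- rep(TRUE, n)
    if (sex) { chrom <- c(chrom, "chrX"); lens <- c(lens, len); auto <- c(auto, FALSE) }
    GenomeLayout(chrom, lens, auto)
}

gr1 <- function(start0, end0, strand = "+", chrom = "chr1", layout = NULL) {
    si <- if (is.null(layout)) NULL else GenomeInfoDb::Seqinfo(
        chromNames(layout), as.integer(chromLengths(layout)))
    if (is.null(si))
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
    else
        GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = strand, seqinfo = si)
}

# Random 0-based intervals on [0, L), returned as a matrix.
rand_iv <- function(n, L, max_w = 500) {
    w <- sample.int(max_w, n, replace = TRUE)
    s <- floor(runif(n) * (L - w))
    cbind(start0 = s, end0 = s + w)
}

# Write lines to a temp file and return the path.
tmpfile <- function(lines, ext = ".bed") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}
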