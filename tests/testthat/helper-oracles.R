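# Independent brute-force oracles: plain base-R loops over per-base vectors,
# deliberately sharing no code with the package internals.

# Runs of TRUE in a logical vector -> 0-based half-open (start0, end0) matrix.
oracle_runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(start0 = starts[r$values], end0 = ends[r$values])
}

# Merge 0-based half-open intervals whose gap is strictly < gap.
oracle_merge <- function(iv, gap) {
    if (nrow(iv) == 0) return(iv)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    out <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
        if (iv[i, 1] - out[nrow(out), 2] < gap)
            out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
        else out <- rbind(out, iv[i, , drop = FALSE])
    }
    out
}

# Per-base subtraction oracle on one chromosome of length L.
# a, b: matrices of 0-based half-open intervals.
oracle_subtract_mask <- function(a, b, L) {
    am <- logical(L); bm <- logical(L)
    for (i in seq_len(nrow(a))) am[seq(a[i, 1] + 1, a[i, 2])] <- TRUE
    if (nrow(b)) for (i in seq_len(nrow(b))) bm[seq(b[i, 1] + 1, b[i, 2])] <- TRUE
    oracle_runs(am & !bm)
}

# Full discovery oracle on one chromosome, one strand: per-base depth vector,
# gene/blacklist interval matrices (0-based half-open).
oracle_discover <- function(depth, genes, blacklist, q, base_gap, seg_gap,
                            min_len) {
    L <- length(depth)
    if (nrow(genes)) for (i in seq_len(nrow(genes)))
        depth[seq(genes[i, 1] + 1, genes[i, 2])] <- 0L
    covered <- depth[depth >= 1L]
    if (length(covered) == 0) return(matrix(numeric(0), 0, 2))
    s <- sort(covered)
    h <- min(floor(q * length(s) + 1e-9) + 1, length(s))
    thr <- s[h]
    keep <- depth >= thr
    if (nrow(blacklist)) for (i in seq_len(nrow(blacklist)))
        keep[seq(blacklist[i, 1] + 1, blacklist[i, 2])] <- FALSE
    iv <- oracle_runs(keep)
    if (nrow(iv) == 0) return(iv)
    iv <- oracle_merge(iv, base_gap)
    iv <- oracle_merge(iv, seg_gap)
    iv[iv[, 2] - iv[, 1] >= min_len, , drop = FALSE]
}

# Double-loop minimal-expression filter oracle.
oracle_filter_min_expressed <- function(counts, autosome, min_reads,
                                        min_samples, autosomal_only) {
    keep <- logical(nrow(counts))
    for (i in seq_len(nrow(counts))) {
        nq <- 0L
        for (j in seq_len(ncol(counts)))
            if (counts[i, j] >= min_reads) nq <- nq + 1L
        keep[i] <- nq >= min_samples && (!autosomal_only || autosome[i])
    }
    keep
}

# Active-region post-processing oracle: per-base mask on one chromosome.
oracle_active_regions <- function(segs, states, active, merge_gap, min_len, L) {
    m <- logical(L)
    for (i in seq_len(nrow(segs)))
        if (states[i] %in% active) m[seq(segs[i, 1] + 1, segs[i, 2])] <- TRUE
    iv <- oracle_runs(m)
    if (nrow(iv) == 0) return(iv)
    iv <- oracle_merge(iv, merge_gap)
    iv[iv[, 2] - iv[, 1] >= min_len, , drop = FALSE]
}

# Direct purity definition: loop over clusters, take the biggest label class.
oracle_purity <- function(assign, labels) {
    tot <- 0
    for (cl in unique(assign)) {
        in_cl <- labels[assign == cl]
        best <- 0
        for (lb in unique(in_cl)) best <- max(best, sum(in_cl == lb))
        tot <- tot + best
    }
    tot / length(assign)
}

# GRanges <-> 0-based interval matrix helpers for oracle comparisons.
gr_to_iv <- function(gr) {
    if (length(gr) == 0) return(matrix(numeric(0), 0, 2))
    cbind(start0 = GenomicRanges::start(gr) - 1, end0 = GenomicRanges::end(gr))
}
iv_to_gr <- function(iv, chrom, layout, strand = "+") {
    if (nrow(iv) == 0)
        return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
            chromNames(layout), as.integer(chromLengths(layout)))))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(iv[, 1] + 1, iv[, 2]),
                           strand = strand)
}
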