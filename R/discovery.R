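#' Parameters of the vlincRNA discovery procedure
#'
#' Defaults follow the published procedure: a mapping-quality floor of 40
#' (applied upstream, when alignments are turned into coverage), removal of
#' covered bases below the third quartile (Q3) of read density, merging of
#' surviving bases less than 500 bp apart, merging of the resulting segments
#' less than 10 kb apart, a 50 kb minimum call length, a 10 kb
#' "far-from-genes" distance, and 25% reciprocal overlap for catalog
#' comparison.
#'
#' @param density_quantile covered-base depth quantile used as threshold.
#' @param base_merge_gap bp; covered bases closer than this merge.
#' @param segment_merge_gap bp; segments closer than this merge.
#' @param min_length bp; minimum call length.
#' @param far_gene_dist bp; minimum gene distance for the far-from-genes set.
#' @param reciprocal_overlap_frac fraction for catalog sharing.
#' @param mapq_min documented mapping-quality floor (not applied here;
#'   coverage inputs are expected to be pre-filtered).
#' @param bridge_masked if TRUE (default), merging may bridge gaps created
#'   by gene masking, density filtering or blacklisting (bases were removed,
#'   not turned into barriers). If FALSE, masked regions break merges.
#' @param joint_quantile compute one density threshold across both strands
#'   instead of per strand.
#' @return a named list of validated parameters.
#' @export
discoveryParams <- function(density_quantile = 0.75, base_merge_gap = 500,
                            segment_merge_gap = 10000, min_length = 50000,
                            far_gene_dist = 10000, reciprocal_overlap_frac = 0.25,
                            mapq_min = 40, bridge_masked = TRUE,
                            joint_quantile = FALSE) {
    stopifnot(density_quantile > 0, density_quantile < 1,
              base_merge_gap > 0, segment_merge_gap > 0, min_length > 0,
              far_gene_dist > 0,
              reciprocal_overlap_frac > 0, reciprocal_overlap_frac <= 1,
              min_length >= segment_merge_gap)
    list(density_quantile = density_quantile, base_merge_gap = base_merge_gap,
         segment_merge_gap = segment_merge_gap, min_length = min_length,
         far_gene_dist = far_gene_dist,
         reciprocal_overlap_frac = reciprocal_overlap_frac,
         mapq_min = mapq_min, bridge_masked = bridge_masked,
         joint_quantile = joint_quantile)
}

## Total covered bases of a track (for stage logging).
.coveredBases <- function(track) {
    f <- function(rl) sum(vapply(rl, function(r)
        sum(as.numeric(runLength(r))[runValue(r) >= 1L]), 0))
    f(track@plus) + f(track@minus)
}

#' Discover vlincRNAs from pooled strand-specific coverage
#'
#' The pipeline, in fixed order: (1) strand-aware removal of covered bases
#' overlapping protein-coding genes; (2) per-strand read-density quantile
#' filter (keep depth >= threshold); (3) removal of bases overlapping
#' blacklisted regions (both strands); (4) merge surviving bases less than
#' \code{base_merge_gap} apart; (5) merge the resulting segments less than
#' \code{segment_merge_gap} apart; (6) keep segments of length >=
#' \code{min_length}. Calls get deterministic ids
#' \code{vlinc_<chrom>_<start0>_<strand>} (0-based start).
#'
#' @param track pooled [CoverageTrack-class].
#' @param genes stranded \code{GRanges} of protein-coding genes.
#' @param blacklist unstranded \code{GRanges} of excluded regions.
#' @param params see [discoveryParams()].
#' @return a sorted \code{GRanges} with metadata columns \code{id},
#'   \code{call_class} ("all") and \code{score} (= length). Thresholds and
#'   stage-by-stage covered-base counts are attached via
#'   \code{S4Vectors::metadata()}.
#' @export
discoverVlincs <- function(track, genes, blacklist = NULL,
                           params = discoveryParams()) {
    if (is.null(blacklist)) blacklist <- .emptyGR(track@layout)
    log <- list()
    log$input_bases <- .coveredBases(track)

    masked <- maskCoverage(track, genes, strand_aware = TRUE)
    log$after_gene_mask <- .coveredBases(masked)

    dt <- densityThreshold(masked, q = params$density_quantile,
                           joint = params$joint_quantile)
    log$thresholds <- dt$thresholds
    log$after_density <- .coveredBases(dt$track)

    bl <- maskCoverage(dt$track, blacklist, strand_aware = FALSE)
    log$after_blacklist <- .coveredBases(bl)

    cov <- coveredRanges(bl)
    seg <- mergeWithin(cov, params$base_merge_gap)
    if (!params$bridge_masked)
        seg <- .breakAtMasked(seg, genes, blacklist, params$base_merge_gap)
    log$segments_base_merge <- length(seg)
    seg <- mergeWithin(seg, params$segment_merge_gap)
    if (!params$bridge_masked)
        seg <- .breakAtMasked(seg, genes, blacklist, 0)
    log$segments_segment_merge <- length(seg)

    calls <- seg[width(seg) >= params$min_length]
    calls <- sort(calls)
    mcols(calls)$id <- sprintf("vlinc_%s_%d_%s", as.character(seqnames(calls)),
                               start(calls) - 1L, as.character(strand(calls)))
    mcols(calls)$call_class <- rep("all", length(calls))
    mcols(calls)$score <- width(calls)
    names(calls) <- mcols(calls)$id
    metadata(calls) <- log
    calls
}

## Hard-break mode: masked regions cut merged segments instead of being
## bridged. Same-strand gene bases and blacklist bases are both barriers.
.breakAtMasked <- function(seg, genes, blacklist, regap) {
    barrier <- c(granges(genes), granges(blacklist))
    out <- subtractIntervals(seg, barrier, strand_aware = TRUE)
    out
}

#' Select calls far from protein-coding genes
#'
#' Keeps calls lying at least \code{far_gene_dist} bp from every gene,
#' regardless of strand orientation (overlap counts as distance 0), and
#' relabels them \code{call_class = "far_from_genes"}.
#'
#' @param calls output of [discoverVlincs()].
#' @param genes \code{GRanges} of protein-coding genes.
#' @param params see [discoveryParams()].
#' @return the surviving, relabelled subset of \code{calls}.
#' @export
farFromGenes <- function(calls, genes, params = discoveryParams()) {
    out <- distanceFilter(calls, genes, params$far_gene_dist)
    if (length(out)) mcols(out)$call_class <- "far_from_genes"
    out
}
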