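#' Assemble a 450K-style probe matrix
#'
#' Wraps post-normalization beta values, detection p-values and probe
#' annotation into a \code{RangedSummarizedExperiment}. Array
#' preprocessing/normalization is out of scope; the matrix is accepted as
#' produced by the array pipeline.
#'
#' @param beta numeric matrix probes x samples, values in [0, 1]; rownames
#'   are probe ids.
#' @param detection_p numeric matrix of detection p-values, same shape.
#' @param annotation data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos} (0-based) and \code{snp_overlap} (logical/0-1).
#' @param layout a [GenomeLayout-class].
#' @return a \code{RangedSummarizedExperiment} with assays \code{beta} and
#'   \code{detection_p}; \code{snp_overlap} lives in \code{rowData}.
#' @export
makeProbeMatrix <- function(beta, detection_p, annotation, layout) {
    beta <- as.matrix(beta); detection_p <- as.matrix(detection_p)
    stopifnot(identical(dim(beta), dim(detection_p)))
    if (any(beta < 0 | beta > 1, na.rm = TRUE))
        stop("beta values must lie in [0, 1]")
    idx <- match(rownames(beta), annotation$probe_id)
    if (anyNA(idx)) stop("every probe needs an annotation row")
    ann <- annotation[idx, , drop = FALSE]
    rr <- .gr0(layout, ann$chrom, ann$pos, ann$pos + 1)
    names(rr) <- ann$probe_id
    mcols(rr)$snp_overlap <- as.logical(ann$snp_overlap)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta, detection_p = detection_p), rowRanges = rr)
}

#' Apply the standard probe filters
#'
#' Removes failed probes (detection p-value above \code{det_p_thresh} in
#' strictly more than \code{max_fail_frac} of samples), probes on
#' non-autosomal chromosomes, and probes overlapping SNPs.
#'
#' @param pm probe matrix from [makeProbeMatrix()].
#' @param det_p_thresh detection p-value cutoff (default 0.01).
#' @param max_fail_frac maximum tolerated failing-sample fraction
#'   (default 0.20; a probe failing in exactly 20% of samples is kept).
#' @param layout a [GenomeLayout-class] supplying autosome flags.
#' @return the filtered probe matrix.
#' @export
filterProbes <- function(pm, det_p_thresh = 0.01, max_fail_frac = 0.20, layout) {
    detp <- SummarizedExperiment::assay(pm, "detection_p")
    fail_frac <- rowMeans(detp > det_p_thresh)
    auto <- isAutosome(layout)[as.character(seqnames(SummarizedExperiment::rowRanges(pm)))]
    snp <- SummarizedExperiment::rowData(pm)$snp_overlap
    keep <- fail_frac <= max_fail_frac & auto & !snp
    pm[keep, ]
}

#' Mean probe beta per promoter per sample
#'
#' Per region and sample, the mean beta over probes overlapping the region;
#' a probe overlapping several regions contributes to each. Regions with no
#' overlapping probe are dropped from the matrix and reported separately.
#'
#' @param pm probe matrix (ideally after [filterProbes()]).
#' @param regions named \code{GRanges} (e.g. refined promoters).
#' @return a list: \code{means} (region x sample matrix, only regions with
#'   probes), \code{n_regions_with_probes}, \code{n_probes_used},
#'   \code{regions_without_probes} (names).
#' @export
probePromoterMeans <- function(pm, regions) {
    ids <- names(regions)
    if (is.null(ids)) ids <- as.character(seq_along(regions))
    beta <- SummarizedExperiment::assay(pm, "beta")
    hits <- findOverlaps(SummarizedExperiment::rowRanges(pm), regions,
                         ignore.strand = TRUE)
    with_probes <- sort(unique(subjectHits(hits)))
    if (length(hits) == 0) {
        return(list(means = matrix(numeric(0), 0, ncol(beta),
                                   dimnames = list(NULL, colnames(beta))),
                    n_regions_with_probes = 0L, n_probes_used = 0L,
                    regions_without_probes = ids))
    }
    grp <- factor(subjectHits(hits), levels = with_probes)
    sums <- rowsum(beta[queryHits(hits), , drop = FALSE], grp)
    cnt <- as.integer(table(grp))
    means <- sums / cnt
    rownames(means) <- ids[with_probes]
    list(means = means,
         n_regions_with_probes = length(with_probes),
         n_probes_used = length(unique(queryHits(hits))),
         regions_without_probes = ids[setdiff(seq_along(regions), with_probes)])
}

#' Correlate and cluster samples on promoter methylation
#'
#' Pairwise Pearson correlations of samples over regions
#' (pairwise-complete observations), then hierarchical clustering on the
#' distance 1 - r with the same linkage machinery as the expression module.
#'
#' @param mat region x sample matrix of methylation means (NAs allowed).
#' @param k number of clusters.
#' @param linkage as in [hierarchicalClusters()].
#' @return a list: \code{correlation} (sample x sample matrix) and
#'   \code{clusters} (a [ClusterResult-class]).
#' @export
methCorrelationCluster <- function(mat, k, linkage = "complete") {
    if (ncol(mat) < 2) stop("need at least two samples")
    r <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
    if (anyNA(r)) {
        warning("some sample pairs share fewer than 2 complete observations; correlation missing")
    }
    d <- as.dist(1 - r)
    if (anyNA(d)) stop("cannot cluster: missing correlations")
    method <- if (linkage == "ward") "ward.D2" else linkage
    tree <- hclust(d, method = method)
    assign <- cutree(tree, k = k)
    list(correlation = r,
         clusters = new("ClusterResult", k = as.integer(k),
                        assignment = setNames(as.integer(assign), colnames(mat)),
                        linkage = linkage, tree = tree))
}
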