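#' Assemble a region x sample count matrix
#'
#' Wraps counts, the calls they were computed over, and sample metadata into
#' a \code{RangedSummarizedExperiment}. The per-region autosome flag (used
#' by [filterMinExpressed()]) is taken from the layout.
#'
#' @param counts integer matrix, regions x samples; rownames are call ids.
#' @param calls \code{GRanges} of the counted calls (named by id).
#' @param meta data.frame with columns \code{sample_id},
#'   \code{immunophenotype}, \code{subtype}, \code{batch}; one row per
#'   counts column, matched by \code{sample_id}.
#' @param layout a [GenomeLayout-class].
#' @return a \code{RangedSummarizedExperiment} with assay \code{counts}.
#' @export
makeCountMatrix <- function(counts, calls, meta, layout) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != floor(counts)))
        stop("counts must be non-negative integers")
    if (anyDuplicated(meta$sample_id)) stop("sample ids must be unique")
    if (is.null(colnames(counts))) colnames(counts) <- meta$sample_id
    if (!setequal(colnames(counts), meta$sample_id))
        stop("every counts column needs a metadata row (and vice versa)")
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    idx <- match(rownames(counts), names(calls))
    if (anyNA(idx)) stop("counts rownames must match call ids")
    rr <- calls[idx]
    mcols(rr)$autosome <- isAutosome(layout)[as.character(seqnames(rr))]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = rr,
        colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
}

#' Count fragments per call per sample (htseq-count dialect)
#'
#' A fragment is counted for a call iff it overlaps the call on the same
#' strand; fragments overlapping two or more calls on that strand are
#' discarded as ambiguous (union-mode "ambiguous" semantics).
#'
#' @param fragments named list of stranded \code{GRanges}, one per sample.
#' @param calls \code{GRanges} of calls, named by id.
#' @return integer matrix, calls x samples.
#' @export
countFragments <- function(fragments, calls) {
    stopifnot(!is.null(names(fragments)))
    ids <- names(calls)
    if (is.null(ids)) ids <- mcols(calls)$id
    out <- vapply(fragments, function(fr) {
        hits <- findOverlaps(fr, calls, ignore.strand = FALSE)
        nh <- tabulate(queryHits(hits), nbins = length(fr))
        keep <- nh[queryHits(hits)] == 1L
        tabulate(subjectHits(hits)[keep], nbins = length(calls))
    }, integer(length(calls)))
    out <- matrix(out, nrow = length(calls),
                  dimnames = list(ids, names(fragments)))
    out
}

#' Keep autosomal, minimally expressed regions
#'
#' Retains a region iff (when \code{autosomal_only}) it lies on an autosome
#' and at least \code{min_samples} samples have at least \code{min_reads}
#' reads (both bounds inclusive). Region order is preserved.
#'
#' @param se \code{SummarizedExperiment} from [makeCountMatrix()].
#' @param min_reads minimum reads per qualifying sample.
#' @param min_samples minimum number of qualifying samples.
#' @param autosomal_only drop regions on non-autosomes.
#' @return the filtered \code{SummarizedExperiment}.
#' @export
filterMinExpressed <- function(se, min_reads = 100, min_samples = 3,
                               autosomal_only = TRUE) {
    counts <- SummarizedExperiment::assay(se, "counts")
    ok <- rowSums(counts >= min_reads) >= min_samples
    if (autosomal_only) {
        auto <- SummarizedExperiment::rowData(se)$autosome
        if (is.null(auto)) stop("rowData lacks the autosome flag")
        ok <- ok & auto
    }
    se[ok, ]
}

#' Size-factor normalization and log2 transform
#'
#' A stand-in for a regularized-log transform, labelled as such: size
#' factors are median-of-ratios over regions with all-positive counts
#' (count / geometric mean of the region), and the output is
#' \code{log2(count / size_factor + pseudocount)}. When no region has
#' all-positive counts the size factors fall back to total-count scaling,
#' with a warning. Not equivalent to a shrinkage-based regularized log.
#'
#' @param se a \code{SummarizedExperiment} with a \code{counts} assay, or a
#'   plain counts matrix.
#' @param pseudocount added inside the log (default 1, so zero counts map
#'   to 0).
#' @return a list: \code{mat} (normalized log2 matrix), \code{size_factors}
#'   (named), \code{method} (a label describing the transform).
#' @export
normalizeLog <- function(se, pseudocount = 1) {
    counts <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "counts") else as.matrix(se)
    allpos <- rowSums(counts > 0) == ncol(counts)
    if (any(allpos)) {
        ref <- counts[allpos, , drop = FALSE]
        loggeo <- rowMeans(log(ref))
        sf <- apply(ref, 2, function(col) median(exp(log(col) - loggeo)))
        method <- "median-of-ratios size factors + log2 (rld surrogate)"
    } else {
        warning("no region with all-positive counts; falling back to total-count size factors")
        tot <- colSums(counts)
        sf <- tot / exp(mean(log(tot)))
        method <- "total-count size factors + log2 (rld surrogate)"
    }
    mat <- log2(sweep(counts, 2, sf, "/") + pseudocount)
    list(mat = mat, size_factors = setNames(sf, colnames(counts)), method = method)
}

#' Hierarchical clustering of samples on expression
#'
#' Agglomerative clustering of samples (columns) on Euclidean distance over
#' regions, cut at \code{k} clusters. Deterministic given the input; ties in
#' merge distances follow \code{stats::hclust}'s documented behaviour.
#'
#' @param mat normalized matrix, regions x samples.
#' @param k number of clusters (1 <= k <= number of samples).
#' @param linkage one of "complete" (default), "single", "average", "ward".
#' @return a [ClusterResult-class].
#' @export
hierarchicalClusters <- function(mat, k, linkage = c("complete", "single",
                                                     "average", "ward")) {
    linkage <- match.arg(linkage)
    n <- ncol(mat)
    if (k < 1 || k > n) stop(sprintf("k must be in 1..%d", n))
    method <- if (linkage == "ward") "ward.D2" else linkage
    tree <- hclust(dist(t(mat)), method = method)
    assign <- cutree(tree, k = k)
    new("ClusterResult", k = as.integer(k),
        assignment = setNames(as.integer(assign), colnames(mat)),
        linkage = linkage, tree = tree)
}

#' Cluster purity against true labels
#'
#' purity = (1/N) * sum over clusters of the size of the cluster's largest
#' true-label class. Lies in (0, 1]; invariant to relabelling of either
#' side.
#'
#' @param assignment cluster labels (a [ClusterResult-class] or a named
#'   vector).
#' @param labels true labels, named by the same samples.
#' @return a fraction in (0, 1].
#' @export
clusterPurity <- function(assignment, labels) {
    if (is(assignment, "ClusterResult")) assignment <- clusterAssignment(assignment)
    if (!is.null(names(assignment)) && !is.null(names(labels))) {
        if (!setequal(names(assignment), names(labels)))
            stop("assignment and labels cover different sample sets")
        labels <- labels[names(assignment)]
    } else if (length(assignment) != length(labels)) {
        stop("assignment and labels cover different sample sets")
    }
    tab <- table(assignment, labels)
    sum(apply(tab, 1, max)) / length(assignment)
}

#' Rank regions specific to one subtype
#'
#' Per region, fold = mean linear-scale expression in the subtype divided by
#' the largest other-subtype mean. Linear-scale expression is recovered from
#' the normalized log2 matrix as \code{max(2^value - pseudocount, 0)}.
#' Regions with fold >= \code{min_fold} (inclusive) are kept and sorted by
#' descending fold; a region expressed only in the subtype (all other means
#' 0) gets fold \code{Inf} and ranks first.
#'
#' @param mat normalized log2 matrix, regions x samples.
#' @param meta sample metadata with \code{sample_id} and \code{subtype}.
#' @param subtype the subtype of interest (must be present).
#' @param min_fold inclusive fold-change threshold (default 2).
#' @param top_n optional cap on the number of regions returned.
#' @param pseudocount the pseudocount used by [normalizeLog()].
#' @return data.frame (id, fold, mean_subtype, best_other), sorted by
#'   descending fold.
#' @export
subtypeSpecific <- function(mat, meta, subtype, min_fold = 2, top_n = NULL,
                            pseudocount = 1) {
    meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
    if (!subtype %in% meta$subtype)
        stop(sprintf("subtype '%s' absent from metadata", subtype))
    lin <- pmax(2^mat - pseudocount, 0)
    in_mean <- rowMeans(lin[, meta$subtype == subtype, drop = FALSE])
    others <- setdiff(unique(meta$subtype), subtype)
    other_means <- vapply(others, function(s)
        rowMeans(lin[, meta$subtype == s, drop = FALSE]), numeric(nrow(mat)))
    best_other <- if (length(others)) apply(matrix(other_means, nrow = nrow(mat)),
                                            1, max) else rep(0, nrow(mat))
    fold <- ifelse(best_other > 0, in_mean / best_other,
                   ifelse(in_mean > 0, Inf, 0))
    out <- data.frame(id = rownames(mat), fold = fold, mean_subtype = in_mean,
                      best_other = best_other)
    out <- out[out$fold >= min_fold, , drop = FALSE]
    out <- out[order(-out$fold, -out$mean_subtype), , drop = FALSE]
    if (!is.null(top_n)) out <- head(out, top_n)
    rownames(out) <- NULL
    out
}

#' Project samples on principal components
#'
#' Region-centered SVD of the normalized matrix. For determinism each
#' component's sign is fixed so its largest-magnitude region loading is
#' positive.
#'
#' @param mat normalized matrix, regions x samples.
#' @param n_components number of components (<= min dimension).
#' @return a list: \code{coords} (samples x components),
#'   \code{var_frac} (variance fractions, non-increasing),
#'   \code{loadings} (regions x components).
#' @export
pcaProject <- function(mat, n_components = 2) {
    if (n_components > min(dim(mat)))
        stop("n_components exceeds matrix dimensions")
    if (all(apply(mat, 1, function(r) diff(range(r)) == 0)))
        stop("degenerate all-constant matrix")
    pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
    k <- n_components
    flip <- vapply(seq_len(k), function(j) {
        l <- pc$rotation[, j]
        sign(l[which.max(abs(l))])
    }, 0)
    flip[flip == 0] <- 1
    coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
    loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
    var_frac <- pc$sdev^2 / sum(pc$sdev^2)
    list(coords = coords, var_frac = var_frac[seq_len(k)], loadings = loadings)
}
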