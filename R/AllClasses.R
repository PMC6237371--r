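#' @import methods
#' @importFrom S4Vectors Rle runValue runLength mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges RleList coverage reduce width start end resize findOverlaps countOverlaps Views viewSums
#' @importFrom GenomicRanges GRanges seqnames strand strand<- granges pintersect
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths seqinfo seqinfo<- keepSeqlevels
#' @importFrom stats rpois rnbinom rbinom rbeta runif median quantile prcomp hclust cutree dist as.dist cor fisher.test setNames aggregate
#' @importFrom utils head tail
#' @importFrom data.table fread fwrite data.table rbindlist as.data.table
NULL

#' Genome layout: chromosome names, lengths and autosome flags
#'
#' A minimal genome model. Autosome status is an explicit per-chromosome
#' flag (used by the "autosomal vlincRNAs only" expression filter and the
#' sex-chromosome probe filter); it is never inferred by parsing names.
#'
#' @slot chrom character vector of unique chromosome names (ordered).
#' @slot length integer-valued numeric vector of chromosome lengths (bp > 0).
#' @slot autosome logical vector, one flag per chromosome.
#' @export
setClass("GenomeLayout",
    representation(chrom = "character", length = "numeric", autosome = "logical"))

setValidity("GenomeLayout", function(object) {
    msg <- NULL
    n <- length(object@chrom)
    if (length(object@length) != n || length(object@autosome) != n)
        msg <- c(msg, "chrom, length and autosome must have equal length")
    if (anyDuplicated(object@chrom))
        msg <- c(msg, "chromosome names must be unique")
    if (any(is.na(object@length)) || any(object@length <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    if (any(is.na(object@autosome)))
        msg <- c(msg, "autosome flags must be TRUE/FALSE, never NA")
    if (is.null(msg)) TRUE else msg
})

#' Strand-resolved run-length coverage over a genome
#'
#' Per-base read depth stored as one integer \code{Rle} per chromosome and
#' strand. Runs are canonical (adjacent equal-depth runs merged by the Rle
#' representation itself); uncovered bases carry depth 0.
#'
#' @slot layout a [GenomeLayout-class].
#' @slot plus,minus \code{RleList}, one integer Rle per chromosome, each of
#'   length equal to the chromosome length.
#' @export
setClass("CoverageTrack",
    representation(layout = "GenomeLayout", plus = "RleList", minus = "RleList"))

setValidity("CoverageTrack", function(object) {
    lay <- object@layout
    for (sl in c("plus", "minus")) {
        x <- slot(object, sl)
        if (!identical(names(x), lay@chrom))
            return(sprintf("%s strand must have one Rle per layout chromosome, in order", sl))
        if (!all(vapply(x, length, 0) == lay@length))
            return(sprintf("%s strand Rle lengths must match chromosome lengths", sl))
        if (any(vapply(x, function(r) any(runValue(r) < 0), NA)))
            return("coverage depths must be non-negative")
    }
    TRUE
})

#' Candidate and refined vlincRNA promoters
#'
#' Candidate promoters are the +/- \code{flank} window around each call's
#' 5' start of expression, clipped to the chromosome. Refinement replaces a
#' candidate by the longest overlapping active chromatin region; candidates
#' with no overlapping active region stay unrefined.
#'
#' @slot candidates named \code{GRanges}, one window per vlincRNA id; strand
#'   carries the source call's strand (used for profile orientation only).
#' @slot refined named \code{GRanges}; names are a subset of candidate names.
#' @slot layout a [GenomeLayout-class].
#' @export
setClass("PromoterSet",
    representation(candidates = "GRanges", refined = "GRanges", layout = "GenomeLayout"))

setValidity("PromoterSet", function(object) {
    if (is.null(names(object@candidates)) || anyDuplicated(names(object@candidates)))
        return("candidates must be uniquely named by vlincRNA id")
    if (length(object@refined) &&
        !all(names(object@refined) %in% names(object@candidates)))
        return("refined names must be a subset of candidate names")
    TRUE
})

#' Per-CpG methylation counts
#'
#' One row per CpG: methylated and unmethylated read counts. The beta value
#' (methylated fraction) is defined only where total coverage > 0.
#'
#' @slot layout a [GenomeLayout-class].
#' @slot sites width-1 \code{GRanges} with integer metadata columns
#'   \code{meth} and \code{unmeth}; positions unique per chromosome.
#' @export
setClass("MethylationTrack",
    representation(layout = "GenomeLayout", sites = "GRanges"))

setValidity("MethylationTrack", function(object) {
    s <- object@sites
    if (length(s)) {
        if (any(width(s) != 1)) return("CpG sites must have width 1")
        if (!all(c("meth", "unmeth") %in% names(mcols(s))))
            return("sites need meth and unmeth metadata columns")
        if (any(mcols(s)$meth < 0) || any(mcols(s)$unmeth < 0))
            return("methylation counts must be non-negative")
        key <- paste(seqnames(s), start(s))
        if (anyDuplicated(key)) return("CpG positions must be unique per chromosome")
    }
    TRUE
})

#' Promoter / active-region overlap enrichment
#'
#' Observed overlap of \code{n} promoters with active chromatin regions
#' against a shuffled background, with fold enrichment, a Fisher exact test
#' on observed vs rounded mean-random counts, and an empirical permutation
#' p-value.
#'
#' @slot n promoter count.
#' @slot n_obs promoters overlapping at least one active region.
#' @slot random_counts per-replicate overlap counts (may be empty when the
#'   result was built from summary counts alone).
#' @slot mean_random mean of the random overlap counts.
#' @slot fold (n_obs/n) / (mean_random/n).
#' @slot fisher_p two-sided Fisher exact p on the 2x2 table.
#' @slot perm_p empirical permutation p, (1 + #\{replicates >= n_obs\}) / (reps + 1);
#'   \code{NA} when no replicates were run.
#' @slot table the 2x2 integer table \code{[[n_obs, n - n_obs], [round(mean_random), n - round(mean_random)]]}.
#' @export
setClass("EnrichmentResult",
    representation(n = "integer", n_obs = "integer", random_counts = "numeric",
                   mean_random = "numeric", fold = "numeric",
                   fisher_p = "numeric", perm_p = "numeric", table = "matrix"))

#' Result of cutting a hierarchical clustering at k clusters
#'
#' @slot k number of clusters.
#' @slot assignment named integer vector, sample -> cluster in 1..k.
#' @slot linkage agglomeration method used.
#' @slot tree the underlying \code{hclust} object.
#' @export
setClass("ClusterResult",
    representation(k = "integer", assignment = "integer", linkage = "character",
                   tree = "ANY"))

setValidity("ClusterResult", function(object) {
    if (is.null(names(object@assignment))) return("assignment must be named by sample")
    if (length(object@assignment) &&
        (min(object@assignment) < 1L || max(object@assignment) > object@k))
        return("cluster labels must lie in 1..k")
    TRUE
})
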