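#' @rdname GenomeLayout-class
#' @param x object.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname GenomeLayout-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname GenomeLayout-class
#' @export
setGeneric("isAutosome", function(x) standardGeneric("isAutosome"))

#' @rdname CoverageTrack-class
#' @param x object.
#' @param ... further arguments.
#' @export
setGeneric("strandCoverage", function(x, ...) standardGeneric("strandCoverage"))
#' @rdname CoverageTrack-class
#' @export
setGeneric("genomeLayout", function(x) standardGeneric("genomeLayout"))

#' @rdname PromoterSet-class
#' @param x object.
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname PromoterSet-class
#' @export
setGeneric("refined", function(x) standardGeneric("refined"))
#' @rdname PromoterSet-class
#' @export
setGeneric("refinedFraction", function(x) standardGeneric("refinedFraction"))

#' @rdname MethylationTrack-class
#' @param x object.
#' @export
setGeneric("cpgSites", function(x) standardGeneric("cpgSites"))
#' @rdname MethylationTrack-class
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname ClusterResult-class
#' @param x object.
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

## ---- GenomeLayout ----

#' @rdname GenomeLayout-class
#' @export
setMethod("chromNames", "GenomeLayout", function(x) x@chrom)
#' @rdname GenomeLayout-class
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) setNames(x@length, x@chrom))
#' @rdname GenomeLayout-class
#' @export
setMethod("isAutosome", "GenomeLayout", function(x) setNames(x@autosome, x@chrom))
#' @rdname GenomeLayout-class
#' @param object object.
#' @export
setMethod("show", "GenomeLayout", function(object) {
    cat(sprintf("GenomeLayout: %d chromosome(s), %.1f Mb total (%d autosomal)\n",
        length(object@chrom), sum(object@length) / 1e6, sum(object@autosome)))
})
#' @rdname GenomeLayout-class
#' @export
setMethod("length", "GenomeLayout", function(x) length(x@chrom))

## ---- CoverageTrack ----

#' @rdname CoverageTrack-class
#' @param strand "+" or "-".
#' @export
setMethod("strandCoverage", "CoverageTrack", function(x, strand = c("+", "-")) {
    strand <- match.arg(strand)
    if (strand == "+") x@plus else x@minus
})
#' @rdname CoverageTrack-class
#' @export
setMethod("genomeLayout", "CoverageTrack", function(x) x@layout)
#' @rdname CoverageTrack-class
#' @param object object.
#' @export
setMethod("show", "CoverageTrack", function(object) {
    cov_bases <- function(rl) sum(vapply(rl, function(r)
        sum(as.numeric(runLength(r))[runValue(r) >= 1L]), 0))
    cat(sprintf(
        "CoverageTrack over %d chromosome(s): %.2f Mb covered (+), %.2f Mb covered (-)\n",
        length(object@layout@chrom),
        cov_bases(object@plus) / 1e6, cov_bases(object@minus) / 1e6))
})

## ---- PromoterSet ----

#' @rdname PromoterSet-class
#' @export
setMethod("candidates", "PromoterSet", function(x) x@candidates)
#' @rdname PromoterSet-class
#' @export
setMethod("refined", "PromoterSet", function(x) x@refined)
#' @rdname PromoterSet-class
#' @export
setMethod("refinedFraction", "PromoterSet", function(x) {
    if (length(x@candidates) == 0) return(NA_real_)
    length(x@refined) / length(x@candidates)
})
#' @rdname PromoterSet-class
#' @param object object.
#' @export
setMethod("show", "PromoterSet", function(object) {
    cat(sprintf("PromoterSet: %d candidate promoter(s), %d refined (%.1f%%)\n",
        length(object@candidates), length(object@refined),
        100 * ifelse(length(object@candidates), refinedFraction(object), NA)))
})
#' @rdname PromoterSet-class
#' @export
setMethod("length", "PromoterSet", function(x) length(x@candidates))

## ---- MethylationTrack ----

#' @rdname MethylationTrack-class
#' @export
setMethod("cpgSites", "MethylationTrack", function(x) x@sites)
#' @rdname MethylationTrack-class
#' @export
setMethod("betaValues", "MethylationTrack", function(x) {
    tot <- mcols(x@sites)$meth + mcols(x@sites)$unmeth
    ifelse(tot > 0, mcols(x@sites)$meth / tot, NA_real_)
})
#' @rdname MethylationTrack-class
#' @export
setMethod("genomeLayout", "MethylationTrack", function(x) x@layout)
#' @rdname MethylationTrack-class
#' @param object object.
#' @export
setMethod("show", "MethylationTrack", function(object) {
    b <- betaValues(object)
    cat(sprintf("MethylationTrack: %d CpG(s), %d covered, mean beta %.3f\n",
        length(object@sites), sum(!is.na(b)), mean(b, na.rm = TRUE)))
})
#' @rdname MethylationTrack-class
#' @export
setMethod("length", "MethylationTrack", function(x) length(x@sites))

## ---- EnrichmentResult ----

#' @rdname EnrichmentResult-class
#' @param object object.
#' @export
setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult: %.1f%% (%d/%d) observed vs %.2f%% mean random (%.1f/%d)\n",
        100 * object@n_obs / object@n, object@n_obs, object@n,
        100 * object@mean_random / object@n, object@mean_random, object@n))
    cat(sprintf("  fold = %.2f; Fisher p = %.2g; permutation p = %s (%d replicates)\n",
        object@fold, object@fisher_p,
        ifelse(is.na(object@perm_p), "NA", sprintf("%.2g", object@perm_p)),
        length(object@random_counts)))
})

## ---- ClusterResult ----

#' @rdname ClusterResult-class
#' @export
setMethod("clusterAssignment", "ClusterResult", function(x) x@assignment)
#' @rdname ClusterResult-class
#' @param object object.
#' @export
setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: %d sample(s) in k = %d cluster(s) (%s linkage)\n",
        length(object@assignment), object@k, object@linkage))
})
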