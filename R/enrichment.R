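## Build an EnrichmentResult from counts (shared by the shuffle-based test
## and the summary-count constructor).
.enrichResult <- function(n, n_obs, random_counts, mean_random, perm_p) {
    if (n_obs == 0 && mean_random == 0) {
        warning("no observed and no random overlap; fold defined as 0")
        fold <- 0
    } else if (mean_random == 0) {
        warning("no random overlap; fold is Inf")
        fold <- Inf
    } else {
        fold <- (n_obs / n) / (mean_random / n)
    }
    mr <- as.integer(round(mean_random))
    tab <- matrix(c(n_obs, n - n_obs, mr, n - mr), nrow = 2, byrow = TRUE,
                  dimnames = list(c("observed", "random"),
                                  c("overlap", "no_overlap")))
    fisher_p <- fisher.test(tab)$p.value
    new("EnrichmentResult", n = as.integer(n), n_obs = as.integer(n_obs),
        random_counts = as.numeric(random_counts),
        mean_random = as.numeric(mean_random), fold = fold,
        fisher_p = fisher_p, perm_p = perm_p, table = tab)
}

#' Promoter / active-region overlap enrichment with a shuffled background
#'
#' Counts the candidate promoters overlapping at least one active region
#' (>= 1 bp, strand-agnostic), then re-places the promoter windows uniformly
#' at random \code{n_shuffles} times ([shuffleIntervals()] semantics) and
#' recounts. Fold enrichment is the observed overlap fraction over the mean
#' random fraction. Reports a two-sided Fisher exact p on the 2x2 table of
#' observed vs rounded mean-random counts, and the empirical permutation p
#' \code{(1 + #\{replicates >= observed\}) / (n_shuffles + 1)}.
#'
#' @param promoters a [PromoterSet-class] or a \code{GRanges} of promoter
#'   windows.
#' @param active \code{GRanges} of active chromatin regions.
#' @param layout a [GenomeLayout-class].
#' @param n_shuffles number of random replicates (default 1000).
#' @param seed integer seed for the shuffles.
#' @param exclude optional \code{GRanges} the random placements must avoid.
#' @return an [EnrichmentResult-class].
#' @export
overlapEnrichment <- function(promoters, active, layout, n_shuffles = 1000,
                              seed = 1, exclude = NULL) {
    gr <- if (is(promoters, "PromoterSet")) promoters@candidates else promoters
    n <- length(gr)
    if (n < 1) stop("need at least one promoter")
    if (n_shuffles < 1) stop("n_shuffles must be >= 1")
    n_obs <- sum(countOverlaps(gr, active, ignore.strand = TRUE) > 0)
    set.seed(seed)
    shuf <- .shuffleReps(gr, layout, n_shuffles, exclude)
    hit <- countOverlaps(shuf, active, ignore.strand = TRUE) > 0
    repf <- factor(mcols(shuf)$rep, levels = seq_len(n_shuffles))
    counts <- as.integer(vapply(split(hit, repf), sum, 0L))
    mean_random <- mean(counts)
    perm_p <- (1 + sum(counts >= n_obs)) / (n_shuffles + 1)
    res <- .enrichResult(n, n_obs, counts, mean_random, perm_p)
    res
}

#' Enrichment arithmetic from summary counts
#'
#' Recomputes fold enrichment, observed and mean-random overlap percentages
#' and the Fisher exact p from already-tallied counts (e.g. a published
#' observed count and mean random count), without running shuffles. The
#' permutation p is \code{NA}.
#'
#' @param n_obs observed overlapping promoters.
#' @param mean_random mean random overlapping promoters.
#' @param n total promoters.
#' @return an [EnrichmentResult-class].
#' @examples
#' enrichmentFromCounts(79, 36, 256)   # 30.9% vs 14.06%, 2.2-fold
#' @export
enrichmentFromCounts <- function(n_obs, mean_random, n) {
    .enrichResult(n, n_obs, numeric(0), mean_random, NA_real_)
}

#' Overlap fractions per observed-percentage accessors
#'
#' Convenience accessors for an [EnrichmentResult-class]: observed and mean
#' random overlap, as percentages of the promoter count.
#'
#' @param x an [EnrichmentResult-class].
#' @return a named numeric vector (percent scale).
#' @export
overlapPercentages <- function(x) {
    stopifnot(is(x, "EnrichmentResult"))
    c(observed = 100 * x@n_obs / x@n, random = 100 * x@mean_random / x@n)
}

#' Fold enrichment of an EnrichmentResult
#' @param x an [EnrichmentResult-class].
#' @return the fold enrichment.
#' @export
foldEnrichment <- function(x) { stopifnot(is(x, "EnrichmentResult")); x@fold }

#' Permutation and Fisher p-values of an EnrichmentResult
#' @param x an [EnrichmentResult-class].
#' @return named numeric vector with \code{fisher} and \code{permutation}.
#' @export
enrichmentPvalues <- function(x) {
    stopifnot(is(x, "EnrichmentResult"))
    c(fisher = x@fisher_p, permutation = x@perm_p)
}

#' Active-region overlap stratified by expression
#'
#' Sorts promoters by expression in descending order (bin 1 / Q1 = highest
#' expression), splits them into \code{n_bins} contiguous bins (any
#' remainder spread one-per-bin over the leading bins), and reports the
#' fraction of promoters in each bin overlapping at least one active
#' region. \code{n_bins = 4} gives expression quartiles.
#'
#' @param promoters a [PromoterSet-class] or \code{GRanges}.
#' @param active \code{GRanges} of active regions.
#' @param expression numeric vector named by promoter id (one value per
#'   promoter; missing values are an error).
#' @param n_bins number of expression bins (default 8).
#' @return data.frame (bin, n, n_overlap, frac_overlap); bin 1 = highest
#'   expression.
#' @export
expressionStratifiedOverlap <- function(promoters, active, expression,
                                        n_bins = 8) {
    gr <- if (is(promoters, "PromoterSet")) promoters@candidates else promoters
    ids <- names(gr)
    if (is.null(ids)) stop("promoters must be named")
    if (!all(ids %in% names(expression)) || anyNA(expression[ids]))
        stop("missing expression value for some promoter(s)")
    expr <- expression[ids]
    ord <- order(-expr)
    hit <- (countOverlaps(gr, active, ignore.strand = TRUE) > 0)[ord]
    n <- length(gr)
    base <- n %/% n_bins
    sizes <- rep(base, n_bins) + c(rep(1L, n %% n_bins),
                                   rep(0L, n_bins - n %% n_bins))
    bin <- rep(seq_len(n_bins), times = sizes)
    data.frame(bin = seq_len(n_bins),
               n = sizes,
               n_overlap = as.integer(tapply(hit, bin, sum)),
               frac_overlap = as.numeric(tapply(hit, bin, mean)))
}
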