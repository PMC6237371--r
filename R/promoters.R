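#' Candidate promoters around vlincRNA 5' starts
#'
#' The candidate promoter of a call is the window of \code{flank} bp on each
#' side of its 5' start of expression: the left edge for "+" calls, the
#' right edge for "-" calls (the 5' start of a minus-strand transcript is
#' its right coordinate). Windows are clipped at chromosome bounds. The
#' candidate keeps the call's strand, used only to orient profiles.
#'
#' @param calls stranded \code{GRanges} named by vlincRNA id.
#' @param layout a [GenomeLayout-class].
#' @param flank half-window in bp (default 10000).
#' @return a [PromoterSet-class] with one candidate per call.
#' @export
candidatePromoters <- function(calls, layout, flank = 10000) {
    st <- as.character(strand(calls))
    if (any(!st %in% c("+", "-"))) stop("calls must be stranded (+/-)")
    ids <- names(calls)
    if (is.null(ids)) ids <- mcols(calls)$id
    if (is.null(ids)) stop("calls must carry ids (names or mcols$id)")
    ## 0-based anchor: start for +, (exclusive) end for -
    anchor0 <- ifelse(st == "+", start(calls) - 1L, end(calls))
    s0 <- pmax(anchor0 - flank, 0)
    chr <- as.character(seqnames(calls))
    e0 <- pmin(anchor0 + flank, chromLengths(layout)[chr])
    cand <- GRanges(chr, IRanges(s0 + 1, e0), strand = st,
                    seqinfo = .seqinfo(layout))
    names(cand) <- ids
    new("PromoterSet", candidates = cand,
        refined = GRanges(seqinfo = .seqinfo(layout)), layout = layout)
}

#' Post-process a chromatin-state segmentation into active regions
#'
#' Keeps segments whose state is in \code{active_states} (the states with
#' the H3K4me3 mark present), merges kept segments separated by strictly
#' less than \code{merge_gap} bp, and retains merged regions of length
#' greater than or equal to \code{min_len} bp.
#'
#' @param states unstranded \code{GRanges} with a \code{state} metadata
#'   column (see [readStateBed()]).
#' @param active_states character vector of state labels to keep. The
#'   Roadmap 15-state preset of H3K4me3-present states is available as
#'   [roadmapActiveStates()]. Labels absent from the segmentation simply
#'   contribute nothing (a segmentation with no active state yields an
#'   empty set).
#' @param merge_gap bp (default 1000, strict "<").
#' @param min_len bp (default 400, inclusive ">=").
#' @param known_states optional vocabulary of valid state labels; when
#'   given, an \code{active_states} entry outside it is an error listing
#'   the vocabulary (guards against misspelt state names).
#' @return an unstranded, merged \code{GRanges}.
#' @export
activeRegions <- function(states, active_states, merge_gap = 1000,
                          min_len = 400, known_states = NULL) {
    stopifnot(length(active_states) >= 1)
    lab <- mcols(states)$state
    if (is.null(lab)) stop("states need a 'state' metadata column")
    if (!is.null(known_states)) {
        unknown <- setdiff(active_states, known_states)
        if (length(unknown))
            stop(sprintf("unknown state label(s) %s; known states: %s",
                         paste(unknown, collapse = ", "),
                         paste(sort(known_states), collapse = ", ")))
    }
    kept <- granges(states[lab %in% active_states])
    strand(kept) <- "*"
    merged <- mergeWithin(kept, merge_gap, ignore_strand = TRUE)
    merged[width(merged) >= min_len]
}

#' Roadmap 15-state H3K4me3-present states
#'
#' The state labels of the Roadmap Epigenomics 15-state chromatin model in
#' which the H3K4me3 mark is present (states 1, 2, 3, 10 and 11), shipped
#' as a preset for [activeRegions()] on Roadmap-style segmentations.
#'
#' @return a character vector of state labels.
#' @export
roadmapActiveStates <- function() c("1", "2", "3", "10", "11")

#' Refine candidate promoters with active chromatin regions
#'
#' For each candidate promoter, the longest overlapping active region
#' (leftmost on ties) is retained and reassigned as the active promoter.
#' Candidates overlapping no active region stay unrefined. Refined
#' intervals inherit the candidate's strand (for profile orientation).
#'
#' @param promoters a [PromoterSet-class].
#' @param active \code{GRanges} from [activeRegions()].
#' @return the [PromoterSet-class] with its \code{refined} slot filled.
#' @export
refinePromoters <- function(promoters, active) {
    cand <- promoters@candidates
    if (length(cand) == 0 || length(active) == 0) return(promoters)
    hits <- findOverlaps(cand, active, ignore.strand = TRUE)
    if (length(hits) == 0) return(promoters)
    hdf <- data.frame(q = queryHits(hits), s = subjectHits(hits),
                      w = width(active)[subjectHits(hits)],
                      st = start(active)[subjectHits(hits)])
    ## longest active region per candidate; leftmost start breaks ties
    hdf <- hdf[order(hdf$q, -hdf$w, hdf$st), ]
    hdf <- hdf[!duplicated(hdf$q), ]
    ref <- granges(active)[hdf$s]
    strand(ref) <- strand(cand)[hdf$q]
    names(ref) <- names(cand)[hdf$q]
    new("PromoterSet", candidates = cand, refined = ref,
        layout = promoters@layout)
}
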