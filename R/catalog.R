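#' Compare vlincRNA calls with public catalogs by reciprocal overlap
#'
#' A call \code{u} is shared with a catalog iff some catalog interval
#' \code{v} overlaps it by at least \code{frac} of the length of \emph{each}
#' of \code{u} and \code{v} (reciprocal overlap), on the same strand when
#' the catalog is stranded. Calls shared with no catalog are unique.
#'
#' @param calls \code{GRanges} with an \code{id} metadata column (or names).
#' @param catalogs named list of \code{GRanges}.
#' @param frac reciprocal overlap fraction (default 0.25).
#' @param stranded named logical, one flag per catalog: compare on matching
#'   strand (TRUE) or ignoring strand (FALSE). Defaults to all TRUE.
#' @return a list: \code{per_call} data.frame (id, one logical column per
#'   catalog, n_datasets), \code{per_catalog} named shared-call counts,
#'   \code{unique_ids} ids shared with no catalog, \code{n_unique},
#'   \code{frac_unique}.
#' @export
compareCatalogs <- function(calls, catalogs, frac = 0.25,
                            stranded = setNames(rep(TRUE, length(catalogs)),
                                                names(catalogs))) {
    stopifnot(length(catalogs) >= 1, !is.null(names(catalogs)))
    ids <- mcols(calls)$id
    if (is.null(ids)) ids <- names(calls)
    if (is.null(ids)) ids <- as.character(seq_along(calls))
    shared <- sapply(names(catalogs), function(nm) {
        cat_gr <- catalogs[[nm]]
        ignore <- !isTRUE(stranded[[nm]])
        if (length(cat_gr) == 0 || length(calls) == 0)
            return(rep(FALSE, length(calls)))
        hits <- findOverlaps(calls, cat_gr, ignore.strand = ignore)
        if (length(hits) == 0) return(rep(FALSE, length(calls)))
        ov <- width(pintersect(granges(calls)[queryHits(hits)],
                               granges(cat_gr)[subjectHits(hits)],
                               ignore.strand = TRUE))
        good <- ov >= frac * width(calls)[queryHits(hits)] &
                ov >= frac * width(cat_gr)[subjectHits(hits)]
        flag <- rep(FALSE, length(calls))
        flag[unique(queryHits(hits)[good])] <- TRUE
        flag
    })
    shared <- matrix(shared, nrow = length(calls),
                     dimnames = list(NULL, names(catalogs)))
    n_datasets <- rowSums(shared)
    per_call <- data.frame(id = ids, shared, n_datasets = n_datasets,
                           check.names = FALSE)
    unique_ids <- ids[n_datasets == 0]
    list(per_call = per_call,
         per_catalog = colSums(shared),
         unique_ids = unique_ids,
         n_unique = length(unique_ids),
         frac_unique = if (length(calls)) length(unique_ids) / length(calls)
                       else NA_real_)
}
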