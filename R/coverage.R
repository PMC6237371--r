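#' Construct a coverage track
#'
#' @param layout a [GenomeLayout-class].
#' @param plus,minus optional \code{RleList} of per-chromosome integer
#'   depths; missing chromosomes are filled with zeros.
#' @return a [CoverageTrack-class].
#' @export
CoverageTrack <- function(layout, plus = NULL, minus = NULL) {
    fill <- function(rl) {
        out <- lapply(setNames(seq_along(layout@chrom), layout@chrom), function(i) {
            chr <- layout@chrom[i]
            if (!is.null(rl) && chr %in% names(rl)) {
                r <- rl[[chr]]
                if (length(r) != layout@length[i])
                    stop(sprintf("coverage Rle for %s has length %d, expected %d",
                                 chr, length(r), layout@length[i]))
                r
            } else Rle(0L, as.integer(layout@length[i]))
        })
        RleList(out, compress = FALSE)
    }
    new("CoverageTrack", layout = layout, plus = fill(plus), minus = fill(minus))
}

#' Build a coverage track from depth-weighted stranded ranges
#'
#' Overlapping ranges add their depths (read-pileup semantics); unstranded
#' ranges contribute to both strands.
#'
#' @param gr a \code{GRanges} with a numeric \code{depth} metadata column
#'   (default depth 1 per range when absent).
#' @param layout a [GenomeLayout-class].
#' @return a [CoverageTrack-class].
#' @export
trackFromRanges <- function(gr, layout) {
    depth <- mcols(gr)$depth
    if (is.null(depth)) depth <- rep(1L, length(gr))
    one <- function(keep) {
        g <- gr[keep]
        if (length(g) == 0) return(NULL)
        cov <- coverage(GRanges(seqnames(g), IRanges(start(g), end(g)),
                                seqinfo = .seqinfo(layout)),
                        weight = as.integer(depth[keep]))
        cov[layout@chrom]
    }
    st <- as.character(strand(gr))
    CoverageTrack(layout,
        plus = one(st %in% c("+", "*")),
        minus = one(st %in% c("-", "*")))
}

#' Sum coverage tracks base by base
#'
#' Used to pool per-sample strand-specific coverage before discovery.
#'
#' @param tracks a list of [CoverageTrack-class] objects on one layout.
#' @return a [CoverageTrack-class].
#' @export
poolTracks <- function(tracks) {
    stopifnot(length(tracks) >= 1)
    lay <- tracks[[1]]@layout
    acc_p <- tracks[[1]]@plus
    acc_m <- tracks[[1]]@minus
    for (t in tracks[-1]) {
        if (!identical(t@layout@chrom, lay@chrom))
            stop("all tracks must share one genome layout")
        acc_p <- acc_p + t@plus
        acc_m <- acc_m + t@minus
    }
    new("CoverageTrack", layout = lay,
        plus = RleList(lapply(acc_p, function(r) Rle(as.integer(runValue(r)),
                                                     runLength(r))), compress = FALSE),
        minus = RleList(lapply(acc_m, function(r) Rle(as.integer(runValue(r)),
                                                      runLength(r))), compress = FALSE))
}

#' Covered intervals of a track
#'
#' @param track a [CoverageTrack-class].
#' @param min_depth minimum depth for a base to count as covered.
#' @return a stranded \code{GRanges} of maximal runs with depth >=
#'   \code{min_depth}.
#' @export
coveredRanges <- function(track, min_depth = 1L) {
    one <- function(rl, st) {
        grl <- lapply(names(rl), function(chr) {
            ir <- as(rl[[chr]] >= min_depth, "IRanges")
            if (length(ir) == 0) return(NULL)
            GRanges(chr, ir, strand = st, seqinfo = .seqinfo(track@layout))
        })
        grl[!vapply(grl, is.null, NA)]
    }
    parts <- c(one(track@plus, "+"), one(track@minus, "-"))
    if (length(parts) == 0) return(.emptyGR(track@layout))
    sort(do.call(c, parts))
}

#' Zero coverage over a set of intervals
#'
#' Sets depth to 0 over the given ranges: on the matching strand when
#' \code{strand_aware} (unstranded ranges hit both strands), otherwise on
#' both strands.
#'
#' @param track a [CoverageTrack-class].
#' @param gr intervals to mask.
#' @param strand_aware respect the strand of \code{gr}.
#' @return a [CoverageTrack-class].
#' @export
maskCoverage <- function(track, gr, strand_aware = TRUE) {
    lay <- track@layout
    maskOne <- function(rl, keepstr) {
        g <- if (strand_aware) gr[as.character(strand(gr)) %in% c(keepstr, "*")] else gr
        if (length(g) == 0) return(rl)
        m <- coverage(GRanges(seqnames(g), IRanges(start(g), end(g)),
                              seqinfo = .seqinfo(lay)))[lay@chrom]
        out <- lapply(names(rl), function(chr) {
            r <- rl[[chr]] * (m[[chr]] == 0L)
            Rle(as.integer(runValue(r)), runLength(r))
        })
        RleList(setNames(out, names(rl)), compress = FALSE)
    }
    new("CoverageTrack", layout = lay,
        plus = maskOne(track@plus, "+"), minus = maskOne(track@minus, "-"))
}

## Depth multiset over covered bases of one strand as (value, count) pairs.
.depthMultiset <- function(rl) {
    vals <- unlist(lapply(rl, function(r) runValue(r)[runValue(r) >= 1L]),
                   use.names = FALSE)
    lens <- unlist(lapply(rl, function(r)
        as.numeric(runLength(r))[runValue(r) >= 1L]), use.names = FALSE)
    if (length(vals) == 0) return(NULL)
    agg <- rowsum(lens, vals)
    data.frame(depth = as.integer(rownames(agg)), bases = agg[, 1])[
        order(as.integer(rownames(agg))), ]
}

## Rank-based quantile of a weighted depth multiset: the value at ascending
## rank floor(q*N) + 1 (capped at N). Equals the ordinary nearest rank
## ceiling(q*N) whenever q*N is not integral; when q*N is integral it takes
## the next value up, so "remove bases below Q3" removes at least q of the
## covered bases. E.g. depths {1,1,1,1,2,2,3,100}, q = 0.75 -> 3.
.quantileThreshold <- function(ms, q) {
    N <- sum(ms$bases)
    h <- min(floor(q * N + 1e-9) + 1, N)
    ms$depth[findInterval(h - 1e-9, c(0, cumsum(ms$bases))) ]
}

#' Apply the read-density quantile filter
#'
#' Per strand, the threshold is the \code{q}-quantile of depth over covered
#' bases (depth >= 1), taken at ascending rank floor(q*N) + 1 over the
#' covered-base depth multiset. Bases with depth below the threshold are
#' zeroed; bases at or above it are kept. A strand with no covered bases has
#' an undefined threshold and is left empty with a warning. With
#' \code{joint = TRUE} one threshold is computed over both strands' covered
#' bases.
#'
#' @param track a [CoverageTrack-class].
#' @param q quantile in (0, 1); default 0.75 (Q3).
#' @param joint compute a single genome-wide threshold across both strands.
#' @return a list with \code{track} (filtered [CoverageTrack-class]) and
#'   \code{thresholds} (named numeric, plus/minus; NA where undefined).
#' @export
densityThreshold <- function(track, q = 0.75, joint = FALSE) {
    stopifnot(q > 0, q < 1)
    ms_p <- .depthMultiset(track@plus)
    ms_m <- .depthMultiset(track@minus)
    if (joint) {
        ms <- if (is.null(ms_p)) ms_m else if (is.null(ms_m)) ms_p else {
            both <- rbind(ms_p, ms_m)
            agg <- rowsum(both$bases, both$depth)
            data.frame(depth = as.integer(rownames(agg)), bases = agg[, 1])[
                order(as.integer(rownames(agg))), ]
        }
        thr_p <- thr_m <- if (is.null(ms)) NA_real_ else .quantileThreshold(ms, q)
    } else {
        thr_p <- if (is.null(ms_p)) NA_real_ else .quantileThreshold(ms_p, q)
        thr_m <- if (is.null(ms_m)) NA_real_ else .quantileThreshold(ms_m, q)
    }
    filt <- function(rl, thr, label) {
        if (is.na(thr)) {
            if (sum(vapply(rl, function(r) sum(runValue(r) >= 1L), 0L)) == 0)
                warning(sprintf("no covered bases on %s strand; threshold undefined",
                                label))
            return(rl)
        }
        out <- lapply(rl, function(r) {
            v <- runValue(r)
            v[v < thr] <- 0L
            Rle(v, runLength(r))
        })
        RleList(out, compress = FALSE)
    }
    list(track = new("CoverageTrack", layout = track@layout,
                     plus = filt(track@plus, thr_p, "plus"),
                     minus = filt(track@minus, thr_m, "minus")),
         thresholds = c(plus = thr_p, minus = thr_m))
}
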