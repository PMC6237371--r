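state_gr <- function(iv, states, lay) {
    g <- gr1(iv[, 1], iv[, 2], "*", layout = lay)
    mcols(g)$state <- states
    g
}

test_that("candidate promoters center on the 5' start, clipped to bounds", {
    lay <- tiny_layout(1e6)
    calls <- c(gr1(100000, 160000, "+", layout = lay),
               gr1(100000, 160000, "-", layout = lay),
               gr1(3000, 60000, "+", layout = lay))
    names(calls) <- c("p", "m", "edge")
    ps <- candidatePromoters(calls, lay)
    cand <- candidates(ps)
    expect_equal(unname(gr_to_iv(cand["p"])), unname(cbind(90000, 110000)))
    # 5' start of a minus-strand call is its right coordinate
    expect_equal(unname(gr_to_iv(cand["m"])), unname(cbind(150000, 170000)))
    # clipped at the chromosome start
    expect_equal(unname(gr_to_iv(cand["edge"])), unname(cbind(0, 13000)))
    expect_equal(length(ps), 3)
    expect_length(refined(ps), 0)
})

test_that("active regions merge below 1 kb and keep >= 400 bp, with presets", {
    lay <- tiny_layout(1e6)
    # two 300 bp active segments 800 bp apart -> one 1400 bp region, kept
    st <- state_gr(rbind(c(1000, 1300), c(2100, 2400), c(5000, 5399),
                         c(9000, 20000)),
                   c("Active", "Active", "Active", "Quiescent"), lay)
    act <- activeRegions(st, "Active")
    expect_equal(unname(gr_to_iv(act)), unname(cbind(1000, 2400)))
    # the isolated 399 bp segment was dropped (inclusive >= 400 boundary);
    # a 400 bp one survives
    st2 <- state_gr(rbind(c(5000, 5400)), "Active", lay)
    expect_length(activeRegions(st2, "Active"), 1)
    # no active state present -> empty set
    expect_length(activeRegions(st, "Enhancer"), 0)
    # against a declared vocabulary, an unknown label is an error listing it
    expect_error(activeRegions(st, "Enhancer",
                               known_states = c("Active", "Quiescent")),
                 "Quiescent")
    # roadmap preset labels
    expect_equal(roadmapActiveStates(), c("1", "2", "3", "10", "11"))
})

test_that("active regions equal the filter+merge oracle on random segments", {
    set.seed(13)
    L <- 30000
    lay <- tiny_layout(L)
    labels <- c("A", "B", "C")
    for (rep in 1:60) {
        iv <- rand_iv(sample.int(25, 1), L, max_w = 600)
        sts <- sample(labels, nrow(iv), replace = TRUE)
        gap <- sample.int(500, 1); ml <- sample.int(400, 1)
        got <- activeRegions(state_gr(iv, sts, lay), c("A", "B"),
                             merge_gap = gap, min_len = ml)
        want <- oracle_active_regions(iv, sts, c("A", "B"), gap, ml, L)
        expect_equal(unname(gr_to_iv(got)), unname(want))
    }
})

test_that("refinement picks the longest overlapping active region", {
    lay <- tiny_layout(1e6)
    calls <- gr1(100000, 160000, "+", layout = lay)
    names(calls) <- "v"
    ps <- candidatePromoters(calls, lay)   # candidate [90k, 110k)
    act <- gr1(c(95000, 101000, 300000), c(95500, 103000, 310000), "*",
               layout = lay)
    ref <- refined(refinePromoters(ps, act))
    expect_equal(unname(gr_to_iv(ref["v"])), unname(cbind(101000, 103000)))
    expect_equal(as.character(strand(ref["v"])), "+")
    # no overlap: stays unrefined
    ps2 <- refinePromoters(ps, gr1(300000, 310000, "*", layout = lay))
    expect_length(refined(ps2), 0)
    expect_equal(refinedFraction(ps2), 0)
    # equal lengths: leftmost wins
    tie <- gr1(c(95000, 101000), c(96000, 102000), "*", layout = lay)
    ref3 <- refined(refinePromoters(ps, tie))
    expect_equal(unname(gr_to_iv(ref3["v"])), unname(cbind(95000, 96000)))
})

test_that("enrichment handles saturation, emptiness and the printed counts", {
    lay <- tiny_layout(1e6)
    set.seed(2)
    s0 <- seq(0, 9e5, by = 5e4)[1:10]
    prom <- gr1(s0, s0 + 2e4, layout = lay)
    names(prom) <- paste0("p", 1:10)
    # active covering the whole genome: every replicate saturates, fold 1
    whole <- gr1(0, 1e6, "*", layout = lay)
    en <- overlapEnrichment(prom, whole, lay, n_shuffles = 20, seed = 5)
    expect_equal(en@n_obs, 10L)
    expect_true(all(en@random_counts == 10))
    expect_equal(foldEnrichment(en), 1)
    # empty active set: zero observed, fold 0 by convention, with warning
    expect_warning(
        en0 <- overlapEnrichment(prom, GRanges(), lay, n_shuffles = 20,
                                 seed = 5),
        "fold defined as 0")
    expect_equal(foldEnrichment(en0), 0)
    expect_error(overlapEnrichment(prom, whole, lay, n_shuffles = 0), ">= 1")

    # published worked example: 79/256 observed vs mean 36/256 random
    wk <- enrichmentFromCounts(79, 36, 256)
    expect_equal(round(foldEnrichment(wk), 1), 2.2)
    pct <- overlapPercentages(wk)
    expect_equal(round(unname(pct["observed"]), 1), 30.9)
    expect_equal(round(unname(pct["random"]), 2), 14.06)
    expect_equal(unname(wk@table["observed", ]), c(79, 177))
    expect_equal(unname(wk@table["random", ]), c(36, 220))
    expect_true(is.na(enrichmentPvalues(wk)["permutation"]))
})

test_that("expression-stratified overlap puts the top quartile in bin 1", {
    lay <- tiny_layout(1e7)
    n <- 256
    s0 <- seq(0, 1e7 - 3e4, length.out = n)
    prom <- gr1(round(s0), round(s0) + 2e4, layout = lay)
    names(prom) <- sprintf("p%03d", seq_len(n))
    expr <- setNames(seq_len(n), names(prom))   # p256 highest
    # active regions over the 64 highest-expression promoters only
    top <- names(sort(expr, decreasing = TRUE))[1:64]
    act <- prom[top]; strand(act) <- "*"
    res <- expressionStratifiedOverlap(prom, act, expr, n_bins = 8)
    expect_equal(res$n, rep(32L, 8))
    expect_equal(res$frac_overlap, c(1, 1, 0, 0, 0, 0, 0, 0))
    # quartile mode
    res4 <- expressionStratifiedOverlap(prom, act, expr, n_bins = 4)
    expect_equal(res4$n, rep(64L, 4))
    expect_equal(res4$frac_overlap[1], 1)
    # everything overlapping -> every bin 1.0
    all_act <- gr1(0, 1e7, "*", layout = lay)
    expect_true(all(expressionStratifiedOverlap(prom, all_act, expr,
                                                8)$frac_overlap == 1))
    # remainder spreads over leading bins
    res5 <- expressionStratifiedOverlap(prom[1:10], act, expr[1:10], n_bins = 3)
    expect_equal(res5$n, c(4L, 3L, 3L))
    expect_error(expressionStratifiedOverlap(prom, act, expr[-1], 8),
                 "missing expression")
})

test_that("density profiles are flat for uniform signal and scale-free", {
    lay <- tiny_layout(1e6)
    uni <- gr1(0, 1e6, "*", layout = lay); mcols(uni)$depth <- 4L
    tr <- trackFromRanges(uni, lay)
    regions <- gr1(c(3e5, 6e5), c(3e5 + 100, 6e5 + 100), layout = lay)
    names(regions) <- c("a", "b")
    prof <- densityProfile(tr, regions, window = 10000, n_bins = 20)
    expect_equal(length(prof$profile), 20)
    expect_true(diff(range(prof$profile)) < 1e-9)
    # doubling the signal leaves the normalized profile unchanged
    uni2 <- uni; mcols(uni2)$depth <- 8L
    prof2 <- densityProfile(trackFromRanges(uni2, lay), regions,
                            window = 10000, n_bins = 20)
    expect_equal(prof2$profile, prof$profile)
    # signal concentrated at the centers peaks in the central bins
    peak <- gr1(c(3e5 - 200, 6e5 - 200), c(3e5 + 300, 6e5 + 300), "*",
                layout = lay)
    mcols(peak)$depth <- 50L
    prof3 <- densityProfile(trackFromRanges(peak, lay), regions,
                            window = 10000, n_bins = 21)
    expect_equal(which.max(prof3$profile), 11)
    # bins beyond the chromosome edge are missing, not zero
    edge <- gr1(50, 150, layout = lay); names(edge) <- "e"
    prof4 <- densityProfile(tr, edge, window = 10000, n_bins = 20)
    expect_true(anyNA(prof4$matrix))
})
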