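track_from_depth <- function(depth_plus, layout, depth_minus = NULL) {
    rl <- function(v) {
        if (is.null(v)) return(NULL)
        RleList(chr1 = Rle(as.integer(v)), compress = FALSE)
    }
    CoverageTrack(layout, plus = rl(depth_plus), minus = rl(depth_minus))
}

test_that("density threshold uses the rank convention of the worked multiset", {
    lay <- tiny_layout(8)
    # covered-base depth multiset {1,1,1,1,2,2,3,100}
    tr <- track_from_depth(c(1, 1, 1, 1, 2, 2, 3, 100), lay)
    res <- suppressWarnings(densityThreshold(tr, q = 0.75))  # minus strand empty
    expect_equal(unname(res$thresholds["plus"]), 3)
    kept <- as.integer(strandCoverage(res$track, "+")[["chr1"]])
    expect_equal(kept, c(0, 0, 0, 0, 0, 0, 3, 100))

    # uniform depth: threshold equals it, track unchanged
    lay2 <- tiny_layout(50)
    tr2 <- track_from_depth(rep(7, 50), lay2)
    res2 <- suppressWarnings(densityThreshold(tr2))
    expect_equal(unname(res2$thresholds["plus"]), 7)
    expect_identical(as.integer(strandCoverage(res2$track, "+")[["chr1"]]),
                     rep(7L, 50))

    # empty strand: NA threshold with a warning, strand stays empty
    expect_warning(res3 <- densityThreshold(track_from_depth(rep(0, 50), lay2)),
                   "threshold undefined")
    expect_true(all(is.na(res3$thresholds)))
})

test_that("joint quantile pools both strands into one threshold", {
    lay <- tiny_layout(8)
    tr <- track_from_depth(c(1, 1, 1, 1, 0, 0, 0, 0), lay,
                           depth_minus = c(0, 0, 0, 0, 2, 2, 3, 100))
    res <- densityThreshold(tr, joint = TRUE)
    expect_equal(unname(res$thresholds["plus"]),
                 unname(res$thresholds["minus"]))
    expect_equal(unname(res$thresholds["plus"]), 3)
})

test_that("discovery follows the fixed pipeline order on constructed cases", {
    lay <- tiny_layout(1e6)
    # toys cover only one strand; the empty-strand warning is expected
    discoverVlincs <- function(...) suppressWarnings(vlincscope::discoverVlincs(...))
    p <- discoveryParams(min_length = 50000, base_merge_gap = 500,
                         segment_merge_gap = 10000)

    # one high-depth 80 kb intergenic block -> exactly one call over it
    gr <- gr1(100000, 180000, layout = lay); mcols(gr)$depth <- 50L
    bg <- gr1(400000, 400500, layout = lay); mcols(bg)$depth <- 1L
    tr <- trackFromRanges(c(gr, bg), lay)
    calls <- discoverVlincs(tr, genes = GRanges(), params = p)
    expect_length(calls, 1)
    expect_equal(gr_to_iv(calls), cbind(start0 = 100000, end0 = 180000))
    expect_equal(mcols(calls)$id, "vlinc_chr1_100000_+")

    # all coverage inside same-strand gene bodies -> zero calls
    genes <- gr1(100000, 180000, layout = lay)
    expect_length(discoverVlincs(tr, genes = genes, params = p), 0)

    # two 30 kb blocks 9.9 kb apart (joint span > 50 kb) -> one merged call
    b1 <- gr1(c(0, 39900), c(30000, 69900), layout = lay)
    mcols(b1)$depth <- 50L
    one <- discoverVlincs(trackFromRanges(b1, lay), GRanges(), params = p)
    expect_length(one, 1)
    expect_equal(gr_to_iv(one), cbind(start0 = 0, end0 = 69900))
    # same blocks 10.1 kb apart, each < 50 kb -> zero calls
    b2 <- gr1(c(0, 40100), c(30000, 70100), layout = lay)
    mcols(b2)$depth <- 50L
    expect_length(discoverVlincs(trackFromRanges(b2, lay), GRanges(),
                                 params = p), 0)

    # a 9.9 kb blacklisted hole is removed at base level but bridged by the
    # 10 kb segment merge; a 10 kb hole is not (strict <)
    bl <- gr1(120000, 129900, "*", layout = lay)
    calls_bl <- discoverVlincs(tr, GRanges(), blacklist = bl, params = p)
    expect_equal(gr_to_iv(calls_bl), cbind(start0 = 100000, end0 = 180000))
    bl2 <- gr1(120000, 130000, "*", layout = lay)
    calls_bl2 <- discoverVlincs(tr, GRanges(), blacklist = bl2, params = p)
    expect_equal(gr_to_iv(calls_bl2), cbind(start0 = 130000, end0 = 180000))
})

test_that("discovery equals the brute-force per-base oracle on random toys", {
    set.seed(11)
    L <- 20000
    lay <- tiny_layout(L)
    p <- discoveryParams(density_quantile = 0.75, base_merge_gap = 50,
                         segment_merge_gap = 100, min_length = 500,
                         far_gene_dist = 100)
    for (rep in 1:80) {
        depth <- integer(L)
        blocks <- rand_iv(sample.int(8, 1), L, max_w = 3000)
        for (i in seq_len(nrow(blocks)))
            depth[seq(blocks[i, 1] + 1, blocks[i, 2])] <-
                depth[seq(blocks[i, 1] + 1, blocks[i, 2])] +
                sample.int(30, 1)
        genes <- rand_iv(sample.int(3, 1), L, max_w = 2000)
        black <- rand_iv(sample.int(3, 1), L, max_w = 1000)
        tr <- track_from_depth(depth, lay)
        # minus strand is intentionally empty in these toys
        got <- suppressWarnings(
            discoverVlincs(tr, iv_to_gr(genes, "chr1", lay, "+"),
                           iv_to_gr(black, "chr1", lay, "*"), params = p))
        want <- oracle_discover(depth, genes, black, 0.75, 50, 100, 500)
        expect_equal(unname(gr_to_iv(got[strand(got) == "+"])), unname(want))
        # emitted calls: long enough and mutually disjoint
        if (length(got)) {
            expect_true(all(width(got) >= 500))
            expect_equal(length(reduce(got, min.gapwidth = 0L)), length(got))
        }
    }
})

test_that("far-from-genes relabels survivors of the strand-blind filter", {
    lay <- tiny_layout(1e6)
    gr <- gr1(100000, 180000, layout = lay); mcols(gr)$depth <- 50L
    calls <- suppressWarnings(discoverVlincs(trackFromRanges(gr, lay),
                                             GRanges(),
                                             params = discoveryParams()))
    # gene 10,001 bp away on the opposite strand: kept
    far <- farFromGenes(calls, gr1(50000, 89999, "-", layout = lay))
    expect_length(far, 1)
    expect_equal(mcols(far)$call_class, "far_from_genes")
    # gene 9,999 bp away: removed regardless of strand
    expect_length(farFromGenes(calls, gr1(50000, 90001, "-", layout = lay)), 0)
})

test_that("catalog comparison applies reciprocal overlap and strand flags", {
    lay <- tiny_layout(1e6)
    calls <- gr1(0, 100000, layout = lay)
    mcols(calls)$id <- "u1"
    # identical interval: shared
    res <- compareCatalogs(calls, list(A = gr1(0, 100000, layout = lay)))
    expect_equal(res$per_call$n_datasets, 1)
    expect_equal(res$n_unique, 0)
    # 20 kb overlap = 20% of u, 6.25% of v: not reciprocal at 25%
    v <- gr1(80000, 400000, layout = lay)
    res2 <- compareCatalogs(calls, list(A = v))
    expect_equal(res2$n_unique, 1)
    expect_equal(res2$unique_ids, "u1")
    # same coordinates on the other strand: stranded catalog says unshared,
    # unstranded says shared
    vm <- gr1(0, 100000, "-", layout = lay)
    expect_equal(compareCatalogs(calls, list(A = vm))$n_unique, 1)
    expect_equal(compareCatalogs(calls, list(A = vm),
                                 stranded = c(A = FALSE))$n_unique, 0)
    # counts bounded by the number of datasets
    res3 <- compareCatalogs(calls, list(A = gr1(0, 100000, layout = lay),
                                        B = gr1(0, 100000, layout = lay)))
    expect_equal(res3$per_call$n_datasets, 2)
    expect_equal(unname(res3$per_catalog), c(1, 1))
})
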