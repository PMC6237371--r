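make_calls <- function(lay, n = 4, w = 60000, gap = 100000) {
    s0 <- (seq_len(n) - 1) * (w + gap)
    gr <- gr1(s0, s0 + w, strand = rep(c("+", "-"), length.out = n),
              layout = lay)
    names(gr) <- sprintf("v%d", seq_len(n))
    gr
}

test_that("fragment counting follows the ambiguous-discard dialect", {
    lay <- tiny_layout(1e6)
    calls <- make_calls(lay, n = 2, gap = 5000)   # v1 [0,60k)+, v2 [65k,125k)-
    frags <- list(
        s1 = c(gr1(10, 110, "+", layout = lay),      # inside v1, same strand
               gr1(70000, 70100, "+", layout = lay), # v2 region, wrong strand
               gr1(200000, 200100, "+", layout = lay)), # outside all calls
        s2 = gr1(59990, 65010, "+", layout = lay))   # spans v1 and v2 starts
    cnt <- countFragments(frags, calls)
    expect_equal(cnt["v1", "s1"], 1L)
    expect_equal(cnt["v2", "s1"], 0L)
    # s2's fragment overlaps v1 (+) only, since v2 is minus-strand: counted
    expect_equal(cnt["v1", "s2"], 1L)

    # a fragment overlapping two same-strand calls counts for neither
    calls2 <- calls; strand(calls2) <- "+"
    cnt2 <- countFragments(list(s = gr1(59990, 65010, "+", layout = lay)),
                           calls2)
    expect_equal(unname(cnt2[, "s"]), c(0L, 0L))
})

test_that("minimal-expression filter applies inclusive bounds and autosomes", {
    lay <- tiny_layout(1e6, n = 2, sex = TRUE)
    si <- Seqinfo(chromNames(lay), as.integer(chromLengths(lay)))
    calls <- GRanges(c("chr1", "chr2", "chrX"),
                     IRanges(1, 60000), strand = "+", seqinfo = si)
    names(calls) <- c("a", "b", "x")
    counts <- rbind(a = c(100L, 100L, 100L, 0L),
                    b = c(99L, 500L, 500L, 0L),
                    x = c(10000L, 10000L, 10000L, 10000L))
    meta <- data.frame(sample_id = paste0("s", 1:4),
                       immunophenotype = "pre-B", subtype = "HHD",
                       batch = "b1")
    colnames(counts) <- meta$sample_id
    se <- makeCountMatrix(counts, calls, meta, lay)
    kept <- filterMinExpressed(se)
    # exactly 3 samples at the 100-read threshold: kept (inclusive);
    # 2 qualifying samples: dropped; chrX: dropped despite huge counts
    expect_equal(rownames(kept), "a")
    # without the autosome restriction chrX comes back
    expect_setequal(rownames(filterMinExpressed(se, autosomal_only = FALSE)),
                    c("a", "x"))
})

test_that("minimal-expression filter equals the double-loop oracle", {
    set.seed(3)
    lay <- tiny_layout(1e7, n = 3, sex = TRUE)
    si <- Seqinfo(chromNames(lay), as.integer(chromLengths(lay)))
    for (rep in 1:40) {
        n <- sample(5:25, 1); m <- sample(3:10, 1)
        chrom <- sample(chromNames(lay), n, replace = TRUE)
        calls <- GRanges(chrom, IRanges(1, 60000), strand = "+", seqinfo = si)
        names(calls) <- sprintf("r%d", seq_len(n))
        counts <- matrix(rnbinom(n * m, mu = 120, size = 2), n,
                         dimnames = list(names(calls), sprintf("s%d", 1:m)))
        meta <- data.frame(sample_id = colnames(counts),
                           immunophenotype = "pre-B", subtype = "HHD",
                           batch = "b1")
        se <- makeCountMatrix(counts, calls, meta, lay)
        mr <- sample(50:200, 1); msmp <- sample(1:4, 1)
        got <- rownames(filterMinExpressed(se, min_reads = mr,
                                           min_samples = msmp))
        want <- names(calls)[oracle_filter_min_expressed(
            counts, isAutosome(lay)[chrom], mr, msmp, TRUE)]
        expect_equal(got, want)
    }
})

test_that("normalization recovers size-factor ratios and zero mapping", {
    counts <- rbind(a = c(10L, 20L), b = c(100L, 200L), c = c(30L, 60L))
    colnames(counts) <- c("s1", "s2")
    nl <- normalizeLog(counts)
    # one sample exactly 2x another: size factors in ratio 2, identical
    # normalized columns
    expect_equal(unname(nl$size_factors["s2"] / nl$size_factors["s1"]), 2)
    expect_equal(nl$mat[, "s1"], nl$mat[, "s2"])
    # identical samples: equal size factors and columns
    nl2 <- normalizeLog(cbind(s1 = c(5L, 7L), s2 = c(5L, 7L)))
    expect_equal(unname(nl2$size_factors["s1"]), unname(nl2$size_factors["s2"]))
    # zero count maps to log2(pseudocount) = 0
    counts3 <- rbind(a = c(8L, 8L), b = c(0L, 16L))
    expect_equal(unname(normalizeLog(counts3)$mat["b", 1]), 0)
    # no all-positive region: total-count fallback with warning
    expect_warning(normalizeLog(rbind(a = c(0L, 5L), b = c(5L, 0L))),
                   "total-count")
})

test_that("clustering separates blobs and handles degenerate k", {
    set.seed(21)
    blob <- function(center, n) matrix(rnorm(20 * n, center, 0.2), 20,
                                       dimnames = list(NULL, NULL))
    mat <- cbind(blob(0, 5), blob(10, 5))
    colnames(mat) <- sprintf("s%d", 1:10)
    truth <- rep(c("A", "B"), each = 5)
    cl <- hierarchicalClusters(mat, k = 2)
    expect_equal(clusterPurity(cl, setNames(truth, colnames(mat))), 1)
    # k = n: singletons
    cl_n <- hierarchicalClusters(mat, k = 10)
    expect_equal(sort(unique(clusterAssignment(cl_n))), 1:10)
    # duplicated sample shares its duplicate's cluster at k < n
    mat2 <- cbind(mat, s11 = mat[, "s1"])
    cl2 <- hierarchicalClusters(mat2, k = 5)
    a <- clusterAssignment(cl2)
    expect_equal(unname(a["s11"]), unname(a["s1"]))
    expect_error(hierarchicalClusters(mat, k = 0), "k must be")
    expect_error(hierarchicalClusters(mat, k = 11), "k must be")
})

test_that("purity matches its worked example, symmetry case and oracle", {
    # clusters {A,A,B} and {B,B}: (2 + 2) / 5
    assign <- c(s1 = 1L, s2 = 1L, s3 = 1L, s4 = 2L, s5 = 2L)
    labels <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B", s5 = "B")
    expect_equal(clusterPurity(assign, labels), 0.8)
    # one cluster, uniform labels over L classes -> 1/L
    assign1 <- setNames(rep(1L, 6), paste0("s", 1:6))
    labels1 <- setNames(rep(c("x", "y", "z"), 2), paste0("s", 1:6))
    expect_equal(clusterPurity(assign1, labels1), 1 / 3)
    # invariant to label renaming
    expect_equal(clusterPurity(assign, c(s1 = "Q", s2 = "Q", s3 = "R",
                                         s4 = "R", s5 = "R")), 0.8)
    expect_error(clusterPurity(assign, labels[1:3]), "different sample sets")

    # exhaustive enumeration oracle over all assignments of 6 samples
    labs <- setNames(c("A", "A", "B", "B", "C", "C"), paste0("s", 1:6))
    grid <- expand.grid(rep(list(1:3), 6))
    for (i in seq(1, nrow(grid), by = 7)) {   # every 7th of the 729 cases
        a <- setNames(as.integer(grid[i, ]), names(labs))
        expect_equal(clusterPurity(a, labs), oracle_purity(a, labs))
    }
})

test_that("subtype-specific ranking applies the inclusive two-fold rule", {
    meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                       subtype = rep(c("t12_21", "HHD", "preT"), each = 2))
    lin <- rbind(r1 = c(8, 8, 4, 4, 2, 2),      # fold exactly 2: kept
                 r2 = c(5, 5, 5, 5, 5, 5),      # fold 1: dropped
                 r3 = c(3, 3, 0, 0, 0, 0),      # only in subtype: Inf, first
                 r4 = c(9, 9, 2, 2, 1, 1))      # fold 4.5
    mat <- log2(lin + 1)
    colnames(mat) <- meta$sample_id
    res <- subtypeSpecific(mat, meta, "t12_21")
    expect_equal(res$id, c("r3", "r4", "r1"))
    expect_equal(res$fold[res$id == "r1"], 2)
    expect_true(is.infinite(res$fold[1]))
    expect_equal(subtypeSpecific(mat, meta, "t12_21", top_n = 2)$id,
                 c("r3", "r4"))
    expect_error(subtypeSpecific(mat, meta, "absent"), "absent")
})

test_that("PCA separates constructed clusters deterministically", {
    set.seed(8)
    mat <- cbind(matrix(rnorm(40, 0, 0.1), 8, 5),
                 matrix(rnorm(40, 6, 0.1), 8, 5))
    colnames(mat) <- sprintf("s%d", 1:10)
    pc <- pcaProject(mat, 2)
    # PC1 separates the two groups
    expect_true(all(pc$coords[1:5, 1] < 0) != all(pc$coords[1:5, 1] > 0))
    expect_true(max(pc$coords[1:5, 1]) < min(pc$coords[6:10, 1]) ||
                min(pc$coords[1:5, 1]) > max(pc$coords[6:10, 1]))
    # variance fractions non-negative, non-increasing, sum <= 1
    expect_true(all(pc$var_frac >= 0))
    expect_true(all(diff(pc$var_frac) <= 1e-12))
    expect_lte(sum(pc$var_frac), 1 + 1e-12)
    # duplicated samples land on identical coordinates
    mat2 <- cbind(mat, s11 = mat[, "s1"])
    pc2 <- pcaProject(mat2, 2)
    expect_equal(pc2$coords["s11", ], pc2$coords["s1", ])
    expect_error(pcaProject(matrix(1, 4, 4), 2), "degenerate")
})
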