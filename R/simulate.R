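#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' study conditions the pipeline targets: a 3 x 10 Mb genome carrying 20
#' intergenic transcribed blocks of 50 kb to 1 Mb (log-uniform, matching
#' the published size range), protein-coding genes to exercise masking,
#' four leukemia subtypes of 8 samples each with negative-binomial counts
#' and 8-fold subtype-specific expression, active chromatin states at 90%
#' of expressed-vlincRNA promoters, and promoter hypomethylation
#' (Beta(2,8)) against a hypermethylated genome (Beta(8,2)).
#'
#' The pooled background has two components: scattered depth-1 reads
#' (mean pooled per-base depth \code{background_noise_depth}) emulating
#' dispersed transcriptional noise, and "noise islands" - short, recurrent
#' transcribed loci (repeats, unannotated short RNAs) with appreciable
#' pooled depth, placed at least \code{noise_island_min_gap} bp apart.
#' Island spacing wider than the 10 kb segment-merge gap means background
#' alone can never chain into a >= 50 kb call, while the islands' depth
#' keeps the scattered depth-1 component below the Q3 density threshold.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param n_chrom,chrom_length genome shape (autosomes; one extra sex
#'   chromosome is appended when \code{add_sex_chrom}).
#' @param add_sex_chrom append a non-autosomal chromosome (no planted
#'   features) so autosome filters are exercised.
#' @param n_genes,gene_length_range protein-coding gene count and bp range.
#' @param n_vlincs,vlinc_length_range planted vlincRNA count and bp range
#'   (log-uniform).
#' @param min_feature_gap minimum gap between any two planted features
#'   (genes or vlincRNAs), bp. Kept above the segment-merge gap so
#'   neighbouring features cannot be bridged into one call.
#' @param n_samples_per_subtype named integer vector, subtype -> sample
#'   count.
#' @param expression_mean_range per-vlincRNA base NB mean (uniform draw).
#' @param subtype_fold expression multiplier in the specific subtype.
#' @param n_specific_per_subtype planted subtype-specific vlincRNAs per
#'   subtype.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param background_noise_depth mean pooled per-base depth of scattered
#'   background reads, per strand.
#' @param n_noise_islands islands per strand per genome.
#' @param noise_island_width_range,noise_island_depth_range island width
#'   (bp) and pooled depth ranges.
#' @param noise_island_min_gap minimum island separation, bp.
#' @param read_depth_scale per-sample coverage depth per expression unit:
#'   window depth ~ Poisson(level * read_depth_scale).
#' @param coverage_window bp window within which simulated depth is
#'   constant.
#' @param active_promoter_prob_expressed probability an expressed
#'   vlincRNA promoter carries an active chromatin segment.
#' @param active_length_range active-segment length range, bp.
#' @param n_background_active unrelated active segments per genome.
#' @param meth_beta_active,meth_beta_background Beta(shape1, shape2)
#'   parameters of true methylation inside active segments / elsewhere.
#' @param cpg_spacing bp between simulated CpGs.
#' @param meth_coverage mean read coverage per CpG.
#' @param scale global bp scale factor; < 1 shrinks every bp parameter
#'   proportionally for fast toy runs.
#' @return a validated configuration list (class \code{SimulationConfig}).
#' @export
simConfig <- function(seed = 1,
                      n_chrom = 3, chrom_length = 1e7, add_sex_chrom = FALSE,
                      n_genes = 60, gene_length_range = c(5000, 100000),
                      n_vlincs = 20, vlinc_length_range = c(50000, 1000000),
                      min_feature_gap = 25000,
                      n_samples_per_subtype = c(HHD = 8, t12_21 = 8,
                                                t9_22 = 8, preT = 8),
                      expression_mean_range = c(200, 2000),
                      subtype_fold = 8, n_specific_per_subtype = 3,
                      nb_dispersion = 0.2,
                      background_noise_depth = 0.35,
                      n_noise_islands = 1500,
                      noise_island_width_range = c(500, 4000),
                      noise_island_depth_range = c(3, 12),
                      noise_island_min_gap = 12000,
                      read_depth_scale = 0.01, coverage_window = 500,
                      active_promoter_prob_expressed = 0.9,
                      active_length_range = c(600, 3000),
                      n_background_active = 300,
                      meth_beta_active = c(2, 8),
                      meth_beta_background = c(8, 2),
                      cpg_spacing = 400, meth_coverage = 30,
                      scale = 1) {
    cfg <- as.list(environment())
    if (scale != 1) {
        bp <- c("chrom_length", "gene_length_range", "vlinc_length_range",
                "min_feature_gap", "noise_island_width_range",
                "noise_island_min_gap", "coverage_window",
                "active_length_range", "cpg_spacing")
        for (f in bp) cfg[[f]] <- pmax(round(cfg[[f]] * scale), 1)
        cfg$coverage_window <- max(cfg$coverage_window, 10)
        cfg$cpg_spacing <- max(cfg$cpg_spacing, 5)
    }
    stopifnot(cfg$n_chrom >= 1, cfg$chrom_length > 0, cfg$n_vlincs >= 0,
              cfg$n_genes >= 0, all(cfg$n_samples_per_subtype > 0),
              !is.null(names(cfg$n_samples_per_subtype)),
              cfg$subtype_fold >= 1, cfg$nb_dispersion >= 0,
              cfg$n_specific_per_subtype * length(cfg$n_samples_per_subtype)
                  <= max(cfg$n_vlincs, 1))
    class(cfg) <- "SimulationConfig"
    cfg
}

## Place n features of the given lengths on [0, L) with pairwise gaps
## >= min_gap (also at both ends). Returns 0-based starts, sorted.
.placeOnChrom <- function(lens, L, min_gap) {
    n <- length(lens)
    if (n == 0) return(numeric(0))
    spare <- L - sum(lens) - (n + 1) * min_gap
    if (spare < 0) stop("infeasible packing: genome too small for requested features",
                        call. = FALSE)
    cuts <- sort(runif(n)) * spare
    extra <- diff(c(0, cuts))
    min_gap + cumsum(extra + c(0, head(lens, -1) + min_gap))
}

#' Simulate a genome with planted genes and vlincRNAs
#'
#' Genes and vlincRNAs are placed without overlap, separated by at least
#' \code{min_feature_gap} bp (so every planted vlincRNA is far from genes),
#' with random strands. Subtype-specific vlincRNAs are drawn without
#' replacement; each gets \code{subtype_fold} times its base expression in
#' its subtype. Noise islands are placed per strand with their minimum
#' separation. Deterministic given \code{config$seed}.
#'
#' @param config a [simConfig()] configuration.
#' @return a \code{SyntheticTruth} list: \code{layout}, \code{genes}
#'   (stranded GRanges, mcols \code{gene_level}), \code{vlincs} (stranded
#'   GRanges named by id, mcols \code{base_level},
#'   \code{specific_subtype}), \code{islands} (stranded GRanges, mcols
#'   \code{depth}), \code{expression} (vlinc x subtype mean matrix),
#'   \code{subtypes}, \code{config}.
#' @export
simulateGenome <- function(config) {
    set.seed(config$seed)
    chroms <- sprintf("chr%d", seq_len(config$n_chrom))
    lens <- rep(config$chrom_length, config$n_chrom)
    auto <- rep(TRUE, config$n_chrom)
    if (config$add_sex_chrom) {
        chroms <- c(chroms, "chrX")
        lens <- c(lens, config$chrom_length)
        auto <- c(auto, FALSE)
    }
    layout <- GenomeLayout(chroms, lens, auto)
    placed_chroms <- chroms[auto]

    glen <- round(runif(config$n_genes, config$gene_length_range[1],
                        config$gene_length_range[2]))
    vlen <- round(exp(runif(config$n_vlincs, log(config$vlinc_length_range[1]),
                            log(config$vlinc_length_range[2]))))
    feat_len <- c(glen, vlen)
    feat_is_vlinc <- c(rep(FALSE, config$n_genes), rep(TRUE, config$n_vlincs))
    n_feat <- length(feat_len)

    ## assign features to chromosomes proportional to length, retry on
    ## infeasible packings
    chrom_of <- NULL
    for (try in 1:100) {
        cand <- sample(seq_along(placed_chroms), n_feat, replace = TRUE,
                       prob = lens[match(placed_chroms, chroms)])
        need <- vapply(seq_along(placed_chroms), function(i) {
            l <- feat_len[cand == i]
            sum(l) + (length(l) + 1) * config$min_feature_gap
        }, 0)
        if (all(need <= lens[match(placed_chroms, chroms)])) {
            chrom_of <- cand; break
        }
    }
    if (is.null(chrom_of))
        stop("infeasible packing: genome too small for requested features; increase chrom_length")

    starts0 <- numeric(n_feat)
    for (i in seq_along(placed_chroms)) {
        idx <- which(chrom_of == i)
        if (!length(idx)) next
        ord <- idx[sample(length(idx))]    # random along-chromosome order
        starts0[ord] <- .placeOnChrom(feat_len[ord],
                                      lens[match(placed_chroms[i], chroms)],
                                      config$min_feature_gap)
    }
    st <- sample(c("+", "-"), n_feat, replace = TRUE)
    all_gr <- GRanges(placed_chroms[chrom_of],
                      IRanges(starts0 + 1, width = feat_len), strand = st,
                      seqinfo = .seqinfo(layout))
    genes <- sort(all_gr[!feat_is_vlinc])
    if (length(genes))
        mcols(genes)$gene_level <- runif(length(genes),
                                         config$expression_mean_range[1],
                                         config$expression_mean_range[2])
    vlincs <- sort(all_gr[feat_is_vlinc])
    subtypes <- names(config$n_samples_per_subtype)
    if (length(vlincs)) {
        mcols(vlincs)$id <- sprintf("vlinc_%s_%d_%s",
                                    as.character(seqnames(vlincs)),
                                    start(vlincs) - 1L,
                                    as.character(strand(vlincs)))
        names(vlincs) <- mcols(vlincs)$id
        mcols(vlincs)$base_level <- runif(length(vlincs),
                                          config$expression_mean_range[1],
                                          config$expression_mean_range[2])
        spec <- rep(NA_character_, length(vlincs))
        if (config$n_specific_per_subtype > 0 && length(subtypes)) {
            pick <- sample(length(vlincs),
                           config$n_specific_per_subtype * length(subtypes))
            spec[pick] <- rep(subtypes, each = config$n_specific_per_subtype)
        }
        mcols(vlincs)$specific_subtype <- spec
    }
    expr <- matrix(0, length(vlincs), length(subtypes),
                   dimnames = list(names(vlincs), subtypes))
    if (length(vlincs))
        for (s in subtypes)
            expr[, s] <- mcols(vlincs)$base_level *
                ifelse(!is.na(mcols(vlincs)$specific_subtype) &
                       mcols(vlincs)$specific_subtype == s,
                       config$subtype_fold, 1)

    ## noise islands, per strand, separation >= noise_island_min_gap
    islands <- list()
    for (chr in placed_chroms) {
        L <- lens[match(chr, chroms)]
        n_isl <- round(config$n_noise_islands * L / sum(lens[match(placed_chroms, chroms)]))
        for (strand_i in c("+", "-")) {
            w <- round(runif(n_isl, config$noise_island_width_range[1],
                             config$noise_island_width_range[2]))
            s0 <- tryCatch(.placeOnChrom(w, L, config$noise_island_min_gap),
                           error = function(e)
                               stop("infeasible packing: too many noise islands",
                                    call. = FALSE))
            g <- GRanges(chr, IRanges(s0 + 1, width = w), strand = strand_i,
                         seqinfo = .seqinfo(layout))
            mcols(g)$depth <- round(runif(n_isl,
                                          config$noise_island_depth_range[1],
                                          config$noise_island_depth_range[2]))
            islands[[paste(chr, strand_i)]] <- g
        }
    }
    islands <- if (length(islands)) sort(do.call(c, unname(islands)))
               else .emptyGR(layout)

    structure(list(layout = layout, genes = genes, vlincs = vlincs,
                   islands = islands, expression = expr, subtypes = subtypes,
                   config = config, seed = config$seed),
              class = "SyntheticTruth")
}

#' Sample metadata for a simulated cohort
#'
#' @param truth output of [simulateGenome()].
#' @return data.frame with sample_id, immunophenotype, subtype, batch.
#' @export
simulateSampleMeta <- function(truth) {
    cfg <- truth$config
    rows <- lapply(names(cfg$n_samples_per_subtype), function(s) {
        m <- cfg$n_samples_per_subtype[[s]]
        data.frame(sample_id = sprintf("%s_s%02d", gsub("[^A-Za-z0-9]", "", s),
                                       seq_len(m)),
                   immunophenotype = if (grepl("preT|pre-T", s)) "pre-T"
                                     else if (grepl("control", s)) "control"
                                     else "pre-B",
                   subtype = s, batch = "batch1",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

## Windowed Poisson depth ranges over one feature set for one sample.
.featureDepthRanges <- function(gr, lambda_per_window, win) {
    parts <- lapply(seq_along(gr), function(i) {
        L <- width(gr)[i]
        n_win <- ceiling(L / win)
        d <- rpois(n_win, lambda_per_window[i])
        keep <- d > 0
        if (!any(keep)) return(NULL)
        s <- start(gr)[i] + (which(keep) - 1L) * win
        e <- pmin(s + win - 1L, end(gr)[i])
        GRanges(seqnames(gr)[i], IRanges(s, e), strand = strand(gr)[i],
                depth = d[keep], seqinfo = seqinfo(gr))
    })
    parts[!vapply(parts, is.null, NA)]
}

#' Simulate per-sample strand-specific coverage
#'
#' For each sample: window depth over each planted vlincRNA is
#' Poisson(subtype expression level x \code{read_depth_scale}) on its
#' strand; gene bodies are covered the same way on their strands (to
#' exercise gene masking); noise islands get Poisson(depth / n_samples)
#' per sample so the pooled track reaches their configured depth; and
#' scattered depth-1 background reads are sprinkled per strand. The pooled
#' discovery input is \code{poolTracks()} of the result. Deterministic
#' given the configuration seed.
#'
#' @param truth output of [simulateGenome()].
#' @param meta sample metadata ([simulateSampleMeta()]); defaults to it.
#' @return named list of [CoverageTrack-class], one per sample.
#' @export
simulateCoverage <- function(truth, meta = simulateSampleMeta(truth)) {
    cfg <- truth$config
    set.seed(cfg$seed + 1L)
    lay <- truth$layout
    win <- cfg$coverage_window
    n_samples <- nrow(meta)
    chrlens <- chromLengths(lay)
    out <- vector("list", n_samples)
    for (j in seq_len(n_samples)) {
        subtype <- meta$subtype[j]
        parts <- list()
        if (length(truth$vlincs)) {
            lam <- truth$expression[, subtype] * cfg$read_depth_scale
            parts <- c(parts, .featureDepthRanges(truth$vlincs, lam, win))
        }
        if (length(truth$genes)) {
            lam_g <- mcols(truth$genes)$gene_level * cfg$read_depth_scale
            parts <- c(parts, .featureDepthRanges(truth$genes, lam_g, win))
        }
        if (length(truth$islands)) {
            d <- rpois(length(truth$islands),
                       mcols(truth$islands)$depth / n_samples)
            keep <- d > 0
            if (any(keep)) {
                g <- granges(truth$islands)[keep]
                mcols(g)$depth <- d[keep]
                parts <- c(parts, list(g))
            }
        }
        ## scattered depth-1 reads: mean pooled per-base depth
        ## background_noise_depth => per sample, per strand, per chromosome
        for (chr in chromNames(lay)) {
            L <- chrlens[[chr]]
            for (strand_i in c("+", "-")) {
                n_r <- rpois(1, cfg$background_noise_depth * L /
                                (win * n_samples))
                if (n_r == 0) next
                s0 <- floor(runif(n_r) * (L - win))
                g <- GRanges(chr, IRanges(s0 + 1, width = win),
                             strand = strand_i, seqinfo = .seqinfo(lay))
                mcols(g)$depth <- rep(1L, n_r)
                parts <- c(parts, list(g))
            }
        }
        gr <- if (length(parts)) do.call(c, unname(parts)) else .emptyGR(lay)
        out[[j]] <- trackFromRanges(gr, lay)
    }
    names(out) <- meta$sample_id
    out
}

#' Simulate subtype-structured counts
#'
#' Counts are negative binomial with mean equal to the truth's per-subtype
#' expression level (variance mu + dispersion * mu^2); dispersion 0 gives
#' Poisson. Deterministic given the configuration seed.
#'
#' @param truth output of [simulateGenome()].
#' @param meta sample metadata.
#' @return a list: \code{se} (count matrix as a
#'   \code{RangedSummarizedExperiment}), \code{meta}.
#' @export
simulateCounts <- function(truth, meta = simulateSampleMeta(truth)) {
    cfg <- truth$config
    set.seed(cfg$seed + 2L)
    mu <- truth$expression[, meta$subtype, drop = FALSE]
    counts <- matrix(0L, nrow(mu), ncol(mu),
                     dimnames = list(rownames(mu), meta$sample_id))
    if (length(mu)) {
        counts[] <- as.integer(if (cfg$nb_dispersion > 0)
            rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$nb_dispersion)
        else rpois(length(mu), as.vector(mu)))
    }
    list(se = makeCountMatrix(counts, truth$vlincs, meta, truth$layout),
         meta = meta)
}

#' Simulate a chromatin-state segmentation and WGBS methylation
#'
#' Each expressed vlincRNA promoter carries an "Active" state segment
#' (length uniform in \code{active_length_range}, centered near the 5'
#' start) with probability \code{active_promoter_prob_expressed};
#' additional unrelated Active segments are scattered over the genome; all
#' remaining bases are "Quiescent". CpGs lie every \code{cpg_spacing} bp;
#' their true beta is Beta-distributed with the active parameters inside
#' Active segments and the background parameters elsewhere, and observed
#' counts are binomial at Poisson(\code{meth_coverage}) reads.
#'
#' @param truth output of [simulateGenome()].
#' @return a list: \code{states} (GRanges with \code{state} column,
#'   dense), \code{meth} (a [MethylationTrack-class]),
#'   \code{active_promoter} (named logical per vlincRNA),
#'   \code{promoter_segments} (GRanges of the planted promoter segments,
#'   named by vlincRNA id).
#' @export
simulateChromatinAndMeth <- function(truth) {
    cfg <- truth$config
    set.seed(cfg$seed + 3L)
    lay <- truth$layout
    chrlens <- chromLengths(lay)
    segs <- list()
    active_flag <- setNames(logical(length(truth$vlincs)), names(truth$vlincs))
    if (length(truth$vlincs)) {
        st <- as.character(strand(truth$vlincs))
        anchor0 <- ifelse(st == "+", start(truth$vlincs) - 1L,
                          end(truth$vlincs))
        w <- round(runif(length(truth$vlincs), cfg$active_length_range[1],
                         cfg$active_length_range[2]))
        jit <- round(runif(length(truth$vlincs), -1000, 1000))
        on <- runif(length(truth$vlincs)) < cfg$active_promoter_prob_expressed
        active_flag[] <- on
        if (any(on)) {
            c0 <- anchor0[on] + jit[on]
            s0 <- pmax(c0 - floor(w[on] / 2), 0)
            chr <- as.character(seqnames(truth$vlincs))[on]
            e0 <- pmin(s0 + w[on], chrlens[chr])
            g <- GRanges(chr, IRanges(s0 + 1, e0), seqinfo = .seqinfo(lay))
            names(g) <- names(truth$vlincs)[on]
            segs$promoter <- g
        }
    }
    prom_segs <- if (!is.null(segs$promoter)) segs$promoter else .emptyGR(lay)
    if (cfg$n_background_active > 0) {
        w <- round(runif(cfg$n_background_active, cfg$active_length_range[1],
                         cfg$active_length_range[2]))
        pl <- .drawPlacements(w, lay)
        segs$bg <- GRanges(lay@chrom[pl$chrom], IRanges(pl$start0 + 1, width = w),
                           seqinfo = .seqinfo(lay))
    }
    act <- sort(do.call(c, c(unname(lapply(segs, granges)),
                             list(.emptyGR(lay)))))
    act_red <- reduce(act, ignore.strand = TRUE)
    quiet <- GenomicRanges::gaps(act_red)
    quiet <- quiet[strand(quiet) == "*"]
    states <- c(act, quiet)
    mcols(states)$state <- c(rep("Active", length(act)),
                             rep("Quiescent", length(quiet)))
    states <- sort(states)

    ## CpGs on a fixed grid
    cg <- lapply(chromNames(lay), function(chr) {
        pos0 <- seq(floor(cfg$cpg_spacing / 2), chrlens[[chr]] - 1,
                    by = cfg$cpg_spacing)
        GRanges(chr, IRanges(pos0 + 1, width = 1), seqinfo = .seqinfo(lay))
    })
    cg <- do.call(c, cg)
    in_active <- countOverlaps(cg, act_red, ignore.strand = TRUE) > 0
    beta_true <- numeric(length(cg))
    beta_true[in_active] <- rbeta(sum(in_active), cfg$meth_beta_active[1],
                                  cfg$meth_beta_active[2])
    beta_true[!in_active] <- rbeta(sum(!in_active),
                                   cfg$meth_beta_background[1],
                                   cfg$meth_beta_background[2])
    tot <- rpois(length(cg), cfg$meth_coverage)
    m <- rbinom(length(cg), tot, beta_true)
    meth <- MethylationTrack(lay, as.character(seqnames(cg)), start(cg) - 1L,
                             m, tot - m)
    list(states = states, meth = meth, active_promoter = active_flag,
         promoter_segments = prom_segs)
}

#' Run the full simulation
#'
#' Genome, sample metadata, per-sample coverage (plus the pooled track),
#' counts and chromatin/methylation in one call.
#'
#' @param config a [simConfig()] configuration.
#' @param coverage,chromatin set FALSE to skip the expensive stages.
#' @return a list: \code{truth}, \code{meta}, \code{tracks},
#'   \code{pooled}, \code{counts} (SummarizedExperiment),
#'   \code{chromatin} (see [simulateChromatinAndMeth()]).
#' @export
simulateAll <- function(config = simConfig(), coverage = TRUE,
                        chromatin = TRUE) {
    truth <- simulateGenome(config)
    meta <- simulateSampleMeta(truth)
    tracks <- NULL; pooled <- NULL
    if (coverage) {
        tracks <- simulateCoverage(truth, meta)
        pooled <- poolTracks(tracks)
    }
    cnt <- simulateCounts(truth, meta)
    chrom <- if (chromatin) simulateChromatinAndMeth(truth) else NULL
    list(truth = truth, meta = meta, tracks = tracks, pooled = pooled,
         counts = cnt$se, chromatin = chrom)
}

#' Compare discovered calls with planted truth
#'
#' Per planted vlincRNA, the best Jaccard index (intersection over union)
#' among same-strand calls; a planted transcript is recovered when its best
#' Jaccard reaches \code{min_jaccard}.
#'
#' @param calls discovered \code{GRanges}.
#' @param truth_vlincs planted \code{GRanges}.
#' @param min_jaccard recovery threshold (default 0.8).
#' @return a list: \code{jaccard} (named per planted vlincRNA),
#'   \code{recovered} (logical), \code{recovery_rate}, \code{n_calls}.
#' @export
evaluateRecovery <- function(calls, truth_vlincs, min_jaccard = 0.8) {
    jac <- setNames(numeric(length(truth_vlincs)), names(truth_vlincs))
    if (length(calls) && length(truth_vlincs)) {
        hits <- findOverlaps(truth_vlincs, calls, ignore.strand = FALSE)
        if (length(hits)) {
            inter <- width(pintersect(granges(truth_vlincs)[queryHits(hits)],
                                      granges(calls)[subjectHits(hits)],
                                      ignore.strand = TRUE))
            uni <- width(truth_vlincs)[queryHits(hits)] +
                   width(calls)[subjectHits(hits)] - inter
            j <- inter / uni
            best <- tapply(j, queryHits(hits), max)
            jac[as.integer(names(best))] <- best
        }
    }
    rec <- jac >= min_jaccard
    list(jaccard = jac, recovered = rec,
         recovery_rate = if (length(jac)) mean(rec) else NA_real_,
         n_calls = length(calls))
}
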