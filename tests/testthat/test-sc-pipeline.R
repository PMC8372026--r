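# Minimal SCE with a logcounts assay set directly.
lcSCE <- function(m) {
    SingleCellExperiment::SingleCellExperiment(assays = list(logcounts = m))
}

test_that("QC keeps cells and genes exactly at the inclusive thresholds", {
    nGenes <- 400
    m <- matrix(0, nGenes, 6,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("c%d", 1:6)))
    m[seq_len(300), 1] <- 1     # exactly 300 detected genes: kept
    m[seq_len(299), 2] <- 1     # 299: removed
    m[seq_len(350), 3:6] <- 1   # comfortably above threshold
    # gene 370 in exactly 3 surviving cells, gene 380 in 2
    m["g370", 3:5] <- 1
    m["g380", 3:4] <- 1
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m))
    out <- qcFilter(sce)
    expect_true("c1" %in% colnames(out))
    expect_false("c2" %in% colnames(out))
    expect_true("g370" %in% rownames(out))
    expect_false("g380" %in% rownames(out))
    expect_equal(S4Vectors::metadata(out)$qc$cells_removed, 1)
    # idempotence: a second pass removes nothing
    out2 <- qcFilter(out)
    expect_identical(dim(out2), dim(out))
    expect_equal(S4Vectors::metadata(out2)$qc$cells_removed, 0)
})

test_that("log-normalized cells de-log to exactly the scale factor", {
    sce <- twoTypeSCE(nGenes = 200, nPerGroup = 30, seed = 5)
    sce <- logNormalizeCounts(qcFilter(sce, minGenesPerCell = 10))
    back <- colSums(expm1(SummarizedExperiment::assay(sce, "logcounts")))
    expect_equal(unname(back), rep(1e4, ncol(sce)), tolerance = 1e-9)
})

test_that("PCA captures a planted rank-one structure with stable signs", {
    set.seed(17)
    u <- rnorm(60); v <- abs(rnorm(150)) + 0.5
    m <- outer(v, u) + matrix(rnorm(150 * 60, sd = 0.01), 150, 60)
    m <- m - min(m)   # keep logcounts non-negative
    dimnames(m) <- list(sprintf("g%d", 1:150), sprintf("c%d", 1:60))
    sce <- hvgScalePca(lcSCE(m), nHvg = 150, nPcs = 5)
    emb <- SingleCellExperiment::reducedDim(sce, "PCA")
    expect_equal(dim(emb), c(60L, 5L))
    varFrac <- apply(emb, 2, stats::var) / sum(apply(emb, 2, stats::var))
    expect_gt(varFrac[1], 0.95)
    # deterministic across repeated calls, including component signs
    emb2 <- SingleCellExperiment::reducedDim(
        hvgScalePca(lcSCE(m), nHvg = 150, nPcs = 5), "PCA")
    expect_identical(emb, emb2)
})

test_that("regressing out a covariate removes its axis from the embedding", {
    set.seed(23)
    covar <- rnorm(80)
    signal <- rnorm(80)
    # 60 covariate-driven genes dominate 20 signal genes, so the naive
    # leading component must track the covariate
    m <- rbind(outer(rep(1, 60), covar) * 2,
               outer(rep(1, 20), signal)) +
        matrix(rnorm(80 * 80, sd = 0.05), 80, 80)
    dimnames(m) <- list(sprintf("g%d", 1:80), sprintf("c%d", 1:80))
    plain <- SingleCellExperiment::reducedDim(
        hvgScalePca(lcSCE(m), nHvg = 80, nPcs = 2), "PCA")
    adj <- SingleCellExperiment::reducedDim(
        hvgScalePca(lcSCE(m), nHvg = 80, nPcs = 2,
                    covariates = covar), "PCA")
    expect_gt(abs(cor(plain[, 1], covar)), 0.9)
    expect_lt(max(abs(cor(adj, covar))), 0.2)        # gone after regression
    expect_gt(abs(cor(adj[, 1], signal)), 0.9)       # signal survives
})

test_that("graph clustering recovers well-separated groups", {
    set.seed(31)
    centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
    truth <- rep(1:3, each = 70)
    emb <- centers[truth, ] + matrix(rnorm(210 * 2), 210, 2)
    labels <- clusterCells(emb, k = 30, seed = 2)
    expect_equal(length(labels), 210)
    expect_gt(mclust::adjustedRandIndex(labels, truth), 0.9)
    expect_identical(labels, clusterCells(emb, k = 30, seed = 2))
    expect_error(clusterCells(emb[1:10, ], k = 15), "more cells")
})

test_that("Wilcoxon p-values are invariant to monotone transforms", {
    sce <- twoTypeSCE(nGenes = 150, nPerGroup = 25, seed = 9)
    sce <- logNormalizeCounts(qcFilter(sce, minGenesPerCell = 10))
    d1 <- wilcoxonDEG(sce, "true_type", "RGC", "IP")
    warped <- sce
    lc <- SummarizedExperiment::assay(sce, "logcounts")
    SummarizedExperiment::assay(warped, "logcounts") <- lc^3 + 2 * lc
    d2 <- wilcoxonDEG(warped, "true_type", "RGC", "IP")
    expect_equal(d2$p_value[match(d1$gene, d2$gene)], d1$p_value,
                 tolerance = 1e-12)
})

test_that("tiny groups switch to the exact test with a warning", {
    m <- matrix(runif(40 * 5), 40, 5,
                dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:5)))
    expect_warning(
        wilcoxonDEG(lcSCE(m), c("A", "A", "B", "B", "B"), "A", "B"),
        "fewer than 3")
})

test_that("cluster annotation applies the margin rule and flags absent markers", {
    # 3 clusters x 2 cells; marker rows engineered per cluster
    m <- matrix(0, 4, 6,
                dimnames = list(c("Hes5", "Pax6", "Eomes", "Tubb3"),
                                sprintf("c%d", 1:6)))
    clusters <- rep(1:3, each = 2)
    m[c("Hes5", "Pax6"), clusters == 1] <- 3       # clean RGC call
    m["Eomes", clusters == 2] <- 3                 # clean IP call
    m[c("Hes5", "Pax6"), clusters == 3] <- 1.00    # near-tie with IP
    m["Eomes", clusters == 3] <- 0.97
    sets <- list(RGC = c("Hes5", "Pax6", "Nes"), IP = c("Eomes", "Hes6"),
                 EN = c("Neurod6", "Snap25"))
    expect_warning(ann <- annotateAndCompose(lcSCE(m), clusters, sets,
                                             margin = 0.05),
                   "no markers present.*EN")
    expect_equal(ann$calls$type, c("RGC", "IP", "unassigned"))
    expect_equal(ann$cellTypes, rep(c("RGC", "IP", "unassigned"), each = 2))
    # widen nothing: with a tighter margin the near-tie resolves
    suppressWarnings(
        ann2 <- annotateAndCompose(lcSCE(m), clusters, sets, margin = 0.01))
    expect_equal(ann2$calls$type[3], "RGC")
})

test_that("composition tables recover the simulated group mixtures", {
    props <- rbind(CAG = c(RGC = 0.25, IP = 0.25, EN = 0.50),
                   Hes5 = c(RGC = 0.77, IP = 0.15, EN = 0.08))
    sce <- simulateCounts(nGenes = 900,
                          nCellsPerGroup = c(CAG = 200, Hes5 = 300),
                          typeProportions = props, markersPerType = 30,
                          markerLogFC = 3, seed = 41)
    sce <- logNormalizeCounts(qcFilter(sce, minGenesPerCell = 50))
    truth <- SummarizedExperiment::colData(sce)$true_type
    group <- SummarizedExperiment::colData(sce)$group
    sets <- lapply(c(RGC = "RGC", IP = "IP", EN = "EN"),
                   function(tp) markerGenes(sce, tp))
    # annotate using the true types as "clusters": isolates the scoring
    clusters <- as.integer(factor(truth))
    ann <- annotateAndCompose(sce, clusters, sets, groups = group)
    expect_setequal(unique(ann$cellTypes), c("RGC", "IP", "EN"))
    expect_equal(mean(ann$cellTypes == truth), 1)
    pg <- ann$composition$percent_within_group
    expect_equal(colSums(pg), c(CAG = 100, Hes5 = 100))
    expect_equal(unname(pg["EN", "CAG"]), 50, tolerance = 8)
    expect_equal(unname(pg["RGC", "Hes5"]), 77, tolerance = 8)
})
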