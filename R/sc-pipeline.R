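#' Quality-control filtering of a count matrix
#'
#' Removes low-quality cells first (fewer than \code{minGenesPerCell}
#' detected genes; "at least 300" keeps a cell with exactly 300), then
#' genes detected in fewer than \code{minCellsPerGene} of the surviving
#' cells ("at least three" keeps a gene seen in exactly 3).  The order
#' matters (gene detection is recounted on surviving cells) and is fixed
#' cells-then-genes.  Removal counts are stored in
#' \code{metadata(sce)$qc}.
#'
#' @param sce a \code{SingleCellExperiment} with assay \code{counts}.
#' @param minGenesPerCell minimum detected genes per cell (default 300).
#' @param minCellsPerGene minimum cells expressing a gene (default 3).
#' @return the filtered \code{SingleCellExperiment}.
#' @importFrom S4Vectors metadata metadata<-
#' @export
qcFilter <- function(sce, minGenesPerCell = 300L, minCellsPerGene = 3L) {
    stopifnot(minGenesPerCell >= 0, minCellsPerGene >= 0)
    m <- assay(sce, "counts")
    keepCells <- colSums(m > 0) >= minGenesPerCell
    m2 <- m[, keepCells, drop = FALSE]
    keepGenes <- rowSums(m2 > 0) >= minCellsPerGene
    if (!any(keepCells) || !any(keepGenes))
        stop(sprintf("QC removed everything: %d/%d cells and %d/%d genes failed",
                     sum(!keepCells), ncol(m), sum(!keepGenes), nrow(m)))
    out <- sce[keepGenes, keepCells]
    metadata(out)$qc <- list(cells_removed = sum(!keepCells),
                             genes_removed = sum(!keepGenes),
                             minGenesPerCell = minGenesPerCell,
                             minCellsPerGene = minCellsPerGene)
    out
}

#' Global-scaling log-normalization
#'
#' Per cell: \code{log(1 + count / total * scale)} with natural log and
#' \code{scale = 1e4}, stored as assay \code{logcounts}.  The de-logged
#' (\code{expm1}) values of every cell then sum exactly to \code{scale}.
#'
#' @param sce post-QC \code{SingleCellExperiment}.
#' @param scale scaling factor (default \code{1e4}).
#' @return \code{sce} with an added \code{logcounts} assay.
#' @importFrom SummarizedExperiment assay<-
#' @export
logNormalizeCounts <- function(sce, scale = 1e4) {
    m <- assay(sce, "counts")
    totals <- colSums(m)
    if (any(totals == 0)) stop("cell with zero total counts")
    assay(sce, "logcounts") <- log1p(sweep(m, 2, totals, "/") * scale)
    metadata(sce)$normalization <- list(method = "LogNormalize",
                                        scale = scale)
    sce
}

#' Variable-gene selection, covariate regression, scaling and PCA
#'
#' Selects highly variable genes by binned mean/dispersion z-scores
#' (dispersion = variance/mean of the de-logged normalized values, genes
#' binned by mean, dispersion z-scored within bin; top \code{nHvg}
#' retained), regresses each gene on the supplied per-cell covariates
#' (e.g. detected-molecule counts, mitochondrial fraction) keeping the
#' residuals, scales genes to unit variance with values clipped at
#' +-10, and computes the top principal components.  PC signs follow a
#' deterministic convention: the loading of largest magnitude on each
#' component is positive.
#'
#' @param sce \code{SingleCellExperiment} with \code{logcounts}.
#' @param nHvg number of variable genes to keep (default
#'   \code{min(1000, nrow)}).
#' @param nPcs number of principal components (default 10).
#' @param covariates optional numeric matrix/data.frame (cells x
#'   covariates) to regress out.
#' @param clip absolute clip value after scaling (default 10).
#' @return \code{sce} with \code{reducedDim(sce, "PCA")} set (cells x
#'   \code{nPcs}) and HVG bookkeeping in \code{metadata(sce)$hvg}.
#' @importFrom SingleCellExperiment reducedDim reducedDim<-
#' @export
hvgScalePca <- function(sce, nHvg = NULL, nPcs = 10L, covariates = NULL,
                        clip = 10) {
    lc <- assay(sce, "logcounts")
    if (is.null(nHvg)) nHvg <- min(1000L, nrow(lc))
    if (nrow(lc) < nPcs) stop("fewer genes than requested components")
    expd <- expm1(lc)
    mu <- rowMeans(expd)
    v <- apply(expd, 1, stats::var)
    disp <- ifelse(mu > 0, v / pmax(mu, 1e-12), 0)
    nb <- max(1L, min(20L, floor(nrow(lc) / 10)))
    bins <- cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
    z <- disp
    for (b in unique(bins)) {
        i <- bins == b
        s <- stats::sd(disp[i])
        z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
    }
    hvg <- order(z, decreasing = TRUE)[seq_len(min(nHvg, nrow(lc)))]
    hvg <- sort(hvg)
    x <- lc[hvg, , drop = FALSE]

    # residuals against covariates (intercept always included)
    design <- cbind(intercept = rep(1, ncol(x)))
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        stopifnot(nrow(covariates) == ncol(x))
        design <- cbind(design, covariates)
    }
    qrd <- qr(design)
    resid <- t(qr.resid(qrd, t(x)))

    sds <- apply(resid, 1, stats::sd)
    sds[sds == 0] <- 1
    scaled <- resid / sds
    scaled[scaled > clip] <- clip
    scaled[scaled < -clip] <- -clip

    pc <- stats::prcomp(t(scaled), center = TRUE, scale. = FALSE,
                        rank. = nPcs)
    rot <- pc$rotation
    emb <- pc$x
    for (j in seq_len(ncol(rot))) {
        if (rot[which.max(abs(rot[, j])), j] < 0) {
            rot[, j] <- -rot[, j]
            emb[, j] <- -emb[, j]
        }
    }
    reducedDim(sce, "PCA") <- emb
    metadata(sce)$hvg <- list(method = "binned mean/dispersion z-score",
                              n = length(hvg),
                              genes = rownames(lc)[hvg])
    metadata(sce)$pca <- list(nPcs = ncol(emb), sdev = pc$sdev)
    sce
}

#' Graph-based clustering of cells in PC space
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance in the embedding)
#' and partitions it with Louvain modularity optimization at the given
#' resolution.  Seeded for reproducibility.
#'
#' @param x a \code{SingleCellExperiment} with a \code{"PCA"} reduced
#'   dimension, or a cells x dims numeric matrix.
#' @param k neighbors per cell (default 20).
#' @param resolution Louvain resolution (default 1).
#' @param seed integer seed.
#' @return integer vector of cluster labels (1-based), one per cell.
#' @export
clusterCells <- function(x, k = 20L, resolution = 1, seed = 1L) {
    emb <- if (is(x, "SingleCellExperiment")) reducedDim(x, "PCA") else
        as.matrix(x)
    n <- nrow(emb)
    if (n <= k) stop("need more cells than neighbors k")
    d <- as.matrix(stats::dist(emb))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
    edges <- cbind(rep(seq_len(n), each = k), as.vector(nn))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- as.integer(igraph::membership(cl))
    if (n < 100 && max(labels) > 10)
        warning("more than 10 clusters from fewer than 100 cells; ",
                "resolution is probably too high")
    labels
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on the log-normalized
#' values, Benjamini-Hochberg adjustment across all tested genes, and a
#' log2 fold change computed on the de-logged normalized means with a
#' pseudocount of 1: \code{log2((meanA + 1)/(meanB + 1))}.  A gene is
#' called significant when \code{adj_p < alpha} and
#' \code{|log2fc| > log2fcMin} (defaults 0.05 and 0.3).  Groups smaller
#' than 3 cells trigger a warning and the exact small-sample null
#' distribution is used.
#'
#' @param sce \code{SingleCellExperiment} with \code{logcounts}.
#' @param groups vector of group labels per cell, or the name of a
#'   \code{colData} column.
#' @param groupA,groupB the two labels to compare (A vs B).
#' @param log2fcMin,alpha significance thresholds.
#' @return \code{DataFrame} with columns gene, log2fc, p_value, adj_p,
#'   pct_a, pct_b, significant; rows sorted by adj_p then p.
#' @export
wilcoxonDEG <- function(sce, groups, groupA, groupB,
                        log2fcMin = 0.3, alpha = 0.05) {
    lc <- assay(sce, "logcounts")
    if (length(groups) == 1 && is.character(groups))
        groups <- colData(sce)[[groups]]
    stopifnot(length(groups) == ncol(lc))
    ia <- which(groups == groupA)
    ib <- which(groups == groupB)
    if (!length(ia) || !length(ib)) stop("both groups must be nonempty")
    exact <- FALSE
    if (length(ia) < 3 || length(ib) < 3) {
        warning("group with fewer than 3 cells: exact null distribution used")
        exact <- TRUE
    }
    a <- lc[, ia, drop = FALSE]
    b <- lc[, ib, drop = FALSE]
    p <- vapply(seq_len(nrow(lc)), function(i) {
        xa <- a[i, ]; xb <- b[i, ]
        if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1])
            return(1)
        suppressWarnings(stats::wilcox.test(xa, xb,
                                            exact = if (exact) TRUE else NULL,
                                            correct = TRUE)$p.value)
    }, numeric(1))
    meanA <- rowMeans(expm1(a))
    meanB <- rowMeans(expm1(b))
    log2fc <- log2((meanA + 1) / (meanB + 1))
    adj <- stats::p.adjust(p, method = "BH")
    out <- DataFrame(gene = rownames(lc), log2fc = log2fc, p_value = p,
                     adj_p = adj,
                     pct_a = rowMeans(a > 0), pct_b = rowMeans(b > 0),
                     significant = adj < alpha & abs(log2fc) > log2fcMin)
    out[order(out$adj_p, out$p_value), ]
}

#' Marker-based cluster annotation and group composition
#'
#' Assigns each cluster to the cell type whose marker set has the highest
#' mean log-normalized expression across the cluster's cells; when the
#' runner-up score is within \code{margin} (relative, default 5\%) of the
#' top score the cluster is left \code{"unassigned"}.  Types none of
#' whose markers are present in the matrix are unassignable (with a
#' warning).  Also tabulates, per promoter group, how its cells
#' distribute over the assigned types.
#'
#' @param sce \code{SingleCellExperiment} with \code{logcounts}.
#' @param clusters integer cluster labels per cell.
#' @param markerSets named list of character vectors, e.g.
#'   \code{list(RGC = c("Hes5","Pax6","Nes"), IP = c("Eomes","Hes6"),
#'   EN = c("Neurod6","Tubb3","Dcx","Snap25"))}.
#' @param groups per-cell group labels (or \code{colData} column name)
#'   for the composition table; optional.
#' @param margin relative tie margin (default 0.05).
#' @return list with \code{calls} (data.frame cluster/type + one score
#'   column per type), \code{cellTypes} (per-cell assigned type) and,
#'   when groups are given, \code{composition} (data.frame with counts
#'   and percentages of each group within each type).
#' @export
annotateAndCompose <- function(sce, clusters, markerSets, groups = NULL,
                               margin = 0.05) {
    lc <- assay(sce, "logcounts")
    stopifnot(length(clusters) == ncol(lc), length(markerSets) >= 1,
              !is.null(names(markerSets)))
    present <- lapply(markerSets, function(g) intersect(g, rownames(lc)))
    empty <- names(present)[lengths(present) == 0]
    if (length(empty))
        warning("no markers present for type(s): ",
                paste(empty, collapse = ", "), "; unassignable")
    cls <- sort(unique(clusters))
    scores <- matrix(NA_real_, length(cls), length(markerSets),
                     dimnames = list(as.character(cls), names(markerSets)))
    for (ci in seq_along(cls)) {
        cells <- clusters == cls[ci]
        for (tp in names(present))
            if (length(present[[tp]]))
                scores[ci, tp] <- mean(lc[present[[tp]], cells, drop = FALSE])
    }
    call <- apply(scores, 1, function(s) {
        s[is.na(s)] <- -Inf
        o <- order(s, decreasing = TRUE)
        top <- s[o[1]]
        second <- if (length(s) > 1) s[o[2]] else -Inf
        if (!is.finite(top) || top <= 0) return("unassigned")
        if (is.finite(second) && (top - second) < margin * abs(top))
            return("unassigned")
        names(s)[o[1]]
    })
    calls <- data.frame(cluster = cls, type = unname(call),
                        scores, check.names = FALSE)
    cellTypes <- unname(call[as.character(clusters)])
    out <- list(calls = calls, cellTypes = cellTypes)
    if (!is.null(groups)) {
        if (length(groups) == 1 && is.character(groups))
            groups <- colData(sce)[[groups]]
        tab <- table(type = cellTypes, group = groups)
        pctWithinType <- 100 * prop.table(tab, margin = 1)
        out$composition <- list(counts = tab,
                                percent_within_type = pctWithinType,
                                percent_within_group =
                                    100 * prop.table(tab, margin = 2))
    }
    out
}
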