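# Small builders shared across test files.

# Count SCE with two pure-type groups, convenient for DEG truth checks.
twoTypeSCE <- function(nGenes = 600, nPerGroup = 100, markersPerType = 20,
                       logFC = 2, seed = 1) {
    simulateCounts(nGenes = nGenes,
                   nCellsPerGroup = c(A = nPerGroup, B = nPerGroup),
                   typeProportions = rbind(A = c(RGC = 1, IP = 0, EN = 0),
                                           B = c(RGC = 0, IP = 1, EN = 0)),
                   markersPerType = markersPerType, markerLogFC = logFC,
                   seed = seed)
}

markerGenes <- function(sce, types) {
    rownames(sce)[SummarizedExperiment::rowData(sce)$marker_type %in% types]
}

# Direct hypergeometric upper-tail sum via log binomial coefficients;
# independent of stats::fisher.test and stats::*hyper.
hyperTail <- function(overlap, regulonSize, querySize, universeSize) {
    kmax <- min(regulonSize, querySize)
    ks <- overlap:kmax
    lp <- lchoose(querySize, ks) +
        lchoose(universeSize - querySize, regulonSize - ks) -
        lchoose(universeSize, regulonSize)
    sum(exp(lp))
}

# Exact two-sided Wilcoxon rank-sum p for untied samples by full
# enumeration of group assignments, using the same doubled-tail
# definition as the exact test.
enumWilcoxP <- function(a, b) {
    n <- length(a) + length(b)
    pooled <- c(a, b)
    stopifnot(!anyDuplicated(pooled))
    r <- rank(pooled)
    wObs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    combs <- utils::combn(n, length(a))
    ws <- apply(combs, 2, function(idx)
        sum(r[idx]) - length(a) * (length(a) + 1) / 2)
    pLess <- mean(ws <= wObs)
    pGreater <- mean(ws >= wObs)
    min(1, 2 * min(pLess, pGreater))
}
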