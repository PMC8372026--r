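.rankBins <- function(x, b) {
    n <- length(x)
    r <- rank(x, ties.method = "first")
    as.integer(floor((r - 1) * b / n) + 1L)
}

.miFromBins <- function(bx, by, b) {
    n <- length(bx)
    joint <- tabulate(bx + b * (by - 1L), nbins = b * b)
    p <- joint / n
    px <- tabulate(bx, nbins = b) / n
    py <- tabulate(by, nbins = b) / n
    nz <- p > 0
    sum(p[nz] * log(p[nz])) - sum(px[px > 0] * log(px[px > 0])) -
        sum(py[py > 0] * log(py[py > 0]))
}

#' Mutual information by equal-frequency rank binning
#'
#' Nonparametric mutual information (in nats) between two equal-length
#' vectors: values are ranked, ranks are cut into \code{bins}
#' equal-frequency bins (default \eqn{\lceil\sqrt{n/5}\rceil}, so the
#' expected joint cell count is about 5), and the plug-in MI of the
#' binned joint distribution is returned.  Rank binning makes the
#' estimate invariant under monotone transforms of either input.  A
#' constant input carries no information: MI 0 is returned with
#' attribute \code{constant = TRUE}.
#'
#' @param x,y numeric vectors, \code{length >= 8}.
#' @param bins number of bins per margin; default
#'   \code{ceiling(sqrt(n/5))}.
#' @return MI in nats, with attributes \code{bins} (estimator setting)
#'   and \code{constant}.
#' @examples
#' x <- rnorm(1000)
#' mutualInformation(x, x, bins = 4)   # ~ log(4)
#' @export
mutualInformation <- function(x, y, bins = NULL) {
    stopifnot(length(x) == length(y), length(x) >= 8)
    n <- length(x)
    if (is.null(bins)) bins <- ceiling(sqrt(n / 5))
    bins <- as.integer(bins)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
        out <- 0
        attr(out, "bins") <- bins
        attr(out, "constant") <- TRUE
        return(out)
    }
    out <- .miFromBins(.rankBins(x, bins), .rankBins(y, bins), bins)
    attr(out, "bins") <- bins
    attr(out, "constant") <- FALSE
    out
}

#' Infer mutual-information regulons with permutation and bootstrap
#' filtering
#'
#' For each transcription factor, computes the binned MI between the TF
#' and every other gene, builds a per-TF null MI distribution by
#' permuting the cell labels of the TF (\code{nPerm} permutations, each
#' scored against one of the candidate targets in rotation; under
#' equal-frequency binning the null depends only on the sample size and
#' bin count, so the pooled null is shared across a TF's targets), and
#' keeps edges whose smoothed empirical p value
#' \code{(1 + #\{null >= obs\})/(1 + nPerm)} passes Benjamini-Hochberg at
#' \code{alpha} across that TF's targets.  When \code{nBoot > 0}, cells
#' are then resampled with replacement and an edge is retained only if
#' its recomputed MI clears the TF's permutation critical value in at
#' least \code{supportMin} of the resamples.  The surviving target set
#' of each TF is its regulon; a TF never belongs to its own regulon.
#'
#' @param exprs genes x cells numeric matrix with row names.
#' @param tfs character vector of TF row names.
#' @param nPerm permutations for the null (default 1000; fewer than 100
#'   warns).
#' @param alpha significance level for the BH-adjusted permutation p.
#' @param nBoot bootstrap resamples (0 disables the bootstrap filter).
#' @param supportMin minimum fraction of resamples re-detecting an edge
#'   (default 0.95).
#' @param bins bins per margin for the MI estimator; default
#'   \code{ceiling(sqrt(n/5))}.
#' @param seed integer seed.
#' @return a \code{\linkS4class{RegulonSet}}.
#' @export
inferRegulons <- function(exprs, tfs, nPerm = 1000L, alpha = 0.05,
                          nBoot = 0L, supportMin = 0.95, bins = NULL,
                          seed = 1L) {
    stopifnot(is.matrix(exprs), !is.null(rownames(exprs)),
              all(tfs %in% rownames(exprs)), ncol(exprs) >= 8)
    if (nPerm < 100) warning("fewer than 100 permutations: p values coarse")
    n <- ncol(exprs)
    if (is.null(bins)) bins <- ceiling(sqrt(n / 5))
    bins <- as.integer(bins)
    set.seed(seed)
    binIdx <- t(apply(exprs, 1, .rankBins, b = bins))
    rows <- rownames(exprs)

    edgeList <- vector("list", length(tfs))
    critVals <- numeric(length(tfs))
    names(critVals) <- tfs
    for (ti in seq_along(tfs)) {
        tf <- tfs[ti]
        targets <- setdiff(rows, tf)
        bx <- binIdx[tf, ]
        obs <- vapply(targets, function(tg)
            .miFromBins(bx, binIdx[tg, ], bins), numeric(1))
        null <- numeric(nPerm)
        for (p in seq_len(nPerm)) {
            tg <- targets[((p - 1L) %% length(targets)) + 1L]
            null[p] <- .miFromBins(sample(bx), binIdx[tg, ], bins)
        }
        permP <- vapply(obs, function(m) (1 + sum(null >= m)) / (1 + nPerm),
                        numeric(1))
        adjP <- stats::p.adjust(permP, method = "BH")
        keep <- adjP < alpha
        critVals[ti] <- stats::quantile(null, 1 - alpha, names = FALSE)
        edgeList[[ti]] <- DataFrame(tf = rep(tf, sum(keep)),
                                    target = targets[keep],
                                    mi = unname(obs[keep]),
                                    perm_p = unname(permP[keep]),
                                    adj_perm_p = unname(adjP[keep]))
    }
    edges <- do.call(rbind, edgeList)

    if (nBoot > 0 && nrow(edges)) {
        support <- numeric(nrow(edges))
        for (b in seq_len(nBoot)) {
            idx <- sample.int(n, replace = TRUE)
            res <- exprs[, idx, drop = FALSE]
            resBins <- t(apply(res[unique(c(edges$tf, edges$target)), ,
                                   drop = FALSE], 1, .rankBins, b = bins))
            mib <- vapply(seq_len(nrow(edges)), function(e)
                .miFromBins(resBins[edges$tf[e], ],
                            resBins[edges$target[e], ], bins), numeric(1))
            support <- support + (mib >= critVals[edges$tf])
        }
        edges$support <- support / nBoot
        edges <- edges[edges$support >= supportMin, , drop = FALSE]
    }

    regs <- split(edges$target, factor(edges$tf, levels = tfs))
    regs <- lapply(regs, as.character)
    new("RegulonSet", edges = edges, regulons = regs,
        params = list(estimator = "equal-frequency rank binning",
                      bins = bins, nPerm = nPerm, alpha = alpha,
                      nBoot = nBoot, supportMin = supportMin, seed = seed))
}

#' Data-processing-inequality pruning of an edge set
#'
#' For every triangle formed by two TFs and a shared target (where the
#' TF-TF edge is itself in the edge set), removes the weakest of the
#' three edges when its MI falls below \code{min(other two) * (1 -
#' epsilon)}; with \code{epsilon = 1} nothing is removed.  Indirect
#' TF-target edges mediated by a second TF are pruned this way.  Off by
#' default in the inference pipeline; apply explicitly when wanted.
#'
#' @param x a \code{\linkS4class{RegulonSet}}.
#' @param epsilon tolerance in [0, 1].
#' @return a \code{RegulonSet} with the pruned edge table and rebuilt
#'   regulons.
#' @export
dpiFilter <- function(x, epsilon = 0) {
    stopifnot(is(x, "RegulonSet"), epsilon >= 0, epsilon <= 1)
    edges <- x@edges
    if (!nrow(edges)) return(x)
    key <- paste(edges$tf, edges$target)
    mi <- stats::setNames(edges$mi, key)
    lookup <- function(a, b) {
        v <- mi[paste(a, b)]
        if (is.na(v)) v <- mi[paste(b, a)]
        v
    }
    tfsHere <- unique(edges$tf)
    drop <- logical(nrow(edges))
    for (i in seq_along(tfsHere)) for (j in seq_along(tfsHere)) {
        if (i == j) next
        tf1 <- tfsHere[i]; tf2 <- tfsHere[j]
        miTT <- lookup(tf1, tf2)
        if (is.na(miTT)) next
        shared <- intersect(edges$target[edges$tf == tf1],
                            edges$target[edges$tf == tf2])
        shared <- setdiff(shared, c(tf1, tf2))
        for (tg in shared) {
            trip <- c(lookup(tf1, tg), lookup(tf2, tg), miTT)
            w <- which.min(trip)
            if (trip[w] < min(trip[-w]) * (1 - epsilon)) {
                victim <- switch(w,
                                 paste(tf1, tg), paste(tf2, tg),
                                 paste(tf1, tf2))
                drop[key == victim] <- TRUE
                if (w == 3) drop[key == paste(tf2, tf1)] <- TRUE
            }
        }
    }
    edges <- edges[!drop, , drop = FALSE]
    regs <- split(edges$target, factor(edges$tf, levels = names(x@regulons)))
    regs <- lapply(regs, as.character)
    new("RegulonSet", edges = edges, regulons = regs,
        params = c(x@params, list(dpiEpsilon = epsilon)))
}

#' Master-regulator analysis by Fisher's exact enrichment
#'
#' Tests each regulon for over-representation of a query gene list (e.g.
#' differentially expressed genes) within a gene universe using the
#' one-sided Fisher's exact test on the 2x2 membership table, adjusts
#' across regulons with Benjamini-Hochberg, and flags TFs with adjusted
#' p below \code{alpha} (default 0.01) as master regulators.
#'
#' @param regulons a \code{\linkS4class{RegulonSet}} or named list of
#'   character vectors.
#' @param queryGenes character vector, subset of \code{universe}.
#' @param universe character vector of all genes considered.
#' @param alpha master-regulator threshold on the adjusted p.
#' @return an \code{\linkS4class{MRAResult}}.
#' @export
masterRegulatorAnalysis <- function(regulons, queryGenes, universe,
                                    alpha = 0.01) {
    if (is(regulons, "RegulonSet")) regulons <- regulons@regulons
    stopifnot(is.list(regulons), !is.null(names(regulons)))
    if (!length(queryGenes)) stop("empty query gene list")
    if (!all(queryGenes %in% universe))
        stop("query genes must be a subset of the universe")
    universe <- unique(universe)
    query <- unique(queryGenes)
    nU <- length(universe)
    nQ <- length(query)
    res <- lapply(names(regulons), function(tf) {
        reg <- intersect(regulons[[tf]], universe)
        k <- length(intersect(reg, query))
        tab <- matrix(c(k, length(reg) - k,
                        nQ - k, nU - length(reg) - nQ + k), 2, 2)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        data.frame(tf = tf, regulon_size = length(reg), overlap = k,
                   query_size = nQ, universe_size = nU, fisher_p = p)
    })
    tb <- do.call(rbind, res)
    tb$adj_p <- stats::p.adjust(tb$fisher_p, method = "BH")
    tb$is_master <- tb$adj_p < alpha
    tb <- tb[order(tb$adj_p, tb$fisher_p), ]
    rownames(tb) <- NULL
    new("MRAResult", table = DataFrame(tb),
        params = list(alpha = alpha, n_query = nQ, n_universe = nU))
}
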