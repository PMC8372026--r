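#' Simulate expression data with planted TF-target dependencies
#'
#' Generates per-cell expression for a set of transcription factors and
#' their planted target genes, plus independent background genes, for
#' benchmarking mutual-information regulon inference.  Each TF is drawn
#' independently (standard normal across cells); each of its targets is
#' \code{dependenceStrength * f(TF) + sqrt(1 - dependenceStrength^2) *
#' noise}, with \code{f} a monotone nonlinearity (scaled \code{tanh}), so
#' planted edges carry positive mutual information and non-edges are
#' independent.  Planted regulons are disjoint by construction.
#'
#' @param nTfs number of transcription factors.
#' @param targetsPerTf planted targets per TF.
#' @param nBackground additional genes independent of every TF.
#' @param nCells number of cells.
#' @param dependenceStrength in [0, 1]; 0 = independence, 1 = noise-free
#'   monotone dependence (up to \code{noiseSd}).
#' @param noiseSd additional observation noise added to every gene.
#' @param seed integer seed.
#' @return list with \code{exprs} (genes x cells numeric matrix),
#'   \code{tfs} (character vector of TF names) and \code{regulons}
#'   (named list: true target sets per TF).
#' @export
simulateRegnet <- function(nTfs = 5, targetsPerTf = 8, nBackground = 20,
                           nCells = 500, dependenceStrength = 0.8,
                           noiseSd = 0.1, seed = 1L) {
    stopifnot(nTfs >= 1, targetsPerTf >= 1, nCells >= 8,
              dependenceStrength >= 0, dependenceStrength <= 1,
              noiseSd >= 0)
    set.seed(seed)
    tfs <- sprintf("TF_%02d", seq_len(nTfs))
    exprs <- matrix(0, nTfs * (1 + targetsPerTf) + nBackground, nCells)
    genes <- character(nrow(exprs))
    regulons <- vector("list", nTfs)
    names(regulons) <- tfs
    row <- 1L
    for (i in seq_len(nTfs)) {
        tfx <- stats::rnorm(nCells)
        genes[row] <- tfs[i]
        exprs[row, ] <- tfx
        row <- row + 1L
        tg <- sprintf("%s_target_%02d", tfs[i], seq_len(targetsPerTf))
        regulons[[i]] <- tg
        for (j in seq_len(targetsPerTf)) {
            indep <- stats::rnorm(nCells)
            y <- dependenceStrength * tanh(tfx) * 1.6 +
                sqrt(max(0, 1 - dependenceStrength^2)) * indep
            genes[row] <- tg[j]
            exprs[row, ] <- y
            row <- row + 1L
        }
    }
    if (nBackground > 0) {
        bg <- sprintf("bg_%03d", seq_len(nBackground))
        genes[row:(row + nBackground - 1)] <- bg
        exprs[row:(row + nBackground - 1), ] <-
            stats::rnorm(nBackground * nCells)
    }
    if (noiseSd > 0)
        exprs <- exprs + stats::rnorm(length(exprs), sd = noiseSd)
    rownames(exprs) <- genes
    colnames(exprs) <- sprintf("cell_%04d", seq_len(nCells))
    list(exprs = exprs, tfs = tfs, regulons = regulons)
}
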