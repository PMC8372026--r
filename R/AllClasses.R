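#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

.PHASES <- c("G1", "S", "G2", "M", "G0")
.POP_COLUMNS <- c("cell_id", "gfp", "cycling", "phase_at_sacrifice",
                  "brdu", "edu", "ki67", "mcm2", "pvim", "depth", "zone")

#' PopulationTable: per-cell records from a pulse-labeling experiment
#'
#' Holds one row per cell with electroporation label (\code{gfp}), cycling
#' status, cell-cycle phase at sacrifice, thymidine-analog flags
#' (\code{brdu}, \code{edu}), proliferation-marker flags (\code{ki67},
#' \code{mcm2}), the mitotic marker \code{pvim}, a normalized tissue depth
#' (0 = apical/ventricular surface, 1 = basal/pial surface) and a zone
#' label.  Instances are produced by \code{\link{simulatePopulation}} or
#' read from CSV with \code{\link{readPopulationTable}}.
#'
#' @slot cells a \code{DataFrame} with the per-cell columns listed above.
#' @slot params list of simulation/import parameters (may be empty).
#' @slot issues character vector of structural warnings attached at
#'   creation time (e.g. a label window so long that the single-labeled
#'   class is structurally empty).
#'
#' @exportClass PopulationTable
setClass("PopulationTable",
         slots = c(cells = "DataFrame", params = "list", issues = "character"))

setValidity("PopulationTable", function(object) {
    df <- object@cells
    missing <- setdiff(.POP_COLUMNS, colnames(df))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (anyDuplicated(df$cell_id))
        return("duplicated cell_id")
    if (!all(df$phase_at_sacrifice %in% .PHASES))
        return("phase_at_sacrifice outside {G1,S,G2,M,G0}")
    for (fl in c("gfp", "cycling", "brdu", "edu", "ki67", "mcm2", "pvim"))
        if (!is.logical(df[[fl]]))
            return(paste("column", fl, "must be logical"))
    if (any(df$pvim & df$phase_at_sacrifice != "M"))
        return("pvim implies phase M")
    if (any(!df$cycling & df$phase_at_sacrifice != "G0"))
        return("non-cycling cells must be in G0")
    if (any(df$depth < 0 | df$depth > 1))
        return("depth outside [0,1]")
    TRUE
})

#' CountSummary: aggregated cell counts for kinetics estimation
#'
#' Category counts among labeled (GFP+) ventricular-zone cells, the inputs
#' of the dual-pulse S-phase/cell-cycle estimators.
#'
#' @slot n_gfp total labeled cells.
#' @slot n_brdu_edu double-labeled (BrdU+EdU+) cells.
#' @slot n_brdu_only single-labeled (BrdU+EdU-) cells.
#' @slot n_edu EdU+ cells.
#' @slot n_marker proliferation-marker-positive labeled cells.
#' @slot marker which marker \code{n_marker} counts ("mcm2" or "ki67").
#' @slot n_ki67_brdu,n_ki67neg_brdu Ki67+BrdU+ / Ki67-BrdU+ counts for
#'   cell-cycle-exit analysis.
#'
#' @exportClass CountSummary
setClass("CountSummary",
         slots = c(n_gfp = "integer", n_brdu_edu = "integer",
                   n_brdu_only = "integer", n_edu = "integer",
                   n_marker = "integer", marker = "character",
                   n_ki67_brdu = "integer", n_ki67neg_brdu = "integer"))

setValidity("CountSummary", function(object) {
    cnts <- c(object@n_gfp, object@n_brdu_edu, object@n_brdu_only,
              object@n_edu, object@n_marker, object@n_ki67_brdu,
              object@n_ki67neg_brdu)
    if (any(cnts < 0)) return("all counts must be >= 0")
    if (object@n_brdu_edu + object@n_brdu_only > object@n_gfp)
        return("BrdU+ classes exceed n_gfp")
    if (object@n_marker > object@n_gfp)
        return("n_marker exceeds n_gfp")
    TRUE
})

#' KineticsEstimate: S-phase/cell-cycle duration and growth fraction
#'
#' Result container for the dual-pulse estimators, optionally with
#' cell-level bootstrap percentile confidence intervals.
#'
#' @slot ts,tc hours; \code{tc >= ts} at the point estimate.
#' @slot growthFraction fraction of labeled cells scored cycling.
#' @slot marker proliferation marker used for the growth fraction.
#' @slot ci numeric matrix (rows ts/tc/growthFraction, cols lower/upper);
#'   all-NA when \code{nBoot = 0}.
#' @slot nBoot,seed bootstrap settings.
#' @slot nDropped resamples discarded because an estimator was undefined.
#' @slot counts the \code{CountSummary} the point estimates used.
#'
#' @exportClass KineticsEstimate
setClass("KineticsEstimate",
         slots = c(ts = "numeric", tc = "numeric",
                   growthFraction = "numeric", marker = "character",
                   ci = "matrix", nBoot = "integer", seed = "integer",
                   nDropped = "integer", counts = "CountSummary"))

setValidity("KineticsEstimate", function(object) {
    if (object@ts <= 0) return("ts must be > 0")
    if (object@tc < object@ts) return("tc must be >= ts")
    if (object@growthFraction <= 0 || object@growthFraction > 1)
        return("growthFraction must be in (0,1]")
    TRUE
})

#' BinHistogram: laminar bin distribution of cell depths
#'
#' Counts and percentages of cells across equal-width bins of the
#' normalized depth axis, enumerated 1..n from basal to apical as in
#' cortical-plate quantifications.
#'
#' @slot counts integer counts, bin 1 = most basal.
#' @slot percent percentages summing to 100.
#' @slot nBins number of bins (default workflows use 10).
#'
#' @exportClass BinHistogram
setClass("BinHistogram",
         slots = c(counts = "integer", percent = "numeric",
                   nBins = "integer"))

setValidity("BinHistogram", function(object) {
    if (length(object@counts) != object@nBins ||
        length(object@percent) != object@nBins)
        return("counts/percent length must equal nBins")
    if (any(object@counts < 0)) return("negative counts")
    if (abs(sum(object@percent) - 100) > 1e-9)
        return("percentages must sum to 100")
    TRUE
})

#' RegulonSet: mutual-information regulons for a set of transcription factors
#'
#' Edge table and per-TF target sets surviving the permutation (and
#' optionally bootstrap / data-processing-inequality) filters.
#'
#' @slot edges \code{DataFrame} with columns tf, target, mi, perm_p,
#'   adj_perm_p and (when bootstrapped) support.
#' @slot regulons named list mapping each TF to its character vector of
#'   target genes; a TF never contains itself.
#' @slot params estimator and filter settings (bin rule, permutations,
#'   bootstrap support threshold, seed).
#'
#' @exportClass RegulonSet
setClass("RegulonSet",
         slots = c(edges = "DataFrame", regulons = "list", params = "list"))

setValidity("RegulonSet", function(object) {
    need <- c("tf", "target", "mi", "perm_p")
    missing <- setdiff(need, colnames(object@edges))
    if (length(missing))
        return(paste("edge table missing:", paste(missing, collapse = ", ")))
    if (nrow(object@edges) && any(object@edges$mi < 0))
        return("mutual information must be >= 0")
    self <- mapply(function(tf, tg) tf %in% tg,
                   names(object@regulons), object@regulons)
    if (length(self) && any(self))
        return("a TF may not be a member of its own regulon")
    TRUE
})

#' MRAResult: master-regulator enrichment of a query gene list
#'
#' One row per regulon with the one-sided Fisher's exact enrichment p
#' value, its Benjamini-Hochberg adjustment across regulons, and the
#' master-regulator flag at adjusted p < 0.01.
#'
#' @slot table \code{DataFrame} with columns tf, regulon_size, overlap,
#'   query_size, universe_size, fisher_p, adj_p, is_master.
#' @slot params list (query/universe sizes, alpha).
#'
#' @exportClass MRAResult
setClass("MRAResult", slots = c(table = "DataFrame", params = "list"))

setValidity("MRAResult", function(object) {
    tb <- object@table
    need <- c("tf", "regulon_size", "overlap", "fisher_p", "adj_p",
              "is_master")
    missing <- setdiff(need, colnames(tb))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (nrow(tb) && any(tb$overlap > tb$regulon_size))
        return("overlap exceeds regulon size")
    if (nrow(tb) && any(tb$adj_p + 1e-12 < tb$fisher_p))
        return("adjusted p below raw p")
    TRUE
})
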