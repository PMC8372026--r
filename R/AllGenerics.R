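#' Accessors for ProgenitorKit result classes
#'
#' \code{cellData} returns the per-cell \code{DataFrame} of a
#' \code{\linkS4class{PopulationTable}}; \code{simParams} its generating
#' parameters.  \code{miEdges} and \code{regulons} expose the edge table
#' and target sets of a \code{\linkS4class{RegulonSet}};
#' \code{mraTable} the per-regulon enrichment table of an
#' \code{\linkS4class{MRAResult}}; \code{binCounts} and
#' \code{binPercent} the two views of a
#' \code{\linkS4class{BinHistogram}}.
#'
#' @param x the object.
#' @return See the description of each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname accessors
#' @export
setGeneric("miEdges", function(x) standardGeneric("miEdges"))

#' @rdname accessors
#' @export
setGeneric("regulons", function(x) standardGeneric("regulons"))

#' @rdname accessors
#' @export
setGeneric("mraTable", function(x) standardGeneric("mraTable"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setGeneric("binPercent", function(x) standardGeneric("binPercent"))

setMethod("cellData", "PopulationTable", function(x) x@cells)
setMethod("simParams", "PopulationTable", function(x) x@params)
setMethod("miEdges", "RegulonSet", function(x) x@edges)
setMethod("regulons", "RegulonSet", function(x) x@regulons)
setMethod("mraTable", "MRAResult", function(x) x@table)
setMethod("binCounts", "BinHistogram", function(x) x@counts)
setMethod("binPercent", "BinHistogram", function(x) x@percent)

#' @export
setMethod("show", "PopulationTable", function(object) {
    df <- object@cells
    cat("PopulationTable with", nrow(df), "cells\n")
    cat("  cycling:", sum(df$cycling), " quiescent:", sum(!df$cycling), "\n")
    cat("  BrdU+EdU+:", sum(df$brdu & df$edu),
        " BrdU+EdU-:", sum(df$brdu & !df$edu),
        " EdU+:", sum(df$edu), "\n")
    if (length(object@issues))
        cat("  issues:", paste(object@issues, collapse = "; "), "\n")
})

#' @export
setMethod("show", "CountSummary", function(object) {
    cat("CountSummary (marker:", object@marker, ")\n")
    cat("  GFP+:", object@n_gfp,
        " BrdU+EdU+:", object@n_brdu_edu,
        " BrdU+EdU-:", object@n_brdu_only,
        " EdU+:", object@n_edu, "\n")
    cat("  marker+:", object@n_marker,
        " Ki67+BrdU+:", object@n_ki67_brdu,
        " Ki67-BrdU+:", object@n_ki67neg_brdu, "\n")
})

#' @export
setMethod("show", "KineticsEstimate", function(object) {
    cat("KineticsEstimate (marker:", object@marker, ")\n")
    cat(sprintf("  Ts: %.2f h   Tc: %.2f h   GF: %.3f\n",
                object@ts, object@tc, object@growthFraction))
    if (object@nBoot > 0) {
        ci <- object@ci
        cat(sprintf("  95%% bootstrap CIs (n_boot = %d):\n", object@nBoot))
        cat(sprintf("    Ts [%.2f, %.2f]  Tc [%.2f, %.2f]  GF [%.3f, %.3f]\n",
                    ci["ts", 1], ci["ts", 2], ci["tc", 1], ci["tc", 2],
                    ci["growthFraction", 1], ci["growthFraction", 2]))
        if (object@nDropped > 0)
            cat("  dropped resamples:", object@nDropped, "\n")
    }
})

#' @export
setMethod("show", "BinHistogram", function(object) {
    cat("BinHistogram,", object@nBins,
        "bins (1 = basal ... ", object@nBins, "= apical)\n")
    print(data.frame(bin = seq_len(object@nBins), count = object@counts,
                     percent = round(object@percent, 2)), row.names = FALSE)
})

#' @export
setMethod("show", "RegulonSet", function(object) {
    cat("RegulonSet:", length(object@regulons), "regulons,",
        nrow(object@edges), "edges\n")
    sizes <- lengths(object@regulons)
    if (length(sizes))
        cat("  regulon sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                                      collapse = " "), "\n")
})

#' @export
setMethod("show", "MRAResult", function(object) {
    tb <- object@table
    cat("MRAResult:", nrow(tb), "regulons tested,",
        sum(tb$is_master), "master regulator(s) at adj p <",
        object@params$alpha, "\n")
})
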