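#' Background-corrected mean fluorescence intensity
#'
#' Per-cell MFI on a 0-255 a.u. scale, corrected by the background of the
#' cell's section and expressed as percent of the remaining dynamic range:
#' \code{((raw - background) / (255 - background)) * 100}.  Values where
#' the raw intensity falls below background come out negative; they are
#' preserved (clipping would bias group means) and flagged via the
#' \code{"negative"} attribute.
#'
#' @param raw raw intensity, in [0, 255].
#' @param background per-section background, in [0, 255); recycled.
#' @return numeric vector of corrected intensities (percent of dynamic
#'   range), with attribute \code{negative} marking cells below
#'   background.
#' @examples
#' correctedMFI(128, 1)   # 50
#' @export
correctedMFI <- function(raw, background) {
    stopifnot(all(raw >= 0), all(raw <= 255), all(background >= 0))
    if (any(background >= 255))
        stop("invalid record: background must be < 255")
    out <- (raw - background) / (255 - background) * 100
    attr(out, "negative") <- out < 0
    out
}

#' Group summaries of corrected MFI with the animal as averaging unit
#'
#' Computes per-animal mean corrected MFI, then group mean and SEM over
#' the animal means (the animal, not the cell, is the experimental unit).
#' Also returns the all-cell frequency distribution of corrected
#' intensities per group for distribution plots.
#'
#' @param records data.frame with columns \code{group}, \code{animal_id},
#'   \code{raw_intensity}, \code{background} (and optionally
#'   \code{cell_id}).
#' @param breaks intensity breaks for the per-cell frequency histogram
#'   (passed to \code{hist}); default 10 equal bins over the observed
#'   range.
#' @return list with \code{animal_means} (data.frame group/animal/mean/n),
#'   \code{group_summary} (data.frame group/mean/sem/n_animals; SEM is
#'   \code{NA} for single-animal groups) and \code{cell_distribution}
#'   (data.frame group/mid/percent).
#' @export
mfiGroupSummary <- function(records, breaks = 10) {
    need <- c("group", "animal_id", "raw_intensity", "background")
    stopifnot(all(need %in% names(records)))
    if (nrow(records) == 0L) stop("no cells supplied")
    records$mfi <- as.numeric(correctedMFI(records$raw_intensity,
                                           records$background))
    byAnimal <- aggregate(mfi ~ group + animal_id, data = records, mean)
    nCells <- aggregate(mfi ~ group + animal_id, data = records, length)
    byAnimal$n_cells <- nCells$mfi
    grp <- split(byAnimal, byAnimal$group)
    groupSummary <- do.call(rbind, lapply(grp, function(g) {
        data.frame(group = g$group[1], mean = mean(g$mfi),
                   sem = if (nrow(g) > 1)
                       stats::sd(g$mfi) / sqrt(nrow(g)) else NA_real_,
                   n_animals = nrow(g))
    }))
    rownames(groupSummary) <- NULL
    brk <- if (length(breaks) == 1)
        seq(min(records$mfi), max(records$mfi), length.out = breaks + 1)
    else breaks
    dist <- do.call(rbind, lapply(split(records, records$group), function(g) {
        h <- graphics::hist(g$mfi, breaks = brk, plot = FALSE,
                            include.lowest = TRUE)
        data.frame(group = g$group[1], mid = h$mids,
                   percent = 100 * h$counts / sum(h$counts))
    }))
    rownames(dist) <- NULL
    list(animal_means = byAnimal, group_summary = groupSummary,
         cell_distribution = dist)
}

#' Laminar bin distribution of cell depths
#'
#' Divides the depth axis (0 = apical/ventricular, 1 = basal/pial) into
#' \code{nBins} equal-width bins enumerated 1..n from basal to apical, as
#' in cortical-plate quantifications, and returns counts and percentages
#' per bin.  A depth exactly on an interior boundary is assigned to the
#' higher-index (more apical) bin; depth 1 falls in bin 1, depth 0 in
#' bin \code{nBins}.
#'
#' @param depths numeric vector of normalized depths in [0, 1].
#' @param nBins number of bins (default 10).
#' @return a \code{\linkS4class{BinHistogram}}.
#' @export
binDistribution <- function(depths, nBins = 10L) {
    if (length(depths) == 0L) stop("no depths supplied")
    if (any(depths < 0 | depths > 1)) stop("depth outside [0,1]")
    stopifnot(nBins >= 1)
    # index counted from the apical side; boundary depths round apical-ward
    apicalIdx <- ceiling(depths * nBins)
    apicalIdx[apicalIdx == 0L] <- 1L
    bin <- nBins - apicalIdx + 1L
    counts <- tabulate(bin, nbins = nBins)
    new("BinHistogram", counts = as.integer(counts),
        percent = 100 * counts / sum(counts), nBins = as.integer(nBins))
}

#' Merge adjacent bins of a BinHistogram
#'
#' Collapses groups of adjacent bins (e.g. 10 bins into upper/lower
#' halves); counts are conserved exactly.
#'
#' @param x a \code{\linkS4class{BinHistogram}}.
#' @param groups integer vector of length \code{nBins} assigning each bin
#'   to a merged bin (must be non-decreasing).
#' @return a \code{BinHistogram} over the merged bins.
#' @export
mergeBins <- function(x, groups) {
    stopifnot(is(x, "BinHistogram"), length(groups) == x@nBins,
              !is.unsorted(groups))
    counts <- as.integer(tapply(x@counts, groups, sum))
    new("BinHistogram", counts = counts,
        percent = 100 * counts / sum(counts),
        nBins = length(counts))
}

#' Per-zone percentages of cells along the depth axis
#'
#' Assigns each depth to a named zone given ordered interior boundary
#' fractions (apical to basal; e.g. \code{c(VZ = 0.35, SVZ = 0.5,
#' IZ = 0.75, CP = 1)} for the four-compartment scheme, or a single
#' boundary for VZ vs rest).  Zones are half-open on the apical side,
#' \code{[a, b)}, with the last zone closed at 1.  Optionally splits the
#' first zone at its midpoint into inner and outer halves (IVZ/OVZ).
#'
#' @param depths numeric vector of depths in [0, 1].
#' @param boundaries named numeric vector of strictly increasing upper
#'   boundaries per zone; the last must be 1.
#' @param splitFirst logical; also report the equal inner/outer split of
#'   the first zone.
#' @return named numeric vector of percentages summing to 100; when
#'   \code{splitFirst} the attribute \code{"split"} carries the
#'   inner/outer percentages of the first zone (of all cells).
#' @export
zoneFractions <- function(depths,
                          boundaries = c(VZ = 0.35, SVZ = 0.5,
                                         IZ = 0.75, CP = 1),
                          splitFirst = FALSE) {
    if (length(depths) == 0L) stop("no depths supplied")
    if (any(depths < 0 | depths > 1)) stop("depth outside [0,1]")
    if (is.null(names(boundaries)) ||
        is.unsorted(boundaries, strictly = TRUE) ||
        abs(boundaries[length(boundaries)] - 1) > 1e-12)
        stop("boundaries must be named, strictly increasing, ending at 1")
    idx <- findInterval(depths, c(0, boundaries[-length(boundaries)]),
                        rightmost.closed = FALSE)
    counts <- tabulate(idx, nbins = length(boundaries))
    out <- 100 * counts / sum(counts)
    names(out) <- names(boundaries)
    if (splitFirst) {
        b1 <- boundaries[1]
        inFirst <- depths < b1
        inner <- sum(depths < b1 / 2)
        outer <- sum(inFirst) - inner
        attr(out, "split") <- 100 * c(inner = inner, outer = outer) /
            length(depths)
    }
    out
}

#' Marker colocalization percentage
#'
#' Percentage of cells positive for flag \code{a} that are also positive
#' for flag \code{b} (e.g. electroporated cells expressing a layer
#' marker): \code{100 * |a & b| / |a|}.
#'
#' @param a,b equal-length logical vectors.
#' @return percentage in [0, 100].
#' @export
colocalizationFraction <- function(a, b) {
    stopifnot(is.logical(a), is.logical(b), length(a) == length(b))
    if (sum(a) == 0L) stop("no positive cells in reference flag")
    100 * sum(a & b) / sum(a)
}
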