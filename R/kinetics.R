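#' Build a CountSummary from explicit counts or a PopulationTable
#'
#' The dual-pulse estimators operate on aggregated category counts among
#' labeled ventricular-zone cells.  \code{countSummary} either wraps
#' explicit counts or derives them from a per-cell table; for tables the
#' default filter restricts to \code{zone == "VZ"} and \code{gfp == TRUE}
#' before counting, matching how such quantifications are scored on tissue
#' sections.
#'
#' @param x a \code{\linkS4class{PopulationTable}}, or missing when
#'   explicit counts are given.
#' @param marker proliferation marker defining the cycling count,
#'   \code{"mcm2"} or \code{"ki67"}.
#' @param restrict logical; apply the VZ/GFP filter (tables only).
#' @param n_gfp,n_brdu_edu,n_brdu_only,n_edu,n_marker,n_ki67_brdu,n_ki67neg_brdu
#'   explicit counts (used when \code{x} is missing).
#' @return a \code{\linkS4class{CountSummary}}.
#' @export
countSummary <- function(x, marker = c("mcm2", "ki67"), restrict = TRUE,
                         n_gfp = 0L, n_brdu_edu = 0L, n_brdu_only = 0L,
                         n_edu = 0L, n_marker = 0L, n_ki67_brdu = 0L,
                         n_ki67neg_brdu = 0L) {
    marker <- match.arg(marker)
    if (missing(x)) {
        return(new("CountSummary",
                   n_gfp = as.integer(n_gfp),
                   n_brdu_edu = as.integer(n_brdu_edu),
                   n_brdu_only = as.integer(n_brdu_only),
                   n_edu = as.integer(n_edu),
                   n_marker = as.integer(n_marker), marker = marker,
                   n_ki67_brdu = as.integer(n_ki67_brdu),
                   n_ki67neg_brdu = as.integer(n_ki67neg_brdu)))
    }
    stopifnot(is(x, "PopulationTable"))
    df <- x@cells
    if (restrict) df <- df[df$zone == "VZ" & df$gfp, , drop = FALSE]
    .tallyCells(df, marker)
}

# tally a per-cell DataFrame into a CountSummary (no table validity:
# also used on bootstrap resamples, where cell_id values repeat)
.tallyCells <- function(df, marker) {
    mk <- if (marker == "mcm2") df$mcm2 else df$ki67
    new("CountSummary",
        n_gfp = nrow(df),
        n_brdu_edu = sum(df$brdu & df$edu),
        n_brdu_only = sum(df$brdu & !df$edu),
        n_edu = sum(df$edu),
        n_marker = sum(mk), marker = marker,
        n_ki67_brdu = sum(df$ki67 & df$brdu),
        n_ki67neg_brdu = sum(!df$ki67 & df$brdu))
}

#' Growth fraction from marker counts
#'
#' The growth fraction (GF) is the proportion of labeled cells that are
#' actively cycling, estimated as marker-positive over all labeled cells:
#' GF = GFP+marker+ / GFP+.  Which marker was counted (Mcm2 or Ki67) is
#' carried in the \code{CountSummary}; the two can differ because Ki67 is
#' largely absent in early G1 and quiescent cells while Mcm2 also marks
#' replication-competent quiescent cells.
#'
#' @param counts a \code{\linkS4class{CountSummary}}.
#' @return fraction in [0, 1].
#' @export
growthFraction <- function(counts) {
    stopifnot(is(counts, "CountSummary"))
    if (counts@n_gfp == 0L)
        stop("growth fraction undefined: no labeled cells (n_gfp = 0)")
    counts@n_marker / counts@n_gfp
}

#' S-phase duration from dual-pulse class counts
#'
#' Ts is the ratio of cells that remain in S phase across both injections
#' (BrdU+EdU+) to cells that left S before the second injection
#' (BrdU+EdU-), multiplied by the inter-injection interval.
#'
#' @param counts a \code{\linkS4class{CountSummary}}.
#' @param interval hours between the two injections (default 1).
#' @return estimated S-phase duration in hours.
#' @export
estimateTs <- function(counts, interval = 1) {
    stopifnot(is(counts, "CountSummary"), interval > 0)
    if (counts@n_brdu_only == 0L)
        stop("Ts undefined: no single-labeled (BrdU+EdU-) cells; ",
             "interval too long relative to Ts or sample too small")
    (counts@n_brdu_edu / counts@n_brdu_only) * interval
}

#' Total cell-cycle duration from Ts, the S-phase fraction and the
#' growth fraction
#'
#' Tc = Ts / (EdU+ / (GFP+ x GF)): Ts divided by the fraction of labeled
#' cells in S phase at the second injection, corrected by the proportion
#' of labeled cells that are actually cycling.
#'
#' @param ts S-phase duration in hours.
#' @param counts a \code{\linkS4class{CountSummary}}.
#' @param gf growth fraction in (0, 1]; defaults to
#'   \code{growthFraction(counts)}.
#' @return estimated cell-cycle duration in hours.
#' @export
estimateTc <- function(ts, counts, gf = growthFraction(counts)) {
    stopifnot(is(counts, "CountSummary"), ts > 0, gf > 0, gf <= 1)
    if (counts@n_edu == 0L)
        stop("Tc undefined: no EdU+ cells")
    ts / (counts@n_edu / (counts@n_gfp * gf))
}

#' Cycling-retained and cycle-exit fractions after a labeling chase
#'
#' Among labeled cells, the fraction still cycling (Ki67+BrdU+) and the
#' fraction that incorporated the analog but has left the cycle
#' (Ki67-BrdU+), the readout used to detect increased cell-cycle exit.
#'
#' @param counts a \code{\linkS4class{CountSummary}}.
#' @return named numeric vector \code{c(cycling_retained, exited)}.
#' @export
exitFractions <- function(counts) {
    stopifnot(is(counts, "CountSummary"))
    if (counts@n_gfp == 0L)
        stop("exit fractions undefined: n_gfp = 0")
    c(cycling_retained = counts@n_ki67_brdu / counts@n_gfp,
      exited = counts@n_ki67neg_brdu / counts@n_gfp)
}

.kineticsPoint <- function(df, marker, interval) {
    cs <- .tallyCells(df, marker)
    gf <- growthFraction(cs)
    ts <- estimateTs(cs, interval)
    tc <- estimateTc(ts, cs, gf)
    c(ts = ts, tc = tc, growthFraction = gf)
}

#' Dual-pulse kinetics with cell-level bootstrap confidence intervals
#'
#' Computes the plug-in Ts/Tc/growth-fraction estimates on the full table
#' (after the VZ/GFP restriction) and, when \code{nBoot > 0}, percentile
#' confidence intervals from resampling cells with replacement.  Resamples
#' on which an estimator is undefined (an empty count class) are dropped
#' and counted; more than 20\% drops triggers a warning.  Uncertainty here
#' is cell-level: with per-animal identifiers unavailable, animal-level
#' SEM (the usual reporting unit of such experiments) cannot be formed.
#'
#' @param table a \code{\linkS4class{PopulationTable}}.
#' @param interval hours between injections.
#' @param marker growth-fraction marker, \code{"mcm2"} or \code{"ki67"}.
#' @param nBoot number of bootstrap resamples (0 = point estimates only).
#' @param level CI level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return a \code{\linkS4class{KineticsEstimate}}.
#' @export
bootstrapKinetics <- function(table, interval = 1,
                              marker = c("mcm2", "ki67"),
                              nBoot = 0L, level = 0.95, seed = 1L) {
    stopifnot(is(table, "PopulationTable"), nBoot >= 0)
    marker <- match.arg(marker)
    df <- table@cells
    df <- df[df$zone == "VZ" & df$gfp, , drop = FALSE]
    if (nrow(df) == 0L) stop("no labeled VZ cells in table")
    pt <- .kineticsPoint(df, marker, interval)
    ci <- matrix(NA_real_, 3, 2,
                 dimnames = list(c("ts", "tc", "growthFraction"),
                                 c("lower", "upper")))
    dropped <- 0L
    if (nBoot > 0) {
        set.seed(seed)
        reps <- matrix(NA_real_, nBoot, 3)
        for (b in seq_len(nBoot)) {
            idx <- sample.int(nrow(df), replace = TRUE)
            est <- tryCatch(.kineticsPoint(df[idx, , drop = FALSE],
                                           marker, interval),
                            error = function(e) NULL)
            if (is.null(est)) dropped <- dropped + 1L else reps[b, ] <- est
        }
        if (dropped > 0.2 * nBoot)
            warning(sprintf("%d of %d bootstrap resamples undefined",
                            dropped, nBoot))
        alpha <- (1 - level) / 2
        ok <- stats::complete.cases(reps)
        if (any(ok))
            for (i in 1:3)
                ci[i, ] <- stats::quantile(reps[ok, i],
                                           c(alpha, 1 - alpha),
                                           names = FALSE)
    }
    new("KineticsEstimate", ts = unname(pt["ts"]), tc = unname(pt["tc"]),
        growthFraction = unname(pt["growthFraction"]), marker = marker,
        ci = ci, nBoot = as.integer(nBoot), seed = as.integer(seed),
        nDropped = dropped,
        counts = .tallyCells(df, marker))
}
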