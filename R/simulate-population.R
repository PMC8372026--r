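#' Simulate an asynchronously cycling progenitor population under
#' dual thymidine-analog pulse labeling
#'
#' Generates a steady-state population of ventricular-zone cells, applies
#' two analog injections (BrdU then EdU by default) at the given times
#' before sacrifice, advances every cell deterministically to sacrifice and
#' scores the marker panel used in the corresponding tissue
#' quantifications: analog incorporation, Ki67, Mcm2 and phospho-vimentin.
#'
#' Cycling cells receive a cycle position uniform on \code{[0, Tc)} at the
#' moment of the first injection (steady-state asynchrony, the assumption
#' under which the dual-pulse estimators are derived).  Phase order is
#' G1, S, G2, M.  Analog \code{j} labels a cell if the cell is in S phase
#' at any instant of \code{[injection_j, injection_j + labelWindows[j]]}
#' (truncated at sacrifice).  By default the first analog remains
#' available until the next injection and later analogs label
#' instantaneously (\code{labelWindows = c(diff of injection times, 0)}),
#' the availability pattern assumed by the classical dual-label
#' estimators: under it the double-labeled fraction is \code{t_s/Tc}, the
#' single-labeled fraction \code{interval/Tc}, and the S-phase and
#' cell-cycle estimators are asymptotically unbiased.  Set
#' \code{labelWindows = 0} for strictly instantaneous pulses (then the
#' double-labeled fraction is \code{(t_s - interval)/Tc} and the S-phase
#' estimator converges to \code{t_s - interval}); any non-negative windows
#' may be supplied to study labeling-availability bias.
#'
#' Ki67 is scored negative in quiescent (G0) cells and in G1 cells within
#' \code{earlyG1Ki67Window} hours of the last mitosis; Mcm2 is scored
#' positive in every cycling cell and in a fraction
#' \code{quiescentMcm2Fraction} of quiescent cells; phospho-vimentin marks
#' M-phase cells only.  Cells crossing mitosis before sacrifice exit the
#' cycle with probability \code{exitProbability} per division and are
#' thereafter quiescent (phase G0, Ki67 negative, labels retained).
#'
#' @param nCells number of cells.
#' @param tG1,tS,tG2,tM phase durations in hours (all > 0).
#' @param growthFraction fraction of cells cycling at the first injection.
#' @param quiescentMcm2Fraction fraction of quiescent cells scored Mcm2+.
#' @param earlyG1Ki67Window hours after mitosis during which G1 cells are
#'   scored Ki67-negative (default 2).
#' @param pulseTimes injection times in hours before sacrifice, strictly
#'   decreasing; default \code{c(1.5, 0.5)} (first analog 1.5 h and second
#'   0.5 h before collection, i.e. a 1 h interval and 0.5 h chase).
#' @param labelWindows analog availability in hours after each injection;
#'   a scalar is recycled.  Default \code{NULL}: window of each analog
#'   extends to the next injection, the last is instantaneous.
#' @param exitProbability probability that a cell leaves the cycle at each
#'   division occurring before sacrifice.
#' @param vzDepth depth (apical = 0) of the ventricular-zone boundary used
#'   to place the simulated cells; all cells are drawn inside it.
#' @param seed integer seed; identical arguments and seed give identical
#'   tables.
#'
#' @return a \code{\linkS4class{PopulationTable}}.
#'
#' @examples
#' pop <- simulatePopulation(2000, tG1 = 8, tS = 5.31, tG2 = 1, tM = 0.83,
#'                           seed = 1)
#' pop
#' @export
simulatePopulation <- function(nCells, tG1, tS, tG2, tM,
                               growthFraction = 1,
                               quiescentMcm2Fraction = 1,
                               earlyG1Ki67Window = 2,
                               pulseTimes = c(1.5, 0.5),
                               labelWindows = NULL,
                               exitProbability = 0,
                               vzDepth = 0.35,
                               seed = 1L) {
    stopifnot(nCells >= 1, tG1 > 0, tS > 0, tG2 > 0, tM > 0,
              growthFraction >= 0, growthFraction <= 1,
              quiescentMcm2Fraction >= 0, quiescentMcm2Fraction <= 1,
              earlyG1Ki67Window >= 0, exitProbability >= 0,
              exitProbability <= 1, length(pulseTimes) >= 1,
              all(pulseTimes >= 0))
    if (is.unsorted(rev(pulseTimes), strictly = TRUE) && length(pulseTimes) > 1)
        stop("pulseTimes must be strictly decreasing (hours before sacrifice)")
    nPulse <- length(pulseTimes)
    tc <- tG1 + tS + tG2 + tM
    # absolute time axis: first injection at 0, sacrifice at `total`
    total <- pulseTimes[1]
    injAt <- pulseTimes[1] - pulseTimes
    if (is.null(labelWindows))
        labelWindows <- c(diff(injAt), 0)[seq_len(nPulse)]
    labelWindows <- rep_len(labelWindows, nPulse)
    stopifnot(all(labelWindows >= 0))

    issues <- character()
    if (any(tS + labelWindows >= tc))
        issues <- c(issues,
            "label window spans a full cycle: single-labeled class structurally empty")
    if (nPulse >= 2 && tS + labelWindows[nPulse] >= tc)
        issues <- c(issues, "every cell labeled by the final analog")

    set.seed(seed)
    cycling0 <- stats::runif(nCells) < growthFraction
    pos0 <- ifelse(cycling0, stats::runif(nCells, 0, tc), NA_real_)

    sStart <- tG1
    sEnd <- tG1 + tS

    # exit time: first division at which the cell leaves the cycle
    nDivMax <- floor((ifelse(cycling0, pos0, 0) + total) / tc)
    exitTime <- rep(Inf, nCells)
    if (exitProbability > 0 && any(nDivMax > 0, na.rm = TRUE)) {
        kmax <- max(nDivMax, na.rm = TRUE)
        for (k in seq_len(kmax)) {
            divT <- k * tc - pos0           # time of k-th division
            at <- which(cycling0 & nDivMax >= k & exitTime == Inf)
            if (!length(at)) break
            leaves <- at[stats::runif(length(at)) < exitProbability]
            exitTime[leaves] <- divT[leaves]
        }
    }

    # analog incorporation: in S during [injAt_j, injAt_j + window_j],
    # truncated at sacrifice and at the cell's exit time
    labels <- matrix(FALSE, nCells, nPulse)
    kmax <- ceiling((total + tS) / tc) + 1
    for (j in seq_len(nPulse)) {
        a <- injAt[j]
        bAll <- pmin(a + labelWindows[j], total, exitTime)
        hit <- rep(FALSE, nCells)
        for (k in 0:kmax) {
            s0 <- sStart - pos0 + k * tc    # S entry (absolute time)
            s1 <- sEnd - pos0 + k * tc      # S exit
            # S interval [s0, s1) intersects closed window [a, b]
            hit <- hit | (!is.na(pos0) & s0 <= bAll & s1 > a & bAll >= a)
        }
        labels[, j] <- hit & cycling0
    }

    exited <- cycling0 & is.finite(exitTime)
    cyclingNow <- cycling0 & !exited
    posT <- ifelse(cyclingNow, (pos0 + total) %% tc, NA_real_)
    phase <- rep("G0", nCells)
    phase[cyclingNow & posT < tG1] <- "G1"
    phase[cyclingNow & posT >= tG1 & posT < sEnd] <- "S"
    phase[cyclingNow & posT >= sEnd & posT < sEnd + tG2] <- "G2"
    phase[cyclingNow & posT >= sEnd + tG2] <- "M"

    ki67 <- cyclingNow & !(phase == "G1" & posT < earlyG1Ki67Window)
    quiescent <- !cyclingNow
    mcm2 <- cyclingNow
    if (any(quiescent))
        mcm2[quiescent] <- stats::runif(sum(quiescent)) < quiescentMcm2Fraction
    pvim <- phase == "M"

    df <- DataFrame(
        cell_id = sprintf("cell_%05d", seq_len(nCells)),
        gfp = rep(TRUE, nCells),
        cycling = cyclingNow,
        phase_at_sacrifice = phase,
        brdu = labels[, 1],
        edu = if (nPulse >= 2) labels[, 2] else rep(FALSE, nCells),
        ki67 = ki67,
        mcm2 = mcm2,
        pvim = pvim,
        depth = stats::runif(nCells, 0, vzDepth),
        zone = rep("VZ", nCells))

    params <- list(nCells = nCells, tG1 = tG1, tS = tS, tG2 = tG2, tM = tM,
                   tc = tc, growthFraction = growthFraction,
                   quiescentMcm2Fraction = quiescentMcm2Fraction,
                   earlyG1Ki67Window = earlyG1Ki67Window,
                   pulseTimes = pulseTimes, labelWindows = labelWindows,
                   exitProbability = exitProbability, seed = seed)
    new("PopulationTable", cells = df, params = params, issues = issues)
}

#' Read / write per-cell population tables as CSV
#'
#' CSV round-trip for \code{\linkS4class{PopulationTable}}; logical flags
#' are stored as 0/1 with a header row.
#'
#' @param x a \code{PopulationTable}.
#' @param path file path.
#' @return \code{readPopulationTable} returns a \code{PopulationTable};
#'   \code{writePopulationTable} returns \code{path} invisibly.
#' @export
writePopulationTable <- function(x, path) {
    stopifnot(is(x, "PopulationTable"))
    df <- as.data.frame(x@cells)
    for (fl in c("gfp", "cycling", "brdu", "edu", "ki67", "mcm2", "pvim"))
        df[[fl]] <- as.integer(df[[fl]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writePopulationTable
#' @export
readPopulationTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (fl in c("gfp", "cycling", "brdu", "edu", "ki67", "mcm2", "pvim"))
        df[[fl]] <- as.logical(df[[fl]])
    new("PopulationTable", cells = DataFrame(df), params = list(),
        issues = character())
}
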