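#' Two-group unpaired t test from raw values
#'
#' Pooled-variance Student's t by default (the convention under which a
#' printed df of n1+n2-2 is consistent), with Welch's unequal-variance
#' form behind \code{variant = "welch"}.  Two-sided p.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return named list \code{t}, \code{df}, \code{p}.
#' @export
tFromRaw <- function(a, b, variant = c("pooled", "welch")) {
    variant <- match.arg(variant)
    stopifnot(length(a) >= 2, length(b) >= 2)
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) != mean(b)) {
        warning("zero variance with unequal means: infinite t")
        return(list(t = sign(mean(a) - mean(b)) * Inf,
                    df = length(a) + length(b) - 2, p = 0))
    }
    ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Reconstruct the unpaired t statistic from printed summary data
#'
#' Inverts the usual reporting format (mean +- SEM, n per group) back to
#' the pooled Student's t: sample SDs are recovered as
#' \code{sem * sqrt(n)}, pooled into the usual variance estimate, and
#' for \code{n1 == n2} the statistic reduces exactly to
#' \code{(m1 - m2) / sqrt(sem1^2 + sem2^2)}.  df = n1 + n2 - 2; the p
#' value is the two-sided tail of the t distribution.  Because published
#' means and SEMs are typically rounded to two decimals, reconstructed t
#' values match printed ones only to about +-0.02-0.03.
#'
#' @param m1,sem1,n1 first group: mean, SEM (> 0), size (>= 2).
#' @param m2,sem2,n2 second group.
#' @return named list \code{t} (sign: group 1 minus group 2), \code{df},
#'   \code{p}.
#' @examples
#' tFromSummary(50.51, 0.66, 4, 81.69, 5.47, 4)   # t ~ -5.66, df 6
#' @export
tFromSummary <- function(m1, sem1, n1, m2, sem2, n2) {
    stopifnot(sem1 > 0, sem2 > 0, n1 >= 2, n2 >= 2)
    if (n1 != n2)
        warning("unequal group sizes: pooled t reconstructed from SEMs and n")
    s1sq <- sem1^2 * n1
    s2sq <- sem2^2 * n2
    df <- n1 + n2 - 2
    spsq <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / df
    t <- (m1 - m2) / sqrt(spsq * (1 / n1 + 1 / n2))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{p.adjust(method = "BH")}, the "adjusted p"
#' used for both the differential-expression and the master-regulator
#' calls.
#'
#' @param p numeric vector of p values in (0, 1].
#' @return adjusted p values, same order as the input.
#' @export
benjaminiHochberg <- function(p) {
    stopifnot(all(p > 0), all(p <= 1))
    stats::p.adjust(p, method = "BH")
}
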