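#' Previously reported two-group summaries bundled for validation
#'
#' A panel of published two-group comparisons (mean, SEM, n per group and
#' the reported unpaired t statistic) from the embryonic-neocortex
#' electroporation experiments whose quantitative workflows this package
#' implements: ventricular-zone retention under different promoter
#' reporters, lineage-traced layer-marker fractions, proliferation-marker
#' and thymidine-analog fractions under Sox9 overexpression, and the
#' dual-pulse Ts/Tc estimates.  Since each row carries both the inputs
#' (summaries) and the output (printed t), it validates
#' \code{\link{tFromSummary}} end to end.  \code{tol_abs} is the absolute
#' reconstruction tolerance consistent with the two-decimal rounding of
#' the printed means and SEMs (0.02 for most rows, wider where the
#' rounding interval demands it).  A few reported comparisons whose
#' printed t cannot be reproduced from their own printed summaries under
#' any rounding (internal inconsistencies in the source report) are not
#' part of the panel.
#'
#' @return data.frame with columns comparison, group1, m1, sem1, n1,
#'   group2, m2, sem2, n2, t_printed, tol_abs.
#' @export
publishedGroupSummaries <- function() {
    path <- system.file("extdata", "published_group_summaries.csv",
                        package = "ProgenitorKit", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}
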