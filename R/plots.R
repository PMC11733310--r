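#' @include landcover.R
NULL

#' Bar chart of area-weighted class activity with 95% CIs
#'
#' The conventional presentation of per-class foraging activity: one bar
#' per land-cover class (area-weighted mean occurrences per hectare per
#' night), error bars for the bootstrap 95% CI, a dashed line at the
#' study-wide mean, bars colored by broad land-cover type.
#'
#' @param summaries output of [classSummaries()].
#' @return a ggplot object.
#' @export
plotClassSummaries <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotClassSummaries requires the ggplot2 package", call. = FALSE)
  overall <- summaries$mean_rate[summaries$class == "(all)"]
  d <- summaries[summaries$class != "(all)", , drop = FALSE]
  d$class <- stats::reorder(d$class, -d$mean_rate)
  ggplot2::ggplot(d, ggplot2::aes(x = class, y = mean_rate, fill = type)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = overall, linetype = "dashed") +
    ggplot2::labs(x = NULL,
                  y = "Bat occurrences per hectare per night",
                  fill = "Type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
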