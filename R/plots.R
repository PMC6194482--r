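#' Plot conditional precision statistics
#'
#' Bar-style panel of one conditional statistic (CSEE, CMAE, CBIAS or mean
#' test length) per true-theta bin, the standard way variable-length CAT
#' designs are inspected: the CSEE panel should sit at or below the
#' termination target across bins, CBIAS near zero.
#'
#' @param summary a `precision_summary` from [conditional_stats()].
#' @param stat which column of the by-bin table to draw.
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_conditional <- function(summary,
                             stat = c("csee", "cmae", "cbias",
                                      "crmse", "mean_length"), ...) {
  stat <- match.arg(stat)
  b <- summary$by_bin
  graphics::barplot(b[[stat]], names.arg = b$bin, las = 2,
                    ylab = toupper(stat), xlab = "true theta bin", ...)
}

#' Plot item exposure against an item parameter
#'
#' Scatter of per-item exposure counts against the discrimination (a) or
#' difficulty (b) parameter; a strong a-exposure trend is the signature of
#' information-greedy selection criteria.
#'
#' @param sim a `cat_sim`.
#' @param param `"a"` or `"b"`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data frame.
#' @export
plot_exposure <- function(sim, param = c("a", "b"), ...) {
  param <- match.arg(param)
  df <- data.frame(x = sim$pool[[param]],
                   exposure = sim$usage$exposure_count)
  graphics::plot(df$x, df$exposure, xlab = sprintf("item %s-parameter", param),
                 ylab = "exposure count", ...)
  invisible(df)
}
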