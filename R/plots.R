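## Base-graphics report plots: per-step Delta-R bars and per-parameter
## distribution histograms with the all-data Gaussian overlay.

#' Bar plot of per-step Delta-R values
#'
#' Mirrors the strategy-progress figures: paired bars of Delta <R_work>
#' and Delta R_cross per step transition, for the overall data or one
#' resolution shell.
#'
#' @param cv a [run_cv()] result.
#' @param shell `"all"`, `"low"` or `"high"`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted matrix.
#' @export
plot_delta_r <- function(cv, shell = "all", ...) {
  dt <- delta_r_table(cv)
  cols <- switch(shell,
                 all = c("d_r_work", "d_r_cross"),
                 low = c("d_r_work_low", "d_r_cross_low"),
                 high = c("d_r_work_high", "d_r_cross_high"),
                 stop("shell must be all, low or high"))
  m <- t(as.matrix(dt[, cols]))
  colnames(m) <- dt$step
  rownames(m) <- c("d<R_work>", "dR_cross")
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    col = c("grey40", "firebrick"),
                    ylab = "Delta R", las = 2, ...)
  graphics::abline(h = 0)
  invisible(m)
}

#' Histogram of one parameter's k-member distribution
#'
#' The k cross-validation values in red with their fitted Gaussian, the
#' all-data value v_total +- s_total as a grey Gaussian overlay.
#'
#' @param report a [parameter_report()].
#' @param parameter free-parameter name.
#' @param ... passed to [graphics::hist()].
#' @export
plot_parameter_distribution <- function(report, parameter, ...) {
  p <- report$parameters
  row <- p[p$parameter == parameter, ]
  if (!nrow(row)) stop("parameter '", parameter, "' not in report")
  ## member values are recoverable from the report summary only as the
  ## fitted Gaussian; the histogram needs the raw values
  vals <- attr(report, "members")[[parameter]]
  xr <- range(c(vals, row$v_total + c(-4, 4) * row$s_total))
  h <- graphics::hist(vals, breaks = max(5, report$k %/% 2), plot = FALSE)
  graphics::hist(vals, breaks = h$breaks, col = "mistyrose",
                 border = "firebrick", freq = FALSE, xlim = xr,
                 main = parameter, xlab = "value", ...)
  xs <- seq(xr[1], xr[2], length.out = 201)
  if (row$s_total > 0)
    graphics::lines(xs, stats::dnorm(xs, row$v_total, row$s_total),
                    col = "grey40", lwd = 2)
  if (row$s_mean > 0)
    graphics::lines(xs, stats::dnorm(xs, row$v_mean, row$s_mean),
                    col = "firebrick", lwd = 2)
  invisible(NULL)
}
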