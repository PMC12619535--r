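#' Forest-plot table for a meta-analysis fit
#'
#' Builds the rows a forest plot displays: one row per study with its effect,
#' 95% CI (from the study's own sampling variance) and weight percent, plus a
#' final summary row carrying the pooled estimate and its CI. Weight percents
#' sum to 100.
#'
#' @param x an `mcid_meta` fit.
#' @return data frame with columns `label`, `md`, `ci_low`, `ci_high`,
#'   `weight_percent`; the last row (`label = "RE pooled"`) is the summary,
#'   with `weight_percent = 100`.
#' @export
forest_data <- function(x) {
  stopifnot(inherits(x, "mcid_meta"))
  crit <- stats::qnorm(1 - (1 - x$level) / 2)
  rows <- data.frame(
    label = x$slab,
    md = x$yi,
    ci_low = x$yi - crit * sqrt(x$vi),
    ci_high = x$yi + crit * sqrt(x$vi),
    weight_percent = 100 * as.numeric(x$weights),
    stringsAsFactors = FALSE)
  summary_row <- data.frame(
    label = "RE pooled", md = x$mu, ci_low = x$ci_low, ci_high = x$ci_high,
    weight_percent = 100, stringsAsFactors = FALSE)
  out <- rbind(rows, summary_row)
  rownames(out) <- NULL
  out
}

#' Draw a forest plot
#'
#' Base-graphics forest plot: one square marker (area proportional to weight)
#' with a CI whisker per study, a diamond for the pooled estimate, a dashed
#' vertical null line at zero, and an annotation of tau-squared and I².
#'
#' @param x an `mcid_meta` fit.
#' @param xlab x-axis label.
#' @param main plot title.
#' @param ... passed to [graphics::plot.default()].
#' @return invisibly, the [forest_data()] table that was drawn.
#' @export
plot.mcid_meta <- function(x, xlab = "Mean difference (MCID units)",
                           main = "Unified functional MCID outcome", ...) {
  rows <- forest_data(x)
  k <- nrow(rows) - 1L
  studies <- rows[seq_len(k), ]
  pooled <- rows[k + 1L, ]
  ypos <- rev(seq_len(k))
  xlim <- range(0, rows$ci_low, rows$ci_high)
  xlim <- xlim + c(-0.05, 0.3) * diff(xlim)

  op <- graphics::par(mar = c(4.5, 10, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xlim, ylim = c(-1.2, k + 0.8), yaxt = "n",
                 ylab = "", xlab = xlab, main = main, bty = "n", ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::segments(studies$ci_low, ypos, studies$ci_high, ypos)
  cex <- 0.6 + 1.4 * sqrt(studies$weight_percent / 100)
  graphics::points(studies$md, ypos, pch = 15, cex = cex)
  graphics::axis(2, at = ypos, labels = studies$label, las = 1, tick = FALSE,
                 cex.axis = 0.85)
  graphics::text(xlim[2], ypos,
                 sprintf("%.2f [%.2f, %.2f] %4.1f%%", studies$md,
                         studies$ci_low, studies$ci_high,
                         studies$weight_percent),
                 adj = 1, cex = 0.75)
  # pooled-estimate diamond
  graphics::polygon(c(pooled$ci_low, pooled$md, pooled$ci_high, pooled$md),
                    c(0, 0.3, 0, -0.3), col = "grey30", border = NA)
  graphics::axis(2, at = 0, labels = pooled$label, las = 1, tick = FALSE,
                 cex.axis = 0.85, font = 2)
  graphics::text(xlim[2], 0,
                 sprintf("%.2f [%.2f, %.2f]", pooled$md, pooled$ci_low,
                         pooled$ci_high), adj = 1, cex = 0.75, font = 2)
  graphics::mtext(sprintf("tau^2 = %.3f, I^2 = %.1f%% (%s)", x$tau2,
                          x$i2, x$band),
                  side = 1, line = 3, adj = 0, cex = 0.8)
  invisible(rows)
}

#' Write a forest plot to an image file
#'
#' Renders the forest plot of a fit to SVG or PNG, chosen by the file
#' extension.
#'
#' @param x an `mcid_meta` fit.
#' @param path output file ending in `.svg` or `.png`.
#' @param width,height device size in inches.
#' @param ... passed to [plot.mcid_meta()].
#' @return invisibly, `path`.
#' @export
render_forest <- function(x, path, width = 8, height = NULL, ...) {
  stopifnot(inherits(x, "mcid_meta"))
  if (x$k < 1L) stop("no studies to plot", call. = FALSE)
  if (is.null(height)) height <- 1.5 + 0.35 * x$k
  ext <- tolower(tools::file_ext(path))
  opened <- tryCatch({
    switch(ext,
      svg = grDevices::svg(path, width = width, height = height),
      png = grDevices::png(path, width = width, height = height,
                           units = "in", res = 150),
      stop("unsupported extension '", ext, "'; use .svg or .png",
           call. = FALSE))
    TRUE
  }, error = function(e) {
    stop("cannot open graphics file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(x, ...)
  invisible(path)
}
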