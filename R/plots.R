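# Base-graphics figures: circular scatter of per-bird mean vectors with
# second-order group vectors (home at the top), and box-and-point panels
# per metric.

#' Box statistics with 1.5 x IQR whiskers
#'
#' Quartiles by the default (type 7) quantile rule; whiskers reach the
#' most extreme observations within 1.5 interquartile ranges of the box.
#'
#' @param x Numeric vector.
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
box_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  inside <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr])
}

#' Circular scatter of per-bird mean vectors
#'
#' Each bird's mean vector is drawn inside the unit circle with the home
#' direction (0 degrees) at the top; arrows show the second-order mean
#' vector of each group x site cell.
#'
#' @param points `data.frame` from [bird_vector_points()].
#' @param main Plot title.
#' @return Invisibly, the second-order vectors per cell.
#' @export
plot_mean_vectors <- function(points, main = "Mean vectors") {
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 256)
  graphics::lines(sin(th), cos(th), col = "grey50")
  graphics::segments(0, -1, 0, 1, col = "grey85", lty = 3)
  graphics::segments(-1, 0, 1, 0, col = "grey85", lty = 3)
  graphics::text(0, 1.08, "home")
  # direction 0 at top: plot (sin, cos) of the vector angle
  cols <- c(experimental = "forestgreen", control = "goldenrod3")
  pch <- c("1" = 1, "2" = 2)
  cells <- split(points, list(points$group, points$release_site),
                 drop = TRUE)
  if (length(cells) == 0) {
    warning("no birds to plot")
    return(invisible(NULL))
  }
  so <- lapply(cells, function(p) {
    graphics::points(p$y, p$x, col = cols[p$group[1]],
                     pch = pch[[as.character(p$release_site[1])]])
    v <- second_order_mean_vector(p)
    graphics::arrows(0, 0, v$y, v$x, length = 0.08,
                     col = cols[p$group[1]],
                     lty = if (p$release_site[1] ==
                               sort(unique(points$release_site))[1]) 1
                           else 2)
    v
  })
  invisible(so)
}

#' Box-and-point panels for one metric
#'
#' One box per release-site x treatment-group cell with 1.5 x IQR
#' whiskers and the individual birds overplotted; panels side by side for
#' each analysis radius present.
#'
#' @param metrics Metric table from [compute_metrics()].
#' @param metric Metric column name.
#' @param radii Radii to draw (default: all present).
#' @return Invisibly, `NULL`.
#' @export
plot_metric_boxes <- function(metrics, metric,
                              radii = sort(unique(metrics$radius_m))) {
  cols <- c(experimental = "forestgreen", control = "goldenrod3")
  op <- graphics::par(mfrow = c(1, length(radii)))
  on.exit(graphics::par(op))
  for (r in radii) {
    m <- metrics[metrics$radius_m == r, ]
    cells <- split(m[[metric]],
                   interaction(factor(m$group,
                                      levels = c("control",
                                                 "experimental")),
                               factor(m$release_site), drop = FALSE))
    keep <- vapply(cells, length, integer(1)) > 0
    if (any(!keep)) {
      warning("empty cell(s) omitted: ",
              paste(names(cells)[!keep], collapse = ", "))
    }
    cells <- cells[keep]
    graphics::plot(NA, xlim = c(0.5, length(cells) + 0.5),
                   ylim = range(unlist(cells)), xaxt = "n",
                   xlab = "", ylab = metric,
                   main = paste0(r / 1000, " km radius"))
    graphics::axis(1, at = seq_along(cells), labels = names(cells),
                   las = 2, cex.axis = 0.7)
    for (i in seq_along(cells)) {
      b <- box_stats(cells[[i]])
      grp <- sub("\\..*$", "", names(cells)[i])
      graphics::rect(i - 0.3, b$q1, i + 0.3, b$q3, border = cols[grp])
      graphics::segments(i - 0.3, b$median, i + 0.3, b$median,
                         lwd = 2, col = cols[grp])
      graphics::segments(i, b$q3, i, b$whisker_hi, col = cols[grp])
      graphics::segments(i, b$q1, i, b$whisker_lo, col = cols[grp])
      graphics::points(jitter(rep(i, length(cells[[i]])), amount = 0.08),
                       cells[[i]], pch = 16, cex = 0.6,
                       col = grDevices::adjustcolor(cols[grp], 0.6))
    }
  }
  invisible(NULL)
}

#' @export
plot.homing_analysis <- function(x, ...) {
  nr <- length(x$vectors)
  op <- graphics::par(mfrow = c(1, nr))
  on.exit(graphics::par(op))
  for (r in names(x$vectors)) {
    plot_mean_vectors(x$vectors[[r]]$points,
                      main = paste0(as.numeric(r) / 1000, " km radius"))
  }
  invisible(x)
}
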