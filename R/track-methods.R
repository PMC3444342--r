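#' @export
print.power_track <- function(x, ...) {
  cat(sprintf("<power_track> %s: %d windows (window=%d bp, step=%d bp, backend=%s, anchor=%s)\n",
              x$seq_id, length(x$values), x$config$window, x$config$step,
              x$config$backend, x$config$anchor))
  if (length(x$values) > 0L) {
    cat(sprintf("  positions %s..%s; power range [%.4g, %.4g]\n",
                fmt_num(x$positions[1L]), fmt_num(x$positions[length(x$positions)]),
                min(x$values), max(x$values)))
  }
  invisible(x)
}

#' @export
#' @method summary power_track
summary.power_track <- function(object, ...) {
  v <- object$values
  out <- list(
    seq_id = object$seq_id,
    n_windows = length(v),
    window = object$config$window,
    step = object$config$step,
    mean = mean(v),
    sd_pop = sqrt(mean((v - mean(v))^2)),
    quartiles = stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1))
  )
  class(out) <- "summary.power_track"
  out
}

#' @export
print.summary.power_track <- function(x, ...) {
  cat(sprintf("Power track for %s: %d windows of %d bp (step %d bp)\n",
              x$seq_id, x$n_windows, x$window, x$step))
  cat(sprintf("  mean power %.4g, population sd %.4g\n", x$mean, x$sd_pop))
  print(signif(x$quartiles, 4))
  invisible(x)
}

#' @export
#' @method as.data.frame power_track
as.data.frame.power_track <- function(x, ...) {
  data.frame(seq_id = x$seq_id, position = x$positions, power = x$values,
             stringsAsFactors = FALSE)
}

#' Plot a power track
#'
#' Base-graphics line plot of combined period-3 power along the sequence.
#' Truth or annotation intervals can be underlaid as shaded rectangles,
#' and called regions as a rug of segments.
#'
#' @param x A `power_track`.
#' @param truth Optional `genomic_intervals` to shade.
#' @param calls Optional `region_calls` to mark.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot power_track
#' @export
plot.power_track <- function(x, truth = NULL, calls = NULL, ...) {
  graphics::plot(x$positions, x$values, type = "l",
                 xlab = sprintf("position on %s (bp)", x$seq_id),
                 ylab = "combined power at f = 1/3", ...)
  if (!is.null(truth) && nrow(truth) > 0L) {
    usr <- graphics::par("usr")
    graphics::rect(truth$start, usr[3L], truth$end, usr[4L],
                   col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  }
  if (!is.null(calls) && nrow(calls) > 0L) {
    graphics::segments(calls$start, 0, calls$end, 0, lwd = 4, col = "firebrick")
  }
  invisible(x)
}
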