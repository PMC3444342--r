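pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Call candidate coding regions from a power track
#'
#' Thresholds the track at `tau = mean + k_sigma * sd` (population sd, for
#' determinism), takes maximal runs of anchored positions with power >= tau
#' as intervals, merges runs separated by less than `merge_gap` bp, and
#' discards intervals shorter than `min_len` bp. This calling rule is a
#' pragmatic reduction of "each peak is a probable coding region" to a
#' reproducible procedure; the defaults are deliberately permissive and
#' should be tuned per application.
#'
#' @param track A `power_track` (non-empty).
#' @param k_sigma Threshold stringency in population-sd units (>= 0).
#' @param min_len Minimum region length in bp (>= 1).
#' @param merge_gap Runs closer than this many bp are merged.
#' @return A `region_calls` data.frame: `seq_id`, `start`, `end` (0-based
#'   half-open), `peak_power`, `mean_power`, sorted by `start`, pairwise
#'   disjoint; threshold stored in `attr(, "threshold")`.
#' @export
call_regions <- function(track, k_sigma = 2, min_len = 30L, merge_gap = 50L) {
  stopifnot(inherits(track, "power_track"))
  if (length(track$values) == 0L) stop_input("empty power track")
  stopifnot(k_sigma >= 0, min_len >= 1, merge_gap >= 0)
  v <- track$values
  pos <- track$positions
  tau <- mean(v) + k_sigma * pop_sd(v)
  above <- v >= tau
  empty <- function() {
    out <- data.frame(seq_id = character(0), start = numeric(0), end = numeric(0),
                      peak_power = numeric(0), mean_power = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "threshold") <- tau
    class(out) <- c("region_calls", "data.frame")
    out
  }
  if (!any(above)) return(empty())
  r <- rle(above)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- data.frame(first = idx_start[r$values], last = idx_end[r$values])
  # anchored-position runs -> half-open bp intervals
  runs$start <- pos[runs$first]
  runs$end <- pos[runs$last] + 1
  # merge runs separated by < merge_gap bp
  merged <- runs[1L, c("start", "end")]
  for (i in seq_len(nrow(runs))[-1L]) {
    j <- nrow(merged)
    if (runs$start[i] - merged$end[j] < merge_gap) {
      merged$end[j] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, c("start", "end")])
    }
  }
  merged <- merged[merged$end - merged$start >= min_len, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty())
  # summarize over the above-threshold positions so mean_power >= tau even
  # when sub-threshold gap positions were absorbed by merging
  stats_for <- function(s, e) {
    inside <- pos >= s & pos < e & above
    c(peak = max(v[inside]), mean = mean(v[inside]))
  }
  st <- t(mapply(stats_for, merged$start, merged$end))
  out <- data.frame(seq_id = track$seq_id, start = merged$start, end = merged$end,
                    peak_power = st[, "peak"], mean_power = st[, "mean"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$start), , drop = FALSE]
  attr(out, "threshold") <- tau
  class(out) <- c("region_calls", "data.frame")
  out
}

#' @export
print.region_calls <- function(x, ...) {
  cat(sprintf("%d region call(s); threshold tau = %.6g\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x) > 0L) print.data.frame(x, ...)
  invisible(x)
}

#' Merge overlapping or touching intervals
#'
#' Sorts intervals on a single sequence and unions any pair that overlaps
#' or shares a boundary, returning a pairwise-disjoint set. Nested
#' intervals collapse into their enclosing one — e.g. two alternative
#' exon variants that share a start merge into a single distinct coding
#' region.
#'
#' @param intervals A `genomic_intervals` data.frame on one `seq_id`.
#' @return Merged `genomic_intervals`, sorted, disjoint; labels of merged
#'   members are joined with `","`.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L) return(intervals)
  if (length(unique(intervals$seq_id)) > 1L) {
    stop_input("merge_intervals requires intervals on a single seq_id")
  }
  iv <- intervals[order(intervals$start, intervals$end), , drop = FALSE]
  starts <- iv$start[1L]
  ends <- iv$end[1L]
  labels <- iv$label[1L]
  for (i in seq_len(nrow(iv))[-1L]) {
    j <- length(starts)
    if (iv$start[i] <= ends[j]) {  # overlap or touching
      ends[j] <- max(ends[j], iv$end[i])
      labels[j] <- if (is.na(labels[j])) iv$label[i] else
        paste(c(labels[j], iv$label[i]), collapse = ",")
    } else {
      starts <- c(starts, iv$start[i])
      ends <- c(ends, iv$end[i])
      labels <- c(labels, iv$label[i])
    }
  }
  genomic_intervals(seq_id = iv$seq_id[1L], start = starts, end = ends, label = labels)
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Compare region calls against a truth interval set
#'
#' A truth interval counts as detected when some single call covers at
#' least `min_overlap_frac` of its length; a call is supporting when it
#' achieves that for at least one truth interval. Recall is the detected
#' fraction of truths; precision the supporting fraction of calls (defined
#' as 1 when there are no calls, with a message).
#'
#' @param calls A `region_calls` data.frame (or any data.frame with
#'   `start`/`end`).
#' @param truth A `genomic_intervals` truth set.
#' @param min_overlap_frac Required overlap as a fraction of the truth
#'   interval's length, in (0, 1].
#' @return An object of class `call_evaluation`: list with `detected`
#'   (logical per truth), `supporting` (logical per call), `recall`,
#'   `precision`, `n_calls`, `n_truth`.
#' @export
evaluate_calls <- function(calls, truth, min_overlap_frac = 0.5) {
  stopifnot(min_overlap_frac > 0, min_overlap_frac <= 1)
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  if (n_truth == 0L) stop_input("empty truth set")
  if (n_calls == 0L) {
    message("no calls; precision defined as 1 on the empty set")
    out <- list(detected = rep(FALSE, n_truth), supporting = logical(0),
                recall = 0, precision = 1, n_calls = 0L, n_truth = n_truth)
    class(out) <- "call_evaluation"
    return(out)
  }
  ov <- outer(seq_len(n_calls), seq_len(n_truth), function(i, j) {
    overlap_len(calls$start[i], calls$end[i], truth$start[j], truth$end[j])
  })
  need <- min_overlap_frac * (truth$end - truth$start)
  hit <- sweep(ov, 2L, need, `>=`)  # calls x truths
  detected <- apply(hit, 2L, any)
  supporting <- apply(hit, 1L, any)
  out <- list(detected = detected, supporting = supporting,
              recall = mean(detected), precision = mean(supporting),
              n_calls = n_calls, n_truth = n_truth)
  class(out) <- "call_evaluation"
  out
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat(sprintf("call evaluation: recall %.3f (%d/%d truths), precision %.3f (%d/%d calls)\n",
              x$recall, sum(x$detected), x$n_truth,
              x$precision, sum(x$supporting), max(x$n_calls, 1L)))
  invisible(x)
}
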