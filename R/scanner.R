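#' Sliding-window scan configuration
#'
#' The defaults follow established practice for period-3 exon detection: a
#' 351 bp window balances noise (too-short windows) against boundary blur
#' (too-long windows), and the window advances 1 bp at a time. Output
#' coordinates are anchored at the window center by default so track peaks
#' line up with exon midpoints; `anchor = "start"` gives plain window
#' starts (handy for bedGraph).
#'
#' @param window Window length in bp (>= 3; default 351).
#' @param step Shift in bp between consecutive windows (>= 1; default 1).
#' @param backend `"goertzel"` (default) or `"fft"`.
#' @param anchor `"center"` (default; requires odd `window`) or `"start"`.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(window = 351L, step = 1L,
                        backend = c("goertzel", "fft"),
                        anchor = c("center", "start")) {
  backend <- match.arg(backend)
  anchor <- match.arg(anchor)
  if (!is_count(window, min = 3L)) stop_input("window must be an integer >= 3")
  if (!is_count(step, min = 1L)) stop_input("step must be an integer >= 1")
  if (anchor == "center" && window %% 2L == 0L) {
    stop_input("anchor = \"center\" requires an odd window length (got ", window, ")")
  }
  structure(
    list(window = as.integer(window), step = as.integer(step),
         backend = backend, anchor = anchor, f_n = 1/3),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> window=%d bp, step=%d bp, backend=%s, anchor=%s, f=1/3\n",
              x$window, x$step, x$backend, x$anchor))
  invisible(x)
}

n_windows_for <- function(L, config) {
  if (L < config$window) {
    stop_input("sequence length ", L, " is shorter than the window (", config$window, " bp)")
  }
  as.integer((L - config$window) %/% config$step + 1L)
}

anchor_positions <- function(starts_bp, config) {
  if (config$anchor == "center") starts_bp + (config$window - 1L) %/% 2L else starts_bp
}

new_power_track <- function(seq_id, positions, values, config) {
  structure(
    list(seq_id = seq_id, positions = as.numeric(positions),
         values = as.numeric(values), config = config),
    class = "power_track"
  )
}

# FFT backend: full transform per window, f = 1/3 bin extracted. Windows
# are batched into matrices so mvfft amortizes the per-call overhead.
scan_fft_values <- function(enc, config, first_window, n_win) {
  w <- config$window
  if (w %% 3L != 0L) {
    warning("window length ", w, " not divisible by 3; using nearest FFT bin",
            call. = FALSE)
  }
  k <- round(w / 3)
  starts <- (first_window + seq_len(n_win) - 1L) * config$step  # 0-based bp
  out <- numeric(n_win)
  block <- 512L
  for (b0 in seq(1L, n_win, by = block)) {
    b1 <- min(b0 + block - 1L, n_win)
    idx <- outer(0L:(w - 1L), starts[b0:b1], `+`) + 1L
    acc <- 0
    for (u in list(enc$A, enc$C, enc$G, enc$T)) {
      m <- matrix(u[idx], nrow = w)
      acc <- acc + Mod(stats::mvfft(m)[k + 1L, ])^2
    }
    out[b0:b1] <- acc
  }
  out
}

scan_values <- function(enc, config, first_window, n_win) {
  if (config$backend == "goertzel") {
    .scan_p3_cpp(enc$A, enc$C, enc$G, enc$T, config$window, config$step,
                 as.integer(first_window), as.integer(n_win))
  } else {
    scan_fft_values(enc, config, first_window, n_win)
  }
}

#' Scan a sequence with a sliding period-3 power window
#'
#' Slides a `window`-bp frame across the sequence in `step`-bp shifts,
#' computing at each position the combined (A+C+G+T) spectral power at
#' normalized frequency 1/3. Every window is computed from scratch by the
#' selected backend. Peaks in the resulting track indicate probable
#' protein-coding regions.
#'
#' @param seq A [dna_seq()] (or character scalar); must be at least
#'   `window` bp long.
#' @param config A [scan_config()].
#' @return A `power_track`: per-window anchored positions (0-based bp) and
#'   combined powers, with `length = floor((L - window)/step) + 1`.
#' @examples
#' scan("AAACCC", scan_config(window = 3, anchor = "start"))$values  # 0 2 2 0
#' @export
scan <- function(seq, config = scan_config()) {
  seq <- as_dna_seq(seq)
  stopifnot(inherits(config, "scan_config"))
  n_win <- n_windows_for(seq$length, config)
  enc <- voss_encode(seq)
  values <- scan_values(enc, config, 0L, n_win)
  starts <- (seq_len(n_win) - 1L) * config$step
  new_power_track(seq$id, anchor_positions(starts, config), values, config)
}

#' Plan chunked execution of a scan
#'
#' Partitions the window-start indices `0 .. n_windows-1` into consecutive
#' ranges of `chunk_windows` (the last possibly smaller). Each chunk's
#' residue span is `(windows_in_chunk - 1)*step + window` bp, so adjacent
#' spans overlap by `window - step` bp and every window is computed exactly
#' once — the bookkeeping that makes chunked (parallel) scanning exactly
#' equivalent to the serial scan.
#'
#' @param L Sequence length in bp (>= window).
#' @param config A [scan_config()].
#' @param chunk_windows Windows per chunk (>= 1).
#' @return An object of class `chunk_plan`: data.frame `chunks` with
#'   columns `first`, `last` (window indices), `start_bp`, `end_bp`
#'   (residue span), plus `chunk_size` and `overlap_bp`.
#' @export
plan_chunks <- function(L, config = scan_config(), chunk_windows) {
  stopifnot(inherits(config, "scan_config"))
  if (!is_count(chunk_windows, min = 1L)) stop_input("chunk_windows must be >= 1")
  n_win <- n_windows_for(L, config)
  first <- seq(0L, n_win - 1L, by = as.integer(min(chunk_windows, n_win)))
  last <- pmin(first + as.integer(min(chunk_windows, n_win)) - 1L, n_win - 1L)
  chunks <- data.frame(
    first = first, last = last,
    start_bp = first * config$step,
    end_bp = last * config$step + config$window
  )
  structure(
    list(chunks = chunks, chunk_size = as.integer(min(chunk_windows, n_win)),
         overlap_bp = config$window - config$step, n_windows = n_win),
    class = "chunk_plan"
  )
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("<chunk_plan> %d windows in %d chunk(s) of <= %d; adjacent residue spans overlap %d bp\n",
              x$n_windows, nrow(x$chunks), x$chunk_size, x$overlap_bp))
  invisible(x)
}

#' Chunked, optionally parallel scan
#'
#' Splits the scan into chunks via [plan_chunks()], executes them (with
#' `parallel::mclapply` when `workers > 1`), and reassembles results in
#' chunk order. Because windows are independent and the Goertzel backend
#' uses exact integer arithmetic, the output is identical — bitwise for
#' `backend = "goertzel"` — to [scan()] for every choice of `workers` and
#' `chunk_windows`.
#'
#' @param seq A [dna_seq()] or character scalar.
#' @param config A [scan_config()].
#' @param workers Number of concurrent workers (>= 1).
#' @param chunk_windows Windows per chunk (default 50000).
#' @return A `power_track`, identical to `scan(seq, config)`.
#' @export
scan_parallel <- function(seq, config = scan_config(), workers = 1L,
                          chunk_windows = 50000L) {
  seq <- as_dna_seq(seq)
  stopifnot(inherits(config, "scan_config"))
  if (!is_count(workers, min = 1L)) stop_input("workers must be >= 1")
  n_win <- n_windows_for(seq$length, config)
  plan <- plan_chunks(seq$length, config, chunk_windows)
  enc <- voss_encode(seq)
  run_chunk <- function(i) {
    ch <- plan$chunks[i, ]
    scan_values(enc, config, ch$first, ch$last - ch$first + 1L)
  }
  parts <- if (workers == 1L) {
    lapply(seq_len(nrow(plan$chunks)), run_chunk)
  } else {
    parallel::mclapply(seq_len(nrow(plan$chunks)), run_chunk,
                       mc.cores = workers, mc.preschedule = TRUE)
  }
  failed <- vapply(parts, inherits, logical(1), "try-error")
  if (any(failed)) stop("parallel chunk execution failed: ", parts[[which(failed)[1L]]])
  values <- unlist(parts, use.names = FALSE)
  stopifnot(length(values) == n_win)
  starts <- (seq_len(n_win) - 1L) * config$step
  new_power_track(seq$id, anchor_positions(starts, config), values, config)
}

#' Resource budget for the parallel-instance calculator
#'
#' Describes a parallel device in abstract units: total processing units
#' and the per-instance cost of one single-nucleotide FFT plus
#' miscellaneous work, and likewise for memory (with a per-instance setup
#' term). Units only need to be mutually consistent.
#'
#' @param pu_total,pu_fft,pu_misc Processing-unit counts (> 0).
#' @param mem_total,mem_fft,mem_misc,mem_setup Memory amounts (> 0).
#' @return An object of class `resource_budget`.
#' @export
resource_budget <- function(pu_total, pu_fft, pu_misc,
                            mem_total, mem_fft, mem_misc, mem_setup) {
  vals <- c(pu_total = pu_total, pu_fft = pu_fft, pu_misc = pu_misc,
            mem_total = mem_total, mem_fft = mem_fft, mem_misc = mem_misc,
            mem_setup = mem_setup)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_input("all resource budget fields must be positive and finite")
  }
  structure(as.list(vals), class = "resource_budget")
}

#' Advisory upper bound on concurrent parallel instances
#'
#' Each parallel instance must run four single-nucleotide FFTs (one per
#' indicator vector) plus miscellaneous work, so the processing-unit side
#' bounds the instance count by `pu_total / (4*pu_fft + pu_misc)`; the
#' memory side adds a per-instance setup term, giving
#' `mem_total / (4*mem_fft + mem_misc + mem_setup)`. The usable bound is
#' the floor of the smaller of the two. Advisory only: it documents how to
#' size a device and does not gate execution.
#'
#' @param budget A [resource_budget()].
#' @return Integer upper bound (may be 0 if the budget admits no instance).
#' @export
max_parallel_instances <- function(budget) {
  stopifnot(inherits(budget, "resource_budget"))
  n1 <- budget$pu_total / (4 * budget$pu_fft + budget$pu_misc)
  n2 <- budget$mem_total / (4 * budget$mem_fft + budget$mem_misc + budget$mem_setup)
  as.integer(floor(min(n1, n2)))
}
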