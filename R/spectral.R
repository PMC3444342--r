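#' General Goertzel recursion at a normalized frequency
#'
#' Iterates `y[n] = x[n] + 2*cos(2*pi*f_n)*y[n-1] - y[n-2]` with
#' `y[-1] = y[-2] = 0` and returns the final pair `(y[N], y[N-1])`, which
#' carries all the information needed for the single-bin power. For
#' `f_n = 1/3` the feedback coefficient is exactly -1 (used in exact form,
#' not via the trigonometric evaluation, so the specialized
#' multiplication-free recursion is reproduced bit for bit) and the
#' recursion needs no multiplications at all — the property that makes this
#' filter attractive for scanning long genomes.
#'
#' @param x Numeric vector (non-empty).
#' @param f_n Normalized frequency in cycles/sample; `1/3` is the supported
#'   use for codon-periodicity detection.
#' @return An object of class `goertzel_state`: list with `y_N`, `y_Nm1`,
#'   `n_processed`, `f_n` and the feedback coefficient `coef`.
#' @seealso [goertzel_power()], [goertzel_period3()]
#' @export
goertzel_recursion <- function(x, f_n = 1/3) {
  if (length(x) == 0L) stop_input("empty input vector")
  stopifnot(is.numeric(x), is.numeric(f_n), length(f_n) == 1L, f_n > 0, f_n < 1/2)
  coef <- if (f_n == 1/3) -1 else 2 * cos(2 * pi * f_n)
  y1 <- 0
  y2 <- 0
  for (xi in x) {
    y <- xi + coef * y1 - y2
    y2 <- y1
    y1 <- y
  }
  structure(
    list(y_N = y1, y_Nm1 = y2, n_processed = length(x), f_n = f_n, coef = coef),
    class = "goertzel_state"
  )
}

#' Single-bin power from a Goertzel state
#'
#' Computes `|X(f_n)|^2 = y_N^2 + y_{N-1}^2 - 2*cos(2*pi*f_n)*y_N*y_{N-1}`.
#' At `f_n = 1/3` this is `y_N^2 + y_{N-1}^2 + y_N*y_{N-1}`, a
#' positive-semidefinite quadratic form (zero only when both terms vanish).
#'
#' @param state A `goertzel_state`.
#' @return Nonnegative power.
#' @export
goertzel_power <- function(state) {
  stopifnot(inherits(state, "goertzel_state"))
  state$y_N^2 + state$y_Nm1^2 - state$coef * state$y_N * state$y_Nm1
}

#' @export
print.goertzel_state <- function(x, ...) {
  cat(sprintf("<goertzel_state> f_n=%.6g, n=%d, y_N=%.6g, y_Nm1=%.6g, power=%.6g\n",
              x$f_n, x$n_processed, x$y_N, x$y_Nm1, goertzel_power(x)))
  invisible(x)
}

#' Period-3 spectral power of a binary vector (specialized Goertzel)
#'
#' Runs the multiplication-free recursion `y[n] = x[n] - y[n-1] - y[n-2]`
#' (the general recursion with feedback coefficient exactly -1) and returns
#' `P = y_N^2 + y_{N-1}^2 + y_N*y_{N-1}`. On 0/1 input all arithmetic is
#' exact integer arithmetic, so results are bitwise reproducible.
#'
#' @param x Binary (0/1) vector, e.g. one Voss indicator window.
#' @return Nonnegative power at normalized frequency 1/3.
#' @examples
#' goertzel_period3(c(1, 0, 0, 1, 0, 0))  # 4
#' @export
goertzel_period3 <- function(x) {
  if (length(x) == 0L) stop_input("empty input vector")
  if (!all(x == 0 | x == 1)) stop_input("input must be a binary (0/1) vector")
  .goertzel_p3_cpp(as.integer(x))
}

#' Direct single-bin DFT power at frequency 1/3 (oracle / FFT-bin target)
#'
#' Computes `|sum_n x[n] * exp(-2i*pi*k*n/N)|^2` at bin `k = N/3` by direct
#' complex summation. This is the brute-force reference the Goertzel path
#' is checked against, and the bin the FFT backend extracts. In exact mode
#' the length must be divisible by 3 so the bin is an integer; otherwise
#' the nearest integer bin is used with a warning (FFT backend behaviour).
#'
#' @param x Numeric vector.
#' @param exact Reject lengths not divisible by 3 (`TRUE`, oracle mode) or
#'   fall back to the nearest bin with a warning (`FALSE`).
#' @return Nonnegative power.
#' @export
dft_power_period3 <- function(x, exact = TRUE) {
  n <- length(x)
  if (n == 0L) stop_input("empty input vector")
  if (n %% 3L != 0L) {
    if (exact) stop_input("length ", n, " not divisible by 3; no exact f=1/3 bin")
    warning("length ", n, " not divisible by 3; using nearest bin k=",
            round(n / 3), call. = FALSE)
  }
  k <- round(n / 3)
  Mod(sum(x * exp(-2i * pi * k * (seq_len(n) - 1L) / n)))^2
}

#' Combined spectral power of one window
#'
#' Applies the selected backend to each of the four indicator sub-vectors
#' of the window and sums the four powers — the final per-window output of
#' the detector. Backends agree exactly on binary input up to
#' floating-point tolerance of the FFT.
#'
#' @param vectors A `voss_encoding`.
#' @param start 0-based window start.
#' @param n Window length (>= 3).
#' @param backend `"goertzel"` (default, exact integer arithmetic) or
#'   `"fft"` (full transform, f = 1/3 bin extracted).
#' @return An object of class `window_power`: list with `p_A`, `p_C`,
#'   `p_G`, `p_T` and their sum `combined`.
#' @export
window_power <- function(vectors, start, n, backend = c("goertzel", "fft")) {
  backend <- match.arg(backend)
  if (!is_count(n, min = 3L)) stop_input("window length must be >= 3")
  win <- indicator_slice(vectors, start, n)
  one <- function(u) {
    if (backend == "goertzel") {
      .goertzel_p3_cpp(u)
    } else {
      if (n %% 3L != 0L) {
        warning("window length ", n, " not divisible by 3; using nearest FFT bin",
                call. = FALSE)
      }
      Mod(stats::fft(u)[round(n / 3) + 1L])^2
    }
  }
  p <- c(A = one(win$A), C = one(win$C), G = one(win$G), T = one(win$T))
  structure(
    list(p_A = p[["A"]], p_C = p[["C"]], p_G = p[["G"]], p_T = p[["T"]],
         combined = sum(p), backend = backend),
    class = "window_power"
  )
}

#' @export
print.window_power <- function(x, ...) {
  cat(sprintf("<window_power> combined=%.6g (A=%.6g C=%.6g G=%.6g T=%.6g; %s)\n",
              x$combined, x$p_A, x$p_C, x$p_G, x$p_T, x$backend))
  invisible(x)
}
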