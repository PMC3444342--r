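#' Voss binary indicator encoding of a DNA sequence
#'
#' Represents a DNA string as four aligned binary vectors, one per
#' nucleotide: `u_X[i] = 1` iff residue `i` is `X`. At an `N` position all
#' four indicators are 0, so ambiguous bases contribute nothing to any
#' spectral power downstream. This one-hot representation is what turns a
#' symbolic sequence into signals amenable to DSP.
#'
#' @param seq A [dna_seq()] (or a character scalar, normalized on the fly).
#' @return An object of class `voss_encoding`: a list with integer 0/1
#'   vectors `A`, `C`, `G`, `T` and the common length `L`.
#' @examples
#' v <- voss_encode("ACGT")
#' v$A  # 1 0 0 0
#' @export
voss_encode <- function(seq) {
  seq <- as_dna_seq(seq)
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) stop_input("unnormalized character in sequence: '", bad[1L], "'")
  structure(
    list(
      A = as.integer(chars == "A"),
      C = as.integer(chars == "C"),
      G = as.integer(chars == "G"),
      T = as.integer(chars == "T"),
      L = length(chars)
    ),
    class = "voss_encoding"
  )
}

#' @export
print.voss_encoding <- function(x, ...) {
  cat(sprintf("<voss_encoding> %d bp; base counts A=%d C=%d G=%d T=%d N=%d\n",
              x$L, sum(x$A), sum(x$C), sum(x$G), sum(x$T),
              x$L - sum(x$A) - sum(x$C) - sum(x$G) - sum(x$T)))
  invisible(x)
}

#' Extract an aligned window from an encoding
#'
#' @param vectors A `voss_encoding`.
#' @param start 0-based window start offset.
#' @param n Window length; requires `0 <= start` and `start + n <= L`.
#' @return A `voss_encoding` of length `n`.
#' @export
indicator_slice <- function(vectors, start, n) {
  stopifnot(inherits(vectors, "voss_encoding"))
  if (!is_count(start, min = 0L) || !is_count(n, min = 1L) || start + n > vectors$L) {
    stop_bounds("window [", start, ", ", start + n, ") out of range for length ", vectors$L)
  }
  idx <- (start + 1L):(start + n)
  structure(
    list(A = vectors$A[idx], C = vectors$C[idx], G = vectors$G[idx],
         T = vectors$T[idx], L = as.integer(n)),
    class = "voss_encoding"
  )
}

# Inverse mapping, used by tests to check encode/decode identity on N-free
# sequences. Positions with all-zero columns decode to N.
voss_decode <- function(vectors) {
  stopifnot(inherits(vectors, "voss_encoding"))
  chars <- rep("N", vectors$L)
  chars[vectors$A == 1L] <- "A"
  chars[vectors$C == 1L] <- "C"
  chars[vectors$G == 1L] <- "G"
  chars[vectors$T == 1L] <- "T"
  paste(chars, collapse = "")
}
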