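CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                          c("A", "C", "G", "T"), paste0))

#' Specification for a synthetic codon-biased test sequence
#'
#' Describes a background sequence with embedded "coding" regions whose
#' codon usage is skewed toward one dominant codon, producing a tunable
#' period-3 spectral signal: `bias = 0` is indistinguishable from the
#' uniform background, `bias = 1` is a perfect 3-periodic repeat.
#'
#' @param total_len Total sequence length in bp.
#' @param regions Two-column matrix or data.frame of 0-based half-open
#'   `(start, end)` truth intervals; pairwise disjoint, inside the
#'   sequence, lengths divisible by 3 (codon-aligned so the period-3 phase
#'   is coherent).
#' @param bias Mixing weight in `[0, 1]` toward the dominant codon.
#' @param seed Integer RNG seed; all draws are governed by it and the
#'   global RNG state is left untouched.
#' @param dominant_codon Codon favoured inside regions (default `"ATG"`).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(total_len, regions, bias, seed, dominant_codon = "ATG") {
  stopifnot(is_count(total_len, min = 3L))
  regions <- as.data.frame(regions)
  names(regions)[1:2] <- c("start", "end")
  stopifnot(is.numeric(bias), length(bias) == 1L, bias >= 0, bias <= 1)
  stopifnot(is_count(seed, min = 0L) || (is.numeric(seed) && seed == floor(seed)))
  stopifnot(dominant_codon %in% CODONS)
  if (nrow(regions) > 0L) {
    if (any(regions$start < 0 | regions$end > total_len | regions$start >= regions$end)) {
      stop_input("regions must satisfy 0 <= start < end <= total_len")
    }
    if (any((regions$end - regions$start) %% 3 != 0)) {
      stop_input("region lengths must be divisible by 3 (codon-aligned)")
    }
    o <- order(regions$start)
    regions <- regions[o, , drop = FALSE]
    if (nrow(regions) > 1L && any(regions$start[-1L] < regions$end[-nrow(regions)])) {
      stop_input("regions must be pairwise disjoint")
    }
  }
  structure(
    list(total_len = as.integer(total_len), regions = regions,
         bias = bias, seed = as.integer(seed), dominant_codon = dominant_codon),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic sequence with codon-biased regions
#'
#' Background positions are drawn i.i.d. uniform over `{A, C, G, T}`.
#' Inside each truth region the sequence is drawn codon by codon: with
#' probability `bias` the dominant codon, otherwise a codon uniform over
#' all 64 (so `bias = 0` reduces exactly to the background distribution).
#' Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param id Identifier for the generated sequence.
#' @return List with `seq` (a [dna_seq()]) and `truth` (the spec's regions
#'   as `genomic_intervals`, labelled `region1..k`).
#' @export
generate_synthetic <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  chars <- with_seed(spec$seed, {
    chars <- sample(c("A", "C", "G", "T"), spec$total_len, replace = TRUE)
    if (nrow(spec$regions) > 0L) {
      for (i in seq_len(nrow(spec$regions))) {
        s <- spec$regions$start[i]
        e <- spec$regions$end[i]
        ncod <- (e - s) / 3
        dom <- stats::runif(ncod) < spec$bias
        codons <- ifelse(dom, spec$dominant_codon,
                         sample(CODONS, ncod, replace = TRUE))
        chars[(s + 1):e] <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
      }
    }
    chars
  })
  truth <- if (nrow(spec$regions) > 0L) {
    genomic_intervals(seq_id = id, start = spec$regions$start, end = spec$regions$end,
                      label = paste0("region", seq_len(nrow(spec$regions))))
  } else {
    genomic_intervals(character(0), numeric(0), numeric(0))
  }
  list(seq = dna_seq(paste(chars, collapse = ""), id = id), truth = truth)
}

#' HFE2 exon intervals (chromosome 1, GRCh37)
#'
#' The five exons of the human hemochromatosis type 2 (HFE2) gene used as
#' the package's built-in real-gene interval fixture, in the internal
#' 0-based half-open convention so that `end - start` reproduces the
#' published exon lengths (236, 186, 37, 560, 1232 bp). Exon 3a is nested
#' inside exon 3b (two transcript variants), so merging yields four
#' distinct coding regions.
#'
#' @return A `genomic_intervals` data.frame of the five exons, sorted by
#'   start.
#' @examples
#' ex <- hfe2_exons()
#' ex$end - ex$start
#' nrow(merge_intervals(ex))  # 4
#' @export
hfe2_exons <- function() {
  genomic_intervals(
    seq_id = "chr1",
    start = c(145413191, 145414693, 145415278, 145415278, 145416313),
    end   = c(145413427, 145414879, 145415315, 145415838, 145417545),
    label = c("exon1", "exon2", "exon3a", "exon3b", "exon4")
  )
}

#' End-to-end detection benchmark on synthetic sequences
#'
#' For each seed: generate a synthetic sequence with `n_regions` embedded
#' codon-biased regions, scan it, call regions, and evaluate against the
#' truth intervals. Regions are placed evenly with equal flanking gaps.
#'
#' @param seeds Integer vector of generator seeds.
#' @param total_len Sequence length in bp.
#' @param n_regions Number of embedded regions.
#' @param region_len Region length in bp (divisible by 3).
#' @param bias Codon-usage skew in `[0, 1]`.
#' @param config A [scan_config()].
#' @param k_sigma,min_len,merge_gap Passed to [call_regions()].
#' @param min_overlap_frac Passed to [evaluate_calls()].
#' @return List with `mean_recall`, `mean_precision` and a per-seed
#'   data.frame `per_seed`.
#' @export
detection_benchmark <- function(seeds = 0:9, total_len = 20000L, n_regions = 3L,
                                region_len = 900L, bias = 0.8,
                                config = scan_config(),
                                k_sigma = 2, min_len = 30L, merge_gap = 50L,
                                min_overlap_frac = 0.5) {
  gap <- floor((total_len - n_regions * region_len) / (n_regions + 1))
  starts <- gap * seq_len(n_regions) + region_len * (seq_len(n_regions) - 1L)
  regions <- cbind(start = starts, end = starts + region_len)
  per_seed <- data.frame(seed = seeds, recall = NA_real_, precision = NA_real_,
                         n_calls = NA_integer_)
  for (i in seq_along(seeds)) {
    sim <- generate_synthetic(
      synthetic_spec(total_len, regions, bias, seed = seeds[i])
    )
    track <- scan(sim$seq, config)
    calls <- call_regions(track, k_sigma = k_sigma, min_len = min_len,
                          merge_gap = merge_gap)
    ev <- evaluate_calls(calls, sim$truth, min_overlap_frac = min_overlap_frac)
    per_seed$recall[i] <- ev$recall
    per_seed$precision[i] <- ev$precision
    per_seed$n_calls[i] <- ev$n_calls
  }
  list(mean_recall = mean(per_seed$recall),
       mean_precision = mean(per_seed$precision),
       per_seed = per_seed)
}
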