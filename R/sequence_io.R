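IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a validated DNA sequence record
#'
#' A `dna_seq` holds an identifier and a residue string over the alphabet
#' `{A, C, G, T, N}`. Input is passed through [normalize_sequence()], so
#' lower case, `U` and (by default) IUPAC ambiguity codes are accepted.
#'
#' @param residues Character scalar of residues (any case; whitespace ignored).
#' @param id Character scalar identifier.
#' @param strict If `TRUE`, ambiguity codes other than `N` are rejected
#'   instead of being mapped to `N`.
#' @return An object of class `dna_seq` with fields `id`, `residues` and
#'   `length` (bp).
#' @examples
#' s <- dna_seq("acgtacgt", id = "demo")
#' s$length
#' @export
dna_seq <- function(residues, id = "seq", strict = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- normalize_sequence(residues, strict = strict)
  structure(
    list(id = as.character(id), residues = res, length = nchar(res)),
    class = "dna_seq"
  )
}

#' @export
print.dna_seq <- function(x, ...) {
  preview <- if (x$length > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat(sprintf("<dna_seq> %s: %d bp\n  %s\n", x$id, x$length, preview))
  invisible(x)
}

as_dna_seq <- function(x, id = "seq") {
  if (inherits(x, "dna_seq")) return(x)
  if (is.character(x) && length(x) == 1L) return(dna_seq(x, id = id))
  stop_input("expected a dna_seq or a single character string")
}

#' Normalize a raw nucleotide string
#'
#' Uppercases, strips whitespace, maps `U` to `T` (so RNA-derived FASTA
#' works), and handles IUPAC ambiguity codes: by default every code other
#' than `N` is mapped to `N` (with a warning); in strict mode they are
#' rejected. Any character outside the IUPAC nucleotide alphabet is a
#' format error naming the character. The function is idempotent.
#'
#' @param raw Character scalar.
#' @param strict Reject ambiguity codes other than `N`?
#' @return Normalized character scalar over `{A, C, G, T, N}`.
#' @examples
#' normalize_sequence("acgu")    # "ACGT"
#' normalize_sequence("ACRT")    # "ACNT", with a warning
#' @export
normalize_sequence <- function(raw, strict = FALSE) {
  stopifnot(is.character(raw), length(raw) == 1L)
  x <- toupper(gsub("[ \t\r\n\f\v]+", "", raw))
  x <- chartr("U", "T", x)
  bad <- regmatches(x, regexpr(sprintf("[^ACGTN%s]", paste(IUPAC_AMBIG, collapse = "")), x))
  if (length(bad) > 0L) {
    stop_format("invalid nucleotide character '", bad, "' (not an IUPAC code)")
  }
  if (grepl(sprintf("[%s]", paste(IUPAC_AMBIG, collapse = "")), x)) {
    if (strict) {
      amb <- regmatches(x, regexpr(sprintf("[%s]", paste(IUPAC_AMBIG, collapse = "")), x))
      stop_format("ambiguity code '", amb, "' not allowed in strict mode")
    }
    warning("ambiguity codes mapped to N", call. = FALSE)
    x <- chartr(paste(IUPAC_AMBIG, collapse = ""), strrep("N", length(IUPAC_AMBIG)), x)
  }
  x
}

#' Read DNA sequences from a FASTA file
#'
#' FASTA parsing (headers, wrapped lines, multiple records) is delegated to
#' Biostrings; residues are then normalized with [normalize_sequence()] so
#' the package's alphabet policy applies uniformly. Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @param strict Passed to [normalize_sequence()].
#' @return List of [dna_seq()] records, one per FASTA entry.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot open FASTA file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop_format("empty FASTA file (line 1): ", path)
  if (!startsWith(first, ">")) {
    stop_format("malformed FASTA header at line 1 (expected '>'): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_format("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- dna_seq(as.character(set[[i]]), id = ids[i], strict = strict)
  }
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs A `dna_seq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$residues, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open throughout the package, matching BED:
#' interval length is `end - start`.
#'
#' @param seq_id Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, exclusive; must satisfy `start < end`.
#' @param label Optional character vector.
#' @param score Optional numeric vector.
#' @return A `data.frame` with class `genomic_intervals`.
#' @export
genomic_intervals <- function(seq_id, start, end, label = NA_character_, score = NA_real_) {
  n <- max(length(seq_id), length(start), length(end))
  df <- data.frame(
    seq_id = rep_len(as.character(seq_id), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    label = rep_len(as.character(label), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0L) {
    stop_format("invalid interval at row ", bad[1L], ": need 0 <= start < end, got [",
                df$start[bad[1L]], ", ", df$end[bad[1L]], ")")
  }
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

interval_lengths <- function(intervals) intervals$end - intervals$start

#' Read an interval table (BED3+)
#'
#' Coordinates are taken as 0-based half-open per the BED convention.
#' Column 4, when present, becomes the label; column 5 the score.
#'
#' @param path Path to a BED3/BED4/BED5 file.
#' @return A `genomic_intervals` data.frame in file order (possibly empty).
#' @export
read_interval_table <- function(path) {
  if (!file.exists(path)) stop("cannot open BED file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track\\b|browser\\b)", lines))
  if (length(keep) == 0L) {
    return(genomic_intervals(character(0), numeric(0), numeric(0) + 1))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ln <- keep[i]
    if (length(f) < 3L) stop_format("BED line ", ln, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e)) stop_format("BED line ", ln, ": non-numeric coordinates")
    if (s >= e) stop_format("BED line ", ln, ": start >= end (", f[2L], " >= ", f[3L], ")")
  }
  genomic_intervals(
    seq_id = vapply(fields, `[`, character(1), 1L),
    start = as.numeric(vapply(fields, `[`, character(1), 2L)),
    end = as.numeric(vapply(fields, `[`, character(1), 3L)),
    label = vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, character(1)),
    score = suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5L) f[5L] else NA_character_, character(1))
    ))
  )
}

#' Write an interval table as BED
#'
#' Emits BED4 when labels are present (BED5 when scores are too), else BED3.
#'
#' @param intervals A `genomic_intervals` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(intervals, path) {
  cols <- list(intervals$seq_id, fmt_num(intervals$start), fmt_num(intervals$end))
  if (!all(is.na(intervals$label)) || !all(is.na(intervals$score))) {
    cols <- c(cols, list(ifelse(is.na(intervals$label), ".", intervals$label)))
    if (!all(is.na(intervals$score))) {
      cols <- c(cols, list(ifelse(is.na(intervals$score), "0", fmt_num(intervals$score))))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a power track in bedGraph or fixed-step WIG format
#'
#' bedGraph lines are `seq_id<TAB>start<TAB>end<TAB>value` with 0-based
#' half-open coordinates; each window's anchor position spans `step` bases.
#' WIG output uses a `fixedStep` declaration (1-based start, as WIG
#' requires) and is only valid because track spacing is uniform.
#'
#' @param track A `power_track` from [scan()].
#' @param path Output path.
#' @param format `"bedgraph"` or `"wig"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  stopifnot(inherits(track, "power_track"))
  if (length(track$positions) == 0L) stop_input("refusing to write an empty track")
  step <- track$config$step
  if (format == "bedgraph") {
    lines <- paste(track$seq_id, fmt_num(track$positions),
                   fmt_num(track$positions + step), fmt_num(track$values), sep = "\t")
  } else {
    lines <- c(
      sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
              track$seq_id, as.integer(track$positions[1L]) + 1L,
              as.integer(step), as.integer(step)),
      fmt_num(track$values)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a power track written by [write_track()]
#'
#' Supports bedGraph and fixed-step WIG. The anchor/value pairs round-trip
#' exactly; scan configuration other than the step cannot be recovered from
#' the file and is reconstructed minimally.
#'
#' @param path Path to a bedGraph or WIG file.
#' @return A `power_track` (with a minimal config).
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("cannot open track file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L) stop_format("empty track file: ", path)
  if (grepl("^fixedStep", lines[1L])) {
    hdr <- lines[1L]
    get_kv <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
    seq_id <- get_kv("chrom")
    start1 <- as.numeric(get_kv("start"))
    step <- as.numeric(get_kv("step"))
    values <- as.numeric(lines[-1L])
    positions <- start1 - 1 + step * (seq_len(length(values)) - 1L)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L)) stop_format("malformed bedGraph line in ", path)
    seq_id <- fields[[1L]][1L]
    positions <- as.numeric(vapply(fields, `[`, character(1), 2L))
    ends <- as.numeric(vapply(fields, `[`, character(1), 3L))
    values <- as.numeric(vapply(fields, `[`, character(1), 4L))
    step <- if (length(positions) > 1L) positions[2L] - positions[1L] else ends[1L] - positions[1L]
  }
  new_power_track(seq_id = seq_id, positions = positions, values = values,
                  config = scan_config(window = 3L, step = as.integer(step),
                                       anchor = "start"))
}
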