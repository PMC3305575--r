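# Internal helpers shared across the pipeline stages.

#' Derive a per-stage random seed from a master seed
#'
#' Each pipeline stage draws from its own seed stream so that stages can be
#' re-run independently yet a single master seed fixes every emitted file.
#' Streams are kept below 2^31 - 1 so they are always valid R integer seeds.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character); hashed into an offset.
#' @return An integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  off <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + off) %% 2147483647L)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

#' Hamming distance between equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Merge possibly-overlapping intervals
#'
#' Intervals are half-open `[start, end)` (BED convention). Output is sorted
#' by contig then start, with touching or overlapping intervals coalesced.
#'
#' @param intervals Tibble with columns `contig`, `start`, `end`.
#' @return Tibble of merged intervals.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  intervals |>
    arrange(.data$contig, .data$start, .data$end) |>
    group_by(.data$contig) |>
    mutate(.grp = cumsum(.data$start > cummax(dplyr::lag(.data$end,
                                                         default = -Inf)))) |>
    group_by(.data$contig, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("contig", "start", "end")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate an in-frame DNA coding sequence to amino acids
#'
#' Standard genetic code; stop codons are rendered as `*`.
#' @keywords internal
translate_cds <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n == 0) return("")
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Depth of sorted read intervals at query positions
#'
#' Counts reads (rows of `starts`/`ends`, 1-based inclusive) covering each
#' position, using two binary searches rather than an explicit pileup.
#' @keywords internal
interval_depth <- function(starts, ends, pos) {
  if (length(starts) == 0) return(rep(0L, length(pos)))
  n_start <- findInterval(pos, sort(starts))        # starts <= pos
  n_ended <- findInterval(pos - 1L, sort(ends))     # ends < pos
  as.integer(n_start - n_ended)
}

#' Phred quality characters to error probabilities (Phred+33)
#' @keywords internal
qual_to_error <- function(qchars) {
  10^(-(utf8ToInt(qchars) - 33) / 10)
}

phred_chr <- function(q) intToUtf8(q + 33L, multiple = FALSE)
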