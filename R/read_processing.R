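# Read-level processing: barcode demultiplexing of pooled reads and the two
# read filters applied before variant calling — PCR-duplicate removal
# (best mapping quality per coordinate pair) and the mapping-quality cutoff.
# The pipeline applies duplicate removal first, then the mapq filter.

#' Validate a barcode manifest
#'
#' Barcodes must be unique, equal length, and pairwise Hamming distance
#' strictly greater than `2 * max_mismatch`, which guarantees every tag
#' within `max_mismatch` of a barcode has a unique nearest barcode.
#'
#' @param manifest Tibble (sample, barcode) with attribute `max_mismatch`.
#' @return The manifest, invisibly valid; aborts on violation.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(all(c("sample", "barcode") %in% names(manifest)))
  mm <- attr(manifest, "max_mismatch") %||% 0L
  bc <- manifest$barcode
  if (anyDuplicated(bc)) abort("barcodes must be unique.")
  if (length(unique(nchar(bc))) != 1) abort("barcodes must be equal length.")
  if (length(bc) > 1) {
    for (i in seq_len(length(bc) - 1)) {
      for (j in seq(i + 1, length(bc))) {
        if (hamming(bc[i], bc[j]) <= 2L * mm) {
          abort(sprintf(
            "barcodes %s and %s are within 2*max_mismatch = %d mismatches.",
            bc[i], bc[j], 2L * mm))
        }
      }
    }
  }
  invisible(manifest)
}

#' Assign pooled reads to samples by barcode tag
#'
#' Each read is assigned to the unique sample whose barcode lies within
#' `max_mismatch` of the read's tag; reads matching no barcode are counted
#' as unassigned. The manifest's pairwise-distance invariant makes the
#' assignment a partition: no tag can match two barcodes.
#'
#' @param reads Read tibble with a `tag` column.
#' @param manifest Barcode manifest (validated on entry).
#' @return List: `reads` (assigned reads with a `sample` column),
#'   `n_unassigned`, and `report` (tibble sample, n_assigned).
#' @export
assign_barcodes <- function(reads, manifest) {
  validate_manifest(manifest)
  mm <- attr(manifest, "max_mismatch") %||% 0L
  tags <- unique(reads$tag)
  bmat <- do.call(rbind, strsplit(manifest$barcode, ""))
  assign_one <- function(tag) {
    tchr <- strsplit(tag, "")[[1]]
    if (length(tchr) != ncol(bmat)) return(NA_character_)
    d <- rowSums(bmat != matrix(tchr, nrow(bmat), ncol(bmat), byrow = TRUE))
    hit <- which(d <= mm)
    if (length(hit) == 1) manifest$sample[hit] else NA_character_
  }
  lookup <- vapply(tags, assign_one, character(1))
  sample <- unname(lookup[reads$tag])
  assigned <- reads |> mutate(sample = sample) |> filter(!is.na(sample))
  report <- manifest |>
    left_join(assigned |> count(.data$sample, name = "n_assigned"),
              by = "sample") |>
    mutate(n_assigned = ifelse(is.na(.data$n_assigned), 0L,
                               .data$n_assigned)) |>
    select("sample", "n_assigned")
  list(reads = assigned, n_unassigned = sum(is.na(sample)), report = report)
}

#' Remove PCR duplicates
#'
#' Reads sharing mapped coordinates are presumed PCR duplicates of one
#' fragment: within each `(contig, start, end)` group (optionally also
#' strand), only the read with the top mapping quality is retained. Mapq
#' ties are broken by the lexicographically first `read_id` so the result
#' is deterministic. Output is coordinate-sorted.
#'
#' @param reads Reads of a single sample.
#' @param by_strand Also split duplicate groups by strand (default FALSE:
#'   duplicates are defined by coordinates alone).
#' @return The retained reads.
#' @export
remove_duplicates <- function(reads, by_strand = FALSE) {
  keys <- c("contig", "start", "end", if (by_strand) "strand")
  if (!"read_id" %in% names(reads)) {
    reads <- reads |> mutate(read_id = sprintf("r%07d", row_number()))
  }
  reads |>
    arrange(dplyr::across(dplyr::all_of(keys)), desc(.data$mapq),
            .data$read_id) |>
    distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE) |>
    arrange(.data$contig, .data$start, .data$end)
}

#' Filter reads on mapping quality
#'
#' Retains reads with `mapq >= min_mapq` (a mapq exactly at the threshold
#' passes), preserving input order.
#'
#' @param reads Read tibble.
#' @param min_mapq Minimum mapping quality (default 50).
#' @return The retained reads.
#' @export
filter_mapq <- function(reads, min_mapq = 50) {
  reads |> filter(.data$mapq >= min_mapq)
}
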