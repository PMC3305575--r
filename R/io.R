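# Plain-text interchange: the internal aligned-read dialect, phenotype and
# truth tables, barcode manifests, PED/MAP and VCF writers live with their
# modules; the generic table formats are here.

READS_COLS <- c(read_id = "c", tag = "c", contig = "c", start = "i",
                end = "i", strand = "c", mapq = "i", bases = "c",
                quals = "c")

#' Write/read the internal aligned-read table
#'
#' Tab-separated dialect mirroring coordinate-sorted alignment records:
#' `read_id, tag, contig, start (1-based), end (inclusive), strand (+/-),
#' mapq, bases, quals (Phred+33)`. A `sample` column is present after
#' demultiplexing; a `truth_sample` column may be present in simulator
#' output.
#'
#' @param reads Read tibble.
#' @param path Output file.
#' @return `path` (write) or the read tibble.
#' @export
write_reads <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  spec <- ifelse(hdr %in% names(READS_COLS), READS_COLS[hdr], "c")
  readr::read_tsv(path, col_types = paste(spec, collapse = ""))
}

#' Write/read a phenotype table
#'
#' Two columns: `sample`, `status` (1 = control, 2 = case; PLINK coding).
#' @param phenotypes Tibble (sample, status).
#' @param path File path.
#' @return `path` or the tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes[, c("sample", "status")], path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, col_types = "ci")
}

#' Write/read a truth set
#'
#' Emits `<prefix>.sites.tsv` (site table) and `<prefix>.genotypes.tsv`
#' (long table: site_id, sample, genotype as minor-allele dosage).
#' @param truth A `truth_set`.
#' @param prefix Output path prefix.
#' @return `prefix` or a `truth_set`.
#' @export
write_truth <- function(truth, prefix) {
  readr::write_tsv(truth$sites, paste0(prefix, ".sites.tsv"))
  long <- as_tibble(as.table(truth$genotypes), .name_repair = "minimal") |>
    setNames(c("sample", "site_id", "genotype"))
  readr::write_tsv(long, paste0(prefix, ".genotypes.tsv"))
  invisible(prefix)
}

#' @rdname write_truth
#' @param phenotypes Phenotype tibble to reattach when reading.
#' @export
read_truth <- function(prefix, phenotypes) {
  sites <- readr::read_tsv(paste0(prefix, ".sites.tsv"),
                           col_types = readr::cols(pos = "i",
                                                   .default = "?"))
  long <- readr::read_tsv(paste0(prefix, ".genotypes.tsv"),
                          col_types = "cci")
  wide <- long |> tidyr::pivot_wider(names_from = "site_id",
                                     values_from = "genotype")
  geno <- as.matrix(wide[, -1])
  rownames(geno) <- wide$sample
  structure(list(sites = sites, genotypes = geno[, sites$site_id,
                                                 drop = FALSE],
                 phenotypes = phenotypes),
            class = "truth_set")
}

#' Write/read a barcode manifest
#'
#' TSV with columns `sample`, `barcode`; `max_mismatch` is carried in a
#' `#max_mismatch=` header line. Reading re-validates the pairwise-distance
#' invariant (see [validate_manifest()]).
#' @param manifest Manifest tibble from [make_barcode_manifest()].
#' @param path File path.
#' @return `path` or the validated manifest.
#' @export
write_manifest <- function(manifest, path) {
  mm <- attr(manifest, "max_mismatch") %||% 0L
  readr::write_lines(sprintf("#max_mismatch=%d", mm), path)
  readr::write_tsv(manifest, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  mm <- as.integer(sub("#max_mismatch=", "", first, fixed = TRUE))
  m <- readr::read_tsv(path, skip = 1, col_types = "cc")
  validate_manifest(structure(m, max_mismatch = mm))
}
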