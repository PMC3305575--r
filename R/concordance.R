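# Agreement statistics between callsets and genotype sets: repeat-run
# callset overlap and cross-platform genotype concordance stratified by
# genotype class.

#' Callset overlap
#'
#' Fraction of callset B's variants (keyed by contig, pos, ref, alt) that
#' are also present in callset A — the repeat-run reproducibility measure.
#'
#' @param callset_a,callset_b Call tibbles with `contig`, `pos`, `ref`,
#'   `alt` (PASS calls are expected; rows are deduplicated on the key).
#' @return Tibble (n_b, n_shared, percent) with percent to one decimal.
#' @export
callset_overlap <- function(callset_a, callset_b) {
  key <- function(d) unique(paste(d$contig, d$pos, d$ref, d$alt))
  kb <- key(callset_b)
  if (length(kb) == 0) abort("callset_b is empty.")
  n_shared <- sum(kb %in% key(callset_a))
  tibble(n_b = length(kb), n_shared = n_shared,
         percent = round(100 * n_shared / length(kb), 1))
}

#' Genotype agreement between two platforms
#'
#' Pairs genotypes over shared `(sample, site_id)` keys, excludes pairs
#' missing on either side, and stratifies by the genotype in set A (the
#' validation platform): homozygous reference versus variant-carrying (het
#' or homvar). Agreement requires identical genotypes. The overall rate is
#' symmetric in the inputs; the stratification follows input A by
#' convention.
#'
#' @param genotypes_a,genotypes_b Long tibbles (sample, site_id, genotype)
#'   with genotype as dosage 0/1/2 or NA.
#' @return Tibble with one row per stratum (homref, variant) and an
#'   `overall` row: n_compared, n_agreeing, percent (one decimal).
#' @export
genotype_agreement <- function(genotypes_a, genotypes_b) {
  j <- inner_join(genotypes_a, genotypes_b, by = c("sample", "site_id"),
                  suffix = c("_a", "_b")) |>
    filter(!is.na(.data$genotype_a), !is.na(.data$genotype_b))
  if (nrow(j) == 0) abort("no shared non-missing (sample, site) pairs.")
  j <- j |>
    mutate(stratum = ifelse(.data$genotype_a == 0L, "homref", "variant"),
           agree = .data$genotype_a == .data$genotype_b)
  strata <- j |>
    group_by(.data$stratum) |>
    summarise(n_compared = dplyr::n(), n_agreeing = sum(.data$agree),
              .groups = "drop")
  bind_rows(strata,
            tibble(stratum = "overall", n_compared = nrow(j),
                   n_agreeing = sum(j$agree))) |>
    mutate(percent = round(100 * .data$n_agreeing / .data$n_compared, 1))
}
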