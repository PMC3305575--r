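# Pileup-based variant calling. Pileups are built only at positions where a
# sample shows at least one mismatch against the panel reference (the role
# classical PILEUP files played for sites with mismatches); candidate calls
# are then screened by depth, allele balance, strand bias and a
# Phred-scaled call quality from a binomial sequencing-error model.

#' Calling parameters
#'
#' @param min_base_qual Base observations below this Phred quality are
#'   excluded from pileup counts.
#' @param min_alt_reads Minimum variant-supporting reads for a candidate
#'   call.
#' @param hom_threshold Genotype boundary: allele balance below it is called
#'   heterozygous, at or above homozygous-variant.
#' @param min_ab Allele-balance QC floor: calls with allele balance strictly
#'   below fail `low_allele_balance` (a balance exactly at the floor
#'   passes).
#' @param min_depth Depth required for a confident call; lower depth fails
#'   `low_depth`.
#' @param min_call_quality Phred-scaled call-quality floor; lower fails
#'   `low_quality`.
#' @return List of class `call_params`.
#' @export
call_params <- function(min_base_qual = 20, min_alt_reads = 2,
                        hom_threshold = 0.8, min_ab = 0.20, min_depth = 10,
                        min_call_quality = 20) {
  structure(as.list(environment()), class = "call_params")
}

#' Build per-site pileups over the target
#'
#' Scans each sample's reads for mismatches against the panel reference and
#' returns the full column of base observations (reference and variant, with
#' base quality, strand and mapq) at every position where the sample shows
#' at least one mismatch. Observations below `min_base_qual` are excluded
#' from the pileup. Reads on contigs absent from the panel are dropped and
#' counted in the `n_offpanel` attribute (with a warning).
#'
#' @param reads Demultiplexed, filtered reads with a `sample` column.
#' @param panel A `seq_panel`.
#' @param min_base_qual Minimum base quality for an observation to count.
#' @return Observation tibble (sample, contig, pos, ref, base, qual, strand,
#'   mapq) of class `pileup`.
#' @export
build_pileup <- function(reads, panel, min_base_qual = 20) {
  stopifnot("sample" %in% names(reads))
  onpanel <- reads$contig %in% names(panel$reference)
  n_off <- sum(!onpanel)
  if (n_off > 0) {
    warn(sprintf("%d reads on contigs absent from the panel were dropped.",
                 n_off))
  }
  reads <- reads[onpanel, , drop = FALSE]

  per <- reads |>
    group_by(.data$sample, .data$contig) |>
    group_map(function(rr, key) {
      ref <- panel$reference[[key$contig]]
      widths <- rr$end - rr$start + 1L
      big_read <- paste(rr$bases, collapse = "")
      big_ref <- paste(substring(ref, rr$start, rr$end), collapse = "")
      mism <- which(charToRaw(big_read) != charToRaw(big_ref))
      if (length(mism) == 0) return(NULL)
      cum <- cumsum(widths)
      ridx <- findInterval(mism - 1L, cum) + 1L
      gpos <- rr$start[ridx] + (mism - (cum[ridx] - widths[ridx])) - 1L
      cp <- sort(unique(gpos))
      # all reads covering each candidate position
      ord <- order(rr$start)
      st <- rr$start[ord]
      en <- rr$end[ord]
      j_hi <- findInterval(en, cp)
      j_lo <- findInterval(st - 1L, cp) + 1L
      cnt <- pmax(j_hi - j_lo + 1L, 0L)
      keep <- cnt > 0L
      rsel <- ord[keep][rep(seq_len(sum(keep)), cnt[keep])]
      sidx <- sequence(cnt[keep], from = j_lo[keep])
      pos <- cp[sidx]
      off <- pos - rr$start[rsel] + 1L
      base <- substr(rr$bases[rsel], off, off)
      qchr <- substr(rr$quals[rsel], off, off)
      tibble(sample = key$sample, contig = key$contig, pos = pos,
             ref = substring(ref, pos, pos),
             base = base,
             qual = utf8ToInt(paste(qchr, collapse = "")) - 33L,
             strand = rr$strand[rsel], mapq = rr$mapq[rsel])
    }, .keep = FALSE)

  obs <- bind_rows(per) |>
    filter(.data$qual >= min_base_qual) |>
    arrange(.data$sample, .data$contig, .data$pos)
  attr(obs, "n_offpanel") <- n_off
  class(obs) <- c("pileup", class(obs))
  obs
}

summarise_sites <- function(obs, params) {
  obs |>
    group_by(.data$sample, .data$contig, .data$pos, .data$ref) |>
    summarise(
      depth = dplyr::n(),
      alt = {
        tb <- sort(table(.data$base[.data$base != .data$ref]),
                   decreasing = TRUE)
        if (length(tb) == 0) NA_character_ else names(tb)[1]
      },
      n_alt_passing = {
        tb <- table(.data$base[.data$base != .data$ref])
        sum(tb >= params$min_alt_reads)
      },
      alt_reads = sum(.data$base == alt[1]),
      ref_reads = sum(.data$base == .data$ref),
      alt_plus = sum(.data$base == alt[1] & .data$strand == "+"),
      alt_minus = sum(.data$base == alt[1] & .data$strand == "-"),
      cov_plus = sum(.data$strand == "+"),
      cov_minus = sum(.data$strand == "-"),
      mean_err = mean(10^(-.data$qual / 10)),
      .groups = "drop"
    )
}

finish_calls <- function(sites, params) {
  sites |>
    filter(!is.na(.data$alt), .data$alt_reads >= params$min_alt_reads) |>
    mutate(
      var_type = dplyr::case_when(
        .data$alt == "-" ~ "deletion",
        stringr::str_starts(.data$alt, stringr::fixed("+")) ~ "insertion",
        TRUE ~ "SNV"),
      allele_balance = .data$alt_reads /
        (.data$ref_reads + .data$alt_reads),
      multiallelic = .data$n_alt_passing > 1L,
      call_quality = -10 * log10(
        pmax(pbinom(.data$alt_reads - 1L, .data$depth, .data$mean_err,
                    lower.tail = FALSE), 1e-300)),
      genotype = ifelse(.data$allele_balance < params$hom_threshold,
                        "het", "homvar")
    ) |>
    select("sample", "contig", "pos", "ref", "alt", "var_type", "depth",
           "ref_reads", "alt_reads", "allele_balance", "alt_plus",
           "alt_minus", "cov_plus", "cov_minus", "call_quality", "genotype",
           "multiallelic")
}

#' Call candidate variants from a pileup
#'
#' A candidate call is emitted at every site with at least
#' `min_alt_reads` variant-supporting observations. The majority
#' non-reference allele is called (multi-allelic sites are flagged), allele
#' balance is `alt / (ref + alt)` reads, and call quality is the
#' Phred-scaled probability of seeing at least that many variant reads from
#' sequencing error alone, under a binomial model whose error rate is the
#' mean quality-implied error of the site's observations. Genotype is
#' heterozygous below the `hom_threshold` allele balance, homozygous-variant
#' otherwise.
#'
#' @param pileup Observation tibble from [build_pileup()].
#' @param params A [call_params()] list.
#' @return Candidate call tibble (no QC verdict yet; see [qc_filter()]).
#' @export
call_variants <- function(pileup, params = call_params()) {
  finish_calls(summarise_sites(pileup, params), params)
}

#' Call a single pileup site
#'
#' Single-site convenience wrapper around the same logic as
#' [call_variants()].
#'
#' @param site_obs Observations of one (sample, contig, pos): columns
#'   `sample`, `contig`, `pos`, `ref`, `base`, `qual`, `strand`, `mapq`.
#' @param params A [call_params()] list.
#' @return A one-row call tibble, or a zero-row tibble when no allele
#'   reaches `min_alt_reads`.
#' @export
call_site <- function(site_obs, params = call_params()) {
  stopifnot(length(unique(site_obs$pos)) <= 1)
  call_variants(site_obs, params)
}

#' Apply variant quality control
#'
#' Implements the post-calling QC: a call fails `low_allele_balance` when
#' its allele balance is below 20% (exactly 20% passes), `strand_bias` when
#' the variant allele was not observed on both the forward and reverse
#' orientation, `low_depth` below 10 reads, and `low_quality` below the
#' call-quality floor. Sites whose entire coverage is single-stranded
#' cannot satisfy the strand criterion and fail it too, but are flagged
#' separately in `single_strand_site` so users may exempt them. Failed
#' calls are retained with their reasons: downstream genotyping needs them
#' to distinguish missing from homozygous-reference.
#'
#' @param calls Call tibble from [call_variants()].
#' @param params A [call_params()] list.
#' @return Calls with `qc_status` (PASS/FAIL), `fail_reasons`
#'   (comma-joined) and `single_strand_site` columns.
#' @export
qc_filter <- function(calls, params = call_params()) {
  reasons <- list(
    low_allele_balance = calls$allele_balance < params$min_ab,
    strand_bias = calls$alt_plus == 0L | calls$alt_minus == 0L,
    low_depth = calls$depth < params$min_depth,
    low_quality = calls$call_quality < params$min_call_quality
  )
  rmat <- do.call(cbind, reasons)
  fail_reasons <- if (nrow(calls) == 0) character(0) else {
    apply(rmat, 1, function(r) paste(names(reasons)[r], collapse = ","))
  }
  calls |>
    mutate(qc_status = ifelse(fail_reasons == "", "PASS", "FAIL"),
           fail_reasons = fail_reasons,
           single_strand_site = .data$cov_plus == 0L | .data$cov_minus == 0L)
}
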