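# Variant consequence classification against the panel's toy gene model,
# novelty lookup against user-supplied known-variant tables, and the
# site-frequency-spectrum summary by functional class.

CONSEQUENCE_SEVERITY <- c(nonsense = 1, frameshift = 2, missense = 3,
                          inframe_indel = 4, synonymous = 5, utr = 6,
                          intronic = 7)

# Per-gene map from genomic position to CDS index (1 = first coding base in
# transcript order), honoring strand.
cds_map <- function(panel, gene) {
  gc <- panel$cds |> filter(.data$gene == !!gene) |> arrange(.data$start)
  strand <- gc$strand[1]
  pos <- unlist(Map(seq.int, gc$start, gc$end), use.names = FALSE)
  if (strand == "-") pos <- rev(pos)
  tibble(contig = gc$contig[1], gene = gene, strand = strand,
         pos = pos, cds_idx = seq_along(pos))
}

panel_cds_map <- function(panel) {
  bind_rows(lapply(panel$genes$gene, function(g) cds_map(panel, g)))
}

# CDS nucleotide sequence of a gene in transcript order (coding strand).
gene_cds_seq <- function(panel, gene) {
  gc <- panel$cds |> filter(.data$gene == !!gene) |> arrange(.data$start)
  s <- paste(substring(panel$reference[gc$contig], gc$start, gc$end),
             collapse = "")
  if (gc$strand[1] == "-") revcomp(s) else s
}

#' Classify SNVs by coding consequence
#'
#' Each variant's codon is translated before and after the substitution,
#' honoring transcript strand (alleles are reverse-complemented for genes on
#' the minus strand). Positions inside an exon but outside the CDS are `utr`;
#' targeted positions outside exons are `intronic`. A variant hitting several
#' transcripts gets the most severe consequence (nonsense > frameshift >
#' missense > inframe_indel > synonymous > utr > intronic).
#'
#' @param variants Tibble with columns `contig`, `pos`, `ref`, `alt`.
#' @param panel A `seq_panel` providing gene model and reference.
#' @return The input with `gene`, `consequence` and `protein_change`
#'   (e.g. `p.R88X`, `X` denoting a gained stop) columns added.
#' @export
classify_snv <- function(variants, panel) {
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  ref_base <- substring(panel$reference[variants$contig], variants$pos,
                        variants$pos)
  bad <- !is.na(ref_base) & ref_base != variants$ref
  if (any(bad)) {
    abort(sprintf("ref allele mismatch with panel reference at %s:%d",
                  variants$contig[bad][1], variants$pos[bad][1]))
  }

  cmap <- panel_cds_map(panel)
  out <- variants |>
    mutate(.row = row_number()) |>
    left_join(cmap, by = c("contig", "pos"), relationship = "many-to-many")

  coding <- out |> filter(!is.na(.data$cds_idx))
  ann <- NULL
  if (nrow(coding) > 0) {
    cds_seqs <- setNames(
      lapply(unique(coding$gene), function(g) gene_cds_seq(panel, g)),
      unique(coding$gene))
    ann <- coding |>
      mutate(
        codon_no = (.data$cds_idx - 1L) %/% 3L + 1L,
        codon_pos = (.data$cds_idx - 1L) %% 3L + 1L,
        alt_cds = ifelse(.data$strand == "-",
                         unname(COMPLEMENT[.data$alt]), .data$alt)
      ) |>
      rowwise() |>
      mutate(
        codon = substr(cds_seqs[[.data$gene]],
                       (.data$codon_no - 1L) * 3L + 1L, .data$codon_no * 3L),
        aa_ref = unname(Biostrings::GENETIC_CODE[.data$codon]),
        mut_codon = {
          m <- .data$codon
          substr(m, .data$codon_pos, .data$codon_pos) <- .data$alt_cds
          m
        },
        aa_alt = unname(Biostrings::GENETIC_CODE[.data$mut_codon]),
        consequence = dplyr::case_when(
          aa_alt == "*" & aa_ref != "*" ~ "nonsense",
          aa_alt == aa_ref ~ "synonymous",
          TRUE ~ "missense"),
        protein_change = paste0("p.", .data$aa_ref, .data$codon_no,
                                ifelse(.data$aa_alt == "*", "X",
                                       .data$aa_alt))
      ) |>
      ungroup() |>
      select(".row", "gene", "consequence", "protein_change")
  }

  # non-coding: utr if inside an exon, intronic otherwise
  noncoding <- out |> filter(is.na(.data$cds_idx)) |> distinct(.data$.row,
                                                               .keep_all = TRUE)
  nc_ann <- NULL
  if (nrow(noncoding) > 0) {
    in_exon <- vapply(seq_len(nrow(noncoding)), function(i) {
      e <- panel$exons |>
        filter(.data$contig == noncoding$contig[i],
               .data$start <= noncoding$pos[i],
               .data$end >= noncoding$pos[i])
      if (nrow(e) > 0) e$gene[1] else NA_character_
    }, character(1))
    nc_ann <- tibble(.row = noncoding$.row,
                     gene = in_exon,
                     consequence = ifelse(is.na(in_exon), "intronic", "utr"),
                     protein_change = NA_character_)
    # attach nearest gene for intronic sites on the same contig
    if (anyNA(in_exon)) {
      ii <- which(is.na(in_exon))
      nearest <- vapply(ii, function(i) {
        g <- panel$exons |> filter(.data$contig == noncoding$contig[i])
        g$gene[which.min(pmin(abs(g$start - noncoding$pos[i]),
                              abs(g$end - noncoding$pos[i])))]
      }, character(1))
      nc_ann$gene[ii] <- nearest
    }
  }

  all_ann <- bind_rows(ann, nc_ann) |>
    mutate(sev = CONSEQUENCE_SEVERITY[.data$consequence]) |>
    group_by(.data$.row) |>
    arrange(.data$sev, .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  variants |>
    mutate(.row = row_number()) |>
    left_join(all_ann |> select(".row", "gene", "consequence",
                                "protein_change"),
              by = ".row") |>
    select(-".row")
}

#' Classify insertions/deletions by coding consequence
#'
#' A CDS-overlapping indel whose length is not a multiple of three is a
#' `frameshift`; a multiple of three is an `inframe_indel`; otherwise the
#' exon/intron classes apply as for SNVs.
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt`; insertion when
#'   `nchar(alt) > nchar(ref)`, deletion when shorter. `pos` anchors the
#'   first affected base.
#' @param panel A `seq_panel`.
#' @return Input with `gene` and `consequence` columns added.
#' @export
classify_indel <- function(variants, panel) {
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  len_change <- abs(nchar(variants$alt) - nchar(variants$ref))
  if (any(len_change == 0)) abort("indel rows must change allele length.")
  span_end <- variants$pos + pmax(nchar(variants$ref) - 1L, 0L)

  hits_cds <- vapply(seq_len(nrow(variants)), function(i) {
    any(panel$cds$contig == variants$contig[i] &
          panel$cds$start <= span_end[i] &
          panel$cds$end >= variants$pos[i])
  }, logical(1))
  hits_exon <- vapply(seq_len(nrow(variants)), function(i) {
    e <- panel$exons |>
      filter(.data$contig == variants$contig[i],
             .data$start <= span_end[i], .data$end >= variants$pos[i])
    if (nrow(e) > 0) e$gene[1] else NA_character_
  }, character(1))

  variants |>
    mutate(gene = hits_exon,
           consequence = dplyr::case_when(
             hits_cds & len_change %% 3 != 0 ~ "frameshift",
             hits_cds ~ "inframe_indel",
             !is.na(hits_exon) ~ "utr",
             TRUE ~ "intronic"))
}

#' Flag variants as known or novel against lookup tables
#'
#' Membership is exact on the normalized `(contig, pos, ref, alt)` key, as
#' when screening calls against dbSNP-style or 1000-Genomes-style tables.
#' Malformed rows (missing any key field) are skipped and counted.
#'
#' @param variants Tibble keyed by `contig`, `pos`, `ref`, `alt`.
#' @param known_tables A tibble or list of tibbles with the same key columns.
#' @return Input plus logical column `novel`; the number of skipped table
#'   rows is attached as attribute `n_skipped`.
#' @export
flag_novelty <- function(variants, known_tables) {
  if (is.data.frame(known_tables)) known_tables <- list(known_tables)
  known <- bind_rows(lapply(known_tables, function(k) {
    k |> select(any_of(c("contig", "pos", "ref", "alt")))
  }))
  n_skipped <- 0L
  if (nrow(known) > 0) {
    ok <- stats::complete.cases(known)
    n_skipped <- sum(!ok)
    known <- known[ok, , drop = FALSE]
  }
  key <- function(d) paste(d$contig, d$pos, toupper(d$ref), toupper(d$alt))
  res <- variants |>
    mutate(novel = if (nrow(known) == 0) TRUE else !(key(variants) %in%
                                                       key(known)))
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Site-frequency spectrum by functional class
#'
#' Bins variant minor-allele frequencies into a singleton bin (exactly one
#' observed minor allele) followed by frequency intervals, and tabulates
#' counts per consequence class with the nonsynonymous/synonymous ratio per
#' bin (NA when no synonymous variants fall in a bin).
#'
#' @param freqs Tibble with columns `maf` (minor allele frequency on
#'   non-missing chromosomes), `mac` (minor allele count) and `consequence`.
#' @param breaks Increasing upper bin edges on (0, 0.5]; default
#'   `c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)`.
#' @return Tibble with one row per (bin, consequence) count plus per-bin
#'   totals and the nonsynonymous/synonymous ratio.
#' @export
frequency_spectrum <- function(freqs,
                               breaks = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  stopifnot(all(c("maf", "mac", "consequence") %in% names(freqs)))
  stopifnot(all(diff(breaks) > 0), all(breaks > 0))
  labs <- c("singleton",
            paste0("(", c("singleton", utils::head(breaks, -1) * 100),
                   ",", breaks * 100, "%]"))
  bin <- ifelse(freqs$mac == 1L, 1L,
                2L + findInterval(freqs$maf, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE))
  bin <- pmin(bin, length(labs))
  d <- freqs |> mutate(bin = factor(labs[bin], levels = labs))
  nonsyn <- c("missense", "nonsense")
  d |>
    count(.data$bin, .data$consequence, .drop = FALSE, name = "n") |>
    group_by(.data$bin) |>
    mutate(bin_total = sum(.data$n),
           ns_ratio = {
             ns <- sum(.data$n[.data$consequence %in% nonsyn])
             s <- sum(.data$n[.data$consequence %in% "synonymous"])
             if (s == 0) NA_real_ else ns / s
           }) |>
    ungroup()
}
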