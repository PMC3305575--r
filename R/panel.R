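# Synthetic capture-panel construction: a scaled-down analogue of a
# multi-gene hemostasis ("hemostateome") target design, with reference
# sequence, exon/CDS gene models on both strands, and merged target
# intervals covering exons plus intron-exon boundaries.

# Gene-name pool, ordered so that small panels still contain members of both
# functional gene sets used by the collapsing analysis.
PANEL_GENE_POOL <- c(
  "FGA", "PROC", "F5", "SERPINC1", "F2", "PROS1", "FGB", "PROZ", "F7",
  "SERPINA10", "PLAT", "PLCG2", "ANXA5", "MYBPC3", "F11", "KNG1", "FGG",
  "F12", "VWF", "THBD", "F8", "F9", "F10", "F13B", "GP6", "HIVEP1"
)

ANTICOAGULANT_GENES <- c("PROC", "PROS1", "SERPINC1", "PROZ", "SERPINA10",
                         "THBD")
COAGULATION_FACTOR_GENES <- c("FGA", "FGB", "FGG", "F2", "F5", "F7", "F8",
                              "F9", "F10", "F11", "F12", "F13B", "KNG1",
                              "VWF")

#' Build a synthetic capture panel
#'
#' Generates a toy multi-gene panel: per-gene exon/CDS models laid out on a
#' small number of contigs (genes alternate between the + and - strand), a
#' random reference sequence whose coding regions are stop-free in frame, and
#' merged capture-target intervals covering every exon plus a flank over the
#' intron-exon boundaries. The design mimics, at reduced scale, a targeted
#' capture of hemostatic and pro-inflammatory genes.
#'
#' Exon and CDS coordinates are 1-based inclusive; target intervals follow
#' the BED convention (0-based, half-open).
#'
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene Exons per gene (>= 1).
#' @param seed Integer seed; the same seed always yields an identical panel.
#' @param exon_bp,intron_bp Exon and intron sizes in bp.
#' @param utr_bp Untranslated bases at each end of the transcript (carried by
#'   the first and last exon).
#' @param flank_bp Target flank beyond each exon covering splice boundaries.
#' @param genes_per_contig Genes laid head-to-tail per contig.
#' @return An object of class `seq_panel`: a list with tibbles `genes`,
#'   `exons`, `cds`, `targets` (BED convention), `gene_sets`, and a named
#'   character vector `reference`.
#' @examples
#' panel <- build_panel(n_genes = 4, exons_per_gene = 2, seed = 1)
#' panel$genes
#' @export
build_panel <- function(n_genes = 12, exons_per_gene = 4, seed = 1,
                        exon_bp = 120, intron_bp = 200, utr_bp = 30,
                        flank_bp = 10, genes_per_contig = 4) {
  if (n_genes < 1 || exons_per_gene < 1) {
    abort("`n_genes` and `exons_per_gene` must be >= 1.")
  }
  if (exon_bp <= 2 * utr_bp && exons_per_gene == 1) {
    abort("single-exon genes need `exon_bp` > 2 * `utr_bp`.")
  }
  gene_names <- if (n_genes <= length(PANEL_GENE_POOL)) {
    PANEL_GENE_POOL[seq_len(n_genes)]
  } else {
    c(PANEL_GENE_POOL,
      sprintf("GENE%03d", seq_len(n_genes - length(PANEL_GENE_POOL))))
  }

  withr::with_seed(seed, {
    gap <- 400L
    genes <- tibble(
      gene = gene_names,
      contig = paste0("chr", (seq_len(n_genes) - 1) %/% genes_per_contig + 1),
      strand = rep_len(c("+", "-"), n_genes)
    )
    gene_span <- exons_per_gene * exon_bp + (exons_per_gene - 1) * intron_bp

    exons <- genes |>
      mutate(slot = (seq_len(n_genes) - 1) %% genes_per_contig,
             g_start = gap + .data$slot * (gene_span + gap) + 1L) |>
      slice(rep(seq_len(n_genes), each = exons_per_gene)) |>
      group_by(.data$gene) |>
      mutate(exon = row_number()) |>
      ungroup() |>
      mutate(start = .data$g_start + (.data$exon - 1L) * (exon_bp + intron_bp),
             end = .data$start + exon_bp - 1L) |>
      select("gene", "contig", "strand", "exon", "start", "end")

    # CDS: trim the transcript-level UTRs off the terminal exons, then trim
    # the 3' end further so the total CDS length is a codon multiple.
    cds <- exons |>
      mutate(
        start = .data$start + ifelse(.data$exon == 1, utr_bp, 0L),
        end = .data$end - ifelse(.data$exon == exons_per_gene, utr_bp, 0L)
      )
    cds_len <- cds |>
      group_by(.data$gene) |>
      summarise(len = sum(.data$end - .data$start + 1), .groups = "drop")
    cds <- cds |>
      left_join(cds_len, by = "gene") |>
      group_by(.data$gene) |>
      mutate(rem = .data$len %% 3L,
             # shave the genomic 3' (plus) or 5'-most (minus) terminal exon
             end = ifelse(.data$exon == exons_per_gene & .data$strand == "+",
                          .data$end - .data$rem, .data$end),
             start = ifelse(.data$exon == 1 & .data$strand == "-",
                            .data$start + .data$rem, .data$start)) |>
      ungroup() |>
      select("gene", "contig", "strand", "exon", "start", "end")

    contig_len <- exons |>
      group_by(.data$contig) |>
      summarise(len = max(.data$end) + gap, .groups = "drop")
    reference <- setNames(
      vapply(contig_len$len, function(n) {
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
      }, character(1)),
      contig_len$contig
    )

    # overwrite CDS regions with stop-free coding sequence (ATG start)
    sense_codons <- names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"]
    for (g in gene_names) {
      gc <- cds[cds$gene == g, ]
      strand <- gc$strand[1]
      total <- sum(gc$end - gc$start + 1)
      codons <- c("ATG", sample(sense_codons, total / 3 - 1, replace = TRUE))
      coding <- paste(codons, collapse = "")
      genomic <- if (strand == "+") coding else revcomp(coding)
      offset <- 0L
      for (i in seq_len(nrow(gc))) {
        w <- gc$end[i] - gc$start[i] + 1L
        substr(reference[gc$contig[i]], gc$start[i], gc$end[i]) <-
          substr(genomic, offset + 1L, offset + w)
        offset <- offset + w
      }
    }

    targets <- merge_intervals(
      exons |>
        transmute(contig = .data$contig,
                  start = pmax(.data$start - flank_bp - 1L, 0L),  # to 0-based
                  end = .data$end + flank_bp)
    )

    gene_sets <- bind_rows(
      tibble(set = "anticoagulant",
             gene = intersect(gene_names, ANTICOAGULANT_GENES)),
      tibble(set = "coagulation_factor",
             gene = intersect(gene_names, COAGULATION_FACTOR_GENES))
    )

    panel <- structure(
      list(genes = genes |> select("gene", "contig", "strand"),
           exons = exons,
           cds = cds,
           targets = targets,
           reference = reference,
           gene_sets = gene_sets),
      class = "seq_panel"
    )
    validate_panel(panel)
    panel
  })
}

#' Validate panel invariants
#'
#' Checks CDS nesting within exons, codon-multiple CDS length per gene,
#' non-overlapping merged targets, and interval containment in the contigs.
#'
#' @param panel A `seq_panel`.
#' @return The panel, invisibly; aborts on violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "seq_panel"))
  nested <- panel$cds |>
    left_join(panel$exons, by = c("gene", "contig", "strand", "exon"),
              suffix = c("", ".ex"))
  if (any(nested$start < nested$start.ex | nested$end > nested$end.ex)) {
    abort("CDS intervals must nest within exons.")
  }
  len3 <- panel$cds |>
    group_by(.data$gene) |>
    summarise(len = sum(.data$end - .data$start + 1), .groups = "drop")
  if (any(len3$len %% 3 != 0)) abort("CDS length must be a codon multiple.")
  tg <- panel$targets |> arrange(.data$contig, .data$start)
  ovl <- tg |>
    group_by(.data$contig) |>
    filter(dplyr::lead(.data$start) < .data$end) |>
    nrow()
  if (ovl > 0) abort("target intervals overlap after merge.")
  clen <- nchar(panel$reference)
  bad <- tg$end > clen[tg$contig] | tg$start < 0
  if (any(bad)) abort("target interval outside contig bounds.")
  invisible(panel)
}

#' @export
print.seq_panel <- function(x, ...) {
  cat("<seq_panel> ", nrow(x$genes), " genes on ",
      length(x$reference), " contigs; target ",
      sum(x$targets$end - x$targets$start), " bp in ",
      nrow(x$targets), " intervals\n", sep = "")
  invisible(x)
}

#' Total target footprint in bp
#' @param panel A `seq_panel`.
#' @return Integer number of targeted bases.
#' @export
target_size <- function(panel) sum(panel$targets$end - panel$targets$start)

#' Write panel files
#'
#' Emits `reference.fa`, `targets.bed` (0-based half-open), `gene_model.tsv`
#' (exon and CDS rows, 1-based inclusive) and `gene_sets.tsv` under `dir`.
#'
#' @param panel A `seq_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(panel$reference),
    file.path(dir, "reference.fa"))
  readr::write_tsv(panel$targets, file.path(dir, "targets.bed"),
                   col_names = FALSE)
  model <- bind_rows(
    panel$exons |> mutate(feature = "exon"),
    panel$cds |> mutate(feature = "CDS")
  ) |>
    select("gene", "contig", "strand", "feature", "exon", "start", "end") |>
    arrange(.data$contig, .data$start, .data$feature)
  readr::write_tsv(model, file.path(dir, "gene_model.tsv"))
  readr::write_tsv(panel$gene_sets, file.path(dir, "gene_sets.tsv"))
  invisible(dir)
}

#' Read panel files written by [write_panel()]
#' @param dir Directory containing the panel files.
#' @return A `seq_panel`.
#' @export
read_panel <- function(dir) {
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  reference <- setNames(as.character(ref), names(ref))
  targets <- readr::read_tsv(file.path(dir, "targets.bed"),
                             col_names = c("contig", "start", "end"),
                             col_types = "cii")
  model <- readr::read_tsv(file.path(dir, "gene_model.tsv"),
                           col_types = "ccccii") |>
    mutate(exon = as.integer(.data$exon))
  gene_sets <- readr::read_tsv(file.path(dir, "gene_sets.tsv"),
                               col_types = "cc")
  exons <- model |> filter(.data$feature == "exon") |> select(-"feature")
  cds <- model |> filter(.data$feature == "CDS") |> select(-"feature")
  panel <- structure(
    list(genes = exons |> distinct(.data$gene, .data$contig, .data$strand),
         exons = exons, cds = cds, targets = targets,
         reference = reference, gene_sets = gene_sets),
    class = "seq_panel")
  validate_panel(panel)
  panel
}
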