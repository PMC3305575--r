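# Minimal VCF v4.2 text emission/parsing for calls and genotype matrices.
# The FILTER column carries QC fail reasons (semicolon-joined); INFO carries
# DP, ALTR, AB and per-strand alt counts SBP/SBM.

vcf_header <- function(contigs, samples, extra_filters = TRUE) {
  h <- c("##fileformat=VCFv4.2",
         "##source=hemoseq",
         sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                 unname(contigs)),
         "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
         "##INFO=<ID=ALTR,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
         "##INFO=<ID=AB,Number=1,Type=Float,Description=\"Allele balance alt/(ref+alt)\">",
         "##INFO=<ID=SBP,Number=1,Type=Integer,Description=\"Alt reads on + strand\">",
         "##INFO=<ID=SBM,Number=1,Type=Integer,Description=\"Alt reads on - strand\">")
  if (extra_filters) {
    h <- c(h,
           "##FILTER=<ID=low_allele_balance,Description=\"Allele balance below 20%\">",
           "##FILTER=<ID=strand_bias,Description=\"Variant absent from one strand orientation\">",
           "##FILTER=<ID=low_depth,Description=\"Depth below 10X\">",
           "##FILTER=<ID=low_quality,Description=\"Call quality below floor\">")
  }
  c(h,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# indel spelling: internal "-" deletions and "+XX" insertions become
# left-anchored REF/ALT pairs
vcf_alleles <- function(contig, pos, ref, alt, reference) {
  del <- alt == "-"
  ins <- startsWith(alt, "+")
  out_pos <- ifelse(del, pos - 1L, pos)
  anchor <- substring(reference[contig], out_pos, out_pos)
  tibble(pos = out_pos,
         ref = ifelse(del, paste0(anchor, ref), ref),
         alt = dplyr::case_when(del ~ anchor,
                                ins ~ paste0(ref, substring(alt, 2)),
                                TRUE ~ alt))
}

#' Write one sample's QC-annotated calls as VCF v4.2
#'
#' @param calls QC-annotated calls of a single sample.
#' @param panel A `seq_panel` (for contig headers and indel anchors).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(calls, panel, path) {
  stopifnot(length(unique(calls$sample)) <= 1)
  sm <- if (nrow(calls) > 0) calls$sample[1] else "SAMPLE"
  calls <- calls |> arrange(.data$contig, .data$pos)
  al <- vcf_alleles(calls$contig, calls$pos, calls$ref, calls$alt,
                    panel$reference)
  rows <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%.0f\t%s\tDP=%d;ALTR=%d;AB=%.4f;SBP=%d;SBM=%d\tGT\t%s",
    calls$contig, al$pos, al$ref, al$alt,
    pmin(calls$call_quality, 9999),
    ifelse(calls$qc_status == "PASS", "PASS",
           gsub(",", ";", calls$fail_reasons, fixed = TRUE)),
    calls$depth, calls$alt_reads, calls$allele_balance, calls$alt_plus,
    calls$alt_minus,
    ifelse(calls$genotype == "het", "0/1", "1/1"))
  readr::write_lines(c(vcf_header(nchar(panel$reference), sm), rows), path)
  invisible(path)
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' @param gm A `geno_matrix`.
#' @param panel A `seq_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf_matrix <- function(gm, panel, path) {
  gt <- c("0/0", "0/1", "1/1")
  gcol <- apply(gm$geno, 2, function(g) {
    paste(ifelse(is.na(g), "./.", gt[g + 1L]), collapse = "\t")
  })
  al <- vcf_alleles(gm$sites$contig, gm$sites$pos, gm$sites$ref,
                    gm$sites$alt, panel$reference)
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  gm$sites$contig, al$pos, gm$sites$site_id, al$ref, al$alt,
                  gcol)
  readr::write_lines(
    c(vcf_header(nchar(panel$reference), rownames(gm$geno)), rows), path)
  invisible(path)
}

#' Read a VCF written by this package back to a call/genotype tibble
#'
#' Parses CHROM/POS/REF/ALT/FILTER plus GT columns; suitable for the
#' concordance operations, not a general-purpose VCF reader.
#'
#' @param path VCF file.
#' @return Tibble (contig, pos, ref, alt, qc_status) plus one dosage column
#'   per sample.
#' @export
read_vcf <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  if (length(body) < 2) {
    return(tibble(contig = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  qc_status = character(0)))
  }
  f <- strsplit(body[-1], "\t")
  m <- do.call(rbind, f)
  colnames(m) <- hdr
  out <- tibble(contig = m[, "CHROM"], pos = as.integer(m[, "POS"]),
                ref = m[, "REF"], alt = m[, "ALT"],
                qc_status = ifelse(m[, "FILTER"] == "PASS", "PASS", "FAIL"))
  smp <- hdr[-(1:9)]
  dose <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (s in smp) out[[s]] <- unname(dose[m[, s]])
  out
}
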