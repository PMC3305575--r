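# Consequence classification against the toy gene model, novelty lookup,
# and the frequency-spectrum summary.

test_that("canonical substitutions classify by the genetic code", {
  # CDS: M  R(CGA)  K  stop-capable codons placed deliberately
  panel <- toy_gene_panel("ATGCGAAAAGCT")
  s <- panel$cds$start[1]
  # CGA -> TGA at codon-2 position 1: nonsense (Arg -> stop)
  v <- classify_snv(tibble::tibble(contig = "chrT", pos = s + 3L,
                                   ref = "C", alt = "T"), panel)
  expect_identical(v$consequence, "nonsense")
  expect_identical(v$protein_change, "p.R2X")
  # GCT -> GCC at codon-4 position 3: synonymous (Ala)
  v2 <- classify_snv(tibble::tibble(contig = "chrT", pos = s + 11L,
                                    ref = "T", alt = "C"), panel)
  expect_identical(v2$consequence, "synonymous")
  # CGA -> CAA: missense (Arg -> Gln)
  v3 <- classify_snv(tibble::tibble(contig = "chrT", pos = s + 4L,
                                    ref = "G", alt = "A"), panel)
  expect_identical(v3$consequence, "missense")
  expect_identical(v3$protein_change, "p.R2Q")
  # UTR and intron/flank positions
  v4 <- classify_snv(tibble::tibble(contig = "chrT", pos = s - 2L,
                                    ref = "T", alt = "A"), panel)
  expect_identical(v4$consequence, "utr")
  v5 <- classify_snv(tibble::tibble(contig = "chrT", pos = 5L,
                                    ref = "A", alt = "C"), panel)
  expect_identical(v5$consequence, "intronic")
  # disagreeing reference allele is a panel inconsistency
  expect_error(classify_snv(tibble::tibble(contig = "chrT", pos = s,
                                           ref = "G", alt = "T"), panel),
               "ref allele mismatch")
})

test_that("minus-strand classification mirrors the plus-strand case", {
  cds <- "ATGCGAAAAGCT"
  plus <- toy_gene_panel(cds, strand = "+")
  minus <- toy_gene_panel(cds, strand = "-")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # walk every CDS base with every alternate allele
  s_p <- plus$cds$start[1]
  s_m <- minus$cds$start[1]
  e_m <- minus$cds$end[1]
  L <- nchar(cds)
  for (i in seq_len(L)) {
    gp <- s_p + i - 1L
    rp <- unname(substr(plus$reference[["chrT"]], gp, gp))
    # mirrored genomic position on the minus-strand panel
    gmn <- e_m - i + 1L
    rm <- unname(substr(minus$reference[["chrT"]], gmn, gmn))
    expect_identical(rm, unname(comp[rp]))
    for (alt in setdiff(c("A", "C", "G", "T"), rp)) {
      cp <- classify_snv(tibble::tibble(contig = "chrT", pos = gp,
                                        ref = rp, alt = alt), plus)
      cm <- classify_snv(tibble::tibble(contig = "chrT", pos = gmn,
                                        ref = rm, alt = unname(comp[alt])),
                         minus)
      expect_identical(cm$consequence, cp$consequence)
      expect_identical(cm$protein_change, cp$protein_change)
    }
  }
})

test_that("classification equals a full-CDS retranslation oracle", {
  # brute-force oracle: rebuild the whole mutant CDS and translate it
  panel <- small_panel()
  translate <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  for (g in panel$genes$gene) {
    gc <- panel$cds |> dplyr::filter(gene == g) |> dplyr::arrange(start)
    strand <- gc$strand[1]
    gpos <- unlist(Map(seq.int, gc$start, gc$end))
    cds_seq <- paste(substring(panel$reference[gc$contig[1]], gc$start,
                               gc$end), collapse = "")
    if (strand == "-") {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
      gpos <- rev(gpos)
    }
    aa_ref <- translate(cds_seq)
    idx <- withr::with_seed(17 + nchar(g), sample(seq_along(gpos), 30))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    vars <- dplyr::bind_rows(lapply(idx, function(i) {
      p <- gpos[i]
      ref <- substr(panel$reference[gc$contig[1]], p, p)
      tibble::tibble(contig = gc$contig[1], pos = p, ref = ref,
                     alt = setdiff(c("A", "C", "G", "T"), ref), i = i)
    }))
    got <- classify_snv(vars |> dplyr::select(-i), panel)$consequence
    oracle <- vapply(seq_len(nrow(vars)), function(k) {
      i <- vars$i[k]
      alt_cds <- if (strand == "-") comp[[vars$alt[k]]] else vars$alt[k]
      mutant <- cds_seq
      substr(mutant, i, i) <- alt_cds
      aa_mut <- translate(mutant)
      d <- which(utf8ToInt(aa_mut) != utf8ToInt(aa_ref))
      if (length(d) == 0) "synonymous" else
        if (substr(aa_mut, d[1], d[1]) == "*") "nonsense" else "missense"
    }, character(1))
    expect_identical(got, oracle, label = g)
  }
})

test_that("indels classify by frame and location", {
  panel <- toy_gene_panel("ATGCGAAAAGCTTTTGGG")
  s <- panel$cds$start[1]
  one_bp <- classify_indel(tibble::tibble(contig = "chrT", pos = s + 4L,
                                          ref = "GA", alt = "G"), panel)
  expect_identical(one_bp$consequence, "frameshift")
  three_bp <- classify_indel(tibble::tibble(contig = "chrT", pos = s + 3L,
                                            ref = "CGAA", alt = "C"), panel)
  expect_identical(three_bp$consequence, "inframe_indel")
  intronic <- classify_indel(tibble::tibble(contig = "chrT", pos = 3L,
                                            ref = "AA", alt = "A"), panel)
  expect_identical(intronic$consequence, "intronic")
  expect_error(classify_indel(tibble::tibble(contig = "chrT", pos = s,
                                             ref = "A", alt = "C"), panel),
               "change allele length")
})

test_that("novelty lookup is exact on the normalized variant key", {
  vars <- tibble::tibble(contig = c("chr1", "chr1", "chr2"),
                         pos = c(10L, 20L, 30L),
                         ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  known <- tibble::tibble(contig = "chr1", pos = 10L, ref = "a", alt = "g")
  out <- flag_novelty(vars, known)
  expect_identical(out$novel, c(FALSE, TRUE, TRUE))
  # empty tables: everything novel
  expect_true(all(flag_novelty(vars, list())$novel))
  # malformed rows are skipped and counted
  bad <- tibble::tibble(contig = c("chr1", NA), pos = c(20L, 5L),
                        ref = c("C", "A"), alt = c("T", "G"))
  out2 <- flag_novelty(vars, bad)
  expect_identical(attr(out2, "n_skipped"), 1L)
  expect_identical(out2$novel, c(TRUE, FALSE, TRUE))
  # two tables act as a union
  out3 <- flag_novelty(vars, list(known, tibble::tibble(
    contig = "chr2", pos = 30L, ref = "G", alt = "A")))
  expect_identical(out3$novel, c(FALSE, TRUE, FALSE))
})

test_that("frequency spectrum partitions variants and tracks the ns ratio", {
  freqs <- tibble::tibble(
    maf = c(1 / 44, 0.03, 0.04, 0.08, 0.15, 0.45, 0.5),
    mac = c(1L, 2L, 3L, 4L, 7L, 20L, 22L),
    consequence = c("missense", "missense", "synonymous", "missense",
                    "synonymous", "intronic", "missense"))
  sp <- frequency_spectrum(freqs)
  # counts conserve over the partition
  expect_identical(sum(sp$n), nrow(freqs))
  per_bin <- sp |> dplyr::distinct(bin, bin_total, ns_ratio)
  expect_identical(sum(per_bin$bin_total), nrow(freqs))
  # the singleton lands in its own bin
  expect_identical(per_bin$bin_total[per_bin$bin == "singleton"], 1L)
  # (singleton, 5%] holds macs 2-3 here, ratio 1 missense / 1 synonymous
  b2 <- per_bin |> dplyr::filter(bin == "(singleton,5%]")
  expect_identical(b2$bin_total, 2L)
  expect_equal(b2$ns_ratio, 1)
  # all singletons: all mass in bin 1
  all_single <- tibble::tibble(maf = rep(1 / 44, 5), mac = 1L,
                               consequence = "missense")
  sp2 <- frequency_spectrum(all_single)
  tot <- sp2 |> dplyr::distinct(bin, bin_total)
  expect_identical(tot$bin_total[tot$bin == "singleton"], 5L)
  expect_identical(sum(tot$bin_total), 5L)
  # no synonymous variants in a bin: ratio undefined (NA)
  expect_true(is.na(sp2$ns_ratio[sp2$bin == "singleton"][1]))
})

test_that("a neutral simulation reproduces the input frequency spectrum", {
  panel <- small_panel()
  cfg <- sim_config(seed = 55, n_cases = 40, n_controls = 40,
                    n_neutral_sites = 150,
                    common_risk = list(gene = "FGA", q = 0.3, or = 1),
                    rare_burden = list(set = "anticoagulant", per_gene = 1L,
                                       q = 0.02, enrichment = 1))
  truth <- simulate_genotypes(panel, cfg)
  gm <- truth_to_matrix(truth)
  st <- site_stats(gm) |>
    dplyr::inner_join(truth$sites, by = "site_id")
  # observed MAF tracks the generating frequency
  neutral <- st |> dplyr::filter(role == "neutral")
  expect_gt(stats::cor(neutral$maf, pmin(neutral$q_control,
                                         1 - neutral$q_control)), 0.9)
  sp <- frequency_spectrum(st |> dplyr::transmute(maf, mac, consequence))
  expect_identical(sum(sp$n), nrow(st))
})
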