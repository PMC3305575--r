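# Pileup construction, candidate calling and the QC boundary behaviour.

# observations for a single site, built directly
site_obs <- function(n_ref, n_alt, ref = "A", alt = "G", qual = 30L,
                     alt_strands = NULL, ref_strands = NULL, pos = 50L) {
  strands <- function(n, given, default) {
    if (!is.null(given)) rep_len(given, n) else rep_len(default, n)
  }
  tibble::tibble(
    sample = "S1", contig = "chr1", pos = pos, ref = ref,
    base = c(rep(ref, n_ref), rep(alt, n_alt)),
    qual = qual,
    strand = c(strands(n_ref, ref_strands, c("+", "-")),
               strands(n_alt, alt_strands, c("+", "-"))),
    mapq = 60L)
}

test_that("pileup counts overlapping reads and honours base quality", {
  panel <- toy_gene_panel("ATGGCTAAATTTCCCGGG")
  pos <- panel$cds$start[1]        # first CDS base, ref A
  # 10 reads overlap the position; 4 carry a mismatch
  reads <- dplyr::bind_rows(lapply(1:10, function(i) {
    st <- pos - 11L + i
    b <- substr(panel$reference, st, st + 14L)
    if (i <= 4) substr(b, pos - st + 1, pos - st + 1) <- "G"
    make_read(contig = "chrT", start = st, end = st + 14L, bases = b,
              quals = strrep("I", 15L),  # Q40
              read_id = sprintf("r%02d", i))
  }))
  pu <- build_pileup(reads, panel)
  at <- pu |> dplyr::filter(pos == !!pos)
  expect_identical(nrow(at), 10L)                 # depth 10
  expect_identical(sum(at$base == "G"), 4L)

  # a Q15 base is excluded when min_base_qual = 20
  low <- reads
  substr(low$quals[1], pos - low$start[1] + 1, pos - low$start[1] + 1) <- "0"
  pu_low <- build_pileup(low, panel, min_base_qual = 20)
  expect_identical(nrow(pu_low |> dplyr::filter(pos == !!pos)), 9L)

  # off-panel reads are dropped with a warning and counted
  off <- dplyr::bind_rows(reads, make_read(contig = "chrZ", start = 5))
  expect_warning(pu_off <- build_pileup(off, panel), "absent from the panel")
  expect_identical(attr(pu_off, "n_offpanel"), 1L)
})

test_that("allele balance determines the called genotype", {
  half <- call_site(site_obs(5, 5))
  expect_identical(half$allele_balance, 0.5)
  expect_identical(half$genotype, "het")
  expect_identical(half$depth, 10L)

  all_alt <- call_site(site_obs(0, 10))
  expect_identical(all_alt$allele_balance, 1)
  expect_identical(all_alt$genotype, "homvar")

  # below the minimum alt-read support no call is produced
  expect_identical(nrow(call_site(site_obs(10, 1))), 0L)
})

test_that("call quality equals the exact binomial error tail", {
  # 30 observations at Q30 (error 0.001), 2 variant reads:
  # -10 log10 P[X >= 2], X ~ Binomial(30, 0.001)
  res <- call_site(site_obs(28, 2, qual = 30L))
  tail_p <- sum(stats::dbinom(2:30, 30, 0.001))   # enumeration oracle
  expect_equal(res$call_quality, -10 * log10(tail_p), tolerance = 1e-8)
  expect_equal(res$call_quality, 33.69611, tolerance = 1e-4)

  # monotone: lower base qualities give lower call quality, depth fixed
  quals <- c(40L, 30L, 20L, 10L)
  cq <- vapply(quals, function(q) {
    call_site(site_obs(24, 6, qual = q))$call_quality
  }, numeric(1))
  expect_true(all(diff(cq) < 0))
})

test_that("multi-allelic sites emit the majority alt and are flagged", {
  obs <- dplyr::bind_rows(site_obs(10, 4, alt = "G"),
                          site_obs(0, 3, alt = "T"))
  res <- call_site(obs)
  expect_identical(res$alt, "G")
  expect_true(res$multiallelic)
})

test_that("QC boundaries match the documented decisions exactly", {
  params <- call_params()
  # allele balance 0.19 fails, 0.20 passes the balance criterion
  ab19 <- qc_filter(call_site(site_obs(81, 19)), params)
  expect_match(ab19$fail_reasons, "low_allele_balance")
  ab20 <- qc_filter(call_site(site_obs(80, 20)), params)
  expect_false(grepl("low_allele_balance", ab20$fail_reasons))
  expect_identical(ab20$qc_status, "PASS")

  # alt on a single strand orientation fails strand_bias
  sb <- qc_filter(call_site(site_obs(6, 3, alt_strands = "+")), params)
  expect_match(sb$fail_reasons, "strand_bias")
  expect_identical(sb$qc_status, "FAIL")
  both <- qc_filter(call_site(site_obs(6, 4, alt_strands = c("+", "-"))),
                    params)
  expect_false(grepl("strand_bias", both$fail_reasons))

  # depth 9 fails low_depth, depth 10 passes
  d9 <- qc_filter(call_site(site_obs(5, 4)), params)
  expect_match(d9$fail_reasons, "low_depth")
  d10 <- qc_filter(call_site(site_obs(6, 4)), params)
  expect_false(grepl("low_depth", d10$fail_reasons))
  expect_identical(d10$qc_status, "PASS")

  # sites covered on one strand only fail but carry the distinct flag
  ss <- qc_filter(call_site(site_obs(6, 4, alt_strands = "+",
                                     ref_strands = "+")), params)
  expect_match(ss$fail_reasons, "strand_bias")
  expect_true(ss$single_strand_site)
  expect_false(both$single_strand_site)

  # failed calls are retained, never dropped
  expect_identical(nrow(ab19), 1L)
})

test_that("indel observations are called by the same counting rules", {
  del <- call_site(site_obs(7, 5, alt = "-"))
  expect_identical(del$var_type, "deletion")
  expect_identical(del$genotype, "het")
  ins <- call_site(site_obs(2, 10, alt = "+AG"))
  expect_identical(ins$var_type, "insertion")
  expect_identical(ins$genotype, "homvar")
})

test_that("error-free cohort: perfect sensitivity and specificity", {
  fx <- fix_errorfree()
  pass <- fx$calls |> dplyr::filter(qc_status == "PASS")
  truth_carriers <- melt_truth(fx$truth)

  key_call <- paste(pass$sample, pass$contig, pass$pos, pass$alt)
  key_truth <- paste(truth_carriers$sample, truth_carriers$contig,
                     truth_carriers$pos, truth_carriers$alt)
  # no PASS call at a non-truth site
  expect_identical(sum(!key_call %in% key_truth), 0L)
  # every truth variant with adequate double-stranded coverage is found
  missed <- setdiff(key_truth, key_call)
  expect_identical(length(missed), 0L)
  # genotypes agree with truth dosage
  j <- dplyr::inner_join(
    pass |> dplyr::mutate(k = key_call) |> dplyr::select(k, genotype),
    truth_carriers |> dplyr::mutate(k = key_truth) |>
      dplyr::select(k, gt),
    by = "k")
  expect_true(all((j$genotype == "het") == (j$gt == 1L)))
})

test_that("noisy defaults keep het sensitivity and specificity high", {
  panel <- small_panel()
  cfg <- sim_config(seed = 41)    # Q20/Q30 mixture, 42X, duplicates
  truth <- simulate_genotypes(panel, cfg)
  sim <- simulate_reads(panel, truth, cfg)
  dm <- assign_barcodes(sim$reads, sim$manifest)
  fl <- dm$reads |>
    dplyr::group_by(sample) |>
    dplyr::group_modify(~remove_duplicates(.x)) |>
    dplyr::ungroup() |>
    filter_mapq()
  calls <- qc_filter(call_variants(build_pileup(fl, panel)))
  pass <- calls |> dplyr::filter(qc_status == "PASS")
  hets <- melt_truth(truth) |> dplyr::filter(gt == 1L)
  key_call <- paste(pass$sample, pass$contig, pass$pos, pass$alt)
  key_het <- paste(hets$sample, hets$contig, hets$pos, hets$alt)
  sens <- mean(key_het %in% key_call)
  truth_all <- melt_truth(truth)
  spec_fp <- sum(!key_call %in% paste(truth_all$sample, truth_all$contig,
                                      truth_all$pos, truth_all$alt))
  expect_gte(sens, 0.95)
  expect_lte(spec_fp / max(nrow(pass), 1), 0.05)
})
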