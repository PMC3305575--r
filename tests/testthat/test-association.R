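# Allelic tabulation, the exact Fisher test against an enumeration oracle,
# odds ratios, screen filtering/ranking, and the detectable-MAC bound.

toy_matrix <- function(geno, status) {
  n_sites <- ncol(geno)
  sites <- tibble::tibble(site_id = paste0("chr1:", seq_len(n_sites),
                                           ":A:G"),
                          contig = "chr1", pos = seq_len(n_sites),
                          ref = "A", alt = "G")
  samples <- tibble::tibble(sample = paste0("S", seq_len(nrow(geno))),
                            status = status)
  dimnames(geno) <- list(samples$sample, sites$site_id)
  structure(list(sites = sites, samples = samples, geno = geno),
            class = "geno_matrix")
}

test_that("allele_table counts two alleles per non-missing genotype", {
  # 10 case hets, nothing else variant
  geno <- matrix(0L, nrow = 22, ncol = 1)
  geno[1:10, 1] <- 1L
  gm <- toy_matrix(geno, c(rep(2L, 10), rep(1L, 12)))
  at <- allele_table(gm, gm$sites$site_id[1])
  expect_identical(at$table["case", "minor"], 10)
  expect_identical(at$table["case", "major"], 10)
  expect_identical(at$table["control", "minor"], 0)
  expect_identical(sum(at$table), 2 * 22)

  # monomorphic site: minor count 0, MAF 0
  gm0 <- toy_matrix(matrix(0L, 4, 1), c(2L, 2L, 1L, 1L))
  at0 <- allele_table(gm0, gm0$sites$site_id[1])
  expect_identical(at0$table["case", "minor"], 0)
  expect_identical(at0$maf_pooled, 0)

  # hand tabulation with hets, homs and missing
  g <- matrix(c(1L, 2L, NA, 0L, 1L, 0L), ncol = 1)
  gmh <- toy_matrix(g, c(2L, 2L, 2L, 1L, 1L, 1L))
  ath <- allele_table(gmh, gmh$sites$site_id[1])
  expect_identical(ath$table["case", "minor"], 3)    # 1 + 2
  expect_identical(ath$table["case", "major"], 1)
  expect_identical(ath$table["control", "minor"], 1)
  expect_identical(ath$missingness, 1 / 6)

  # fully missing site errors
  expect_error(allele_table(toy_matrix(matrix(NA_integer_, 3, 1),
                                       c(2L, 1L, 1L)), "chr1:1:A:G"),
               "fully missing")
})

test_that("fisher_two_sided equals the enumeration oracle and fisher.test", {
  cases <- list(c(10, 10, 4, 20), c(1, 19, 7, 13), c(0, 12, 5, 7),
                c(3, 3, 3, 3), c(25, 5, 5, 25), c(0, 0, 3, 9),
                c(8, 0, 0, 9))
  for (tb in cases) {
    got <- fisher_two_sided(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    if (sum(tb[1:2]) > 0 && sum(tb[3:4]) > 0 &&
          sum(tb[c(1, 3)]) > 0 && sum(tb[c(2, 4)]) > 0) {
      expect_equal(got, stats::fisher.test(matrix(tb, 2, byrow = TRUE))
                   $p.value, tolerance = 1e-9)
    }
  }
  # frozen worked example
  expect_equal(fisher_two_sided(10, 10, 4, 20), 0.02527501,
               tolerance = 1e-7)
  # identical rows: p = 1; label symmetry
  expect_identical(fisher_two_sided(6, 10, 6, 10), 1)
  expect_identical(fisher_two_sided(9, 4, 2, 11),
                   fisher_two_sided(2, 11, 9, 4))
  # zero margin convention
  expect_identical(fisher_two_sided(0, 10, 0, 12), 1)
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("odds ratio is the cross-product ratio with Woolf interval", {
  # replication-scale table
  o <- odds_ratio_ci(453, 965, 312, 1092)
  expect_equal(o$or, 1.643005, tolerance = 1e-6)
  expect_true(o$ci_lo < o$or & o$or < o$ci_hi)
  # identical rows: OR 1
  expect_equal(odds_ratio_ci(5, 10, 5, 10)$or, 1)
  # zero cell: finite via the +0.5 correction
  z <- odds_ratio_ci(4, 16, 0, 24)
  expect_true(is.finite(z$or) && z$or > 1)
  expect_true(is.finite(z$ci_hi))
})

test_that("screen applies the MAF and missingness boundaries", {
  # 22 samples; site A pooled MAF 0.07 (excluded), site B 0.25 with
  # missingness 0.10 at 20 samples (excluded), site C tested
  g <- matrix(0L, nrow = 20, ncol = 3)
  g[1:3, 1] <- 1L                       # MAF 3/40 = 0.075 < 0.08
  g[1:10, 2] <- 1L
  g[1:2, 2] <- NA                       # missingness exactly 0.10
  g[1:10, 3] <- 1L                      # MAF 0.25, tested
  gm <- toy_matrix(g, c(rep(2L, 10), rep(1L, 10)))
  sc <- screen(gm, screen_config(top_k = 2))
  r <- tidy(sc)
  expect_false(r$tested[r$site_id == "chr1:1:A:G"])
  expect_false(r$tested[r$site_id == "chr1:2:A:G"])
  expect_true(r$tested[r$site_id == "chr1:3:A:G"])
  # a notice is logged when fewer survivors than top_k
  expect_message(screen(gm, screen_config(top_k = 2)), "all selected")
  expect_identical(sum(r$selected), 1L)
  g1 <- glance(sc)
  expect_identical(g1$n_tested, 1L)
})

test_that("screen ranks by p with deterministic tie-breaking", {
  withr::with_seed(7, {
    g <- matrix(rbinom(40 * 6, 2, 0.3), nrow = 40)
    gm <- toy_matrix(g, rep(c(2L, 1L), each = 20))
    sc <- screen(gm, screen_config(top_k = 3))
    r <- tidy(sc) |> dplyr::filter(tested)
    expect_false(is.unsorted(r$p))
    expect_identical(r$rank, seq_len(nrow(r)))
    expect_identical(sum(r$selected), min(3L, nrow(r)))
  })
})

test_that("minimal detectable MAC matches exhaustive enumeration", {
  # 22 individuals: 20 case alleles vs 24 control alleles
  expect_identical(min_detectable_mac(20, 24, 0.05), 4L)
  # oracle confirmation: m = 3 cannot reach p < 0.05, m = 4 can
  expect_gte(fisher_oracle(3, 17, 0, 24), 0.05)
  expect_lt(fisher_oracle(4, 16, 0, 24), 0.05)
  # alpha = 1: any single observation suffices
  expect_identical(min_detectable_mac(20, 24, 1), 1L)
  # monotone non-increasing detectable MAF as samples grow
  sizes <- c(20, 40, 100, 400, 1438)
  mafs <- vapply(sizes, function(n) {
    min_detectable_mac(n, n, 0.05) / (2 * n)
  }, numeric(1))
  expect_true(all(diff(mafs) <= 1e-12))
})

test_that("the screen's attained type-I rate never exceeds the nominal level", {
  # exact tests are valid (conservative): attained level <= alpha + MC error
  withr::with_seed(101, {
    reps <- 150
    nv <- 100
    rej <- vapply(seq_len(reps), function(i) {
      q <- runif(nv, 0.1, 0.45)
      geno <- matrix(rbinom(22 * nv, 2, rep(q, each = 22)), nrow = 22)
      gm <- toy_matrix(geno, c(rep(2L, 10), rep(1L, 12)))
      st <- site_stats(gm)
      keep <- st$maf >= 0.08
      p <- suppressMessages(tidy(screen(gm))$p)
      mean(p[!is.na(p)] < 0.05)
    }, numeric(1))
    rate <- mean(rej)
    mc_se <- stats::sd(rej) / sqrt(reps)
    expect_lte(rate, 0.05 + 3 * mc_se)
    expect_gt(rate, 0)   # the screen does reject sometimes
  })
})
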