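# Independent oracles and printed-table fixtures shared across test files.

# exhaustive hypergeometric enumeration with choose(), independent of the
# dhyper-based implementation
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; r1 <- a + b; n <- a + b + c + d
  if (m == 0 || m == n || r1 == 0 || r1 == n) return(1)
  lo <- max(0, r1 - (n - m)); hi <- min(r1, m)
  x <- lo:hi
  px <- choose(m, x) * choose(n - m, r1 - x) / choose(n, r1)
  p_obs <- px[match(a, x)]
  min(1, sum(px[px <= p_obs * (1 + 1e-7)]))
}

# the anticoagulant-gene nonsynonymous variant table of the sequencing
# cohort: five missense variants with case allele counts (2,1,1,3,2) and
# control counts (0,0,0,0,2) over 10 cases and 12 controls
anticoag_matrix <- function() {
  case_counts <- c(2L, 1L, 1L, 3L, 2L)
  ctrl_counts <- c(0L, 0L, 0L, 0L, 2L)
  geno <- matrix(0L, nrow = 22, ncol = 5)
  for (j in 1:5) {
    if (case_counts[j] > 0) geno[seq_len(case_counts[j]), j] <- 1L
    if (ctrl_counts[j] > 0) geno[10 + seq_len(ctrl_counts[j]), j] <- 1L
  }
  sites <- tibble::tibble(
    site_id = paste0("chr", 1:5, ":100:C:T"), contig = paste0("chr", 1:5),
    pos = 100L, ref = "C", alt = "T")
  samples <- tibble::tibble(sample = sprintf("I%02d", 1:22),
                            status = c(rep(2L, 10), rep(1L, 12)))
  dimnames(geno) <- list(samples$sample, sites$site_id)
  ann <- tibble::tibble(site_id = sites$site_id,
                        gene = c("PROC", "PROC", "SERPINC1", "PROZ",
                                 "PROZ"),
                        consequence = "missense")
  list(gm = structure(list(sites = sites, samples = samples, geno = geno),
                      class = "geno_matrix"),
       ann = ann)
}
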