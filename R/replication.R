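# Two-stage replication: screen hits are first genotyped in a subset
# (stage 1), and only variants whose stage-1 frequencies project at least
# 80% power at p < 0.005 in the full cohort are carried to stage 2; the
# final result combines the per-stage allele tables.

#' Stage configuration
#'
#' @param stage1_n Individuals genotyped at stage 1 (default 284).
#' @param full_n_case,full_n_control Individuals per group in the complete
#'   replication cohort (defaults 719 and 719).
#' @param alpha2 Significance level to be reached in the full cohort
#'   (two-sided; default 0.005).
#' @param power_threshold Minimum projected power for carry-over
#'   (default 0.80; a power exactly at the threshold is carried over).
#' @return List of class `stage_config`.
#' @export
stage_config <- function(stage1_n = 284, full_n_case = 719,
                         full_n_control = 719, alpha2 = 0.005,
                         power_threshold = 0.80) {
  stopifnot(stage1_n <= full_n_case + full_n_control,
            alpha2 > 0, alpha2 < 1, power_threshold > 0,
            power_threshold < 1)
  structure(as.list(environment()), class = "stage_config")
}

#' Power of the two-proportion z-test
#'
#' Normal approximation for comparing two allele proportions: the null
#' standard error pools the two groups, the alternative standard error does
#' not, and power is the probability of rejecting in the direction of the
#' observed effect at two-sided level `alpha`. With `p1 = p2` this reduces
#' to `alpha / 2` (the one-directional null rejection rate).
#'
#' @param p1,p2 Allele proportions in the two groups (strictly inside
#'   (0, 1)).
#' @param n1_alleles,n2_alleles Allele counts per group (2 x individuals).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
two_proportion_power <- function(p1, p2, n1_alleles, n2_alleles,
                                 alpha = 0.005) {
  stopifnot(n1_alleles >= 2, n2_alleles >= 2)
  if (any(p1 <= 0 | p1 >= 1 | p2 <= 0 | p2 >= 1)) {
    abort("degenerate allele frequencies (0 or 1) carry no information.")
  }
  delta <- abs(p1 - p2)
  pbar <- (p1 * n1_alleles + p2 * n2_alleles) / (n1_alleles + n2_alleles)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1_alleles + 1 / n2_alleles))
  se1 <- sqrt(p1 * (1 - p1) / n1_alleles + p2 * (1 - p2) / n2_alleles)
  z <- qnorm(1 - alpha / 2)
  pnorm((delta - z * se0) / se1)
}

#' Select stage-1 variants for stage-2 replication
#'
#' A variant is carried over iff the power projected from its stage-1 case
#' and control allele frequencies, at the full cohort's allele counts and
#' level `alpha2`, reaches the power threshold.
#'
#' @param stage1 Tibble with columns `site_id`, `p_case`, `p_control`
#'   (stage-1 allele frequency estimates). Degenerate estimates (0 or 1 in
#'   either group) get `power = NA` and are never selected.
#' @param config A [stage_config()].
#' @return `stage1` with `power` and `selected` columns.
#' @export
select_for_stage2 <- function(stage1, config = stage_config()) {
  stage1 |>
    rowwise() |>
    mutate(power = if (.data$p_case <= 0 || .data$p_case >= 1 ||
                         .data$p_control <= 0 || .data$p_control >= 1) {
      NA_real_
    } else {
      two_proportion_power(.data$p_case, .data$p_control,
                           2 * config$full_n_case,
                           2 * config$full_n_control, config$alpha2)
    }) |>
    ungroup() |>
    mutate(selected = !is.na(.data$power) &
             .data$power >= config$power_threshold)
}

#' Combined two-stage association analysis
#'
#' Sums the stage-1 and stage-2 allelic 2x2 tables cell-wise and reports
#' the Fisher p, odds ratio and confidence interval of the combined table.
#' An empty stage 2 leaves the stage-1 result unchanged.
#'
#' @param table1,table2 2x2 allele-count matrices (rows case/control,
#'   columns minor/major); `table2` may be NULL.
#' @return Tibble (case_minor, case_major, control_minor, control_major,
#'   maf_case, maf_control, p, or, ci_lo, ci_hi).
#' @export
combined_analysis <- function(table1, table2 = NULL) {
  tab <- table1 + (table2 %||% 0)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  orci <- odds_ratio_ci(a, b, c_, d)
  tibble(case_minor = a, case_major = b, control_minor = c_,
         control_major = d,
         maf_case = a / (a + b), maf_control = c_ / (c_ + d),
         p = fisher_two_sided(a, b, c_, d),
         or = orci$or, ci_lo = orci$ci_lo, ci_hi = orci$ci_hi)
}
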