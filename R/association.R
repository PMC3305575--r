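# Single-variant case-control screen: allelic 2x2 tables, two-sided Fisher
# exact test, odds ratios with Woolf confidence intervals, MAF and
# missingness filters, top-K ranking, and the minimal detectable
# minor-allele count for a given sample size.

#' Screen configuration
#'
#' @param maf_min Minimum pooled minor allele frequency (cases plus
#'   controls, non-missing alleles) for a variant to be tested.
#' @param miss_max Variants with genotype missingness at or above this
#'   fraction are excluded (missingness must be strictly below it).
#' @param top_k Number of top-ranked variants selected for replication.
#' @param alpha Nominal significance level.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(maf_min = 0.08, miss_max = 0.10, top_k = 5,
                          alpha = 0.05) {
  stopifnot(maf_min > 0, maf_min <= 1, miss_max > 0, miss_max <= 1,
            alpha > 0, alpha <= 1, top_k >= 1)
  structure(as.list(environment()), class = "screen_config")
}

#' Allelic 2x2 table for one site
#'
#' Alleles are counted over non-missing genotypes (two per individual; a
#' heterozygote contributes one minor and one major allele). The minor
#' allele is defined on the pooled case-plus-control non-missing alleles.
#'
#' @param gm A `geno_matrix`.
#' @param site_id Site identifier.
#' @return List: `table` (2x2 matrix, rows case/control, columns
#'   minor/major), `maf_pooled`, `missingness`, `minor_is_alt`.
#' @export
allele_table <- function(gm, site_id) {
  j <- match(site_id, gm$sites$site_id)
  if (is.na(j)) abort(sprintf("site %s not in matrix.", site_id))
  g <- gm$geno[, j]
  case <- gm$samples$status == 2L
  if (all(is.na(g))) abort("site is fully missing.")
  alt_case <- sum(g[case], na.rm = TRUE)
  alt_ctrl <- sum(g[!case], na.rm = TRUE)
  n_case <- 2 * sum(!is.na(g[case]))
  n_ctrl <- 2 * sum(!is.na(g[!case]))
  alt_f <- (alt_case + alt_ctrl) / (n_case + n_ctrl)
  minor_is_alt <- alt_f <= 0.5
  minor_case <- if (minor_is_alt) alt_case else n_case - alt_case
  minor_ctrl <- if (minor_is_alt) alt_ctrl else n_ctrl - alt_ctrl
  tab <- matrix(c(minor_case, n_case - minor_case,
                  minor_ctrl, n_ctrl - minor_ctrl),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("minor", "major")))
  list(table = tab, maf_pooled = min(alt_f, 1 - alt_f),
       missingness = mean(is.na(g)), minor_is_alt = minor_is_alt)
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Exact conditional test: the two-sided p-value is the sum of
#' hypergeometric point probabilities not exceeding that of the observed
#' table (the sum-of-smaller-probabilities definition; no mid-p). A zero
#' margin carries no information and returns p = 1. Vectorized over tables.
#'
#' @param a,b,c,d Cell counts: `a` case-minor, `b` case-major, `c`
#'   control-minor, `d` control-major (or any 2x2 layout; the test is
#'   invariant to transposition).
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  stopifnot(length(b) == length(a), length(c) == length(a),
            length(d) == length(a))
  if (length(a) == 0) return(numeric(0))
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative.")
  m <- a + c          # minor-allele total
  r1 <- a + b         # case alleles
  n <- a + b + c + d
  vapply(seq_along(a), function(i) {
    if (m[i] == 0 || m[i] == n[i] || r1[i] == 0 || r1[i] == n[i]) return(1)
    lo <- max(0L, r1[i] - (n[i] - m[i]))
    hi <- min(r1[i], m[i])
    x <- lo:hi
    px <- dhyper(x, m[i], n[i] - m[i], r1[i])
    p_obs <- px[match(a[i], x)]
    # relative tolerance guards against floating-point ties
    min(1, sum(px[px <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Allelic odds ratio with 95% confidence interval
#'
#' Cross-product ratio `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell. The confidence
#' interval is the Woolf (log-OR normal) interval on the same (possibly
#' corrected) counts.
#'
#' @inheritParams fisher_two_sided
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble (or, ci_lo, ci_hi), one row per table.
#' @export
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero
  b <- b + 0.5 * zero
  c <- c + 0.5 * zero
  d <- d + 0.5 * zero
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(or = or, ci_lo = exp(log(or) - z * se),
         ci_hi = exp(log(or) + z * se))
}

#' Single-variant case-control screen
#'
#' Tabulates every site of the genotype matrix, excludes sites below the
#' pooled MAF floor or at/above the missingness ceiling, tests survivors
#' with the two-sided Fisher exact test, and ranks by ascending p (ties
#' broken by larger absolute log odds ratio, then genomic position). The
#' `top_k` highest-ranked variants are marked selected; when fewer
#' survivors exist than `top_k`, all are selected with a notice.
#'
#' @param gm A `geno_matrix`.
#' @param config A [screen_config()].
#' @return Object of class `assoc_screen`: list with `results` (all sites,
#'   with `tested` flag, counts, p, OR, CI, rank) and `config`.
#' @export
screen <- function(gm, config = screen_config()) {
  stats <- site_stats(gm)
  case <- gm$samples$status == 2L
  g <- gm$geno
  alt_case <- colSums(g[case, , drop = FALSE], na.rm = TRUE)
  alt_ctrl <- colSums(g[!case, , drop = FALSE], na.rm = TRUE)
  n_case_al <- 2 * colSums(!is.na(g[case, , drop = FALSE]))
  n_ctrl_al <- 2 * colSums(!is.na(g[!case, , drop = FALSE]))
  tot <- n_case_al + n_ctrl_al
  minor_is_alt <- ifelse(tot > 0, (alt_case + alt_ctrl) / tot <= 0.5, TRUE)
  a <- ifelse(minor_is_alt, alt_case, n_case_al - alt_case)
  c_ <- ifelse(minor_is_alt, alt_ctrl, n_ctrl_al - alt_ctrl)
  res <- gm$sites |>
    mutate(case_minor = as.integer(a), case_major = as.integer(n_case_al - a),
           control_minor = as.integer(c_),
           control_major = as.integer(n_ctrl_al - c_),
           maf_pooled = stats$maf, missingness = stats$missingness,
           tested = .data$maf_pooled >= config$maf_min &
             .data$missingness < config$miss_max & tot > 0)

  tt <- res |> filter(.data$tested)
  p <- fisher_two_sided(tt$case_minor, tt$case_major, tt$control_minor,
                        tt$control_major)
  orci <- odds_ratio_ci(tt$case_minor, tt$case_major, tt$control_minor,
                        tt$control_major)
  tt <- tt |>
    mutate(p = p, or = orci$or, ci_lo = orci$ci_lo, ci_hi = orci$ci_hi) |>
    arrange(.data$p, dplyr::desc(abs(log(.data$or))), .data$contig,
            .data$pos) |>
    mutate(rank = row_number(),
           selected = .data$rank <= config$top_k)
  if (nrow(tt) < config$top_k) {
    inform(sprintf("only %d variants survive filtering (top_k = %d); all selected.",
                   nrow(tt), config$top_k))
  }
  results <- res |>
    left_join(tt |> select("site_id", "p", "or", "ci_lo", "ci_hi", "rank",
                           "selected"),
              by = "site_id") |>
    mutate(selected = ifelse(is.na(.data$selected), FALSE, .data$selected)) |>
    arrange(dplyr::desc(.data$tested), .data$rank, .data$contig, .data$pos)
  structure(list(results = results, config = config), class = "assoc_screen")
}

#' @export
print.assoc_screen <- function(x, ...) {
  n_sel <- sum(x$results$selected)
  cat("<assoc_screen> ", nrow(x$results), " sites, ",
      sum(x$results$tested), " tested, top-", n_sel, " selected\n", sep = "")
  print(x$results |> filter(.data$selected) |>
          select("site_id", "case_minor", "control_minor", "p", "or"), ...)
  invisible(x)
}

#' @rdname screen
#' @param x An `assoc_screen` object.
#' @param ... Unused.
#' @export
tidy.assoc_screen <- function(x, ...) x$results

#' @rdname screen
#' @export
glance.assoc_screen <- function(x, ...) {
  tibble(n_sites = nrow(x$results), n_tested = sum(x$results$tested),
         n_selected = sum(x$results$selected),
         min_p = suppressWarnings(min(x$results$p, na.rm = TRUE)))
}

#' Minimal detectable minor-allele count
#'
#' The smallest minor-allele count `m` such that the maximally unbalanced
#' allelic table (all `m` minor alleles in one group) reaches two-sided
#' Fisher significance below `alpha` — i.e. the MAF floor under which no
#' variant can possibly reach significance at the given sample size.
#'
#' @param n_case_alleles,n_control_alleles Allele totals per group
#'   (2 x individuals when no genotypes are missing).
#' @param alpha Significance level (default 0.05).
#' @return Integer minor-allele count.
#' @export
min_detectable_mac <- function(n_case_alleles, n_control_alleles,
                               alpha = 0.05) {
  stopifnot(n_case_alleles > 0, n_control_alleles > 0)
  for (m in seq_len(n_case_alleles + n_control_alleles)) {
    p <- if (m <= n_case_alleles) {
      fisher_two_sided(m, n_case_alleles - m, 0L, n_control_alleles)
    } else {
      1
    }
    p2 <- if (m <= n_control_alleles) {
      fisher_two_sided(0L, n_case_alleles, m, n_control_alleles - m)
    } else {
      1
    }
    if (min(p, p2) < alpha) return(m)
  }
  abort("no minor-allele count reaches significance at this sample size.")
}
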