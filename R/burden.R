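# Collapsing (burden) analysis: total nonsynonymous minor-allele counts in
# a functional gene set compared between cases and controls with an exact
# binomial allocation test.

#' Collapse qualifying variant alleles over a gene set
#'
#' Per-sample burden is the sum over qualifying sites of minor-allele
#' dosage (het = 1, homvar = 2, missing contributes 0). Qualifying sites
#' are those annotated to a gene of the set with a consequence in
#' `consequences` (nonsynonymous SNVs by default); an optional logical
#' `damaging` column in the annotations restricts further to
#' predicted-damaging sites when `damaging_only = TRUE`.
#'
#' @param gm A `geno_matrix`.
#' @param annotations Tibble with `site_id`, `gene`, `consequence` (and
#'   optionally `damaging`).
#' @param gene_set Character vector of gene names (must be non-empty).
#' @param consequences Qualifying consequence classes.
#' @param damaging_only Restrict to annotated-damaging sites.
#' @return List: `T_case`, `T_control`, `per_sample` (tibble sample,
#'   status, burden), `qualifying_sites`.
#' @export
collapse_burden <- function(gm, annotations, gene_set,
                            consequences = c("missense", "nonsense"),
                            damaging_only = FALSE) {
  if (length(gene_set) == 0) abort("gene set must be non-empty.")
  qual <- annotations |>
    filter(.data$gene %in% gene_set, .data$consequence %in% consequences)
  if (damaging_only) {
    if (!"damaging" %in% names(qual)) {
      abort("`damaging_only = TRUE` needs a `damaging` annotation column.")
    }
    qual <- qual |> filter(.data$damaging)
  }
  sites <- intersect(qual$site_id, gm$sites$site_id)
  g <- gm$geno[, sites, drop = FALSE]
  burden <- rowSums(g, na.rm = TRUE)
  per_sample <- tibble(sample = rownames(gm$geno),
                       status = gm$samples$status, burden = burden)
  list(T_case = sum(burden[gm$samples$status == 2L]),
       T_control = sum(burden[gm$samples$status == 1L]),
       per_sample = per_sample, qualifying_sites = sites)
}

#' Exact binomial burden test
#'
#' Conditional on the total number of observed qualifying alleles
#' `n = T_case + T_control`, each allele falls in a case with probability
#' `p0 = n_case / (n_case + n_control)` under the null of no enrichment.
#' The one-sided (case-excess) p-value is `P(X >= T_case)` for
#' `X ~ Binomial(n, p0)`; `alternative = "two.sided"` doubles the smaller
#' tail (capped at 1). Zero observed alleles give p = 1.
#'
#' @param T_case,T_control Group allele totals at qualifying sites.
#' @param n_case,n_control Individuals per group.
#' @param alternative `"greater"` (case excess; default) or `"two.sided"`.
#' @return The p-value.
#' @export
binomial_burden_test <- function(T_case, T_control, n_case, n_control,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(T_case >= 0, T_control >= 0, n_case >= 1, n_control >= 1)
  n <- T_case + T_control
  if (n == 0) return(1)
  p0 <- n_case / (n_case + n_control)
  upper <- pbinom(T_case - 1, n, p0, lower.tail = FALSE)
  if (alternative == "greater") return(upper)
  lower <- pbinom(T_case, n, p0)
  min(1, 2 * min(upper, lower))
}

#' Run the burden analysis for one gene set
#'
#' Convenience wrapper combining [collapse_burden()] and
#' [binomial_burden_test()].
#'
#' @inheritParams collapse_burden
#' @inheritParams binomial_burden_test
#' @param set_name Name of the gene set (for the report).
#' @return Object of class `burden_test` with tidy()/glance() methods.
#' @export
burden_test <- function(gm, annotations, gene_set, set_name = "set",
                        consequences = c("missense", "nonsense"),
                        damaging_only = FALSE,
                        alternative = c("greater", "two.sided")) {
  col <- collapse_burden(gm, annotations, gene_set, consequences,
                         damaging_only)
  n_case <- sum(gm$samples$status == 2L)
  n_control <- sum(gm$samples$status == 1L)
  p <- binomial_burden_test(col$T_case, col$T_control, n_case, n_control,
                            alternative)
  structure(list(set_name = set_name, T_case = col$T_case,
                 T_control = col$T_control,
                 mean_case = col$T_case / n_case,
                 mean_control = col$T_control / n_control,
                 n_case = n_case, n_control = n_control, p = p,
                 qualifying_sites = col$qualifying_sites,
                 per_sample = col$per_sample),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf(paste0("<burden_test> %s: %d alleles in %d cases vs %d in %d",
                     " controls (mean %.2f vs %.2f), binomial p = %.3g\n"),
              x$set_name, x$T_case, x$n_case, x$T_control, x$n_control,
              x$mean_case, x$mean_control, x$p))
  invisible(x)
}

#' @rdname burden_test
#' @param x A `burden_test` object.
#' @param ... Unused.
#' @export
tidy.burden_test <- function(x, ...) {
  tibble(gene_set = x$set_name, T_case = x$T_case, T_control = x$T_control,
         mean_case = x$mean_case, mean_control = x$mean_control,
         n_qualifying_sites = length(x$qualifying_sites), p = x$p)
}

#' @rdname burden_test
#' @export
glance.burden_test <- function(x, ...) tidy(x)
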