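# Projection of per-sample calls, QC failures and coverage onto the union
# of variable sites: every sample gets an explicit genotype in
# {homref, het, homvar, missing} at every site found variable in at least
# one individual, with PLINK PED/MAP and multi-sample VCF export.
#
# Genotypes are stored as minor(alt)-allele dosage: 0 = homref, 1 = het,
# 2 = homvar, NA = missing.

#' Union of variable sites across callsets
#'
#' Sorted, deterministic union of the distinct `(contig, pos, ref, alt)`
#' keys of PASS calls across all samples. Conflicting reference bases at
#' one position indicate panel inconsistency and raise an error.
#'
#' @param calls QC-annotated call tibble (all samples).
#' @return Site tibble (site_id, contig, pos, ref, alt).
#' @export
union_sites <- function(calls) {
  pass <- calls |> filter(.data$qc_status == "PASS")
  refs <- pass |> distinct(.data$contig, .data$pos, .data$ref)
  if (anyDuplicated(refs[, c("contig", "pos")])) {
    abort("conflicting reference bases at one position across callsets.")
  }
  pass |>
    distinct(.data$contig, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$contig, .data$pos, .data$alt) |>
    mutate(site_id = paste(.data$contig, .data$pos, .data$ref, .data$alt,
                           sep = ":")) |>
    select("site_id", "contig", "pos", "ref", "alt")
}

#' Per-sample read depth at given sites
#'
#' @param reads Reads of the samples (post duplicate/mapq filtering), with a
#'   `sample` column.
#' @param sites Site tibble with `contig`, `pos`.
#' @return Tibble (sample, site_id or contig/pos, depth).
#' @keywords internal
depth_at_sites <- function(reads, sites) {
  reads |>
    group_by(.data$sample, .data$contig) |>
    group_map(function(rr, key) {
      ss <- sites |> filter(.data$contig == key$contig)
      if (nrow(ss) == 0) return(NULL)
      tibble(sample = key$sample, contig = key$contig, pos = ss$pos,
             depth = interval_depth(rr$start, rr$end, ss$pos))
    }) |>
    bind_rows()
}

#' Build the cross-sample genotype matrix
#'
#' For each sample at each union site: a PASS call supplies its genotype
#' (het or homvar); QC-failed variant evidence at the position makes the
#' genotype missing (the evidence is neither trustworthy enough to call nor
#' ignorable); with no variant evidence, a read depth of at least
#' `min_ref_depth` supports a homozygous-reference call, and anything less
#' is missing.
#'
#' @param calls QC-annotated calls for all samples (PASS and FAIL retained).
#' @param reads Filtered reads for all samples (for reference depth).
#' @param phenotypes Tibble (sample, status) with 1 = control, 2 = case.
#' @param min_ref_depth Depth supporting a confident homref genotype
#'   (defaults to the same 10X used for confident variant calls).
#' @return A `geno_matrix`: list with `sites`, `samples` and integer matrix
#'   `geno` (samples x sites; NA = missing).
#' @export
build_genotype_matrix <- function(calls, reads, phenotypes,
                                  min_ref_depth = 10) {
  sites <- union_sites(calls)
  samples <- phenotypes$sample
  geno <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(sites),
                 dimnames = list(samples, sites$site_id))

  if (nrow(sites) > 0) {
    sitekey <- paste(sites$contig, sites$pos)
    upos <- sites |> distinct(.data$contig, .data$pos)
    ukey <- paste(upos$contig, upos$pos)
    dep <- depth_at_sites(reads |> filter(.data$sample %in% samples), upos)
    dmat <- matrix(0L, nrow = length(samples), ncol = nrow(upos),
                   dimnames = list(samples, ukey))
    dmat[cbind(match(dep$sample, samples),
               match(paste(dep$contig, dep$pos), ukey))] <- dep$depth
    dsite <- dmat[, sitekey, drop = FALSE]  # multi-allelic sites share depth
    geno[] <- ifelse(dsite >= min_ref_depth, 0L, NA_integer_)

    # QC-failed variant evidence at a position -> missing
    fails <- calls |> filter(.data$qc_status != "PASS",
                             .data$sample %in% samples)
    if (nrow(fails) > 0) {
      fmat <- matrix(FALSE, nrow = length(samples), ncol = nrow(upos),
                     dimnames = list(samples, ukey))
      fk <- paste(fails$contig, fails$pos)
      hit <- fk %in% ukey
      fmat[cbind(match(fails$sample[hit], samples),
                 match(fk[hit], ukey))] <- TRUE
      geno[fmat[, sitekey, drop = FALSE]] <- NA_integer_
    }

    # PASS calls supply their genotype at their own alt
    pass <- calls |> filter(.data$qc_status == "PASS",
                            .data$sample %in% samples) |>
      mutate(col = match(paste(.data$contig, .data$pos, .data$ref,
                               .data$alt, sep = ":"),
                         sites$site_id))
    geno[cbind(match(pass$sample, samples), pass$col)] <-
      ifelse(pass$genotype == "het", 1L, 2L)
  }

  structure(list(sites = sites,
                 samples = phenotypes |> select("sample", "status"),
                 geno = geno),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$geno), " samples x ", ncol(x$geno),
      " sites; missing ",
      sprintf("%.1f%%", 100 * mean(is.na(x$geno))), "\n", sep = "")
  invisible(x)
}

#' Tidy a genotype matrix to long form
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return Long tibble (sample, status, site_id, genotype) where genotype is
#'   the minor-allele dosage (NA = missing).
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(sample = rep(rownames(x$geno), ncol(x$geno)),
         site_id = rep(colnames(x$geno), each = nrow(x$geno)),
         genotype = as.vector(x$geno)) |>
    left_join(x$samples, by = "sample") |>
    select("sample", "status", "site_id", "genotype")
}

#' Per-site summary statistics
#'
#' Missingness is the fraction of samples with a missing genotype; minor
#' allele frequency is computed over non-missing alleles only (the minor
#' allele is whichever of ref/alt is rarer in the pooled non-missing
#' genotypes).
#'
#' @param gm A `geno_matrix`.
#' @return Tibble (site_id, n_homref, n_het, n_homvar, n_missing,
#'   missingness, alt_freq, maf, mac).
#' @export
site_stats <- function(gm) {
  g <- gm$geno
  n <- nrow(g)
  n_missing <- colSums(is.na(g))
  n_het <- colSums(g == 1L, na.rm = TRUE)
  n_homvar <- colSums(g == 2L, na.rm = TRUE)
  n_homref <- n - n_missing - n_het - n_homvar
  alleles <- 2 * (n - n_missing)
  alt_alleles <- colSums(g, na.rm = TRUE)
  alt_freq <- ifelse(alleles > 0, alt_alleles / alleles, NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  mac <- pmin(alt_alleles, alleles - alt_alleles)
  tibble(site_id = gm$sites$site_id, n_homref = as.integer(n_homref),
         n_het = as.integer(n_het), n_homvar = as.integer(n_homvar),
         n_missing = as.integer(n_missing),
         missingness = n_missing / n, alt_freq = alt_freq, maf = maf,
         mac = as.integer(mac))
}

#' Genotyping success rate
#'
#' Fraction of (sample, site) genotypes that are non-missing.
#' @param gm A `geno_matrix`.
#' @return A proportion.
#' @export
genotyping_success <- function(gm) mean(!is.na(gm$geno))

#' Write PLINK PED/MAP text files
#'
#' MAP rows are `(contig, site_id, 0, pos)`; PED rows are
#' `(FID, IID, 0, 0, sex, phenotype, allele pairs)` with actual bases as
#' alleles and `0 0` for missing, whitespace-delimited (PLINK 1 text
#' dialect). Sex is written as 0 (unknown) unless a `sex` column is present
#' in `gm$samples`.
#'
#' @param gm A `geno_matrix`.
#' @param prefix Output path prefix (writes `<prefix>.ped`,
#'   `<prefix>.map`).
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(gm, prefix) {
  map <- sprintf("%s\t%s\t0\t%d", gm$sites$contig, gm$sites$site_id,
                 gm$sites$pos)
  readr::write_lines(map, paste0(prefix, ".map"))

  n <- nrow(gm$geno)
  sex <- if ("sex" %in% names(gm$samples)) gm$samples$sex else rep(0L, n)
  allele_pair <- function(g, ref, alt) {
    dplyr::case_when(is.na(g) ~ "0 0",
                     g == 0L ~ paste(ref, ref),
                     g == 1L ~ paste(ref, alt),
                     TRUE ~ paste(alt, alt))
  }
  pairs <- vapply(seq_len(ncol(gm$geno)), function(j) {
    allele_pair(gm$geno[, j], gm$sites$ref[j], gm$sites$alt[j])
  }, character(n))
  if (n == 1) pairs <- matrix(pairs, nrow = 1)
  ped <- paste(gm$samples$sample, gm$samples$sample, 0, 0, sex,
               gm$samples$status,
               if (ncol(gm$geno) > 0) apply(pairs, 1, paste, collapse = " ")
               else "")
  readr::write_lines(trimws(ped), paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK PED/MAP text files back to a genotype matrix
#'
#' Inverse of [write_ped_map()] for site ids in the `contig:pos:ref:alt`
#' form; a write/read round trip reproduces the matrix exactly.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A `geno_matrix`.
#' @export
read_ped_map <- function(prefix) {
  map <- readr::read_tsv(paste0(prefix, ".map"),
                         col_names = c("contig", "site_id", "cm", "pos"),
                         col_types = "ccii")
  parts <- stringr::str_split_fixed(map$site_id, ":", 4)
  sites <- tibble(site_id = map$site_id, contig = map$contig, pos = map$pos,
                  ref = parts[, 3], alt = parts[, 4])
  ped <- readr::read_lines(paste0(prefix, ".ped"))
  toks <- strsplit(trimws(ped), "\\s+")
  samples <- tibble(sample = vapply(toks, `[[`, character(1), 2),
                    status = as.integer(vapply(toks, `[[`, character(1), 6)))
  geno <- matrix(NA_integer_, nrow = length(toks), ncol = nrow(sites),
                 dimnames = list(samples$sample, sites$site_id))
  for (i in seq_along(toks)) {
    al <- toks[[i]][-(1:6)]
    if (length(al) != 2 * nrow(sites)) abort("malformed PED row.")
    a1 <- al[c(TRUE, FALSE)]
    a2 <- al[c(FALSE, TRUE)]
    miss <- a1 == "0" | a2 == "0"
    dose <- (a1 == sites$alt) + (a2 == sites$alt)
    geno[i, ] <- ifelse(miss, NA_integer_, as.integer(dose))
  }
  structure(list(sites = sites, samples = samples, geno = geno),
            class = "geno_matrix")
}
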