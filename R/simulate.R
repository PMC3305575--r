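# Synthetic cohort generator: truth genotypes under a retrospective
# case-control model and pre-aligned barcoded reads with PCR duplicates,
# quality-driven base errors and a configurable on-target fraction.

#' Simulation configuration
#'
#' Houses the study-design constants of the emulated experiment: a pilot
#' sequencing cohort of 10 cases and 12 controls at 42X mean on-target
#' coverage with 7% of raw reads on target, one common missense risk SNP
#' (control MAF 0.22, allelic odds ratio 1.45) and an excess of rare
#' missense alleles in the anticoagulant gene set in cases.
#'
#' @param n_cases,n_controls Individuals per group in the sequencing cohort.
#' @param mean_depth Mean on-target coverage per sample (reads per site).
#' @param on_target_fraction Proportion of raw reads mapping to the target.
#' @param dup_rate Proportion of fragments emitted twice (PCR duplicates).
#' @param read_len Maximum read length in bp.
#' @param read_len_jitter Reads are right-trimmed by 0 to this many bases
#'   (uniformly), emulating adaptor/quality trimming; this also makes
#'   fragment coordinates distinctive enough that non-duplicate fragments
#'   never collide.
#' @param base_qualities,base_quality_probs Two-point Phred quality mixture
#'   for simulated bases; error per base is `10^(-Q/10)`.
#' @param mapq,low_mapq,low_mapq_frac Simulated mapping quality: `mapq` by
#'   default, down-weighted to `low_mapq` for a `low_mapq_frac` fraction of
#'   reads (exercises the mapping-quality filter).
#' @param barcode_length,max_mismatch Barcode tag length and the maximum
#'   Hamming mismatch tolerated at demultiplexing.
#' @param common_risk List `(gene, q, or)`: the common risk SNP is placed at
#'   a missense-capable CDS position of `gene`, with control minor allele
#'   frequency `q` and allelic odds ratio `or`.
#' @param rare_burden List `(set, per_gene, q, enrichment)`: each gene of
#'   gene set `set` receives `per_gene` rare missense sites at control MAF
#'   `q`, with case allele frequency `enrichment * q`.
#' @param n_neutral_sites Background variable sites spread over the target,
#'   with control MAF log-uniform on `neutral_maf_range` (an approximation
#'   of the 1/x neutral frequency spectrum).
#' @param neutral_maf_range Range of neutral control MAFs.
#' @param seed Master seed; fixes all downstream randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 10, n_controls = 12, mean_depth = 42,
                       on_target_fraction = 0.07, dup_rate = 0.10,
                       read_len = 50, read_len_jitter = 15L,
                       base_qualities = c(20L, 30L),
                       base_quality_probs = c(0.5, 0.5),
                       mapq = 60L, low_mapq = 30L, low_mapq_frac = 0.05,
                       barcode_length = 6L, max_mismatch = 1L,
                       common_risk = list(gene = "FGA", q = 0.22, or = 1.45),
                       rare_burden = list(set = "anticoagulant",
                                          per_gene = 1L, q = 0.02,
                                          enrichment = 5),
                       n_neutral_sites = 40L,
                       neutral_maf_range = c(0.01, 0.5),
                       seed = 1L) {
  cfg <- as.list(environment())
  props <- c(cfg$on_target_fraction, cfg$dup_rate, cfg$low_mapq_frac,
             cfg$common_risk$q, cfg$rare_burden$q)
  if (any(props < 0 | props > 1)) abort("proportions must lie in [0, 1].")
  if (cfg$common_risk$or <= 0) abort("odds ratio must be positive.")
  if (cfg$mean_depth <= 0) abort("mean_depth must be positive.")
  if (cfg$n_cases < 1 || cfg$n_controls < 1) abort("need >= 1 per group.")
  structure(cfg, class = "sim_config")
}

#' Case allele frequency implied by an allelic odds ratio
#'
#' Retrospective sampling model: with control minor allele frequency `q` and
#' allelic odds ratio `or`, cases carry the minor allele at frequency
#' `or * q / (1 + q * (or - 1))`. Reduces to `q` when `or = 1`.
#'
#' @param q Control minor allele frequency.
#' @param or Allelic odds ratio.
#' @return Case minor allele frequency.
#' @export
case_allele_freq <- function(q, or) {
  stopifnot(all(q >= 0 & q <= 1), all(or > 0))
  or * q / (1 + q * (or - 1))
}

sample_ids <- function(n_cases, n_controls) {
  c(sprintf("DVT_P_%02d", seq_len(n_cases)),
    sprintf("DVT_C_%02d", seq_len(n_controls)))
}

# pick CDS positions of `gene` where some alternate allele is missense
pick_missense_sites <- function(panel, gene, n) {
  cmap <- cds_map(panel, gene)
  cand <- cmap[sample.int(nrow(cmap)), ]
  found <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(found) >= n) break
    ref <- substr(panel$reference[cand$contig[i]], cand$pos[i], cand$pos[i])
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    for (alt in sample(alts)) {
      cls <- classify_snv(tibble(contig = cand$contig[i], pos = cand$pos[i],
                                 ref = ref, alt = alt), panel)
      if (cls$consequence == "missense") {
        found[[length(found) + 1]] <- cls
        break
      }
    }
  }
  if (length(found) < n) {
    abort(sprintf("could not place %d missense sites in gene %s", n, gene))
  }
  bind_rows(found) |> arrange(.data$contig, .data$pos)
}

#' Simulate truth genotypes for a case-control cohort
#'
#' Control genotypes are drawn under Hardy-Weinberg equilibrium at each
#' site's control minor allele frequency. At the common risk site the case
#' allele frequency follows [case_allele_freq()]; at rare-burden sites the
#' case allele frequency is the control frequency times the configured
#' enrichment (capped at 0.5). Neutral background sites share the same
#' frequency in both groups.
#'
#' @param panel A `seq_panel`.
#' @param config A `sim_config`.
#' @return A `truth_set`: list with `sites` (tibble: site_id, contig, pos,
#'   ref, alt, gene, consequence, role, q_control, q_case), `genotypes`
#'   (samples x sites integer matrix of minor-allele dosages 0/1/2) and
#'   `phenotypes` (tibble: sample, status with 1 = control, 2 = case).
#' @export
simulate_genotypes <- function(panel, config = sim_config()) {
  stopifnot(inherits(panel, "seq_panel"), inherits(config, "sim_config"))
  if (!config$common_risk$gene %in% panel$genes$gene) {
    abort("risk gene is not on the panel.")
  }
  with_stage_seed(config$seed, "genotypes", {
    risk <- pick_missense_sites(panel, config$common_risk$gene, 1) |>
      mutate(role = "risk", q_control = config$common_risk$q,
             q_case = case_allele_freq(config$common_risk$q,
                                       config$common_risk$or))

    burden_genes <- panel$gene_sets |>
      filter(.data$set == config$rare_burden$set) |>
      pull("gene")
    if (length(burden_genes) == 0) abort("rare-burden gene set is empty.")
    burden <- bind_rows(lapply(burden_genes, function(g) {
      pick_missense_sites(panel, g, config$rare_burden$per_gene)
    })) |>
      mutate(role = "burden", q_control = config$rare_burden$q,
             q_case = pmin(config$rare_burden$enrichment *
                             config$rare_burden$q, 0.5))

    # neutral sites: uniform over targeted positions, log-uniform MAF
    tpos <- panel$targets |>
      rowwise() |>
      reframe(contig = .data$contig,
              pos = seq.int(.data$start + 1L, .data$end))
    taken <- paste(c(risk$contig, burden$contig), c(risk$pos, burden$pos))
    tpos <- tpos |> filter(!paste(.data$contig, .data$pos) %in% taken)
    idx <- sample.int(nrow(tpos), min(config$n_neutral_sites, nrow(tpos)))
    r <- config$neutral_maf_range
    neutral <- tpos[idx, ] |>
      mutate(ref = substring(panel$reference[.data$contig], .data$pos,
                             .data$pos),
             alt = vapply(.data$ref,
                          function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                     b), 1),
                          character(1), USE.NAMES = FALSE)) |>
      classify_snv(panel) |>
      mutate(role = "neutral",
             q_control = r[1] * (r[2] / r[1])^runif(length(idx)),
             q_case = .data$q_control)

    sites <- bind_rows(risk, burden, neutral) |>
      arrange(.data$contig, .data$pos) |>
      mutate(site_id = paste(.data$contig, .data$pos, .data$ref, .data$alt,
                             sep = ":")) |>
      select("site_id", "contig", "pos", "ref", "alt", "gene",
             "consequence", "protein_change", "role", "q_control", "q_case")

    samples <- sample_ids(config$n_cases, config$n_controls)
    status <- c(rep(2L, config$n_cases), rep(1L, config$n_controls))
    freq <- rbind(matrix(rep(sites$q_case, config$n_cases),
                         nrow = config$n_cases, byrow = TRUE),
                  matrix(rep(sites$q_control, config$n_controls),
                         nrow = config$n_controls, byrow = TRUE))
    geno <- matrix(rbinom(length(freq), 2L, as.vector(freq)),
                   nrow = nrow(freq),
                   dimnames = list(samples, sites$site_id))

    structure(list(sites = sites, genotypes = geno,
                   phenotypes = tibble(sample = samples, status = status)),
              class = "truth_set")
  })
}

#' Perfect genotype matrix from a truth set
#'
#' Projects the simulated truth genotypes directly into a `geno_matrix`
#' (no reads, no missingness): the genotype-level analogue of a sequencing
#' run with perfect calling, used for genotype-level simulation studies of
#' the association, burden and replication stages.
#'
#' @param truth A `truth_set`.
#' @param segregating_only Drop sites with no carrier in the cohort
#'   (default TRUE, matching the variable-site union of a real run).
#' @return A `geno_matrix`.
#' @export
truth_to_matrix <- function(truth, segregating_only = TRUE) {
  keep <- if (segregating_only) colSums(truth$genotypes) > 0 else
    rep(TRUE, ncol(truth$genotypes))
  sites <- truth$sites[keep, c("site_id", "contig", "pos", "ref", "alt")]
  structure(list(sites = sites,
                 samples = truth$phenotypes |> select("sample", "status"),
                 geno = truth$genotypes[, keep, drop = FALSE]),
            class = "geno_matrix")
}

#' Redraw genotypes for an existing truth set
#'
#' Keeps the site panel (positions, frequencies, roles) and draws a fresh
#' genotype realization — the cheap way to run replicate simulations over
#' the same design.
#'
#' @param truth A `truth_set`.
#' @return A `truth_set` with new genotypes.
#' @export
redraw_genotypes <- function(truth) {
  freq <- t(vapply(truth$phenotypes$status,
                   function(s) if (s == 2L) truth$sites$q_case else
                     truth$sites$q_control,
                   numeric(nrow(truth$sites))))
  geno <- matrix(rbinom(length(freq), 2L, as.vector(freq)),
                 nrow = nrow(freq),
                 dimnames = dimnames(truth$genotypes))
  structure(list(sites = truth$sites, genotypes = geno,
                 phenotypes = truth$phenotypes),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", nrow(x$phenotypes), " samples (",
      sum(x$phenotypes$status == 2), " cases), ", nrow(x$sites),
      " variable sites\n", sep = "")
  invisible(x)
}

#' Generate a barcode manifest
#'
#' Draws random sample barcodes whose pairwise Hamming distance exceeds
#' `2 * max_mismatch`, guaranteeing unambiguous assignment at that mismatch
#' tolerance.
#'
#' @param samples Character vector of sample ids.
#' @param barcode_length Tag length in bases.
#' @param max_mismatch Mismatches tolerated at demultiplexing.
#' @return Tibble (sample, barcode) with attribute `max_mismatch`.
#' @export
make_barcode_manifest <- function(samples, barcode_length = 6L,
                                  max_mismatch = 1L) {
  min_dist <- 2L * max_mismatch + 1L
  codes <- character(0)
  tries <- 0L
  while (length(codes) < length(samples)) {
    cand <- paste(sample(c("A", "C", "G", "T"), barcode_length,
                         replace = TRUE), collapse = "")
    if (all(vapply(codes, function(b) hamming(b, cand) >= min_dist,
                   logical(1)))) {
      codes <- c(codes, cand)
    }
    tries <- tries + 1L
    if (tries > 20000L) {
      abort("cannot place barcodes at the required distance; increase length.")
    }
  }
  structure(tibble(sample = samples, barcode = codes),
            max_mismatch = max_mismatch)
}

# draw per-base Phred qualities from the configured mixture
draw_quals <- function(n, config) {
  sample(config$base_qualities, n, replace = TRUE,
         prob = config$base_quality_probs)
}

# apply quality-implied errors to a concatenated base string
apply_errors <- function(bases_chr, quals_int) {
  err <- runif(length(quals_int)) < 10^(-quals_int / 10)
  if (any(err)) {
    alt <- c("A", "C", "G", "T")
    cur <- bases_chr[err]
    bases_chr[err] <- vapply(cur, function(b) sample(setdiff(alt, b), 1),
                             character(1), USE.NAMES = FALSE)
  }
  bases_chr
}

#' Simulate barcoded aligned reads for a cohort
#'
#' Reads are emitted pre-aligned at their true coordinates (mapping itself is
#' out of scope): per target interval, fragment counts are Poisson so that
#' interior coverage has mean `mean_depth`; a `dup_rate` fraction of
#' fragments is emitted twice with identical coordinates (PCR duplicates
#' carry independent sequencing errors and mapping quality); per-base errors
#' follow the Phred quality mixture; each read carries its sample's barcode
#' tag, itself subject to sequencing error. Off-target reads are bookkeeping
#' rows (flagged, no sequence) so files stay small.
#'
#' @param panel A `seq_panel`.
#' @param truth A `truth_set` from [simulate_genotypes()].
#' @param config A `sim_config`.
#' @param manifest Optional barcode manifest; generated when `NULL`.
#' @param run_id Integer distinguishing repeat sequencing runs of the same
#'   cohort (fresh error/coverage realization, same truth).
#' @param samples Subset of samples to sequence (default: all).
#' @return List with `reads` (tibble: read_id, tag, contig, start, end,
#'   strand, mapq, bases, quals, plus `truth_sample`, the generating sample,
#'   kept for recovery checks), `manifest`, per-sample `counts`
#'   (n_on_target, n_off_target) and cohort totals `n_on_target`,
#'   `n_off_target`. Off-target reads are counted, never emitted as rows.
#' @export
simulate_reads <- function(panel, truth, config = sim_config(),
                           manifest = NULL, run_id = 1L, samples = NULL) {
  stopifnot(inherits(panel, "seq_panel"), inherits(truth, "truth_set"))
  samples <- samples %||% truth$phenotypes$sample
  if (is.null(manifest)) {
    manifest <- with_stage_seed(config$seed, "barcodes",
      make_barcode_manifest(truth$phenotypes$sample, config$barcode_length,
                            config$max_mismatch))
  }
  L <- config$read_len
  clen <- nchar(panel$reference)

  per_sample <- lapply(samples, function(sm) {
    with_stage_seed(config$seed, paste0("reads_run", run_id, "_", sm), {
      gt <- truth$genotypes[sm, ]
      carried <- truth$sites[gt > 0, , drop = FALSE]
      carried$dose <- gt[gt > 0]
      # two haplotypes per contig; het alleles land on a random haplotype
      haps <- list()
      for (ctg in names(panel$reference)) {
        h <- c(panel$reference[[ctg]], panel$reference[[ctg]])
        cs <- carried[carried$contig == ctg, , drop = FALSE]
        for (i in seq_len(nrow(cs))) {
          on <- if (cs$dose[i] == 2L) 1:2 else sample(1:2, 1)
          for (k in on) substr(h[k], cs$pos[i], cs$pos[i]) <- cs$alt[i]
        }
        haps[[ctg]] <- h
      }
      # Fragment coordinates are drawn to be unique per sample (variable
      # trimmed read lengths make this feasible at 42X), so that reads
      # sharing (contig, start, end) are exactly the emitted PCR duplicates.
      frags <- panel$targets |>
        rowwise() |>
        reframe({
          ctg <- .data$contig
          s1 <- .data$start + 1L  # 1-based interval start
          e1 <- .data$end
          n <- rpois(1, config$mean_depth * (e1 - s1 + L) /
                       (L - config$read_len_jitter / 2))
          f <- tibble(start = integer(0), end = integer(0))
          while (nrow(f) < n) {
            st <- pmax(1L, sample.int(e1 - s1 + L, n - nrow(f),
                                      replace = TRUE) + s1 - L)
            len <- sample.int(config$read_len_jitter + 1L, n - nrow(f),
                              replace = TRUE) - 1L
            f <- distinct(bind_rows(
              f, tibble(start = st,
                        end = pmin(st + L - 1L - len, clen[ctg]))))
            f <- f[f$end >= f$start, , drop = FALSE]
          }
          tibble(contig = ctg, start = f$start, end = f$end)
        })
      n_frag <- nrow(frags)
      frags <- frags |>
        mutate(hap = sample(1:2, n_frag, replace = TRUE),
               strand = sample(c("+", "-"), n_frag, replace = TRUE))
      dup <- frags[runif(n_frag) < config$dup_rate, , drop = FALSE]
      reads <- bind_rows(frags, dup)
      n <- nrow(reads)
      reads$mapq <- ifelse(runif(n) < config$low_mapq_frac,
                           config$low_mapq, config$mapq)
      hap_key <- paste0(reads$contig, "#", reads$hap)
      hap_seq <- setNames(unlist(haps),
                          as.vector(outer(1:2, names(haps),
                                          function(k, c0) paste0(c0, "#", k))))
      raw <- substring(hap_seq[hap_key], reads$start, reads$end)
      widths <- reads$end - reads$start + 1L
      qn <- draw_quals(sum(widths), config)
      base_chr <- strsplit(paste(raw, collapse = ""), "", fixed = TRUE)[[1]]
      base_chr <- apply_errors(base_chr, qn)
      big_b <- paste(base_chr, collapse = "")
      big_q <- intToUtf8(qn + 33L)
      ends <- cumsum(widths)
      starts <- ends - widths + 1L
      reads$bases <- substring(big_b, starts, ends)
      reads$quals <- substring(big_q, starts, ends)
      # barcode tag with sequencing errors
      bc <- manifest$barcode[manifest$sample == sm]
      tq <- draw_quals(n * nchar(bc), config)
      tchr <- apply_errors(rep(strsplit(bc, "")[[1]], n), tq)
      tg_end <- seq_len(n) * nchar(bc)
      reads$tag <- substring(paste(tchr, collapse = ""),
                             tg_end - nchar(bc) + 1L, tg_end)
      # off-target reads are bookkept as a count, not emitted rows: they
      # carry no sequence of interest and would dominate file size
      f <- config$on_target_fraction
      n_off <- rpois(1, n * (1 - f) / f)
      reads$truth_sample <- sm
      list(reads = reads, n_off = n_off, bc = bc)
    })
  })

  reads <- bind_rows(lapply(per_sample, `[[`, "reads")) |>
    mutate(read_id = sprintf("r%07d", row_number())) |>
    select("read_id", "tag", "contig", "start", "end", "strand", "mapq",
           "bases", "quals", "truth_sample")
  counts <- tibble(
    sample = samples,
    n_on_target = vapply(per_sample, function(x) nrow(x$reads), integer(1)),
    n_off_target = vapply(per_sample, function(x) as.integer(x$n_off),
                          integer(1)))
  list(reads = reads, manifest = manifest, counts = counts,
       n_on_target = sum(counts$n_on_target),
       n_off_target = sum(counts$n_off_target))
}
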