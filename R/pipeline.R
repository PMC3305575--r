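# End-to-end orchestration: simulate -> demux -> read filters -> calling ->
# genotype matrix -> association screen -> burden -> two-stage replication
# -> annotation -> concordance, with a JSON run manifest recording seeds,
# parameters and per-stage record counts. Re-running an identical
# configuration reproduces every output byte-for-byte.

#' Capture-enrichment fold
#'
#' Ratio of the on-target read fraction to the target's share of the
#' genome: `(on_target_reads / total_reads) / (target_bp / genome_bp)`.
#'
#' @param on_target_reads,total_reads Read counts.
#' @param target_bp Target footprint in bp.
#' @param genome_bp Genome size in bp (default 3e9, the human genome scale).
#' @return Enrichment fold (a single number).
#' @export
compute_enrichment <- function(on_target_reads, total_reads, target_bp,
                               genome_bp = 3e9) {
  if (total_reads <= 0 || target_bp <= 0 || genome_bp <= 0) {
    abort("counts and sizes must be positive.")
  }
  (on_target_reads / total_reads) / (target_bp / genome_bp)
}

#' Coverage summary over the target
#'
#' Per-sample mean depth over targeted positions and the fractions covered
#' at >= 1X, >= 10X and >= 20X.
#'
#' @param reads Filtered reads with a `sample` column.
#' @param panel A `seq_panel`.
#' @return Tibble (sample, mean_depth, pct_1x, pct_10x, pct_20x).
#' @export
coverage_summary <- function(reads, panel) {
  tpos <- panel$targets |>
    rowwise() |>
    reframe({
      ctg <- .data$contig
      s1 <- .data$start + 1L
      e1 <- .data$end
      tibble(contig = ctg, pos = seq.int(s1, e1))
    })
  reads |>
    group_by(.data$sample) |>
    group_map(function(rr, key) {
      d <- unlist(lapply(split(tpos, tpos$contig), function(pp) {
        r2 <- rr[rr$contig == pp$contig[1], ]
        interval_depth(r2$start, r2$end, pp$pos)
      }), use.names = FALSE)
      tibble(sample = key$sample, mean_depth = mean(d),
             pct_1x = mean(d >= 1), pct_10x = mean(d >= 10),
             pct_20x = mean(d >= 20))
    }) |>
    bind_rows()
}

#' Pipeline configuration
#'
#' Collects every stage's parameter block around a single master seed. Any
#' block may be an empty list to accept the stage defaults; the whole
#' configuration can equally be given as a YAML file to [run_pipeline()].
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param panel Arguments for [build_panel()], or `list(dir = path)` to
#'   load a previously written panel.
#' @param sim Arguments for [sim_config()] (the seed is injected).
#' @param calling Arguments for [call_params()].
#' @param matrix List with `min_ref_depth`.
#' @param screen Arguments for [screen_config()].
#' @param burden List with `set`, `consequences`.
#' @param replication Arguments for [stage_config()].
#' @param known_tables Optional paths of known-variant TSV tables
#'   (contig, pos, ref, alt) for novelty annotation.
#' @param concordance_sample Sample re-sequenced for the repeat-run
#'   overlap report (default: the first case).
#' @param write_intermediate Write per-stage files (TSV/VCF/PED) under the
#'   run directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, panel = list(), sim = list(),
                       calling = list(), matrix = list(),
                       screen = list(), burden = list(),
                       replication = list(), known_tables = NULL,
                       concordance_sample = NULL,
                       write_intermediate = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Executes simulate, demux, readfilter, call, matrix, assoc, burden,
#' replicate, annotate and concordance in order, writing stage outputs and
#' a JSON manifest under `out_dir`. A stage failure aborts with the stage
#' name; outputs of completed stages are retained for debugging.
#'
#' The replication stages are genotype-level (emulating PCR/Sanger
#' genotyping of new individuals): allele counts for each carried-over
#' variant are drawn from the truth model's group frequencies, so a
#' spuriously selected variant is tested against identical case/control
#' frequencies and fails to replicate in expectation.
#'
#' @param config A [run_config()] or the path to a YAML file of its
#'   arguments.
#' @param out_dir Output directory.
#' @return (Invisibly) a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "hemoseq",
                   version = as.character(packageVersion("hemoseq")),
                   seed = config$seed, stages = list())
  done <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  emit <- function(name, counts) {
    manifest$stages[[name]] <<- counts
    done <<- c(done, name)
  }
  wi <- isTRUE(config$write_intermediate)

  # -- simulate ------------------------------------------------------------
  res <- list()
  stage("simulate", {
    res$panel <- if (!is.null(config$panel$dir)) {
      read_panel(config$panel$dir)
    } else {
      do.call(build_panel, modifyList(list(seed = config$seed),
                                      config$panel))
    }
    simargs <- modifyList(list(seed = config$seed), config$sim)
    res$sim_config <- do.call(sim_config, simargs)
    res$truth <- simulate_genotypes(res$panel, res$sim_config)
    res$sim <- simulate_reads(res$panel, res$truth, res$sim_config)
    if (wi) {
      write_panel(res$panel, file.path(out_dir, "panel"))
      write_truth(res$truth, file.path(out_dir, "truth"))
      write_phenotypes(res$truth$phenotypes,
                       file.path(out_dir, "phenotypes.tsv"))
      write_manifest(res$sim$manifest, file.path(out_dir, "barcodes.tsv"))
      write_reads(res$sim$reads, file.path(out_dir, "reads.tsv"))
    }
    emit("simulate", list(n_samples = nrow(res$truth$phenotypes),
                          n_truth_sites = nrow(res$truth$sites),
                          n_on_target = res$sim$n_on_target,
                          n_off_target = res$sim$n_off_target,
                          target_bp = target_size(res$panel)))
  })

  stage("demux", {
    res$demux <- assign_barcodes(res$sim$reads, res$sim$manifest)
    stopifnot(nrow(res$demux$reads) + res$demux$n_unassigned ==
                nrow(res$sim$reads))
    if (wi) readr::write_tsv(res$demux$report,
                             file.path(out_dir, "demux_report.tsv"))
    emit("demux", list(n_assigned = nrow(res$demux$reads),
                       n_unassigned = res$demux$n_unassigned))
  })

  stage("readfilter", {
    dedup <- res$demux$reads |>
      group_by(.data$sample) |>
      group_modify(~remove_duplicates(.x)) |>
      ungroup()
    res$filtered <- filter_mapq(dedup, min_mapq = 50)
    if (wi) write_reads(res$filtered, file.path(out_dir,
                                                "reads.filtered.tsv"))
    emit("readfilter", list(n_in = nrow(res$demux$reads),
                            n_after_dedup = nrow(dedup),
                            n_after_mapq = nrow(res$filtered)))
  })

  stage("call", {
    params <- do.call(call_params, config$calling)
    res$call_params <- params
    pu <- build_pileup(res$filtered, res$panel, params$min_base_qual)
    res$calls <- qc_filter(call_variants(pu, params), params)
    stopifnot(sum(res$calls$qc_status == "PASS") +
                sum(res$calls$qc_status == "FAIL") == nrow(res$calls))
    if (wi) readr::write_tsv(res$calls, file.path(out_dir, "calls.tsv"))
    emit("call", list(n_calls = nrow(res$calls),
                      n_pass = sum(res$calls$qc_status == "PASS"),
                      n_fail = sum(res$calls$qc_status == "FAIL")))
  })

  stage("matrix", {
    min_ref_depth <- config$matrix$min_ref_depth %||% 10
    res$gm <- build_genotype_matrix(res$calls, res$filtered,
                                    res$truth$phenotypes, min_ref_depth)
    if (wi) {
      write_ped_map(res$gm, file.path(out_dir, "cohort"))
      write_vcf_matrix(res$gm, res$panel, file.path(out_dir, "cohort.vcf"))
    }
    emit("matrix", list(n_sites = nrow(res$gm$sites),
                        genotyping_success = genotyping_success(res$gm)))
  })

  stage("assoc", {
    scfg <- do.call(screen_config, config$screen)
    res$screen <- screen(res$gm, scfg)
    if (wi) readr::write_tsv(tidy(res$screen),
                             file.path(out_dir, "assoc.tsv"))
    emit("assoc", list(n_tested = sum(res$screen$results$tested),
                       n_selected = sum(res$screen$results$selected)))
  })

  stage("annotate", {
    snvs <- res$gm$sites |> filter(nchar(.data$ref) == 1,
                                   nchar(.data$alt) == 1,
                                   .data$alt %in% c("A", "C", "G", "T"))
    res$annotations <- classify_snv(snvs, res$panel)
    known <- lapply(config$known_tables %||% list(),
                    function(p) readr::read_tsv(p, col_types = "cicc"))
    res$annotations <- flag_novelty(res$annotations, known)
    ann_stats <- site_stats(res$gm) |>
      inner_join(res$annotations, by = "site_id")
    res$spectrum <- frequency_spectrum(ann_stats)
    if (wi) {
      readr::write_tsv(res$annotations, file.path(out_dir,
                                                  "annotations.tsv"))
      readr::write_tsv(res$spectrum, file.path(out_dir, "spectrum.tsv"))
    }
    emit("annotate", list(n_annotated = nrow(res$annotations),
                          n_novel = sum(res$annotations$novel)))
  })

  stage("burden", {
    set_name <- config$burden$set %||% "anticoagulant"
    consequences <- config$burden$consequences %||% c("missense",
                                                      "nonsense")
    genes <- res$panel$gene_sets |>
      filter(.data$set == set_name) |> pull("gene")
    res$burden <- burden_test(res$gm, res$annotations, genes,
                              set_name = set_name,
                              consequences = consequences)
    if (wi) readr::write_tsv(tidy(res$burden),
                             file.path(out_dir, "burden.tsv"))
    emit("burden", list(T_case = res$burden$T_case,
                        T_control = res$burden$T_control,
                        p = res$burden$p))
  })

  stage("replicate", {
    rcfg <- do.call(stage_config, config$replication)
    res$replication <- with_stage_seed(config$seed, "replication",
      simulate_replication(res$screen, res$truth, rcfg))
    if (wi) readr::write_tsv(res$replication,
                             file.path(out_dir, "replication.tsv"))
    emit("replicate",
         list(n_stage1 = nrow(res$replication),
              n_stage2 = sum(res$replication$selected)))
  })

  stage("concord", {
    sm <- config$concordance_sample %||% res$truth$phenotypes$sample[1]
    rerun <- simulate_reads(res$panel, res$truth, res$sim_config,
                            manifest = res$sim$manifest, run_id = 2L,
                            samples = sm)
    r2 <- rerun$reads |> mutate(sample = .data$truth_sample)
    r2f <- filter_mapq(remove_duplicates(r2), 50) |>
      mutate(sample = sm)
    calls2 <- qc_filter(call_variants(
      build_pileup(r2f, res$panel, res$call_params$min_base_qual),
      res$call_params), res$call_params)
    first <- res$calls |> filter(.data$sample == sm,
                                 .data$qc_status == "PASS")
    second <- calls2 |> filter(.data$qc_status == "PASS")
    res$concordance <- callset_overlap(first, second)
    if (wi) readr::write_tsv(res$concordance,
                             file.path(out_dir, "concordance.tsv"))
    emit("concord", list(percent_rediscovered = res$concordance$percent))
  })

  stage("report", {
    res$coverage <- coverage_summary(res$filtered, res$panel)
    res$enrichment <- compute_enrichment(
      res$sim$n_on_target, res$sim$n_on_target + res$sim$n_off_target,
      target_size(res$panel))
    if (wi) readr::write_tsv(res$coverage,
                             file.path(out_dir, "coverage.tsv"))
    emit("report", list(mean_depth = mean(res$coverage$mean_depth),
                        enrichment_fold = res$enrichment))
  })

  manifest$parameters <- list(
    sim = unclass(res$sim_config), calling = unclass(res$call_params),
    screen = unclass(do.call(screen_config, config$screen)),
    replication = unclass(do.call(stage_config, config$replication)))
  manifest$n_stages_completed <- length(done)
  manifest$completed <- done
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

# genotype-level two-stage replication of the screen's carried-over
# variants, drawing allele counts from the truth model's frequencies
simulate_replication <- function(scr, truth, rcfg) {
  sel <- scr$results |> filter(.data$selected)
  if (nrow(sel) == 0) return(tibble())
  n1_case <- round(rcfg$stage1_n / 2)
  n1_ctrl <- rcfg$stage1_n - n1_case
  n2_case <- rcfg$full_n_case - n1_case
  n2_ctrl <- rcfg$full_n_control - n1_ctrl

  qs <- sel |>
    left_join(truth$sites |> select("site_id", "q_control", "q_case"),
              by = "site_id") |>
    mutate(
      # a called site absent from the truth set replicates under the null
      # at its observed pooled frequency
      q_control = ifelse(is.na(.data$q_control), .data$maf_pooled,
                         .data$q_control),
      q_case = ifelse(is.na(.data$q_case), .data$maf_pooled, .data$q_case))

  draw <- function(n_ind, q) rbinom(length(q), 2L * n_ind, q)
  a1 <- draw(n1_case, qs$q_case)
  c1 <- draw(n1_ctrl, qs$q_control)
  stage1 <- tibble(site_id = qs$site_id,
                   p_case = a1 / (2 * n1_case),
                   p_control = c1 / (2 * n1_ctrl))
  gate <- select_for_stage2(stage1, rcfg)

  out <- lapply(seq_len(nrow(qs)), function(i) {
    t1 <- matrix(c(a1[i], 2 * n1_case - a1[i],
                   c1[i], 2 * n1_ctrl - c1[i]), 2, byrow = TRUE)
    t2 <- NULL
    if (gate$selected[i]) {
      a2 <- draw(n2_case, qs$q_case[i])
      c2 <- draw(n2_ctrl, qs$q_control[i])
      t2 <- matrix(c(a2, 2 * n2_case - a2, c2, 2 * n2_ctrl - c2), 2,
                   byrow = TRUE)
    }
    combined_analysis(t1, t2) |>
      mutate(site_id = qs$site_id[i],
             stage1_p_case = stage1$p_case[i],
             stage1_p_control = stage1$p_control[i],
             power = gate$power[i], selected = gate$selected[i],
             .before = 1)
  })
  bind_rows(out)
}
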