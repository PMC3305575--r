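# Shared fixtures, built once per test run and cached in this environment.
# Fixture sizes are deliberately small so the whole suite stays fast; the
# study-scale conditions are exercised in the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default panel (also the panel whose CDS the consequence oracle walks)
fix_panel <- function() cached("panel", function() build_panel(seed = 1))

small_panel <- function() {
  cached("small_panel",
         function() build_panel(n_genes = 4, exons_per_gene = 2, seed = 3))
}

# error-free sequencing of the default cohort over the small panel:
# Q93 bases (error ~ 5e-10), no duplicates, no low-mapq reads
errorfree_config <- function(seed = 5) {
  sim_config(seed = seed, base_qualities = c(93L, 93L), dup_rate = 0,
             low_mapq_frac = 0)
}

fix_errorfree <- function() {
  cached("errorfree", function() {
    panel <- small_panel()
    config <- errorfree_config()
    truth <- simulate_genotypes(panel, config)
    sim <- simulate_reads(panel, truth, config)
    demux <- assign_barcodes(sim$reads, sim$manifest)
    filtered <- demux$reads |>
      dplyr::group_by(sample) |>
      dplyr::group_modify(~remove_duplicates(.x)) |>
      dplyr::ungroup() |>
      filter_mapq()
    calls <- qc_filter(call_variants(build_pileup(filtered, panel)))
    list(panel = panel, config = config, truth = truth, sim = sim,
         demux = demux, filtered = filtered, calls = calls)
  })
}

# truth genotypes in long form (carriers only)
melt_truth <- function(truth) {
  g <- truth$genotypes
  tibble::tibble(sample = rep(rownames(g), ncol(g)),
                 site_id = rep(colnames(g), each = nrow(g)),
                 gt = as.vector(g)) |>
    dplyr::filter(gt > 0) |>
    dplyr::left_join(truth$sites, by = "site_id")
}

# hand-built single-gene panel with a chosen CDS, for targeted
# consequence tests; strand "-" mirrors the same transcript onto the
# reverse strand of the reference
toy_gene_panel <- function(cds, strand = "+", utr = 6L, flank = 4L) {
  stopifnot(nchar(cds) %% 3 == 0)
  pad <- strrep("A", 20)
  genomic <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  ref <- paste0(pad, strrep("T", utr), genomic, strrep("T", utr), pad)
  exon_start <- 21L
  exon_end <- nchar(ref) - 20L
  cds_start <- exon_start + utr
  cds_end <- exon_end - utr
  structure(list(
    genes = tibble::tibble(gene = "TOY", contig = "chrT", strand = strand),
    exons = tibble::tibble(gene = "TOY", contig = "chrT", strand = strand,
                           exon = 1L, start = exon_start, end = exon_end),
    cds = tibble::tibble(gene = "TOY", contig = "chrT", strand = strand,
                         exon = 1L, start = cds_start, end = cds_end),
    targets = tibble::tibble(contig = "chrT",
                             start = exon_start - flank - 1L,
                             end = exon_end + flank),
    reference = c(chrT = ref),
    gene_sets = tibble::tibble(set = character(0), gene = character(0))),
    class = "seq_panel")
}

# reads constructed literally, for read-level unit tests
make_read <- function(contig = "chr1", start, end = start + 9L,
                      bases = NULL, quals = NULL, strand = "+", mapq = 60L,
                      sample = "S1", tag = "ACGTAA",
                      read_id = sprintf("r%04d", start)) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- end - start + 1L
  tibble::tibble(read_id = read_id, tag = tag, contig = contig,
                 start = start, end = end, strand = strand,
                 mapq = as.integer(mapq),
                 bases = bases %||% strrep("A", n),
                 quals = quals %||% strrep("I", n), sample = sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
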