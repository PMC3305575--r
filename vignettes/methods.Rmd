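---
title: "Targeted case-control resequencing of hemostasis gene panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted case-control resequencing of hemostasis gene panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoseq)
library(dplyr)
```

hemoseq reimplements, as one tested pipeline, the analysis of a
multiplexed targeted-resequencing case-control study of deep vein
thrombosis (DVT): barcoded pooled libraries over a capture panel of
hemostatic and pro-inflammatory genes, sequenced at high coverage in a
small discovery cohort, screened variant-by-variant with Fisher's exact
test, collapsed into gene-set burdens, and replicated in a larger cohort
through a power-gated two-stage design. Because no patient data are
available, the package carries a first-class synthetic cohort generator
that reproduces the statistical structure every downstream stage assumes;
all tests and worked examples run on simulated data, and what that does
and does not establish is discussed at the end.

## The synthetic study

`build_panel()` constructs a scaled-down capture design: by default 12
hemostasis genes with 4 exons each (about 6.7 kb of merged target,
roughly 1% of the 644 kb, 186-gene design it emulates), with exon/CDS
models on both strands, stop-free coding sequence, and target intervals
covering every exon plus a 10 bp splice flank. Gene sets
(`anticoagulant`, `coagulation_factor`) drive the collapsing analysis.

`sim_config()` houses the study design constants, which are the
generator's defaults: 10 cases and 12 controls sequenced at a mean
on-target depth of 42X with 7% of raw reads on target; one common
missense risk SNP in *FGA* with control minor allele frequency (MAF)
0.22 and allelic odds ratio 1.45; and one rare missense site per
anticoagulant gene at control MAF 0.02 with a five-fold case enrichment
(matching the observed 0.9 vs 0.18 mean burden). Replication defaults
are 719 cases and 719 controls with a 284-individual stage 1.

Genotypes follow a retrospective sampling model. Controls are
Hardy-Weinberg at each site's control MAF $q$; at the risk site the case
allele frequency is

$$p_\text{case} = \frac{\mathrm{OR}\cdot q}{1 + q(\mathrm{OR}-1)},$$

the allele-frequency form of a fixed allelic odds ratio, which reduces to
$q$ at $\mathrm{OR}=1$ and is analytically checkable — the reason it was
chosen over a liability-threshold model. Rare burden sites multiply $q$
by the configured enrichment in cases (capped at 0.5). Neutral background
sites (40 by default) draw $q$ log-uniformly on $[0.01, 0.5]$, a
practical stand-in for the $1/x$ neutral frequency spectrum.

Reads are emitted pre-aligned at their true coordinates; mapping itself
is out of scope, so mapping quality is simulated (60, with 5% of reads
down-weighted to 30 to exercise the filter). Per-interval fragment counts
are Poisson-calibrated so interior coverage has the configured mean; read
lengths are 50 bp minus a uniform 0-15 bp trim, which makes fragment
coordinates distinctive enough that fragments are generated
coordinate-unique — reads sharing (contig, start, end) are then *exactly*
the intended PCR duplicates (10% of fragments by default, emitted twice
with independent errors and mapping quality). Base errors follow the
Phred convention ($10^{-Q/10}$) with qualities drawn from a Q20/Q30
two-point mixture; the source study reports no error model or duplicate
rate, so these are documented stand-ins. Off-target reads are bookkept as
counts rather than rows: they carry no usable sequence and would
dominate file sizes at a 7% on-target fraction. Barcode tags are
themselves sequenced with errors.

A single master seed fixes every stage through derived per-stage streams,
so identical configurations reproduce every output file byte-for-byte
while repeat "sequencing runs" (`run_id`) get fresh error realizations.

## Read processing

`assign_barcodes()` assigns each read to the unique sample whose barcode
lies within `max_mismatch` of its tag. Manifests are validated against a
pairwise Hamming distance strictly greater than `2 * max_mismatch`, which
makes the nearest barcode unique whenever one qualifies; barcode matching
is global Hamming (no indels in tags), the simplest rule consistent with
that invariant. Unassigned reads are counted, and assigned + unassigned
always equals the input.

`remove_duplicates()` keeps, within every (contig, start, end) group, the
read with the highest mapping quality — the study's stated rule. Grouping
ignores strand by default (the rule names only coordinates); a
`by_strand` flag is available. Mapq ties break on the lexicographically
first read id so output is deterministic. `filter_mapq()` then expunges
reads below 50; a read at exactly 50 survives ("less than 50" was
removed). The pipeline applies duplicate removal *before* the mapq
filter — the order matters, because a low-mapq read can shadow a
high-mapq duplicate.

## Variant calling and QC

`build_pileup()` scans each sample's reads against the reference and
assembles the full observation column (base, quality, strand, mapq) at
every position where that sample shows at least one mismatch — the role
the classical per-site pileup files played. Observations under the base
quality floor (20) are excluded from all counts.

`call_variants()` emits a candidate at every site with at least
`min_alt_reads` (2) variant-supporting observations: the majority
non-reference allele, allele balance $\mathrm{AB} =$ alt / (ref + alt)
reads, per-strand alt counts, and a call quality equal to the
Phred-scaled probability of seeing at least that many variant reads from
sequencing error alone under a binomial model at the mean quality-implied
error of the site's observations. Genotype is heterozygous below an
allele balance of 0.8, homozygous-variant at or above. Multi-allelic
sites emit the majority alt and are flagged. Deletion (`-`) and insertion
(`+XX`) observations go through the same counting rules; no realignment
is attempted.

`qc_filter()` applies the published criteria with exact boundary
semantics: allele balance below 20% fails (0.20 passes); a variant absent
from either strand orientation fails `strand_bias`; depth below 10 fails
`low_depth`; call quality below 20 fails `low_quality`. Sites whose whole
coverage is single-stranded cannot satisfy the strand criterion — they
fail conservatively but carry a distinct `single_strand_site` flag so
users may exempt them. The exact numeric thresholds behind the study's
"high-quality" consensus filter are unpublished; `min_alt_reads`, the
het/hom boundary and the call-quality floor are package defaults chosen
so that the *stated* allele-balance and strand filters are the binding
constraints, and all are configurable. Failed calls are retained with
their reasons — the genotype matrix needs them.

## The genotype matrix

`build_genotype_matrix()` reimplements the projection logic that turns
per-sample calls into a complete samples x sites grid over the union of
variable sites, with an explicit missing/homref distinction: a PASS call
contributes its genotype; QC-failed variant evidence at a position makes
that genotype missing (the evidence is neither trustworthy nor
ignorable); with no variant evidence, read depth of at least
`min_ref_depth` supports homozygous reference, anything less is missing.
`min_ref_depth` defaults to 10, deliberately reusing the study's 10X
confident-call threshold; the original tool's exact depth rule is
unpublished, so this linkage is a documented reconstruction. Site
identifiers are `contig:pos:ref:alt`. Export is PLINK 1 text PED/MAP
(missing = `0 0`, sex 0 unless supplied) with an exact read-back, plus a
multi-sample VCF.

## Association screen

`screen()` computes, per site, the allelic 2x2 table over non-missing
genotypes (two alleles per individual; the minor allele is defined on the
pooled case + control alleles), excludes sites with pooled MAF below 8%
or missingness at or above 10% (strictly-below-10% passes), tests
survivors with `fisher_two_sided()` and ranks them. The Fisher p-value is
the exact conditional two-sided sum of hypergeometric point probabilities
not exceeding the observed table's (no mid-p), with a $1+10^{-7}$
relative guard against floating-point ties; zero-margin tables return 1.
Odds ratios are cross-product ratios with Haldane-Anscombe +0.5 on
zero-cell tables and Woolf (log-normal) 95% intervals. Ties in p break on
larger $|\log \mathrm{OR}|$, then genomic position — the source is silent,
so the rule is simply deterministic. The top 5 are selected for
replication. `min_detectable_mac()` inverts the design: the smallest
minor-allele count whose maximally unbalanced table reaches $p<\alpha$
(4 of 44 alleles, i.e. 9.1% MAF, at the discovery size — slightly above
the study's quoted 8% threshold, which the printed counts do not
reproduce exactly).

## Burden and replication

`burden_test()` collapses minor-allele dosage (het 1, homvar 2, missing
0) over nonsynonymous sites of a gene set and tests the case total
against a binomial allocation null: conditional on $n$ observed alleles,
each falls in a case with probability $n_\text{case}/(n_\text{case} +
n_\text{control})$, and the one-sided case-excess tail is
$P(X \ge T_\text{case})$. Allele-count collapsing (not carrier-count) is
used because it reproduces the published per-group totals (9 vs 2). On
those totals with 10 cases and 12 controls this test gives $p = 0.016$;
the study printed 0.01, and no simple binomial variant tried (including
10 vs 11, suggested by its control mean of 0.18) recovers it, so the
defined default stands and the printed value is not treated as a
reproduction target. A two-sided variant doubles the smaller tail.

`two_proportion_power()` is the carry-over gate: a normal-approximation
two-proportion test with pooled null and unpooled alternative standard
errors, evaluated at the stage-1 frequency estimates and the full
cohort's allele counts (alleles = 2 x individuals, independence assumed —
the study names no method, so this is a documented reconstruction), at
two-sided $\alpha_2 = 0.005$ to match the discovery test's sidedness.
Power at or above 0.80 carries a variant to stage 2; degenerate stage-1
estimates (frequency 0 or 1) are never carried. On the three published
stage-1 frequency pairs that the study stopped after stage 1, the gate
yields powers 0.003, 0.12 and 0.15 — consistent with their fate.
`combined_analysis()` sums per-stage tables cell-wise and reports the
crude Fisher/OR/CI of the total; the study's printed replication OR of
1.45 comes from an unspecified model and differs from the crude
cross-product of its own printed counts (1.64), so the crude estimator is
implemented and the discrepancy documented rather than matched.

## Annotation, spectrum, concordance

`classify_snv()` translates the affected codon before and after
substitution, honoring strand (alleles are reverse-complemented on minus
transcripts, codons may span exon junctions); stop gain is nonsense, same
residue synonymous, otherwise missense, with `p.R88X`-style protein
annotations. Exonic non-CDS positions are UTR, other targeted positions
intronic. Indels are frameshift when the length change is not a multiple
of three. Variants hitting several transcripts take the most severe
consequence (nonsense > frameshift > missense > in-frame > synonymous >
UTR > intronic). Novelty is an exact lookup on (contig, pos, ref, alt)
against user-supplied dbSNP-style tables; no external services are
queried, and damaging-ness is only ever an input column.
`frequency_spectrum()` bins minor-allele frequencies with a dedicated
singleton bin followed by configurable intervals (the published figure's
exact edges are not printed; defaults are 5/10/20/30/40/50%), reporting
per-bin counts by class and the nonsynonymous/synonymous ratio.

`callset_overlap()` and `genotype_agreement()` compute the
reproducibility statistics: the fraction of one run's QC-passed variants
rediscovered in another, and genotype concordance over shared
non-missing (sample, site) pairs stratified by the first input's genotype
(homref vs variant) — the first input plays the validation platform.
Percentages are rounded to one decimal; note that one published
percentage (697/698 as "99.8") appears truncated rather than rounded.

## Numerical and design notes

* Exact tests are conditional and therefore conservative at small
  margins. At the discovery size (20 vs 24 alleles) the attained
  two-sided Fisher rejection rate under a null simulation is about
  0.028-0.03 at nominal 0.05 — an intrinsic property of the test, not an
  implementation artifact; the implementation agrees with
  `fisher.test()` and with an exhaustive enumeration oracle to 1e-10
  over all tables with margins up to 30. Tests assert validity (attained
  level at or below nominal) rather than equality to the nominal level.
* The Woolf interval's coverage for OR 1.5 at the replication size
  measures ~94-95% in simulation, within the expected band.
* All thresholds surface in one place (`run_config()`), defaulting to
  the study's stated values: mapq 50, AB 0.20, 10X, MAF 8%, missingness
  10%, top-5, $\alpha_2$ 0.005, power 0.80.
* Degenerate inputs are contracts, not crashes: empty gene sets,
  fully-missing sites, zero-margin tables, empty callsets and
  conflicting reference bases raise informative errors; zero-information
  cases (no observed burden alleles, zero margins) return p = 1.

## Problem sizes and what the simulations show

The default panel is ~1% of the emulated design's footprint, and test
simulations use it (or a 4-gene version) at the study's 22-sample
discovery size; replication-scale checks (719 + 719) run at genotype
level, where a cohort costs milliseconds. These sizes were chosen so the
entire suite, including 1,000-replicate null calibrations and
200-replicate coverage checks, completes in about a minute while leaving
every statistical gate adequately powered.

The generator emulates coverage structure, barcoded pooling, PCR
duplication, quality-driven errors and the case-control frequency model —
it does not emulate alignment artifacts, capture GC bias, allele-specific
capture, indel-rich regions, colorspace chemistry or population
stratification. Passing tests therefore establish that the pipeline's
*logic* is correct under its stated model, and that its statistical
operating characteristics (type-I control, CI coverage, power gating)
match theory; they cannot certify calling accuracy on real instrument
data. Known limitations beyond that: no copy-number analysis, no
covariate-adjusted or interaction models at replication, no multiplicity
correction at discovery (all deliberate scope bounds of the emulated
analysis), and read-level indel simulation is limited to the calling
interface, since the internal read dialect encodes substitutions only.
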