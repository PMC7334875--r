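---
title: "Methods: expression CROP-seq screen design, simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression CROP-seq screen design, simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropmap)
```

## The problem

Most GWAS risk variants are noncoding and act, when they act at all, by
changing gene expression. A GWAS or eQTL credible interval typically contains
tens to hundreds of variants in linkage disequilibrium with near-identical
statistical support, so statistics alone cannot name the causal SNP.
Expression CROP-seq attacks this experimentally: a pooled lentiviral library
delivers one SNP-targeting CRISPR-Cas9 guide per candidate variant into a
cell population, the integrated guide is expressed as a polyadenylated
transcript and therefore captured by droplet single-cell RNA-seq, and the cis
effect of disrupting each SNP is read out as differential expression of the
linked transcript between cells carrying that guide and all other
single-guide cells.

`cropmap` implements the desk-scale computational side of this workflow:
guide design against candidate SNPs, construction of the guide-detection
reference, a ground-truthed screen simulator, guide-to-cell assignment,
expression QC and normalization, per-SNP association testing with locus-wise
multiple-testing control, and the surrounding screen statistics.

## Guide design

For each SNP we scan a flanking window (default ±30 bp) on both strands for
every protospacer of the configured length (default 19 nt) immediately 5' of
an NGG PAM, the S. pyogenes Cas9 requirement. Candidates with GC fraction
above 0.80 or below 0.40 are discarded as poor cutters; when uniqueness is
required, a candidate must have exactly one perfect protospacer+NGG match in
the reference (counted on both strands, N in the PAM wildcarded). Among
survivors we pick the guide whose cut site is closest to the SNP, breaking
ties by lexicographically smallest protospacer so the choice is
deterministic.

Decisions worth stating explicitly:

* **Cut-site convention.** SpCas9 cuts bluntly 3 bp 5' of the PAM. We report
  the coordinate of the protospacer base immediately 3' of the cut on the
  protospacer strand, mapped to plus-strand coordinates; the SNP distance is
  the absolute difference between this coordinate and the SNP position. This
  is the standard SpCas9 geometry; no alternative convention is supported.
* **Off-target handling.** Scored off-target prediction (CFD/MIT-style, or
  external services) is out of scope. We use exact-match uniqueness counting
  instead: reproducible, dependency-free, and sufficient to separate
  well-behaved guides from promiscuous ones and targeting guides from
  non-targeting negative controls (zero matches).
* **Coordinates.** 1-based inclusive everywhere in the user interface (the
  dbSNP convention); BED input is converted from 0-based half-open on read.
* **N bases.** Windows containing N in the protospacer or PAM are skipped
  silently; the count of skipped windows is attached to the scan result.
* **`max_snp_distance`** (default 10 bp) is advisory: selection warns rather
  than fails when the nearest usable cut site is farther away, because some
  SNPs simply lack close PAMs and the user should decide.

## The guide-detection reference

Standard scRNAseq quantifiers only count reads against annotated genes, so
guide transcripts need their own "genes". Each guide receives one artificial
chromosome: 241 bp of U6 promoter, an 8 bp gap, the 20 bp guide slot, and
261 bp of vector backbone — 530 bp total, with the guide occupying 1-based
positions 250–269. The accompanying GTF annotates each chromosome as a
single-exon gene spanning the full length on the plus strand so counters
attribute guide UMIs to a gene-like feature.

Designed protospacers are 19 nt but the cloned slot is 20 bp; we reconcile
the two by prepending G (the U6 transcription-start preference) until the
slot is full. The default U6/gap/backbone sequences shipped with the package
are synthetic placeholders of the correct lengths — the segment lengths, not
their content, drive every downstream computation — and real vector
sequences can be supplied via `construct_spec()` for use against real data.

## The screen simulator

The simulator exists so that every downstream module can be exercised, with
ground truth, without any external data. Its defaults are the study
conditions the package models throughout:

* **Library**: 67 guides — 57 candidate-SNP guides over three loci (CISD1:
  20, with adjacent genes IPMK and UBE2D1; PARK7: 19, adjacent ERRFI1; DAP:
  18, adjacent ANKRD33B) plus 5 essential-gene positive controls (TUBB,
  RUNX1), 3 non-targeting negative controls and 2 further non-SNP-targeting
  controls. The published control list enumerates 5 + 3 + 1 explicitly while
  the totals require 10; we carry 2 "other" controls to reach the stated
  total and class them `non_snp`.
* **Uptake**: integrations per cell are Poisson(`moi`, default 0.3)
  conditioned on at least one — puromycin selection removes uninfected cells
  — with guide identities drawn without replacement per cell (a duplicate
  integration of the same guide is indistinguishable in UMI space). Cells
  with zero *detected* guides arise only through detection dropout (default
  5% per integrated guide), matching the nonzero "0 gRNA" class seen in real
  assignments.
* **Editing outcomes**, drawn per (cell, targeting guide): the cell carries
  at least one edited allele with probability 0.92; an edited cell is
  single-allele with probability 0.29, and its edit disrupts the targeted
  SNP with probability 0.67. These are the clone-sequencing rates the
  modeled screen reported. Editing states are per cell; clonal lineage
  structure is not modeled.
* **Causality**: only guides listed in `causal_guides` (default: the first
  candidate of each locus, i.e. one causal variant per credible interval)
  shift expression when their SNP is disrupted. All other candidates edit
  but have no cis effect — the situation the assay is designed to resolve.
* **Expression**: gene UMIs are negative binomial (size 10 by default) with
  per-cell library sizes uniform on 2000–7000 and a deterministic
  quantile-spaced log-normal panel of background genes; 13 `MT-` pseudo-genes
  contribute 8% of counts in expectation, leaving headroom under the 25% QC
  cap. Guide features receive zero-truncated Poisson UMIs (mean 3) when
  detected.
* **Effect injection**: the cis effect is multiplicative on the target
  gene's NB mean, with the factor calibrated numerically (pmf summation plus
  root finding, no Monte Carlo) so the expected drop in normalized log2
  expression equals `effect_sd` (default 0.5) baseline standard deviations.
  The baseline mean and SD are computed as a mixture over a 9-point grid of
  library sizes, so the SD includes library-size-driven variation; without
  this the injected shift under-realizes by roughly 15–20%. An `effect_sd`
  too large for the gene's expression level (the required shift exceeding
  the baseline mean) is a parameter error, not a silent truncation.
* **Determinism**: all randomness flows from `params$seed` through a
  save/restore wrapper around R's RNG, so identical seeds give byte-identical
  outputs and package calls never perturb the caller's random stream.

What the generator does **not** emulate: doublets and ambient RNA, batch and
chemistry differences between replicates (replicates differ only by seed),
cell-cycle structure, clonal lineages, gene–gene correlation, and read-level
artifacts (no FASTQ). Passing tests therefore demonstrate correctness of the
statistical machinery under a clean generative model, not robustness to
every failure mode of real droplet data.

## Assignment, QC and normalization

Guide assignment binarizes the guide × cell UMI matrix at UMI > 0 — the
standard CROP-seq rule, taken literally; an optional `min_umi` exists for
noisy data but defaults to 1. Cells with exactly one guide are kept for
association. MOI is estimated from the closed form `lambda =
-log(fraction_zero)` when an uninfected fraction is observable, or by
zero-truncated-Poisson maximum likelihood from the post-selection
multiplicity histogram (`moi_from_multiplicity()`); detection dropout biases
the latter downward, which we document rather than correct.

QC applies, in order: drop cells expressing fewer than 200 genes; drop genes
detected in fewer than 6 remaining cells; keep cells with 2000–7000 total
UMIs (bounds read as **inclusive**, a choice the filter description leaves
open); keep cells with mitochondrial fraction strictly below 25% (strict, as
printed). The order matters — removing a cell can cascade a gene below the
detection floor — and the report counts removals per step. Guide features
are exempt from gene filters and excluded from cell totals so guide
abundance cannot perturb normalization.

Normalization divides by the cell's total gene UMIs, multiplies by 10 000,
and takes log2. A pseudocount of 1 is added after scaling (`log2(1 + x)`):
the transform needs one for zeros, and this is the dominant convention.
Consequently `sum(2^v - 1)` per cell inverts exactly to the scale factor,
which the tests assert to 1e-6 relative error.

## Association testing

Each candidate guide is tested against its locus's target gene (and each
adjacent gene, as negative controls) by univariate OLS of normalized
expression on the guide indicator over kept cells. With a binary regressor
the slope is exactly the group-mean difference and the slope t-test (n − 2
df) is numerically the pooled two-sample t-test; the tests assert agreement
with `t.test(var.equal = TRUE)` to 1e-10 and with `lm()`. Negative beta
means lower expression in guide-carrying cells. The reference group is all
other single-guide cells (not just negative controls), with an option to
restrict to negative-control cells for sensitivity analysis. Degenerate
cases are explicit: fewer than 2 cells in either group flags the result
untestable rather than silently dropping it; zero-variance expression gives
beta 0, p 1.

The locus-wise critical value is `alpha / tests_per_locus` with
`tests_per_locus` fixed at 20 by default — the convention divides by 20
regardless of whether a locus carries 20, 19 or 18 candidates — giving
0.05 / 20 = 0.0025. Covariates (cell cycle, depth) are deliberately absent:
richer models do not change the conclusions in this setting, and the
simplest approach is the one reported; the design leaves a hook via the
`control_cells` option rather than a covariate interface. Replicate
concordance requires significance in both replicates; pairs significant in
exactly one are reported separately as single-replicate nominal
associations.

## Screen statistics

* **Representation/dropout**: per-guide plasmid-read and assigned-cell
  fractions with their log2 ratio; the formal test is an exact two-sided
  binomial test of each guide's cell count against `total_cells * dna_frac`
  with Bonferroni adjustment over guides. The choice of per-total fractions
  is an assumption (the descriptive figure this mirrors does not state its
  normalization), and the binomial test is our formalization of "no
  deviation from equivalence".
* **Effect-size conversion**: an editing-induced shift of `delta` SD units
  corresponds, under the standard additive biallelic eQTL model with unit
  phenotype variance, to `PVE = 2 p (1 - p) beta^2`, with `beta = delta`
  if editing is taken as monoallelic dosage or `delta / 2` if biallelic.
  For `delta = 0.5` the attainable PVE covers the 5–10% range over plausible
  allele frequencies and peaks at p = 0.5 — the algebra behind reading a
  0.5 SD editing effect as a mid-size eQTL.
* **Power**: noncentral-t power of the pooled test with noncentrality
  `delta * sqrt(n1 n0 / (n1 + n0))`, verified against a 20 000-draw Monte
  Carlo of the t statistic. At `n1 = 100` mutated cells against thousands of
  controls and `delta = 0.5`, power exceeds 0.97 even at the adjusted level
  0.0025 — the quantitative content of "a hundred or more edited cells
  suffice".
* **qRT-PCR**: the 2^-ddCt arithmetic with the arithmetic mean over
  housekeeping genes and over negative-control dCt values.
* **Peak overlap**: SNP positions against BED accessibility peaks via
  GenomicRanges, with explicit 0-based half-open to 1-based conversion.

## Validation suite: problem sizes and thresholds

The package chooses the following sizes for its own statistical validation,
mirroring the study conditions at desk scale: null calibration uses 200
simulated screens of ~12 200 cells (about 150 single-guide cells per guide,
`effect_sd = 0`), asserting a per-test rejection rate of 0.05 ± 0.01
nominally and 0.0025 ± 0.0015 at the adjusted level; power uses 100
two-replicate runs with `effect_sd = 0.5` on a designated causal guide with
editing set to certain (`p_edit = 1`, `p_disrupt = 1`), so the ≥ 100
cells-per-guide condition refers to cells actually carrying the SNP
disruption, as the power claim intends — with the default 92%/67% rates the
same per-guide coverage dilutes the realized group difference to ~0.31 SD
and the claim would instead require ~250 cells per guide. Editing-outcome
calibration uses ≥ 10 000 guided cells. Numerical tolerances: NB pmf sums
truncated at the 1 − 1e-12 quantile; root finding to 1e-8; the
OLS/pooled-t equivalence asserted to 1e-10.

## Limitations

Everything upstream of the count matrix (alignment, UMI collapsing, cell
calling) is out of scope; the package consumes or simulates matrices. The
association model is a per-gene OLS on log-normalized counts — no
negative-binomial GLM, mixed model, or conditional-resampling calibration —
which is adequate for moderately expressed target genes and the effect sizes
this assay targets, but will lose power for genes near the detection limit.
Off-target assessment is exact-match counting only. The simulator's clean
generative assumptions are listed above; conclusions about real screens
should lean on the replicate-concordance requirement, which is the
workflow's practical guard against background drift between experiments.
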