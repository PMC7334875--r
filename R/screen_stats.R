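# Screen-level statistics: guide representation (RNA vs plasmid DNA) and
# dropout testing, eQTL effect-size algebra, two-group power, qRT-PCR
# 2^-ddCt arithmetic, and chromatin-accessibility peak overlap.

#' Guide representation in RNA (cells) versus DNA (plasmid reads)
#'
#' Normalizes per-guide plasmid read counts and assigned-cell counts to
#' fractions and reports their log2 ratio; agreement indicates no selection
#' against the guide (essential-gene positive controls are the expected
#' exception).
#'
#' @param dna_counts Named per-guide plasmid read counts.
#' @param rna_cells Named per-guide assigned-cell counts (same guide set).
#' @return Data.frame of class `representation_table` with guide_id,
#'   dna_count, rna_cells, dna_frac, rna_frac, log2_ratio (NA, flagged via
#'   `ratio_defined`, when either fraction is zero).
#' @export
representation_table <- function(dna_counts, rna_cells) {
  if (!setequal(names(dna_counts), names(rna_cells)))
    stop("DNA and RNA tables cover different guide sets", call. = FALSE)
  rna_cells <- rna_cells[names(dna_counts)]
  if (sum(dna_counts) <= 0 || sum(rna_cells) <= 0)
    stop("totals must be positive", call. = FALSE)
  dna_frac <- as.numeric(dna_counts) / sum(dna_counts)
  rna_frac <- as.numeric(rna_cells) / sum(rna_cells)
  defined <- dna_frac > 0 & rna_frac > 0
  out <- data.frame(guide_id = names(dna_counts),
                    dna_count = as.numeric(dna_counts),
                    rna_cells = as.numeric(rna_cells),
                    dna_frac = dna_frac, rna_frac = rna_frac,
                    log2_ratio = ifelse(defined, log2(rna_frac / dna_frac),
                                        NA_real_),
                    ratio_defined = defined)
  class(out) <- c("representation_table", "data.frame")
  out
}

#' Per-guide depletion/enrichment test
#'
#' Exact two-sided binomial test of each guide's assigned-cell count against
#' the expectation `total_cells * dna_frac`, with Bonferroni adjustment over
#' guides by default.  Guides absent from the plasmid pool but present in
#' cells are flagged as anomalies (NA p).
#'
#' @param t A [representation_table()].
#' @param alpha Family-wise level for calls.
#' @param method Multiplicity adjustment passed to [stats::p.adjust()].
#' @return `t` with added columns `p`, `p_adj`, `depleted`, `enriched`,
#'   `anomaly`.
#' @export
depletion_test <- function(t, alpha = 0.05, method = "bonferroni") {
  stopifnot(inherits(t, "representation_table"))
  n_rna <- sum(t$rna_cells)
  p <- vapply(seq_len(nrow(t)), function(i) {
    if (t$dna_frac[i] == 0) return(NA_real_)
    stats::binom.test(round(t$rna_cells[i]), round(n_rna),
                      t$dna_frac[i])$p.value
  }, numeric(1))
  t$p <- p
  t$p_adj <- stats::p.adjust(p, method = method)
  t$anomaly <- t$dna_frac == 0 & t$rna_cells > 0
  call <- !is.na(t$p_adj) & t$p_adj < alpha
  t$depleted <- call & t$rna_frac < t$dna_frac
  t$enriched <- call & t$rna_frac > t$dna_frac
  t
}

#' Variance explained by an eQTL equivalent to an editing-induced shift
#'
#' Converts a per-cell expression shift of `delta_sd` standard-deviation
#' units into the variance a biallelic additive eQTL of allele frequency `p`
#' would explain: the per-allele effect is `beta = delta_sd` when editing is
#' assumed monoallelic (one disrupted allele mimics one dose of the variant)
#' or `delta_sd / 2` when biallelic (two doses produce the shift), and
#' `PVE = 2 p (1 - p) beta^2` with phenotype variance normalized to 1.
#'
#' @param delta_sd Editing-induced shift in SD units (>= 0).
#' @param allele_freq Allele frequency in (0, 1).
#' @param mode `"monoallelic"` or `"biallelic"`.
#' @return Fraction of expression variance explained.
#' @examples
#' pve_from_shift(0.5, 0.5, "biallelic")  # 0.03125
#' @export
pve_from_shift <- function(delta_sd, allele_freq,
                           mode = c("monoallelic", "biallelic")) {
  mode <- match.arg(mode)
  if (any(delta_sd < 0)) stop("delta_sd must be >= 0", call. = FALSE)
  if (any(allele_freq <= 0 | allele_freq >= 1))
    stop("allele_freq must be in (0, 1)", call. = FALSE)
  beta <- if (mode == "monoallelic") delta_sd else delta_sd / 2
  2 * allele_freq * (1 - allele_freq) * beta^2
}

#' Power of the two-sided two-sample t-test
#'
#' Noncentral-t power for detecting a standardized mean difference
#' `delta_sd` between groups of `n1` and `n0` cells at level `alpha`
#' (noncentrality `delta_sd * sqrt(n1 n0 / (n1 + n0))`, `n1 + n0 - 2` df).
#'
#' @param n1,n0 Group sizes (>= 2).
#' @param delta_sd True standardized mean difference.
#' @param alpha Two-sided significance level.
#' @return Rejection probability.
#' @export
power_two_group <- function(n1, n0, delta_sd, alpha = 0.05) {
  if (any(c(n1, n0) < 2)) stop("need n1, n0 >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  df <- n1 + n0 - 2
  ncp <- delta_sd * sqrt(n1 * n0 / (n1 + n0))
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = ct_target - mean(ct_refs)`; `ddCt = dCt - mean(control_dcts)`;
#' fold change `2^-ddCt` relative to the negative-control samples.
#'
#' @param ct_target Target-gene cycle threshold.
#' @param ct_refs Housekeeping-gene Cts (>= 1 value).
#' @param control_dcts dCt values of the negative-control samples (>= 1).
#' @return Fold change relative to controls.
#' @examples
#' fold_change_ddct(25, c(20, 22), c(3, 5))  # 1
#' @export
fold_change_ddct <- function(ct_target, ct_refs, control_dcts) {
  if (!length(ct_refs)) stop("need at least one reference gene", call. = FALSE)
  if (!length(control_dcts)) stop("need at least one control dCt", call. = FALSE)
  if (any(c(ct_target, ct_refs) <= 0)) stop("Cts must be positive", call. = FALSE)
  dct <- ct_target - mean(ct_refs)
  2^(-(dct - mean(control_dcts)))
}

#' Read a BED3+ interval file
#'
#' @param path BED path (0-based half-open intervals; first three columns
#'   chrom, start, end).
#' @return A [GenomicRanges::GRanges] (1-based inclusive internally).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  for (i in seq_along(f)) {
    ok <- length(f[[i]]) >= 3L &&
      !is.na(suppressWarnings(as.numeric(f[[i]][2]))) &&
      !is.na(suppressWarnings(as.numeric(f[[i]][3]))) &&
      as.numeric(f[[i]][2]) < as.numeric(f[[i]][3])
    if (!ok) stop("malformed BED line ", line_no[i], " in ", path,
                  call. = FALSE)
  }
  chrom <- vapply(f, `[[`, "", 1L)
  start0 <- as.numeric(vapply(f, `[[`, "", 2L))
  end0 <- as.numeric(vapply(f, `[[`, "", 3L))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1, end = end0))
}

#' Flag SNPs overlapping accessibility peaks
#'
#' A SNP overlaps when its 1-based position falls inside any peak on its
#' chromosome (BED half-open intervals are converted on read).
#'
#' @param snps Data.frame with `snp_id`, `chrom`, `pos` (or a list of
#'   [snp_target()]s).
#' @param peaks A [GenomicRanges::GRanges] from [read_bed()] or a BED path.
#' @return `snps` as data.frame with a logical `in_peak` column.
#' @export
annotate_peak_overlap <- function(snps, peaks) {
  if (is.character(peaks)) peaks <- read_bed(peaks)
  if (is.list(snps) && !is.data.frame(snps) &&
      all(vapply(snps, inherits, logical(1), "snp_target")))
    snps <- data.frame(snp_id = vapply(snps, `[[`, "", "snp_id"),
                       chrom = vapply(snps, `[[`, "", "chrom"),
                       pos = vapply(snps, function(s) s$pos, integer(1)))
  gr <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos, snps$pos))
  snps$in_peak <- GenomicRanges::countOverlaps(gr, peaks) > 0
  snps
}
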