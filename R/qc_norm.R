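# Cell/gene quality control and library-size log2 normalization of the gene
# portion of the matrix.  Guide features are exempt from the gene filters and
# excluded from cell totals so guide abundance cannot perturb normalization.

#' Quality-control thresholds
#'
#' Defaults follow the standard droplet scRNAseq filters this workflow uses:
#' cells expressing fewer than 200 genes and genes detected in fewer than 6
#' cells are dropped, then cells are kept with total UMIs in
#' `[umi_min, umi_max]` (inclusive) and mitochondrial fraction strictly below
#' `max_mito_fraction`.
#'
#' @param min_genes_per_cell Minimum expressed genes per retained cell.
#' @param min_cells_per_gene Minimum cells expressing a retained gene.
#' @param umi_min,umi_max Inclusive per-cell total-UMI bounds.
#' @param max_mito_fraction Strict upper bound on the mitochondrial count
#'   fraction.
#' @param scale_factor Normalization scale factor.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 200L, min_cells_per_gene = 6L,
                      umi_min = 2000, umi_max = 7000,
                      max_mito_fraction = 0.25, scale_factor = 10000,
                      mito_prefix = "MT-") {
  if (umi_min >= umi_max) stop("umi_min must be < umi_max", call. = FALSE)
  if (any(c(min_genes_per_cell, min_cells_per_gene, umi_min, umi_max,
            max_mito_fraction, scale_factor) <= 0))
    stop("all thresholds must be positive", call. = FALSE)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 umi_min = umi_min, umi_max = umi_max,
                 max_mito_fraction = max_mito_fraction,
                 scale_factor = scale_factor, mito_prefix = mito_prefix),
            class = "qc_params")
}

#' Per-cell mitochondrial count fraction
#'
#' @param m A [cell_screen_matrix()] or a plain cells x genes matrix with
#'   gene colnames.
#' @param mito_prefix Prefix identifying mitochondrial genes.
#' @return Named numeric vector of fractions in `[0, 1]`; all zero (with a
#'   warning) when no gene name carries the prefix.
#' @export
mito_fraction <- function(m, mito_prefix = "MT-") {
  g <- if (inherits(m, "cell_screen_matrix")) extract_gene_matrix(m) else m
  mito <- if (is.null(colnames(g))) logical(ncol(g)) else
    startsWith(colnames(g), mito_prefix)
  if (!any(mito))
    warning("no gene names start with '", mito_prefix,
            "'; mitochondrial fraction is 0 for all cells", call. = FALSE)
  tot <- Matrix::rowSums(g)
  frac <- ifelse(tot > 0, Matrix::rowSums(g[, mito, drop = FALSE]) / tot, 0)
  stats::setNames(as.numeric(frac), rownames(g))
}

#' Apply cell and gene quality-control filters
#'
#' Filters are applied in order: (1) drop cells expressing fewer than
#' `min_genes_per_cell` genes; (2) drop genes detected in fewer than
#' `min_cells_per_gene` of the remaining cells; (3) keep cells whose total
#' gene UMIs lie in `[umi_min, umi_max]`; (4) keep cells with mitochondrial
#' fraction strictly below `max_mito_fraction`.  Cell totals and gene counts
#' consider gene features only; guide-feature columns pass through untouched.
#'
#' @param m A [cell_screen_matrix()].
#' @param p A [qc_params()].
#' @return List with `matrix` (filtered [cell_screen_matrix()]) and `report`
#'   (cells/genes in and out, and removals at each step).
#' @export
qc_filter <- function(m, p = qc_params()) {
  stopifnot(inherits(m, "cell_screen_matrix"), inherits(p, "qc_params"))
  g <- extract_gene_matrix(m)
  report <- list(cells_in = nrow(g), genes_in = ncol(g))

  genes_per_cell <- Matrix::rowSums(g > 0)
  keep1 <- genes_per_cell >= p$min_genes_per_cell
  report$cells_removed_low_genes <- sum(!keep1)
  g <- g[keep1, , drop = FALSE]

  cells_per_gene <- Matrix::colSums(g > 0)
  keepg <- cells_per_gene >= p$min_cells_per_gene
  report$genes_removed_low_cells <- sum(!keepg)
  g <- g[, keepg, drop = FALSE]

  tot <- Matrix::rowSums(g)
  keep3 <- tot >= p$umi_min & tot <= p$umi_max
  report$cells_removed_umi_bounds <- sum(!keep3)
  g <- g[keep3, , drop = FALSE]

  mf <- suppressWarnings(mito_fraction(g, p$mito_prefix))
  keep4 <- mf < p$max_mito_fraction
  report$cells_removed_mito <- sum(!keep4)
  g <- g[keep4, , drop = FALSE]

  report$cells_kept <- nrow(g)
  report$genes_kept <- ncol(g)
  if (nrow(g) == 0L) warning("QC removed all cells", call. = FALSE)

  guide_cols <- m$counts[rownames(g), m$feature_kind == "guide", drop = FALSE]
  out <- cell_screen_matrix(cbind(g, guide_cols),
                            feature_kind = c(rep("gene", ncol(g)),
                                             rep("guide", ncol(guide_cols))))
  list(matrix = out, report = report)
}

#' Library-size log2 normalization
#'
#' Each cell's gene counts are divided by the cell's total gene UMIs,
#' multiplied by `scale_factor`, and transformed as `log2(1 + x)`.  Zeros map
#' to zero, so sparsity is preserved, and per cell the inverse transform
#' sums back to `scale_factor` exactly.
#'
#' @param m A [cell_screen_matrix()] (gene features used) or a cells x genes
#'   count matrix.
#' @param scale_factor Scaling constant (default 10 000).
#' @return An object of class `normalized_matrix`: list with `values`
#'   (sparse cells x genes, log2 scale), `cell_totals_pre_log` (per-cell
#'   total of scaled counts, equal to `scale_factor`) and `scale_factor`.
#' @export
normalize_log2 <- function(m, scale_factor = 10000) {
  g <- if (inherits(m, "cell_screen_matrix")) extract_gene_matrix(m) else
    methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  tot <- Matrix::rowSums(g)
  if (any(tot == 0))
    stop(sum(tot == 0), " cell(s) have zero total counts; run QC first",
         call. = FALSE)
  v <- methods::as(g, "CsparseMatrix")
  # dgCMatrix entry rows: expand @i per column pointer
  row_of <- v@i + 1L
  v@x <- log2(1 + scale_factor * v@x / tot[row_of])
  structure(list(values = v,
                 cell_totals_pre_log = stats::setNames(rep(scale_factor,
                                                           nrow(g)),
                                                       rownames(g)),
                 scale_factor = scale_factor),
            class = "normalized_matrix")
}
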