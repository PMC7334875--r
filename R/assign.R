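# Guide-to-cell assignment from the guide x cell UMI submatrix, plus MOI
# estimation under the Poisson uptake model.

#' Sparse cell x feature count container for a CROP-seq screen
#'
#' Wraps a sparse nonnegative integer matrix (cells in rows) with a
#' per-feature kind label distinguishing transcriptome genes from gRNA
#' detection features.
#'
#' @param counts Sparse (or coercible) nonnegative matrix, cells x features,
#'   with barcode rownames and feature-id colnames.
#' @param feature_kind Character vector, one of `"gene"`/`"guide"` per
#'   feature.
#' @return An object of class `cell_screen_matrix`.
#' @export
cell_screen_matrix <- function(counts, feature_kind) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (length(feature_kind) != ncol(counts))
    stop("feature_kind length must equal ncol(counts)", call. = FALSE)
  if (!all(feature_kind %in% c("gene", "guide")))
    stop("feature_kind entries must be 'gene' or 'guide'", call. = FALSE)
  if (length(counts@x) && min(counts@x) < 0)
    stop("counts must be nonnegative", call. = FALSE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts needs unique feature colnames", call. = FALSE)
  if (!any(feature_kind == "gene"))
    stop("at least one gene feature is required", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell_%d", seq_len(nrow(counts)))
  structure(list(counts = counts, feature_kind = feature_kind,
                 barcodes = rownames(counts)),
            class = "cell_screen_matrix")
}

#' @export
print.cell_screen_matrix <- function(x, ...) {
  cat(sprintf("cell_screen_matrix: %d cells x %d features (%d genes, %d guides)\n",
              nrow(x$counts), ncol(x$counts), sum(x$feature_kind == "gene"),
              sum(x$feature_kind == "guide")))
  invisible(x)
}

#' Extract the guide x cell UMI submatrix
#'
#' @param m A [cell_screen_matrix()].
#' @return Sparse cells x guides matrix (guide-feature columns, order
#'   preserved).
#' @export
extract_guide_matrix <- function(m) {
  stopifnot(inherits(m, "cell_screen_matrix"))
  if (!any(m$feature_kind == "guide"))
    stop("matrix has no guide features", call. = FALSE)
  m$counts[, m$feature_kind == "guide", drop = FALSE]
}

#' Extract the gene x cell UMI submatrix
#'
#' @param m A [cell_screen_matrix()].
#' @return Sparse cells x genes matrix.
#' @export
extract_gene_matrix <- function(m) {
  stopifnot(inherits(m, "cell_screen_matrix"))
  m$counts[, m$feature_kind == "gene", drop = FALSE]
}

#' Assign guides to cells by UMI presence
#'
#' Binarizes the guide UMI matrix at `umi >= min_umi` (default: any UMI, the
#' standard CROP-seq rule), counts guides per cell, and keeps exactly the
#' single-guide cells for downstream association testing.
#'
#' @param m A [cell_screen_matrix()].
#' @param min_umi Minimum UMI count for a guide call (default 1).
#' @return An object of class `guide_assignment`: list with `indicator`
#'   (sparse binary cells x guides), `n_guides_per_cell`, `kept_cells`
#'   (barcodes with exactly one guide) and `assignment` (data.frame barcode,
#'   guide_id, multiplicity over all cells; guide_id is NA unless
#'   multiplicity is 1).
#' @export
assign_guides <- function(m, min_umi = 1L) {
  gm <- extract_guide_matrix(m)
  ind <- Matrix::drop0(methods::as(gm >= min_umi, "CsparseMatrix") * 1)
  mult <- as.integer(Matrix::rowSums(ind))
  kept <- rownames(gm)[mult == 1L]
  one <- ind[mult == 1L, , drop = FALSE]
  guide_of <- colnames(gm)[methods::as(one, "TsparseMatrix")@j + 1L][
    order(methods::as(one, "TsparseMatrix")@i)]
  assignment <- data.frame(barcode = rownames(gm), multiplicity = mult,
                           guide_id = NA_character_)
  assignment$guide_id[mult == 1L] <- guide_of
  structure(list(indicator = ind,
                 n_guides_per_cell = stats::setNames(mult, rownames(gm)),
                 kept_cells = kept, assignment = assignment),
            class = "guide_assignment")
}

#' @export
print.guide_assignment <- function(x, ...) {
  cat(sprintf("guide_assignment: %d cells, %d single-guide cells kept\n",
              length(x$n_guides_per_cell), length(x$kept_cells)))
  print(table(multiplicity = x$n_guides_per_cell))
  invisible(x)
}

#' Estimate MOI from the uninfected fraction
#'
#' Under Poisson uptake the zero-integration fraction is `exp(-lambda)`, so
#' `lambda = -log(fraction_zero)`.
#'
#' @param fraction_zero Fraction of cells with zero integrations, in (0, 1].
#' @return The Poisson rate `lambda` (multiplicity of infection).
#' @examples
#' estimate_moi(exp(-1))  # 1
#' @export
estimate_moi <- function(fraction_zero) {
  if (!is.numeric(fraction_zero) || length(fraction_zero) != 1L ||
      is.na(fraction_zero) || fraction_zero <= 0 || fraction_zero > 1)
    stop("fraction_zero must be a single value in (0, 1]", call. = FALSE)
  -log(fraction_zero)
}

#' Estimate MOI from a post-selection multiplicity histogram
#'
#' After selection the observable guides-per-cell distribution is
#' zero-truncated Poisson; the rate is recovered by maximum likelihood from
#' the truncated mean, `mean(k) = lambda / (1 - exp(-lambda))`.  Detection
#' dropout biases the estimate downward; counts of zero detected guides are
#' excluded as dropout artefacts.
#'
#' @param n_guides_per_cell Integer vector of detected guides per cell.
#' @return Estimated `lambda`.
#' @export
moi_from_multiplicity <- function(n_guides_per_cell) {
  k <- n_guides_per_cell[n_guides_per_cell >= 1L]
  if (!length(k)) stop("no cells with detected guides", call. = FALSE)
  mbar <- mean(k)
  if (mbar <= 1) return(0)
  stats::uniroot(function(l) l / (1 - exp(-l)) - mbar,
                 c(1e-8, mbar * 2 + 10), tol = 1e-10)$root
}

#' Cells per guide with summary statistics
#'
#' Counts single-guide (kept) cells per guide; guides with zero kept cells
#' are reported as 0, not dropped.
#'
#' @param a A [assign_guides()] result.
#' @return List with `counts` (named per-guide kept-cell counts) and
#'   `summary` (mean, sd, min, max; sd is the sample SD).
#' @export
cells_per_guide <- function(a) {
  stopifnot(inherits(a, "guide_assignment"))
  kept <- a$assignment[a$assignment$multiplicity == 1L, ]
  counts <- table(factor(kept$guide_id, levels = colnames(a$indicator)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       summary = c(mean = mean(counts), sd = stats::sd(counts),
                   min = min(counts), max = max(counts)))
}

#' Write a guide assignment table
#'
#' @param a A [assign_guides()] result.
#' @param path TSV path (barcode, guide_id, multiplicity).
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(a, path, seed = NULL) {
  write_tsv_header(a$assignment[, c("barcode", "guide_id", "multiplicity")],
                   path, seed = seed)
}
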