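# Per-eSNP hypothesis testing: univariate OLS of a linked transcript's
# normalized expression on the guide indicator, with a Student's t-test on
# the slope and locus-wise Bonferroni control.  With a binary regressor the
# slope equals the group-mean difference and the slope t-test is numerically
# the pooled two-sample t-test.

#' Multiple-testing parameters
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param tests_per_locus Number of simultaneous tests charged per locus
#'   (default 20, giving the adjusted critical value 0.0025).
#' @return A list of class `mtc_params`.
#' @export
mtc_params <- function(alpha = 0.05, tests_per_locus = 20L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (tests_per_locus < 1) stop("tests_per_locus must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, tests_per_locus = as.integer(tests_per_locus)),
            class = "mtc_params")
}

#' Locus-wise Bonferroni critical value
#'
#' @param p A [mtc_params()].
#' @return `alpha / tests_per_locus`.
#' @examples
#' bonferroni_threshold(mtc_params(0.05, 20))  # 0.0025
#' @export
bonferroni_threshold <- function(p = mtc_params()) {
  stopifnot(inherits(p, "mtc_params"))
  p$alpha / p$tests_per_locus
}

#' Test one (guide, gene) pair
#'
#' Ordinary least squares `y = a + b * g` over single-guide cells, where `g`
#' indicates carrying the guide; `b` equals `mean(y | g = 1) - mean(y | g =
#' 0)` exactly, and the slope t-test on `n - 2` degrees of freedom is the
#' pooled two-sample t-test.  Negative `beta` means lower expression in
#' guide-carrying cells.
#'
#' @param y Numeric normalized-expression vector over kept cells.
#' @param g Binary (0/1 or logical) guide indicator of the same length.
#' @return List with `beta`, `se`, `t`, `df`, `p`, `n1`, `n0`, `untestable`.
#'   Fewer than 2 cells in either group flags the result untestable (with
#'   NA statistics); zero variance in `y` returns `beta = 0`, `p = 1`.
#' @export
test_guide_gene <- function(y, g) {
  g <- as.numeric(g)
  if (length(y) != length(g)) stop("y and g lengths differ", call. = FALSE)
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (!all(g %in% c(0, 1))) stop("g must be binary", call. = FALSE)
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  if (n1 < 2 || n0 < 2)
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_,
                df = n1 + n0 - 2, p = NA_real_, n1 = n1, n0 = n0,
                untestable = TRUE))
  y1 <- y[g == 1]; y0 <- y[g == 0]
  beta <- mean(y1) - mean(y0)
  df <- n1 + n0 - 2
  ss <- sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)
  if (ss == 0)
    return(list(beta = 0, se = 0, t = NA_real_, df = df, p = 1,
                n1 = n1, n0 = n0, untestable = FALSE))
  se <- sqrt(ss / df * (1 / n1 + 1 / n0))
  t <- beta / se
  list(beta = beta, se = se, t = t, df = df,
       p = 2 * stats::pt(-abs(t), df), n1 = n1, n0 = n0, untestable = FALSE)
}

#' Run the per-eSNP association screen
#'
#' For every candidate guide, tests its locus's target gene (role `target`)
#' and each of the locus's adjacent genes (role `adjacent`) by
#' [test_guide_gene()], comparing the guide's single-guide cells against all
#' other single-guide kept cells.  Each locus's tests share the Bonferroni
#' critical value `alpha / tests_per_locus`.
#'
#' @param norm A [normalize_log2()] result.
#' @param assign A [assign_guides()] result.
#' @param design A `screen_design`.
#' @param mtc A [mtc_params()].
#' @param adjacent Include adjacent-gene negative-control tests?
#' @param control_cells `"other"` (default: all other single-guide cells) or
#'   `"negative"` (restrict the reference group to negative-control cells).
#' @return Data.frame of association results sorted by locus then p-value,
#'   with columns guide_id, snp_id, gene, locus, role, n1, n0, beta, se, t,
#'   df, p, alpha_adj, significant, untestable.
#' @export
run_screen <- function(norm, assign, design, mtc = mtc_params(),
                       adjacent = TRUE, control_cells = c("other", "negative")) {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(assign, "guide_assignment"),
            inherits(design, "screen_design"))
  control_cells <- match.arg(control_cells)
  cells <- intersect(rownames(norm$values), assign$kept_cells)
  kept <- assign$assignment[assign$assignment$multiplicity == 1L, ]
  kept <- kept[kept$barcode %in% cells, ]
  alpha_adj <- bonferroni_threshold(mtc)

  specs <- do.call(rbind, lapply(names(design$loci), function(lc) {
    l <- design$loci[[lc]]
    ids <- l$candidate_guide_ids
    rbind(data.frame(guide_id = ids, locus = lc, gene = l$target_gene,
                     role = "target"),
          if (adjacent && length(l$adjacent_genes))
            expand.grid(guide_id = ids, locus = lc, gene = l$adjacent_genes,
                        role = "adjacent", stringsAsFactors = FALSE))
  }))
  genes_avail <- colnames(norm$values)

  res <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    if (!s$guide_id %in% kept$guide_id) {
      warning("guide ", s$guide_id, " has no single-guide cells; skipped",
              call. = FALSE)
      return(NULL)
    }
    in_group <- kept$barcode[kept$guide_id == s$guide_id]
    ref <- if (control_cells == "negative") {
      neg <- design$guides$guide_id[design$guides$control_class == "negative"]
      kept$barcode[kept$guide_id %in% neg]
    } else setdiff(kept$barcode, in_group)
    use <- c(in_group, ref)
    if (!s$gene %in% genes_avail) {
      core <- list(beta = NA_real_, se = NA_real_, t = NA_real_, df = NA_real_,
                   p = NA_real_, n1 = length(in_group), n0 = length(ref),
                   untestable = TRUE)
    } else {
      y <- as.numeric(norm$values[use, s$gene])
      core <- test_guide_gene(y, c(rep(1, length(in_group)),
                                   rep(0, length(ref))))
    }
    snp <- design$guides$snp_id[match(s$guide_id, design$guides$guide_id)]
    data.frame(guide_id = s$guide_id, snp_id = snp, gene = s$gene,
               locus = s$locus, role = s$role, n1 = core$n1, n0 = core$n0,
               beta = core$beta, se = core$se, t = core$t, df = core$df,
               p = core$p, alpha_adj = alpha_adj,
               significant = !core$untestable && !is.na(core$p) &&
                 core$p < alpha_adj,
               untestable = core$untestable)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$locus, out$role != "target", out$p), ]
  rownames(out) <- NULL
  out
}

#' Concordant hits across two replicates
#'
#' A (guide, gene) pair is a hit when it is significant at its locus-wise
#' adjusted threshold in BOTH replicate result tables; pairs significant in
#' only one replicate are reported separately as single-replicate nominal
#' associations.
#'
#' @param resA,resB Result tables from [run_screen()] on the same design.
#' @return List with `hits` and `single_replicate` data.frames (guide_id,
#'   gene, role, p_A, p_B).
#' @export
replicate_concordance <- function(resA, resB) {
  key <- function(r) paste(r$guide_id, r$gene)
  if (!setequal(key(resA), key(resB)))
    stop("replicate result tables test different (guide, gene) pairs",
         call. = FALSE)
  b <- resB[match(key(resA), key(resB)), ]
  merged <- data.frame(guide_id = resA$guide_id, gene = resA$gene,
                       role = resA$role, p_A = resA$p, p_B = b$p,
                       sig_A = resA$significant, sig_B = b$significant)
  list(hits = merged[merged$sig_A & merged$sig_B,
                     c("guide_id", "gene", "role", "p_A", "p_B")],
       single_replicate = merged[xor(merged$sig_A, merged$sig_B),
                                 c("guide_id", "gene", "role", "p_A", "p_B")])
}

#' Manhattan-style table for a locus
#'
#' Joins association results with the design's SNP coordinates for plotting
#' -log10 p along the locus.
#'
#' @param results A [run_screen()] table.
#' @param design The matching `screen_design`.
#' @return Data.frame with chrom, pos, snp_id, guide_id, gene, role, p,
#'   neg_log10_p, significant, sorted by position within locus.
#' @export
manhattan_table <- function(results, design) {
  i <- match(results$guide_id, design$guides$guide_id)
  out <- data.frame(chrom = design$guides$chrom[i], pos = design$guides$pos[i],
                    snp_id = results$snp_id, guide_id = results$guide_id,
                    locus = results$locus, gene = results$gene,
                    role = results$role, p = results$p,
                    neg_log10_p = -log10(results$p),
                    significant = results$significant)
  out <- out[order(out$locus, out$pos), ]
  rownames(out) <- NULL
  out
}
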