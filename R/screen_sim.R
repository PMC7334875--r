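# Synthetic expression CROP-seq screens with ground truth: lentiviral guide
# uptake (zero-truncated Poisson, i.e. post-puromycin selection), editing
# outcomes per guided cell, negative-binomial gene UMIs with injected cis
# effects on each locus's target gene, and guide-feature UMIs with detection
# dropout.

#' The 67-guide screen design used throughout the package
#'
#' Three eQTL loci with 57 candidate-SNP guides — CISD1 (20, adjacent genes
#' IPMK and UBE2D1), PARK7 (19, adjacent ERRFI1), DAP (18, adjacent
#' ANKRD33B) — plus 10 controls: 5 positive controls in the essential genes
#' TUBB and RUNX1, 3 non-targeting negative controls, and 2 further
#' non-SNP-targeting controls.  SNP coordinates and protospacer sequences are
#' synthetic but deterministic given `seed`.
#'
#' @param seed Integer seed for the synthetic sequences/coordinates.
#' @return An object of class `screen_design`: list with `guides` (guide
#'   table), `loci` (per-locus target gene, adjacent genes and candidate
#'   guide ids), `n_candidates` (57) and `n_controls` (10).
#' @export
default_paper_design <- function(seed = 1L) {
  loci <- list(
    CISD1 = list(target_gene = "CISD1", adjacent_genes = c("IPMK", "UBE2D1"),
                 chrom = "chr10", base = 58610000L, n = 20L),
    PARK7 = list(target_gene = "PARK7", adjacent_genes = "ERRFI1",
                 chrom = "chr1", base = 7950000L, n = 19L),
    DAP = list(target_gene = "DAP", adjacent_genes = "ANKRD33B",
               chrom = "chr5", base = 10680000L, n = 18L))
  with_seed(seed, {
    rand_proto <- function(n) {
      vapply(seq_len(n), function(i) {
        repeat {
          p <- paste(sample(c("A", "C", "G", "T"), 19L, replace = TRUE),
                     collapse = "")
          gc <- gc_fraction(p)
          if (gc >= 0.4 && gc <= 0.8) return(p)
        }
      }, character(1))
    }
    cand <- do.call(rbind, lapply(names(loci), function(lc) {
      l <- loci[[lc]]
      pos <- l$base + sort(sample.int(20000L, l$n))
      data.frame(guide_id = sprintf("%s_snp%02d", lc, seq_len(l$n)),
                 snp_id = sprintf("rs%s", format(pos + sample.int(1000L, l$n),
                                                 scientific = FALSE, trim = TRUE)),
                 locus = lc, target_gene = l$target_gene,
                 control_class = "candidate", chrom = l$chrom, pos = pos,
                 protospacer = rand_proto(l$n))
    }))
    ctrl <- data.frame(
      guide_id = c(sprintf("pos_TUBB_%d", 1:3), sprintf("pos_RUNX1_%d", 1:2),
                   sprintf("neg_nt_%d", 1:3), sprintf("ctrl_nonSNP_%d", 1:2)),
      snp_id = NA_character_,
      locus = c(rep("TUBB", 3L), rep("RUNX1", 2L), rep(NA_character_, 3L),
                rep("safe_harbor", 2L)),
      target_gene = c(rep("TUBB", 3L), rep("RUNX1", 2L), rep(NA_character_, 5L)),
      control_class = c(rep("positive", 5L), rep("negative", 3L),
                        rep("non_snp", 2L)),
      chrom = NA_character_, pos = NA_integer_,
      protospacer = rand_proto(10L))
    guides <- rbind(cand, ctrl)
    rownames(guides) <- NULL
    structure(list(
      guides = guides,
      loci = lapply(loci, function(l) {
        ids <- guides$guide_id[guides$control_class == "candidate" &
                               guides$target_gene == l$target_gene]
        list(target_gene = l$target_gene, adjacent_genes = l$adjacent_genes,
             candidate_guide_ids = ids)
      }),
      n_candidates = sum(guides$control_class == "candidate"),
      n_controls = sum(guides$control_class != "candidate")),
      class = "screen_design")
  })
}

#' Default synthetic gene panel
#'
#' Per-gene mean UMI counts for the simulator: the three target genes, their
#' adjacent genes, the two essential positive-control genes, a configurable
#' number of background genes with log-normal mean spread, and 13
#' mitochondrial (`MT-`) pseudo-genes contributing `mito_fraction_mean` of
#' counts in expectation.  Means are deterministic (quantile-spaced, no RNG)
#' and nominally sum to `total_mean` UMIs per cell.
#'
#' @param design A `screen_design` (supplies target/adjacent gene names).
#' @param n_background Number of background genes.
#' @param mito_fraction_mean Expected mitochondrial fraction of counts.
#' @param total_mean Nominal total UMIs per cell before per-cell library-size
#'   scaling.
#' @return Named numeric vector of per-gene mean UMI counts.
#' @export
default_gene_panel <- function(design, n_background = 300L,
                               mito_fraction_mean = 0.08, total_mean = 4500) {
  special <- c(CISD1 = 12, PARK7 = 18, DAP = 8, IPMK = 5, UBE2D1 = 6,
               ERRFI1 = 4, ANKRD33B = 3, TUBB = 40, RUNX1 = 15)
  need <- unique(c(vapply(design$loci, `[[`, "", "target_gene"),
                   unlist(lapply(design$loci, `[[`, "adjacent_genes"))))
  missing <- setdiff(need, names(special))
  if (length(missing)) special[missing] <- 5
  bg <- stats::qlnorm(stats::ppoints(n_background), meanlog = 0, sdlog = 1.6)
  names(bg) <- sprintf("GENE%04d", seq_len(n_background))
  n_mito <- 13L
  mito <- stats::qlnorm(stats::ppoints(n_mito), meanlog = 0, sdlog = 0.5)
  names(mito) <- sprintf("MT-G%02d", seq_len(n_mito))
  non_mito_target <- (1 - mito_fraction_mean) * total_mean
  bg <- bg * (non_mito_target - sum(special)) / sum(bg)
  if (any(bg <= 0)) stop("total_mean too small for the fixed gene means",
                         call. = FALSE)
  mito <- mito * mito_fraction_mean * total_mean / sum(mito)
  c(special, bg, mito)
}

#' Simulation parameters for a synthetic screen
#'
#' Defaults follow the screen this package models: uneven single-guide cell
#' coverage via Poisson uptake conditioned on selection, 92% of guided cells
#' with at least one edited allele, 29% of edited cells with a single edited
#' allele, 67% of edits disrupting the targeted SNP, and a cis effect of 0.5
#' standard-deviation units of normalized log2 expression on the disrupted
#' SNP's target gene.
#'
#' @param n_cells Number of cells surviving selection.
#' @param moi Poisson rate of lentiviral integrations per cell (uptake is
#'   conditioned on >= 1 integration, modelling puromycin selection).
#' @param guide_probs Named probability vector over guides (default uniform).
#' @param p_edit P(guided cell carries >= 1 edited allele).
#' @param p_single_allele P(exactly one edited allele | edited).
#' @param p_disrupt P(edit functionally disrupts the SNP | edited), applied
#'   to candidate-SNP guides.
#' @param effect_sd Mean downward shift, in SDs of normalized log2
#'   expression, of the target gene in cells whose causal-guide SNP is
#'   disrupted.
#' @param causal_guides Guide ids of the truly regulatory SNPs; only
#'   disruption by these guides shifts the target gene.  Default: the first
#'   candidate guide of each locus (one causal variant per credible
#'   interval).
#' @param baseline_means Named per-gene mean UMI vector (default
#'   [default_gene_panel()]).
#' @param dispersion Negative-binomial size (inverse dispersion); `Inf` gives
#'   Poisson counts.
#' @param libsize_range Range of per-cell target library sizes (UMIs).
#' @param mito_fraction_mean Expected mitochondrial count fraction (used when
#'   building the default panel).
#' @param guide_umi_mean Mean UMIs for a detected guide feature.
#' @param detect_dropout P(an integrated guide yields zero UMIs).
#' @param guide_survival Optional named per-guide cell survival probability
#'   (models essential-gene dropout); default 1 for all guides.
#' @param plasmid_reads Total plasmid-pool DNA reads to distribute.
#' @param scale_factor Normalization scale factor used when calibrating the
#'   injected effect.
#' @param n_background Background genes in the default panel.
#' @param seed Integer seed; identical seeds give identical screens.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 6000L, moi = 0.3, guide_probs = NULL,
                       p_edit = 0.92, p_single_allele = 0.29, p_disrupt = 0.67,
                       effect_sd = 0.5, causal_guides = NULL,
                       baseline_means = NULL, dispersion = 10,
                       libsize_range = c(2000, 7000), mito_fraction_mean = 0.08,
                       guide_umi_mean = 3, detect_dropout = 0.05,
                       guide_survival = NULL, plasmid_reads = 1e6,
                       scale_factor = 1e4, n_background = 300L, seed = 1L) {
  probs <- c(p_edit = p_edit, p_single_allele = p_single_allele,
             p_disrupt = p_disrupt, detect_dropout = detect_dropout,
             mito_fraction_mean = mito_fraction_mean)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  if (moi <= 0) stop("moi must be positive", call. = FALSE)
  if (!is.null(guide_probs) && abs(sum(guide_probs) - 1) > 1e-8)
    stop("guide_probs must sum to 1", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), moi = moi,
                 guide_probs = guide_probs, p_edit = p_edit,
                 p_single_allele = p_single_allele, p_disrupt = p_disrupt,
                 effect_sd = effect_sd, causal_guides = causal_guides,
                 baseline_means = baseline_means,
                 dispersion = dispersion, libsize_range = libsize_range,
                 mito_fraction_mean = mito_fraction_mean,
                 guide_umi_mean = guide_umi_mean,
                 detect_dropout = detect_dropout,
                 guide_survival = guide_survival,
                 plasmid_reads = plasmid_reads, scale_factor = scale_factor,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# zero-truncated Poisson draw by inversion
rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

#' Simulate lentiviral guide uptake
#'
#' Integrations per cell are zero-truncated Poisson(`moi`) (puromycin
#' selection removes uninfected cells); guide identities are drawn without
#' replacement per cell from `guide_probs`.
#'
#' @param n_cells Number of cells.
#' @param moi Poisson integration rate.
#' @param guide_ids Guide identifiers.
#' @param guide_probs Probability per guide (default uniform).
#' @return List with `k` (integrations per cell) and `pairs`, a data.frame
#'   of (cell index, guide_id) integration events.  Caller controls the RNG
#'   state.
#' @export
simulate_guide_uptake <- function(n_cells, moi, guide_ids, guide_probs = NULL) {
  G <- length(guide_ids)
  probs <- guide_probs %||% rep(1 / G, G)
  k <- pmin(rztpois(n_cells, moi), G)
  idx1 <- which(k == 1L)
  g1 <- sample.int(G, length(idx1), replace = TRUE, prob = probs)
  multi <- which(k > 1L)
  gm <- lapply(multi, function(c) sample.int(G, k[c], prob = probs))
  pairs <- data.frame(
    cell = c(idx1, rep(multi, k[multi])),
    guide_idx = c(g1, unlist(gm)))
  pairs <- pairs[order(pairs$cell, pairs$guide_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$guide_id <- guide_ids[pairs$guide_idx]
  list(k = k, pairs = pairs)
}

#' Calibrate the multiplicative effect on a gene's NB mean
#'
#' Finds the factor `f` on a gene's negative-binomial mean such that the
#' expected normalized log2 expression, `E[log2(1 + scale * X / L)]`, drops
#' by `effect_sd` baseline standard deviations.  Expectations are computed by
#' direct summation over the NB pmf (deterministic).
#'
#' @param mu_count Baseline expected UMI count of the gene per cell at the
#'   mean library size.
#' @param dispersion NB size parameter (`Inf` = Poisson).
#' @param libsize Per-cell total UMI count; a vector is treated as an
#'   equal-weight grid over the library-size distribution (the gene's mean
#'   scales proportionally), so the baseline SD includes library-size
#'   variation.
#' @param scale_factor Normalization scale factor.
#' @param effect_sd Target shift in baseline-SD units (positive = reduction).
#' @return The factor `f` in (0, 1] (or > 1 for negative `effect_sd`).
#' @export
calibrate_effect_factor <- function(mu_count, dispersion, libsize,
                                    scale_factor, effect_sd) {
  p_gene <- mu_count / mean(libsize)
  moments <- function(f) {
    m1 <- 0; m2 <- 0
    for (L in libsize) {
      mu <- f * p_gene * L
      kmax <- if (is.finite(dispersion))
        stats::qnbinom(1 - 1e-12, size = dispersion, mu = mu)
      else stats::qpois(1 - 1e-12, mu)
      k <- 0:kmax
      pk <- if (is.finite(dispersion))
        stats::dnbinom(k, size = dispersion, mu = mu)
      else stats::dpois(k, mu)
      v <- log2(1 + scale_factor * k / L)
      m1 <- m1 + sum(pk * v) / length(libsize)
      m2 <- m2 + sum(pk * v^2) / length(libsize)
    }
    c(mean = m1, sd = sqrt(max(0, m2 - m1^2)))
  }
  if (effect_sd == 0) return(1)
  base <- moments(1)
  shift <- effect_sd * base["sd"]
  if (shift >= base["mean"])
    stop("infeasible effect: requested shift (", round(shift, 3),
         ") exceeds baseline mean normalized expression (",
         round(base["mean"], 3), ")", call. = FALSE)
  g <- function(f) base["mean"] - moments(f)["mean"] - shift
  interval <- if (effect_sd > 0) c(1e-6, 1) else c(1, 1e3)
  stats::uniroot(g, interval, tol = 1e-8)$root
}

#' Simulate a pooled expression CROP-seq screen
#'
#' Generates per-cell guide uptake, editing-outcome ground truth, gene UMI
#' counts with the cis effect injected into SNP-disrupted cells, guide
#' feature UMIs with detection dropout, and plasmid-pool DNA read counts.
#' Identical `params$seed` gives identical output.
#'
#' @param design A `screen_design` from [default_paper_design()].
#' @param params A [sim_params()].
#' @return An object of class `simulated_screen`: list with `counts` (a
#'   [cell_screen_matrix()]), `guide_truth` (integration events incl.
#'   detection and UMIs), `edit_truth` (per guided cell: `edited`,
#'   `n_alleles`, `disrupted`), `plasmid_counts`, `libsize_target`, and the
#'   `design`/`params` used.
#' @export
simulate_screen <- function(design, params = sim_params()) {
  stopifnot(inherits(design, "screen_design"), inherits(params, "sim_params"))
  with_seed(params$seed, {
    guides <- design$guides
    G <- nrow(guides)
    mu <- params$baseline_means %||%
      default_gene_panel(design, n_background = params$n_background,
                         mito_fraction_mean = params$mito_fraction_mean)
    tg <- vapply(design$loci, `[[`, "", "target_gene")
    if (!all(tg %in% names(mu)))
      stop("baseline_means must include target genes: ",
           paste(setdiff(tg, names(mu)), collapse = ", "), call. = FALSE)

    up <- simulate_guide_uptake(params$n_cells, params$moi, guides$guide_id,
                                params$guide_probs)
    pairs <- up$pairs

    # essential-gene (or other) per-guide survival: a cell dies if any of its
    # integrations fails its survival draw
    if (!is.null(params$guide_survival)) {
      surv <- rep(1, G); names(surv) <- guides$guide_id
      surv[names(params$guide_survival)] <- params$guide_survival
      die <- stats::runif(nrow(pairs)) > surv[pairs$guide_id]
      dead_cells <- unique(pairs$cell[die])
      pairs <- pairs[!pairs$cell %in% dead_cells, , drop = FALSE]
    }
    live <- sort(unique(pairs$cell))
    n <- length(live)
    pairs$cell <- match(pairs$cell, live)
    barcodes <- sprintf("BC%06d", seq_len(n))

    # editing-outcome ground truth for genome-targeting guides
    targeting <- guides$control_class[pairs$guide_idx] != "negative"
    edited <- targeting & stats::runif(nrow(pairs)) < params$p_edit
    n_alleles <- ifelse(edited,
                        ifelse(stats::runif(nrow(pairs)) < params$p_single_allele,
                               1L, 2L), NA_integer_)
    disrupted <- edited &
      guides$control_class[pairs$guide_idx] == "candidate" &
      stats::runif(nrow(pairs)) < params$p_disrupt
    edit_truth <- data.frame(barcode = barcodes[pairs$cell],
                             guide_id = pairs$guide_id,
                             control_class = guides$control_class[pairs$guide_idx],
                             edited = edited, n_alleles = n_alleles,
                             disrupted = disrupted)

    # guide detection and UMIs
    detected <- stats::runif(nrow(pairs)) < 1 - params$detect_dropout
    umi <- integer(nrow(pairs))
    umi[detected] <- rztpois(sum(detected), params$guide_umi_mean)
    guide_truth <- data.frame(barcode = barcodes[pairs$cell],
                              guide_id = pairs$guide_id,
                              detected = detected, umi = umi)

    # gene expression
    L <- stats::runif(n, params$libsize_range[1], params$libsize_range[2])
    sf <- L / sum(mu)
    mu_mat <- outer(sf, mu)
    if (params$effect_sd != 0) {
      causal <- params$causal_guides %||%
        vapply(design$loci, function(l) l$candidate_guide_ids[1], "")
      bad <- setdiff(causal, guides$guide_id[guides$control_class ==
                                               "candidate"])
      if (length(bad))
        stop("causal_guides not candidate guides of this design: ",
             paste(bad, collapse = ", "), call. = FALSE)
      Lgrid <- seq(params$libsize_range[1], params$libsize_range[2],
                   length.out = 9)
      for (lc in names(design$loci)) {
        gene <- design$loci[[lc]]$target_gene
        f <- calibrate_effect_factor(mu[[gene]] * mean(Lgrid) / sum(mu),
                                     params$dispersion, Lgrid,
                                     params$scale_factor, params$effect_sd)
        hit <- pairs$cell[disrupted & pairs$guide_id %in% causal &
                            guides$locus[pairs$guide_idx] == lc]
        if (length(hit)) mu_mat[unique(hit), gene] <-
            mu_mat[unique(hit), gene] * f
      }
    }
    counts <- if (is.finite(params$dispersion))
      stats::rnbinom(n * length(mu), size = params$dispersion, mu = mu_mat)
    else stats::rpois(n * length(mu), mu_mat)
    gene_mat <- Matrix::Matrix(matrix(counts, nrow = n,
                                      dimnames = list(barcodes, names(mu))),
                               sparse = TRUE)

    det <- pairs[detected & umi > 0, , drop = FALSE]
    guide_mat <- Matrix::sparseMatrix(i = det$cell, j = det$guide_idx,
                                      x = umi[detected & umi > 0],
                                      dims = c(n, G),
                                      dimnames = list(barcodes,
                                                      guides$guide_id))
    m <- cell_screen_matrix(cbind(gene_mat, guide_mat),
                            feature_kind = c(rep("gene", length(mu)),
                                             rep("guide", G)))

    plasmid <- as.integer(stats::rmultinom(
      1, params$plasmid_reads,
      params$guide_probs %||% rep(1 / G, G)))
    names(plasmid) <- guides$guide_id

    structure(list(counts = m, guide_truth = guide_truth,
                   edit_truth = edit_truth, plasmid_counts = plasmid,
                   libsize_target = L, design = design, params = params),
              class = "simulated_screen")
  })
}

#' Write a screen in 10x-style MatrixMarket layout
#'
#' Emits `matrix.mtx` (integer coordinate MatrixMarket, features as rows),
#' `features.tsv` (id, name, type: `Gene Expression` or `Guide`) and
#' `barcodes.tsv` into `out_dir`.  For a full `simulated_screen`, the
#' ground-truth tables (`guide_truth.tsv`, `edit_truth.tsv`,
#' `plasmid_counts.tsv`) are written alongside.
#'
#' @param x A `simulated_screen` or [cell_screen_matrix()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_10x_like <- function(x, out_dir) {
  m <- if (inherits(x, "simulated_screen")) x$counts else x
  stopifnot(inherits(m, "cell_screen_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tm <- as(Matrix::t(m$counts), "TsparseMatrix")  # features x cells
  mtx <- file.path(out_dir, "matrix.mtx")
  con <- file(mtx, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "%  cropmap 10x-style counts, features as rows",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x))
    utils::write.table(data.frame(tm@i + 1L, tm@j + 1L, as.integer(tm@x)),
                       con, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)
  feat <- data.frame(id = colnames(m$counts), name = colnames(m$counts),
                     type = ifelse(m$feature_kind == "guide", "Guide",
                                   "Gene Expression"))
  utils::write.table(feat, file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(m$counts) %||% character(), file.path(out_dir, "barcodes.tsv"))
  paths <- file.path(out_dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  if (inherits(x, "simulated_screen")) {
    write_tsv_header(x$guide_truth, file.path(out_dir, "guide_truth.tsv"),
                     seed = x$params$seed)
    write_tsv_header(x$edit_truth, file.path(out_dir, "edit_truth.tsv"),
                     seed = x$params$seed)
    write_tsv_header(data.frame(guide_id = names(x$plasmid_counts),
                                reads = as.integer(x$plasmid_counts)),
                     file.path(out_dir, "plasmid_counts.tsv"),
                     seed = x$params$seed)
    paths <- c(paths, file.path(out_dir, c("guide_truth.tsv", "edit_truth.tsv",
                                           "plasmid_counts.tsv")))
  }
  invisible(paths)
}

#' Read a 10x-style matrix directory
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` as written by [write_10x_like()].
#' @return A [cell_screen_matrix()].
#' @export
read_10x_like <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir, call. = FALSE)
  tm <- Matrix::readMM(mtx)
  feat <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                            stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  m <- Matrix::t(methods::as(tm, "CsparseMatrix"))
  dimnames(m) <- list(barcodes, feat[[1]])
  cell_screen_matrix(m, feature_kind = ifelse(feat[[3]] == "Guide",
                                              "guide", "gene"))
}
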