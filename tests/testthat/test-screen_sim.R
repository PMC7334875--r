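test_that("default design reproduces the 67-guide library composition", {
  d <- default_paper_design(1)
  expect_equal(nrow(d$guides), 67L)
  expect_equal(d$n_candidates, 57L)
  expect_equal(d$n_controls, 10L)
  tab <- table(d$guides$locus[d$guides$control_class == "candidate"])
  expect_equal(as.integer(tab[c("CISD1", "PARK7", "DAP")]), c(20L, 19L, 18L))
  expect_equal(sum(d$guides$control_class == "positive"), 5L)
  expect_equal(sum(d$guides$control_class == "negative"), 3L)
  expect_equal(sum(d$guides$control_class == "non_snp"), 2L)
  # deterministic given seed
  expect_identical(default_paper_design(7)$guides, default_paper_design(7)$guides)
  expect_false(identical(default_paper_design(7)$guides$protospacer,
                         default_paper_design(8)$guides$protospacer))
  # every candidate maps to exactly one target gene
  cand <- d$guides[d$guides$control_class == "candidate", ]
  expect_true(all(cand$target_gene ==
                    vapply(d$loci[cand$locus], `[[`, "", "target_gene")))
})

test_that("guide uptake is zero-truncated Poisson with per-cell distinct guides", {
  d <- default_paper_design(1)
  up <- cropmap:::with_seed(5, simulate_guide_uptake(50000, 0.5,
                                                     d$guides$guide_id))
  expect_true(all(up$k >= 1))
  # no duplicate guide within a cell
  expect_false(any(duplicated(up$pairs[c("cell", "guide_idx")])))
  # chi-square GOF against the zero-truncated Poisson pmf
  lambda <- 0.5
  kmax <- 6
  obs <- tabulate(pmin(up$k, kmax), nbins = kmax)
  pk <- dpois(1:kmax, lambda) / (1 - exp(-lambda))
  pk[kmax] <- 1 - sum(pk[-kmax])
  gof <- suppressWarnings(chisq.test(obs, p = pk))
  expect_gt(gof$p.value, 0.01)
})

test_that("MOI is recovered from simulated multiplicities within 5%", {
  d <- default_paper_design(1)
  for (lambda in c(0.3, 1)) {
    up <- cropmap:::with_seed(9, simulate_guide_uptake(50000, lambda,
                                                       d$guides$guide_id))
    expect_lt(abs(moi_from_multiplicity(up$k) - lambda) / lambda, 0.05)
  }
})

test_that("editing-outcome truth follows the configured probabilities", {
  s <- small_sim(seed = 21, n_cells = 3000)
  et <- s$edit_truth
  expect_true(all(!et$edited[et$control_class == "negative"]))
  targeting <- et[et$control_class != "negative", ]
  expect_equal(mean(targeting$edited), 0.92, tolerance = 0.02)
  expect_equal(mean(targeting$n_alleles[targeting$edited] == 1), 0.29,
               tolerance = 0.05)
  expect_true(all(!targeting$disrupted[!targeting$edited]))
  expect_true(all(et$barcode %in% rownames(s$counts$counts)))
  # p_edit = 0 switches editing (and therefore disruption) off entirely
  s0 <- small_sim(seed = 22, n_cells = 300, p_edit = 0)
  expect_false(any(s0$edit_truth$edited))
  expect_false(any(s0$edit_truth$disrupted))
})

test_that("identical seeds give byte-identical screens; seeds differ otherwise", {
  s1 <- small_sim(seed = 33, n_cells = 200)
  s2 <- small_sim(seed = 33, n_cells = 200)
  d1 <- tempfile(); d2 <- tempfile()
  write_10x_like(s1, d1); write_10x_like(s2, d2)
  expect_identical(readLines(file.path(d1, "matrix.mtx")),
                   readLines(file.path(d2, "matrix.mtx")))
  s3 <- small_sim(seed = 34, n_cells = 200)
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("the injected cis effect shifts normalized expression by effect_sd SDs", {
  design <- default_paper_design(1)
  causal <- design$loci$CISD1$candidate_guide_ids[1]
  probs <- setNames(rep(0.5 / 66, 67), design$guides$guide_id)
  probs[causal] <- 0.5
  params <- sim_params(n_cells = 5000, n_background = 40, guide_probs = probs,
                       p_edit = 1, p_disrupt = 1, effect_sd = 0.5,
                       detect_dropout = 0, seed = 44)
  s <- simulate_screen(design, params)
  norm <- normalize_log2(s$counts)
  causal_cells <- unique(s$edit_truth$barcode[s$edit_truth$guide_id == causal])
  cisd1_guides <- design$loci$CISD1$candidate_guide_ids
  clean <- setdiff(rownames(norm$values),
                   s$edit_truth$barcode[s$edit_truth$guide_id %in% cisd1_guides])
  y1 <- norm$values[causal_cells, "CISD1"]
  y0 <- norm$values[clean, "CISD1"]
  expect_equal((mean(y0) - mean(y1)) / sd(y0), 0.5, tolerance = 0.12)
})

test_that("an infeasible effect size errors at calibration", {
  expect_error(calibrate_effect_factor(0.05, 10, 4500, 1e4, 3),
               "infeasible")
  expect_equal(calibrate_effect_factor(12, 10, 4500, 1e4, 0), 1)
})

test_that("guide survival depletes cells carrying lethal guides", {
  design <- default_paper_design(1)
  surv <- setNames(rep(0.1, 5),
                   design$guides$guide_id[design$guides$control_class ==
                                            "positive"])
  s <- simulate_screen(design, sim_params(n_cells = 2000, n_background = 20,
                                          guide_survival = surv, seed = 55))
  a <- assign_guides(s$counts)
  cpg <- cells_per_guide(a)$counts
  pos <- names(surv)
  expect_lt(mean(cpg[pos]), 0.35 * mean(cpg[setdiff(names(cpg), pos)]))
})

test_that("10x-style writer round-trips and declares nnz correctly", {
  s <- small_sim(seed = 66, n_cells = 50)
  dir <- tempfile()
  write_10x_like(s, dir)
  hdr <- readLines(file.path(dir, "matrix.mtx"), n = 3)
  dims <- as.integer(strsplit(hdr[3], " ")[[1]])
  body <- length(readLines(file.path(dir, "matrix.mtx"))) - 3L
  expect_equal(dims[3], body)
  expect_equal(dims[3], length(s$counts$counts@x))
  back <- read_10x_like(dir)
  expect_equal(as.matrix(back$counts), as.matrix(s$counts$counts))
  expect_identical(back$feature_kind, s$counts$feature_kind)
  expect_identical(rownames(back$counts), rownames(s$counts$counts))
  # truth tables written alongside
  expect_true(file.exists(file.path(dir, "edit_truth.tsv")))
})

test_that("an empty screen still writes a valid MTX header", {
  m <- cell_screen_matrix(
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(0, 2),
                         dimnames = list(character(), c("gA", "guide1"))),
    feature_kind = c("gene", "guide"))
  dir <- tempfile()
  write_10x_like(m, dir)
  hdr <- readLines(file.path(dir, "matrix.mtx"))
  expect_equal(as.integer(strsplit(hdr[3], " ")[[1]]), c(2L, 0L, 0L))
})
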