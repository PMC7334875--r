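test_that("representation fractions normalize and log2 ratios behave", {
  # identical proportions: every log2 ratio is zero
  even <- representation_table(c(g1 = 10, g2 = 20, g3 = 30),
                               c(g1 = 100, g2 = 200, g3 = 300))
  expect_equal(even$log2_ratio, c(0, 0, 0))
  # g1 at twice its DNA share in RNA: log2 ratio exactly 1
  dna <- c(g1 = 2, g2 = 1, g3 = 1, g4 = 4)
  rna <- c(g1 = 4, g2 = 1, g3 = 1, g4 = 2)
  t <- representation_table(dna, rna)
  expect_equal(sum(t$dna_frac), 1)
  expect_equal(sum(t$rna_frac), 1)
  expect_equal(t$log2_ratio[t$guide_id == "g1"], 1)
  zero <- representation_table(c(g1 = 10, g2 = 0), c(g1 = 5, g2 = 3))
  expect_true(is.na(zero$log2_ratio[2]))
  expect_false(zero$ratio_defined[2])
  expect_error(representation_table(dna, rna[1:2]), "different")
  for (seed in 1:5) {
    set.seed(seed)
    t2 <- representation_table(setNames(rpois(10, 50) + 1, letters[1:10]),
                               setNames(rpois(10, 30) + 1, letters[1:10]))
    expect_equal(sum(t2$dna_frac) + sum(t2$rna_frac), 2)
  }
})

test_that("depletion test flags only guides under selection", {
  design <- default_paper_design(1)
  pos <- design$guides$guide_id[design$guides$control_class == "positive"]
  surv <- setNames(rep(0.15, 5), pos)
  s <- simulate_screen(design, sim_params(n_cells = 4000, n_background = 20,
                                          guide_survival = surv, seed = 7))
  a <- assign_guides(s$counts)
  t <- representation_table(s$plasmid_counts, cells_per_guide(a)$counts)
  calls <- depletion_test(t)
  expect_true(all(pos %in% calls$guide_id[calls$depleted]))
  expect_lte(sum(calls$depleted & !calls$guide_id %in% pos), 1L)
  expect_false(any(calls$enriched & calls$guide_id %in% pos))
})

test_that("depletion p-values are uniform under the proportional null", {
  set.seed(42)
  probs <- rep(1 / 40, 40)
  p <- replicate(1000, {
    dna <- as.integer(rmultinom(1, 2e5, probs))
    rna <- as.integer(rmultinom(1, 8000, probs))
    names(dna) <- names(rna) <- paste0("g", 1:40)
    depletion_test(representation_table(dna, rna))$p[1]
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("PVE algebra maps a 0.5 SD shift into the 5-10% eQTL range", {
  expect_equal(pve_from_shift(0, 0.3, "monoallelic"), 0)
  expect_equal(pve_from_shift(0.5, 0.5, "biallelic"), 0.03125)
  # allele frequency solving 2p(1-p) * 0.25 = 0.10
  p10 <- (1 - sqrt(1 - 0.8)) / 2
  expect_equal(pve_from_shift(0.5, p10, "monoallelic"), 0.10)
  grid <- seq(0.01, 0.99, by = 0.005)
  vals <- c(pve_from_shift(0.5, grid, "monoallelic"),
            pve_from_shift(0.5, grid, "biallelic"))
  expect_true(any(vals >= 0.05 & vals <= 0.10))
  # concave in p with the maximum at p = 0.5
  mono <- pve_from_shift(0.5, grid, "monoallelic")
  expect_equal(grid[which.max(mono)], 0.5)
  expect_true(all(diff(mono[grid <= 0.5]) > 0))
  expect_error(pve_from_shift(0.5, 0), "allele_freq")
})

test_that("two-group power is calibrated and monotone", {
  expect_equal(power_two_group(50, 50, 0, alpha = 0.05), 0.05, tolerance = 1e-9)
  pw <- power_two_group(c(10, 50, 100, 400), 6000, 0.5, 0.0025)
  expect_true(all(diff(pw) > 0))
  expect_gt(power_two_group(1e5, 1e5, 0.5, 0.0025), 0.999)
  expect_gt(power_two_group(100, 6000, 0.5, 0.01),
            power_two_group(100, 6000, 0.5, 0.0025))
  expect_gt(power_two_group(100, 6000, 0.8, 0.0025),
            power_two_group(100, 6000, 0.5, 0.0025))
})

test_that("closed-form power matches a Monte-Carlo t-test oracle", {
  # draw the t statistic from its sampling distribution under the alternative
  n1 <- 100; n0 <- 6000; delta <- 0.5; alpha <- 0.0025
  df <- n1 + n0 - 2
  ncp <- delta * sqrt(n1 * n0 / (n1 + n0))
  set.seed(8)
  nrep <- 20000
  tstat <- (rnorm(nrep) + ncp) / sqrt(rchisq(nrep, df) / df)
  mc <- mean(abs(tstat) > qt(1 - alpha / 2, df))
  ana <- power_two_group(n1, n0, delta, alpha)
  se <- sqrt(ana * (1 - ana) / nrep)
  expect_lt(abs(mc - ana), 2 * se + 1e-4)
})

test_that("ddCt fold changes follow the 2^-ddCt arithmetic", {
  expect_equal(fold_change_ddct(25, c(20, 22), c(3, 5)), 1)  # ddCt = 0
  expect_equal(fold_change_ddct(24, 20, 3), 0.5)             # ddCt = 1
  expect_equal(fold_change_ddct(22, 20, 3), 2)               # ddCt = -1
  # a control sample against its own control set is exactly 1
  dct_ctrl <- 4.2
  expect_equal(fold_change_ddct(24.2, 20, dct_ctrl), 1)
  expect_error(fold_change_ddct(25, numeric(), 3), "reference")
  expect_error(fold_change_ddct(25, 20, numeric()), "control")
})

test_that("peak overlap respects BED half-open coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100\tpeak1", "chr2\t10\t20\tpeak2"), bed)
  snps <- data.frame(snp_id = c("a", "b", "c", "d"),
                     chrom = c("chr1", "chr1", "chr2", "chr3"),
                     pos = c(100L, 101L, 15L, 15L))
  ann <- annotate_peak_overlap(snps, bed)
  expect_equal(ann$in_peak, c(TRUE, FALSE, TRUE, FALSE))
  writeLines(c("chr1\t99"), bed)
  expect_error(read_bed(bed), "malformed BED line 1")
  writeLines(c("track name=x", "chr1\t5\t4"), bed)
  expect_error(read_bed(bed), "malformed BED line 2")
})

test_that("peak overlap agrees with a naive interval scan on random fixtures", {
  set.seed(13)
  for (rep in 1:5) {
    starts <- sort(sample.int(1000, 20))
    ends <- starts + sample.int(30, 20, replace = TRUE)
    bed <- tempfile(fileext = ".bed")
    writeLines(sprintf("chrZ\t%d\t%d", starts, ends), bed)
    snps <- data.frame(snp_id = paste0("s", 1:50), chrom = "chrZ",
                       pos = sample.int(1050, 50))
    ann <- annotate_peak_overlap(snps, bed)
    naive <- vapply(snps$pos, function(p)
      any(starts < p & p <= ends), logical(1))
    expect_identical(ann$in_peak, naive)
  }
})
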