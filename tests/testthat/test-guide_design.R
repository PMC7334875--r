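test_that("PAM scan finds the single planted forward candidate", {
  t <- snp_target("rs1", "chr1", 10, paste0(strrep("A", 19), "AGG"), 1, "CISD1")
  hits <- scan_protospacers(t)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$protospacer, strrep("A", 19))
  expect_equal(hits$pam, "AGG")
  expect_equal(hits$strand, "+")
  expect_equal(hits$pam_start, 20L)
  expect_equal(hits$cut_pos, 17L)
  expect_equal(hits$snp_distance, 7L)
})

test_that("flank with no GG on either strand yields no candidates", {
  t <- snp_target("rs1", "chr1", 10, strrep("AT", 20), 1)
  expect_equal(nrow(scan_protospacers(t)), 0L)
})

test_that("scan rejects short flanks and bad characters, skips N windows", {
  expect_error(scan_protospacers(snp_target("r", "c", 5, strrep("A", 21), 1)),
               "shorter")
  expect_error(snp_target("r", "c", 5, "ACGTXACGT", 1), "outside")
  withN <- paste0(strrep("A", 9), "N", strrep("A", 9), "AGG")
  hits <- scan_protospacers(snp_target("r", "c", 5, withN, 1))
  expect_equal(nrow(hits), 0L)
  expect_equal(attr(hits, "n_skipped"), 1L)
})

test_that("scan matches a naive sliding-window oracle on random flanks", {
  for (seed in 1:5) {
    fl <- random_dna(200, seed = seed)
    got <- scan_protospacers(snp_target("rs", "c", 600, fl, 501))
    want <- oracle_scan(fl, 501L)
    key <- function(d) sort(paste(d$protospacer, d$strand, d$pam_start,
                                  d$cut_pos))
    expect_identical(key(got), key(want))
  }
})

test_that("scanning the reverse complement swaps strands and mirrors cuts", {
  fl <- random_dna(180, seed = 42)
  L <- nchar(fl)
  fwd <- scan_protospacers(snp_target("rs", "c", 90, fl, 1))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fl)))
  rev <- scan_protospacers(snp_target("rs", "c", 90, rc, 1))
  expect_setequal(paste(fwd$protospacer, fwd$strand),
                  paste(rev$protospacer, ifelse(rev$strand == "+", "-", "+")))
  expect_setequal(fwd$cut_pos, as.integer(L + 1 - rev$cut_pos))
})

test_that("gc_fraction computes (#G + #C) / length", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("GGGCCCGGGC"), 1)
  expect_error(gc_fraction(""), "nonempty")
})

test_that("cut coordinate sits 3 bp 5' of the PAM and is translation-equivariant", {
  expect_equal(cut_position(21, "+"), 18L)
  expect_equal(cut_position(21, "+") - cut_position(20, "+"), 1L)
  expect_equal(cut_position(50, "-"), 53L)
  # round-trip identity through a coordinate shift
  shift <- 1000L
  expect_equal(cut_position(21 + shift, "+"), cut_position(21, "+") + shift)
})

test_that("genome match counting sees planted guides on both strands", {
  bg <- random_dna(10000, seed = 99)
  proto <- "ACGTTTACGGATCTGAACC"
  site <- paste0(proto, "TGG")
  planted <- paste0(substr(bg, 1, 500), site, substr(bg, 523, 10000))
  ref <- Biostrings::DNAStringSet(c(chrA = planted))
  expect_equal(count_genome_matches(proto, ref), 1L)
  expect_equal(count_genome_matches("TTTTACCGGTTTTACCGGT", ref), 0L)
  rc_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site)))
  planted_rc <- paste0(substr(bg, 1, 500), rc_site, substr(bg, 523, 10000))
  expect_equal(count_genome_matches(
    proto, Biostrings::DNAStringSet(c(chrA = planted_rc))), 1L)
  expect_error(count_genome_matches(proto, "/nonexistent.fa"), "not found")
})

test_that("guide selection filters on GC and uniqueness, then minimizes distance", {
  cand <- data.frame(
    guide_id = paste0("g", 1:4), snp_id = "rs1", locus = "L",
    protospacer = c("ACGTACGTACGTACGTACG", "GGGGGGGGCCCCCCCCGGG",
                    "TTTTACGTACGTACGTACG", "AAGTACGTACGTACGTACG"),
    pam = "AGG", strand = "+", pam_start = c(20, 30, 40, 50),
    cut_pos = c(17, 27, 37, 47), snp_distance = c(7, 1, 3, 3),
    gc = c(0.53, 0.85, 0.47, 0.47), genome_matches = c(1L, 1L, 1L, 1L),
    control_class = "candidate")
  # gc=0.85 guide excluded despite distance 1; tie at distance 3 broken
  # lexicographically
  best <- select_guide(cand)
  expect_equal(best$guide_id, "g4")
  expect_equal(best$protospacer, "AAGTACGTACGTACGTACG")
  # sole candidate with gc over the cap: none selectable
  expect_null(select_guide(cand[2, ]))
  # non-unique guide dropped under require_unique
  cand$genome_matches <- c(1L, 1L, 2L, 0L)
  expect_equal(select_guide(cand)$guide_id, "g1")
  expect_null(select_guide(cand[0, ]))
  expect_error(select_guide(transform(cand, genome_matches = NA_integer_)),
               "genome_matches")
})

test_that("selected guides always satisfy the GC and uniqueness constraints", {
  params <- design_params()
  for (seed in 1:20) {
    n <- 8
    cand <- cropmap:::with_seed(seed, data.frame(
      guide_id = paste0("g", 1:n), snp_id = "rs1", locus = "L",
      protospacer = vapply(1:n, function(i) random_dna(19), ""),
      pam = "AGG", strand = "+", pam_start = 1:n * 10,
      cut_pos = 1:n * 10 - 3, snp_distance = sample(0:25, n, TRUE),
      gc = round(runif(n), 2), genome_matches = sample(0:2, n, TRUE),
      control_class = "candidate"))
    best <- suppressWarnings(select_guide(cand, params))
    surv <- cand[cand$gc >= 0.4 & cand$gc <= 0.8 & cand$genome_matches == 1, ]
    if (is.null(best)) {
      expect_equal(nrow(surv), 0L)
    } else {
      expect_gte(best$gc, params$gc_min)
      expect_lte(best$gc, params$gc_max)
      expect_equal(best$genome_matches, 1L)
      expect_equal(best$snp_distance, min(surv$snp_distance))
    }
  }
})

test_that("design_guides runs scan/count/select end to end on a planted reference", {
  bg <- random_dna(3000, seed = 5)
  ref <- Biostrings::DNAStringSet(c(chr1 = bg))
  snps <- data.frame(snp_id = "rsA", chrom = "chr1", pos = 1500L, locus = "GENE1")
  guides <- design_guides(snps, ref)
  expect_lte(nrow(guides), 1L)
  if (nrow(guides) == 1L) {
    expect_equal(guides$genome_matches, 1L)
    expect_gte(guides$gc, 0.4)
    expect_lte(guides$gc, 0.8)
  }
  # table round-trip
  tmp <- tempfile(fileext = ".tsv")
  write_guide_table(guides, tmp, seed = 5)
  back <- read_guide_table(tmp)
  expect_equal(back$protospacer, guides$protospacer)
})

test_that("SNP table and VCF readers extract id/chrom/pos", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT",
               "chr1\t123\trsX\tA\tG", "chr2\t456\trsY\tC\tT"), vcf)
  df <- read_snp_vcf(vcf, locus = "GENE1")
  expect_equal(df$snp_id, c("rsX", "rsY"))
  expect_equal(df$pos, c(123L, 456L))
  writeLines(c("##fileformat=VCFv4.2", "chr1\t99"), vcf)
  expect_error(read_snp_vcf(vcf), "malformed")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchrom\tpos\tlocus", "rsZ\tchr3\t7\tG"), tsv)
  expect_equal(read_snp_table(tsv)$pos, 7L)
})
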