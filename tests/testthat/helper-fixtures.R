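# Shared fixtures, built in code at test time.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else cropmap:::with_seed(seed, draw())
}

# a tiny screen matrix with known guide columns
tiny_screen_matrix <- function() {
  counts <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 2, 3, 1, 2, 2),
    j = c(1, 2, 1, 3, 2, 4, 4, 5),
    x = c(5, 2, 1, 7, 3, 5, 1, 1),
    dims = c(4, 5),
    dimnames = list(paste0("c", 1:4), c("gA", "gB", "gC", "guide1", "guide2")))
  cell_screen_matrix(counts, feature_kind = c("gene", "gene", "gene",
                                              "guide", "guide"))
}

# small simulated screen shared by several tests (panel sized so default QC
# thresholds are meaningful is not needed here; QC tests build their own)
small_sim <- function(seed = 11, n_cells = 600, effect_sd = 0.5, ...) {
  design <- default_paper_design(1)
  params <- sim_params(n_cells = n_cells, n_background = 40,
                       effect_sd = effect_sd, seed = seed, ...)
  simulate_screen(design, params)
}

# naive O(L) protospacer scan oracle, independent of the implementation:
# slides a window over the flank and its reverse complement with plain
# substring tests, mapping minus-strand coordinates by hand
oracle_scan <- function(flank, flank_start, proto_len = 19L) {
  L <- nchar(flank)
  res <- list()
  for (i in seq_len(max(0L, L - proto_len - 2L))) {
    pam <- substr(flank, i + proto_len, i + proto_len + 2L)
    win <- substr(flank, i, i + proto_len + 2L)
    if (substr(pam, 2, 3) == "GG" && !grepl("N", win)) {
      pam_start <- flank_start + i + proto_len - 1L
      res[[length(res) + 1L]] <- data.frame(
        protospacer = substr(flank, i, i + proto_len - 1L),
        strand = "+", pam_start = pam_start, cut_pos = pam_start - 3L)
    }
  }
  comp <- chartr("ACGT", "TGCA", flank)
  for (i in seq_len(max(0L, L - proto_len - 2L))) {
    # minus-strand guide read 3'->5' along the plus strand: plus positions
    # [i, i+2] hold the PAM (as CCN), [i+3, i+proto_len+2] the protospacer
    pam_plus <- substr(flank, i, i + 2L)
    win <- substr(flank, i, i + proto_len + 2L)
    if (substr(pam_plus, 1, 2) == "CC" && !grepl("N", win)) {
      proto_plus <- substr(flank, i + 3L, i + proto_len + 2L)
      proto <- paste(rev(strsplit(chartr("ACGT", "TGCA", proto_plus),
                                  "")[[1]]), collapse = "")
      pam_start <- flank_start + i + 1L  # rightmost base of plus-strand CCN
      res[[length(res) + 1L]] <- data.frame(
        protospacer = proto, strand = "-", pam_start = pam_start,
        cut_pos = pam_start + 3L)
    }
  }
  if (!length(res)) return(data.frame(protospacer = character(),
                                      strand = character(),
                                      pam_start = integer(),
                                      cut_pos = integer()))
  do.call(rbind, res)
}
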