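# SNP-targeted sgRNA design: PAM scanning, GC/uniqueness filtering, cut-site
# distance selection.  Coordinates are 1-based inclusive throughout the
# user-facing interface (dbSNP convention).

#' Describe a candidate eSNP target
#'
#' Bundles a SNP with the genomic window used for protospacer scanning.
#'
#' @param snp_id Variant identifier (e.g. an rsID).
#' @param chrom Chromosome name.
#' @param pos 1-based genomic coordinate of the variant.
#' @param flank DNA string of the window around the SNP (A/C/G/T/N).
#' @param flank_start 1-based genomic coordinate of the first base of `flank`.
#' @param locus Target-gene symbol the SNP is a candidate eQTL for.
#' @return An object of class `snp_target`.
#' @examples
#' snp_target("rs1", "chr10", 50, strrep("ACGT", 25), 1, "CISD1")
#' @export
snp_target <- function(snp_id, chrom, pos, flank, flank_start, locus = NA_character_) {
  assert_dna(flank, "flank")
  pos <- as.integer(pos); flank_start <- as.integer(flank_start)
  if (pos < flank_start || pos > flank_start + nchar(flank) - 1L)
    stop("SNP position ", pos, " lies outside the flank window", call. = FALSE)
  structure(list(snp_id = as.character(snp_id), chrom = as.character(chrom),
                 pos = pos, flank = flank, flank_start = flank_start,
                 locus = as.character(locus)),
            class = "snp_target")
}

#' Guide design parameters
#'
#' @param protospacer_len Protospacer length in nt (>= 17; default 19).
#' @param gc_min,gc_max Inclusive GC-fraction bounds for a usable guide;
#'   candidates with GC above `gc_max` or below `gc_min` are discarded to
#'   retain cutting efficiency.
#' @param max_snp_distance Advisory cap on cut-site-to-SNP distance in bp;
#'   selection warns (but does not fail) when the best guide exceeds it.
#' @param require_unique If `TRUE`, a selectable guide must have exactly one
#'   perfect protospacer+NGG match in the reference genome.
#' @return A list of class `design_params`.
#' @export
design_params <- function(protospacer_len = 19L, gc_min = 0.40, gc_max = 0.80,
                          max_snp_distance = 10L, require_unique = TRUE) {
  protospacer_len <- as.integer(protospacer_len)
  if (protospacer_len < 17L) stop("protospacer_len must be >= 17", call. = FALSE)
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1))
    stop("need 0 <= gc_min < gc_max <= 1", call. = FALSE)
  structure(list(protospacer_len = protospacer_len, gc_min = gc_min,
                 gc_max = gc_max, max_snp_distance = as.integer(max_snp_distance),
                 require_unique = isTRUE(require_unique)),
            class = "design_params")
}

#' GC fraction of a DNA sequence
#'
#' @param seq Nonempty A/C/G/T string.
#' @return `(#G + #C) / nchar(seq)`.
#' @examples
#' gc_fraction("ATGC")  # 0.5
#' @export
gc_fraction <- function(seq) {
  assert_dna(seq, "seq", allow_n = FALSE)
  lengths(regmatches(seq, gregexpr("[GC]", seq))) / nchar(seq)
}

#' Cas9 blunt-cut coordinate for a guide
#'
#' SpCas9 cuts bluntly 3 bp 5' of the PAM.  The reported coordinate is the
#' protospacer base immediately 3' of the cut on the protospacer strand,
#' mapped to plus-strand genomic coordinates.
#'
#' @param pam_start Plus-strand genomic coordinate of the first PAM base as
#'   read on the guide's strand (for a minus-strand guide this is the
#'   rightmost base of the plus-strand "CCN" triplet).
#' @param strand `"+"` or `"-"`.
#' @return 1-based genomic coordinate of the cut-adjacent base.
#' @examples
#' cut_position(21, "+")  # 18
#' @export
cut_position <- function(pam_start, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  as.integer(pam_start) + ifelse(strand == "+", -3L, 3L)
}

#' Enumerate all protospacer candidates in a SNP's flank
#'
#' Scans both strands of the flank for protospacers of the configured length
#' immediately 5' of an NGG PAM.  Minus-strand hits are reported with the
#' reverse-complemented protospacer and strand `"-"`; all coordinates are
#' mapped back to the plus strand through `flank_start`.  No GC or distance
#' filtering is applied here.  Windows containing `N` in the protospacer or
#' PAM are skipped (their count is returned as an attribute `n_skipped`).
#'
#' @param target A [snp_target()].
#' @param params A [design_params()].
#' @return A data.frame of guide records with columns `guide_id`, `snp_id`,
#'   `locus`, `protospacer`, `pam`, `strand`, `pam_start`, `cut_pos`,
#'   `snp_distance`, `gc`, `genome_matches` (NA until counted) and
#'   `control_class` (`"candidate"`).
#' @export
scan_protospacers <- function(target, params = design_params()) {
  stopifnot(inherits(target, "snp_target"), inherits(params, "design_params"))
  P <- params$protospacer_len
  flank <- target$flank
  L <- nchar(flank)
  if (L < P + 3L)
    stop("flank (", L, " nt) shorter than protospacer_len + PAM (", P + 3L,
         " nt)", call. = FALSE)

  scan_one_strand <- function(seq) {
    # window start i (1-based in seq): protospacer [i, i+P-1], PAM [i+P, i+P+2]
    starts <- seq_len(L - P - 2L)
    win <- substring(seq, starts, starts + P + 2L)
    ok <- substring(win, P + 2L, P + 3L) == "GG"
    skipped <- ok & grepl("N", win, fixed = TRUE)
    list(starts = starts[ok & !skipped], n_skipped = sum(skipped),
         proto = substring(win[ok & !skipped], 1L, P),
         pam = substring(win[ok & !skipped], P + 1L, P + 3L))
  }

  fw <- scan_one_strand(flank)
  rv <- scan_one_strand(revcomp(flank))

  rows <- list()
  if (length(fw$starts)) {
    pam_start <- target$flank_start + fw$starts + P - 1L
    rows$fw <- data.frame(protospacer = fw$proto, pam = fw$pam, strand = "+",
                          pam_start = pam_start,
                          cut_pos = cut_position(pam_start, "+"))
  }
  if (length(rv$starts)) {
    # rc position j maps to plus-strand coordinate flank_start + (L - j)
    pam_start <- target$flank_start + (L - (rv$starts + P))
    rows$rv <- data.frame(protospacer = rv$proto, pam = rv$pam, strand = "-",
                          pam_start = pam_start,
                          cut_pos = cut_position(pam_start, "-"))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protospacer = character(), pam = character(), strand = character(),
               pam_start = integer(), cut_pos = integer())
  out$snp_distance <- abs(out$cut_pos - target$pos)
  out$gc <- if (nrow(out)) vapply(out$protospacer, gc_fraction, numeric(1),
                                  USE.NAMES = FALSE) else numeric()
  out <- data.frame(
    guide_id = if (nrow(out)) sprintf("%s_%s%d", target$snp_id, out$strand,
                                      out$pam_start) else character(),
    snp_id = rep(target$snp_id, nrow(out)),
    locus = rep(target$locus, nrow(out)),
    out,
    genome_matches = rep(NA_integer_, nrow(out)),
    control_class = rep("candidate", nrow(out)),
    row.names = NULL)
  attr(out, "n_skipped") <- fw$n_skipped + rv$n_skipped
  out
}

#' Count perfect genomic matches of protospacer+NGG
#'
#' Counts exact occurrences of the protospacer followed by an NGG PAM (N a
#' wildcard) on either strand of the reference.  A well-designed targeting
#' guide has exactly one match; a non-targeting negative control has zero.
#'
#' @param protospacer Character vector of protospacer sequences.
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return Integer vector of match counts, one per protospacer.
#' @export
count_genome_matches <- function(protospacer, reference) {
  if (is.character(reference)) {
    if (!file.exists(reference))
      stop("reference FASTA not found: ", reference, call. = FALSE)
    reference <- Biostrings::readDNAStringSet(reference)
  }
  stopifnot(is(reference, "DNAStringSet"))
  vapply(protospacer, function(p) {
    assert_dna(p, "protospacer", allow_n = FALSE)
    pat <- Biostrings::DNAString(paste0(p, "NGG"))
    fixed <- c(pattern = FALSE, subject = TRUE)
    sum(Biostrings::vcountPattern(pat, reference, fixed = fixed)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                    reference, fixed = fixed))
  }, integer(1), USE.NAMES = FALSE)
}

#' Select the guide used for one SNP
#'
#' Drops candidates with GC outside `[gc_min, gc_max]` and, when
#' `require_unique`, those without exactly one perfect genomic match; among
#' survivors returns the guide whose cut site is closest to the SNP, breaking
#' ties by lexicographically smallest protospacer.
#'
#' @param candidates Guide-record data.frame from [scan_protospacers()] (with
#'   `genome_matches` filled in when `require_unique`).
#' @param params A [design_params()].
#' @return A single-row guide-record data.frame, or `NULL` if no candidate
#'   survives.
#' @export
select_guide <- function(candidates, params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  if (length(unique(candidates$snp_id)) > 1L)
    stop("candidates must all target the same SNP", call. = FALSE)
  keep <- candidates$gc >= params$gc_min & candidates$gc <= params$gc_max
  if (params$require_unique) {
    if (anyNA(candidates$genome_matches))
      stop("genome_matches must be counted before selection when ",
           "require_unique is set", call. = FALSE)
    keep <- keep & candidates$genome_matches == 1L
  }
  surv <- candidates[keep, , drop = FALSE]
  if (nrow(surv) == 0L) return(NULL)
  surv <- surv[order(surv$snp_distance, surv$protospacer), , drop = FALSE]
  best <- surv[1L, , drop = FALSE]
  if (best$snp_distance > params$max_snp_distance)
    warning("selected guide for ", best$snp_id, " cuts ", best$snp_distance,
            " bp from the SNP (> max_snp_distance)", call. = FALSE)
  rownames(best) <- NULL
  best
}

#' Design one guide per SNP target
#'
#' Runs the scan/count/select pipeline over a table of SNP targets.  Flanks
#' are taken from the table's `flank` column when present, otherwise
#' extracted from `reference` as a window of `2 * flank_radius + 1` bp
#' centred on the SNP.
#'
#' @param snps Data.frame with columns `snp_id`, `chrom`, `pos`, `locus` and
#'   optionally `flank`, `flank_start` (e.g. from [read_snp_table()]).
#' @param reference DNAStringSet or FASTA path; needed for flank extraction
#'   and match counting.
#' @param params A [design_params()].
#' @param flank_radius Half-width of the extracted scan window, in bp.
#' @return Guide-record data.frame with one row per SNP that yielded a
#'   selectable guide; SNPs with no surviving candidate are reported via a
#'   message and omitted.
#' @export
design_guides <- function(snps, reference, params = design_params(),
                          flank_radius = 30L) {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  # match on first word of FASTA headers
  names(reference) <- sub("\\s.*$", "", names(reference))
  targets <- lapply(seq_len(nrow(snps)), function(i) {
    r <- snps[i, ]
    if (!is.null(r$flank) && !is.na(r$flank) && nzchar(r$flank)) {
      fs <- if (!is.null(r$flank_start) && !is.na(r$flank_start))
        r$flank_start else r$pos - (nchar(r$flank) %/% 2L)
      snp_target(r$snp_id, r$chrom, r$pos, r$flank, fs, r$locus)
    } else {
      if (!r$chrom %in% names(reference))
        stop("chromosome ", r$chrom, " not in reference", call. = FALSE)
      lo <- max(1L, r$pos - flank_radius)
      hi <- min(length(reference[[r$chrom]]), r$pos + flank_radius)
      snp_target(r$snp_id, r$chrom, r$pos,
                 as.character(Biostrings::subseq(reference[[r$chrom]], lo, hi)),
                 lo, r$locus)
    }
  })
  picked <- lapply(targets, function(t) {
    cand <- scan_protospacers(t, params)
    if (nrow(cand) && params$require_unique)
      cand$genome_matches <- count_genome_matches(cand$protospacer, reference)
    sel <- select_guide(cand, params)
    if (is.null(sel)) message("no selectable guide for ", t$snp_id)
    sel
  })
  out <- do.call(rbind, picked[!vapply(picked, is.null, logical(1))])
  if (is.null(out))
    out <- scan_protospacers(snp_target("x", "x", 1, strrep("A", 40), 1), params)[0, ]
  rownames(out) <- NULL
  out
}

#' Read a SNP target table
#'
#' TSV with columns `snp_id`, `chrom`, `pos`, `locus` and optional `flank`,
#' `flank_start`.
#' @param path File path.
#' @return Data.frame.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_header(path)
  need <- c("snp_id", "chrom", "pos", "locus")
  if (!all(need %in% names(df)))
    stop("SNP table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$pos <- as.integer(df$pos)
  df
}

#' Read SNP targets from a VCF (CHROM/POS/ID only)
#'
#' @param path VCF file path.
#' @param locus Optional locus label(s) recycled over records.
#' @return Data.frame with `snp_id`, `chrom`, `pos`, `locus`.
#' @export
read_snp_vcf <- function(path, locus = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(data.frame(snp_id = character(), chrom = character(),
                                        pos = integer(), locus = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 3L)
  if (length(bad))
    stop("malformed VCF record at data line ", bad[1L], call. = FALSE)
  data.frame(snp_id = vapply(f, `[[`, "", 3L),
             chrom = vapply(f, `[[`, "", 1L),
             pos = as.integer(vapply(f, `[[`, "", 2L)),
             locus = rep_len(locus, length(f)))
}

#' Write / read a guide library table
#'
#' @param guides Guide-record data.frame.
#' @param path TSV path.
#' @param seed Optional seed recorded in the header comment.
#' @return `path` (write) or the guide data.frame (read).
#' @export
write_guide_table <- function(guides, path, seed = NULL) {
  write_tsv_header(guides, path, seed = seed)
}

#' @rdname write_guide_table
#' @export
read_guide_table <- function(path) read_tsv_header(path)
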