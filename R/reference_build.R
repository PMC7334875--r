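# Extended-reference construction: one artificial chromosome per gRNA so the
# polyadenylated guide transcript is counted like a gene by standard scRNAseq
# quantifiers.  Geometry: 241 bp U6 promoter + 8 bp gap + 20 bp gRNA + 261 bp
# vector backbone = 530 bp per artificial chromosome.

# Synthetic stand-ins for the vector's U6 promoter, gap and backbone: the
# published construct's exact sequences are not redistributable here and only
# the segment lengths matter for guide detection.  Fixed arbitrary sequences
# of the correct lengths.
.SYNTHETIC_U6 <- paste0(
  "CAAGTGACTGGTTACCTCTATGTGCTATTCACTCCATATCTGCTCCAGCAAATAATTGTA",
  "AACCTGCCCTTACAATGCGGTACTTTTCTACAACCCTAATGCTGATAGAATGGTTCCTCG",
  "AAAATGAAAATCATTTGGATAGCATCCTTTTAGTTACGCTTACCTATTACAGAGGTTATT",
  "GTACGGAAAAATTTACATATCTGGGAATTGTGAAGAAACATCTCCTCGCTGTATTTTATC",
  "G")
.SYNTHETIC_GAP <- "AGAGGTAA"
.SYNTHETIC_BACKBONE <- paste0(
  "AGACATTTTGAATCATTTTTATGTGATAAGAACCCATTTCCTCGCGCGTAATCGATTAGC",
  "CCTTTATTTGTCTAAAAACCACAAGAAATCACTCATTTGTGCATTCATCATTTCACCGAT",
  "GGAACGCAGGACCCTGAGACAGGTTATTATAGAACACGGATATGAGAAAAAAATCCTTTG",
  "TGGGAACACAAAAATTACGCTCCTCGTCCCATTAGTCTAGCGAGAAGTTTTTCCCCCCGA",
  "GTTAACGATTGCAAGATAATT")

#' Artificial-chromosome construct layout
#'
#' @param u6_seq 241 bp U6 promoter sequence.
#' @param gap_seq 8 bp spacer between promoter and guide.
#' @param backbone_seq 261 bp vector backbone downstream of the guide.
#' @param guide_len Guide slot width in bp (20).
#' @return A list of class `construct_spec`.  Defaults are synthetic
#'   placeholder sequences of the correct lengths; substitute the real vector
#'   sequences for use against real data.
#' @export
construct_spec <- function(u6_seq = .SYNTHETIC_U6, gap_seq = .SYNTHETIC_GAP,
                           backbone_seq = .SYNTHETIC_BACKBONE, guide_len = 20L) {
  lens <- c(u6 = 241L, gap = 8L, backbone = 261L)
  got <- c(u6 = nchar(u6_seq), gap = nchar(gap_seq), backbone = nchar(backbone_seq))
  if (any(got != lens))
    stop("construct segment length mismatch: ",
         paste(sprintf("%s=%d (want %d)", names(got)[got != lens],
                       got[got != lens], lens[got != lens]), collapse = ", "),
         call. = FALSE)
  if (guide_len != 20L) stop("guide_len must be 20", call. = FALSE)
  for (s in c(u6_seq, gap_seq, backbone_seq)) assert_dna(s, "construct segment")
  structure(list(u6_seq = u6_seq, gap_seq = gap_seq,
                 backbone_seq = backbone_seq, guide_len = as.integer(guide_len)),
            class = "construct_spec")
}

#' Pad a protospacer to the construct's guide slot
#'
#' Cloned guides are 20 bp while designed protospacers may be 19 nt; a 5' G
#' (the U6 transcription-start preference) is prepended until the slot width
#' is reached.
#'
#' @param protospacer Protospacer sequence, at most `guide_len` nt.
#' @param guide_len Target length (default 20).
#' @return Padded sequence of exactly `guide_len` nt.
#' @examples
#' pad_guide(strrep("A", 19))  # "G" + 19 A's
#' @export
pad_guide <- function(protospacer, guide_len = 20L) {
  assert_dna(protospacer, "protospacer")
  n <- nchar(protospacer)
  if (n > guide_len)
    stop("protospacer (", n, " nt) longer than guide slot (", guide_len, ")",
         call. = FALSE)
  paste0(strrep("G", guide_len - n), protospacer)
}

#' Build one guide's artificial chromosome
#'
#' Concatenates U6 promoter, gap, padded guide, and backbone.  The padded
#' guide occupies 1-based positions 250..269 of the 530 bp chromosome.
#'
#' @param guide One-row guide-record data.frame (needs `guide_id`,
#'   `protospacer`).
#' @param spec A [construct_spec()].
#' @return Named character vector of length 1: the chromosome sequence, named
#'   by `guide_id`.
#' @export
build_artificial_chromosome <- function(guide, spec = construct_spec()) {
  stopifnot(inherits(spec, "construct_spec"))
  seq <- paste0(spec$u6_seq, spec$gap_seq,
                pad_guide(guide$protospacer, spec$guide_len),
                spec$backbone_seq)
  stats::setNames(seq, guide$guide_id)
}

#' Write the guide-detection extended reference
#'
#' Appends one artificial chromosome per guide to the genome FASTA and emits
#' a GTF annotating each as a single-exon gene spanning the full 530 bp on
#' the plus strand, so downstream counters attribute guide UMIs to a gene
#' feature.
#'
#' @param genome DNAStringSet or FASTA path of the base genome (may be empty).
#' @param guides Guide-record data.frame with unique `guide_id`s.
#' @param spec A [construct_spec()].
#' @param out_fasta,out_gtf Output paths.
#' @return Invisibly, `c(fasta = out_fasta, gtf = out_gtf)`.
#' @export
write_extended_reference <- function(genome, guides, spec = construct_spec(),
                                     out_fasta, out_gtf) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"))
  if (anyDuplicated(guides$guide_id))
    stop("duplicate guide_id in guide table", call. = FALSE)
  chroms <- vapply(seq_len(nrow(guides)), function(i)
    build_artificial_chromosome(guides[i, ], spec), character(1))
  ext <- c(genome, Biostrings::DNAStringSet(stats::setNames(chroms,
                                                            guides$guide_id)))
  Biostrings::writeXStringSet(ext, out_fasta, width = 60L)

  total_len <- 241L + 8L + spec$guide_len + 261L
  gtf_lines <- unlist(lapply(guides$guide_id, function(id) {
    attr_gene <- sprintf('gene_id "%s"; gene_name "%s";', id, id)
    attr_tx <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                       id, id, id)
    sprintf("%s\tcropmap\t%s\t1\t%d\t.\t+\t.\t%s",
            id, c("gene", "transcript", "exon"), total_len,
            c(attr_gene, attr_tx, attr_tx))
  }))
  writeLines(as.character(gtf_lines %||% character()), out_gtf)
  invisible(c(fasta = out_fasta, gtf = out_gtf))
}
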