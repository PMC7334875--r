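# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package simulations never leak into (or depend on)
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

assert_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a nonempty character string", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, seq))
    stop(what, " contains characters outside ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T", call. = FALSE)
  invisible(seq)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Write a TSV with a commented provenance header
#' @noRd
write_tsv_header <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cropmap %s%s",
                     as.character(utils::packageVersion("cropmap")),
                     if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed))),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
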