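# Orchestration of the screen workflow: simulate -> assign -> qc -> test ->
# report, as one deterministic, re-runnable pipeline over a single config.

#' Pipeline run configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed; replicate `i` simulates with `seed + i - 1`.
#' @param replicates Character vector of replicate labels.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "assign", "qc", "test", "report")` in that order.
#' @param design A `screen_design` (default [default_paper_design()] under
#'   `seed`).
#' @param sim A [sim_params()] template (its seed is overridden per
#'   replicate).
#' @param qc A [qc_params()].
#' @param mtc A [mtc_params()].
#' @param matrix_dir Optional named list/vector of pre-existing 10x-style
#'   matrix directories per replicate (required when `"assign"` or later
#'   stages run without `"simulate"`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       replicates = c("rep1", "rep2"),
                       stages = c("simulate", "assign", "qc", "test", "report"),
                       design = NULL, sim = sim_params(), qc = qc_params(),
                       mtc = mtc_params(), matrix_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"simulate" %in% stages && any(c("assign", "qc", "test") %in% stages)) {
    if (is.null(matrix_dir))
      stop("config field 'matrix_dir' is required when running '",
           intersect(c("assign", "qc", "test"), stages)[1],
           "' without 'simulate'", call. = FALSE)
    miss <- !vapply(file.path(unlist(matrix_dir), "matrix.mtx"), file.exists,
                    logical(1))
    if (any(miss))
      stop("matrix_dir entries without matrix.mtx: ",
           paste(unlist(matrix_dir)[miss], collapse = ", "), call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 replicates = replicates, stages = stages,
                 design = design %||% default_paper_design(seed),
                 sim = sim, qc = qc, mtc = mtc, matrix_dir = matrix_dir),
            class = "run_config")
}

#' Run the screen pipeline
#'
#' Executes the configured stages per replicate, writing per-stage artifacts
#' (10x-style matrix directory, assignment TSV, QC report JSON, association
#' results TSV), a cross-replicate concordance table, and a line-oriented
#' run log.  Identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with per-replicate `results`, the
#'   `concordance` hit list (when >= 2 replicates are tested), artifact
#'   `paths`, and the `log` lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log <<- c(log, line)
    message(line)
  }
  st <- config$stages
  results <- list(); paths <- list()

  for (i in seq_along(config$replicates)) {
    r <- config$replicates[i]
    rdir <- file.path(config$out_dir, r)
    dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
    rseed <- config$seed + i - 1L

    if ("simulate" %in% st) {
      p <- config$sim; p$seed <- rseed
      sim <- simulate_screen(config$design, p)
      mdir <- file.path(rdir, "matrix")
      write_10x_like(sim, mdir)
      say("%s simulate: seed=%d cells=%d", r, rseed, nrow(sim$counts$counts))
    } else {
      mdir <- config$matrix_dir[[r]] %||% config$matrix_dir[[i]]
    }
    paths[[r]] <- list(matrix = mdir)
    if (!any(c("assign", "qc", "test") %in% st)) next

    m <- read_10x_like(mdir)
    a <- assign_guides(m)
    if ("assign" %in% st) {
      paths[[r]]$assignment <- write_assignment(
        a, file.path(rdir, "assignment.tsv"), seed = rseed)
      say("%s assign: %d/%d single-guide cells kept", r,
          length(a$kept_cells), length(a$n_guides_per_cell))
    }
    if (!any(c("qc", "test") %in% st)) next

    qcres <- qc_filter(m, config$qc)
    jsonlite::write_json(qcres$report,
                         file.path(rdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    paths[[r]]$qc_report <- file.path(rdir, "qc_report.json")
    say("%s qc: %d cells, %d genes kept", r, qcres$report$cells_kept,
        qcres$report$genes_kept)
    if (!"test" %in% st) next

    norm <- normalize_log2(qcres$matrix, config$qc$scale_factor)
    res <- run_screen(norm, a, config$design, config$mtc)
    paths[[r]]$results <- write_tsv_header(
      res, file.path(rdir, "results.tsv"), seed = rseed)
    results[[r]] <- res
    say("%s test: %d tests, %d significant at %.4g", r, nrow(res),
        sum(res$significant), bonferroni_threshold(config$mtc))
  }

  concordance <- NULL
  if ("report" %in% st && length(results) >= 2L) {
    concordance <- replicate_concordance(results[[1L]], results[[2L]])
    paths$hits <- write_tsv_header(concordance$hits,
                                   file.path(config$out_dir, "hits.tsv"),
                                   seed = config$seed)
    say("report: %d concordant hits, %d single-replicate nominal",
        nrow(concordance$hits), nrow(concordance$single_replicate))
  }
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(list(results = results, concordance = concordance,
                 paths = paths, log = log))
}
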