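#' Write replicate run results to a directory of CSV files
#'
#' Each replicate r emits `rep<r>_summary.csv` (per-generation population
#' summaries: `generation,mean_fitness,sd_fitness,mean_trait_*,mean_corr_*,
#' pc*`) and `rep<r>_final.csv` (final snapshot:
#' `individual,trait_*,corr_*,fitness`), plus a shared `runs_manifest.json`
#' recording seeds, mode and configuration hash.
#'
#' @param runs a `trace_runs` object.
#' @param dir output directory (created if missing).
#' @export
write_run_results <- function(runs, dir) {
  stopifnot(inherits(runs, "trace_runs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    utils::write.csv(run$summary,
                     file.path(dir, sprintf("rep%03d_summary.csv", r)),
                     row.names = FALSE)
    fin <- data.frame(individual = seq_len(nrow(run$final$traits)),
                      run$final$traits, run$final$corr,
                      fitness = run$final$fitness, check.names = FALSE)
    names(fin) <- c("individual", colnames(run$final$traits),
                    paste0("corr_", seq_len(ncol(run$final$corr))), "fitness")
    utils::write.csv(fin, file.path(dir, sprintf("rep%03d_final.csv", r)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(replicates = length(runs),
         seeds = vapply(runs, `[[`, numeric(1), "seed"),
         mode = runs[[1]]$mode,
         config_hash = runs[[1]]$config_hash),
    file.path(dir, "runs_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_run_results
#' @return `read_run_results()`: a `trace_runs` object (final snapshots and
#'   summaries; enough for [census()] and downstream analysis).
#' @export
read_run_results <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "runs_manifest.json"),
                             simplifyVector = TRUE)
  runs <- lapply(seq_len(man$replicates), function(r) {
    summ <- utils::read.csv(file.path(dir, sprintf("rep%03d_summary.csv", r)))
    fin <- utils::read.csv(file.path(dir, sprintf("rep%03d_final.csv", r)))
    tc <- grep("^trait_", names(fin), value = TRUE)
    cc <- grep("^corr_", names(fin), value = TRUE)
    structure(list(summary = summ,
                   final = list(traits = as.matrix(fin[tc]),
                                corr = as.matrix(fin[cc]),
                                fitness = fin$fitness),
                   seed = man$seeds[r], mode = man$mode,
                   config_hash = man$config_hash),
              class = "trace_run")
  })
  structure(runs, class = "trace_runs")
}
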