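#' Alternative starting phenotypes on the trait-scape
#'
#' `"equidistant_single"` rotates the fitted start about the evolutionary
#' endpoint (default 90 degrees) in the retained 2-D plane, yielding a start
#' whose distance to the endpoint matches the original's to within 1e-6. Its
#' trait vector is the minimum-norm preimage of the rotated coordinate.
#' `"four_subpopulations"` returns four equally weighted starts: the
#' preimages of rotations by 0, 90, 180 and 270 degrees.
#'
#' @param scape a fitted `trait_scape` with `n_axes == 2`.
#' @param kind which variant to build.
#' @param angle rotation angle in degrees for the single-start variant.
#' @return a start specification usable as `sim_config(start_spec = ...)`.
#' @export
start_variants <- function(scape,
                           kind = c("equidistant_single",
                                    "four_subpopulations"),
                           angle = 90) {
  kind <- match.arg(kind)
  if (scape$n_axes != 2L) stop("start variants are defined for 2-D scapes")
  v <- scape$start - scape$end
  if (sqrt(sum(v^2)) < 1e-12) stop("degenerate trait-scape: start == end")
  W <- scape$loadings[, 1:2, drop = FALSE]
  rotate <- function(deg) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    drop(W %*% (scape$end + R %*% v))
  }
  if (kind == "equidistant_single") {
    list(list(weight = 1, traits = rotate(angle)))
  } else {
    lapply(c(0, 90, 180, 270), function(a)
      list(weight = 0.25, traits = rotate(a)))
  }
}

#' Define a grid of simulation study arms
#'
#' One row per arm: an initialization mode, an optional start specification
#' and optional [sim_config()] overrides. Mode names must be unique.
#'
#' @param modes character vector of modes (default: the 9-arm study grid --
#'   mixed plus A1-A4 and E1-E4).
#' @param start_spec optional shared start specification.
#' @param overrides named list of shared `sim_config` overrides.
#' @return a `study_grid`.
#' @export
study_grid <- function(modes = c("mixed", paste0("A", 1:4), paste0("E", 1:4)),
                       start_spec = NULL, overrides = list()) {
  if (anyDuplicated(modes)) stop("mode names must be unique within a grid")
  structure(lapply(modes, function(m)
    list(mode = m, start_spec = start_spec, overrides = overrides)),
    class = "study_grid")
}

#' Run a study grid: simulate, census, and pool type signatures
#'
#' Executes [run_adaptive_walk()] for every grid arm, runs the phenotype
#' [census()] per arm, and pools the per-type mean correlation vectors
#' (labelled `<mode>:<type>`) for downstream multiscale-bootstrap clustering.
#' Optional extra labelled signatures (e.g. empirical ancestral/evolved
#' correlation vectors) are appended to the pooled table. Arm failures are
#' recorded and the grid continues. The manifest records every seed and a
#' content hash of every arm configuration, so a study can be re-executed
#' exactly.
#'
#' @param grid a [study_grid()].
#' @param scape a `trait_scape`.
#' @param corr_table a `correlation_table` (required for A/E arms).
#' @param config baseline [sim_config()] shared by all arms.
#' @param extra_signatures optional named list / matrix of additional
#'   P-vectors to pool.
#' @param out_dir optional directory; when given, per-arm census CSVs, the
#'   pooled signature CSV and the manifest JSON are written there.
#' @return a `trace_study`: list with `censuses`, `runs`, `signatures`
#'   (pooled matrix), `manifest`, `errors`.
#' @export
run_grid <- function(grid, scape, corr_table = NULL, config = sim_config(),
                     extra_signatures = NULL, out_dir = NULL) {
  stopifnot(inherits(grid, "study_grid"))
  censuses <- list()
  all_runs <- list()
  errors <- list()
  sig_rows <- list()
  arms <- list()
  for (row in grid) {
    cfg_args <- unclass(config)
    cfg_args$mode <- row$mode
    if (!is.null(row$start_spec)) cfg_args$start_spec <- row$start_spec
    cfg_args <- utils::modifyList(cfg_args, row$overrides)
    cfg <- do.call(sim_config, cfg_args)
    arms[[row$mode]] <- list(mode = row$mode,
                             seeds = cfg$base_seed + seq_len(cfg$replicates),
                             config_hash = config_hash(unclass(cfg)))
    res <- tryCatch({
      runs <- run_adaptive_walk(cfg, scape, corr_table)
      list(runs = runs, census = census(runs))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[row$mode]] <- conditionMessage(res)
      next
    }
    censuses[[row$mode]] <- res$census
    all_runs[[row$mode]] <- res$runs
    cs <- census_signatures(res$census)
    rownames(cs) <- paste0(row$mode, ":", rownames(cs))
    sig_rows[[row$mode]] <- cs
  }
  signatures <- do.call(rbind, sig_rows)
  if (!is.null(extra_signatures)) {
    ex <- if (is.list(extra_signatures)) {
      do.call(rbind, extra_signatures)
    } else {
      as.matrix(extra_signatures)
    }
    colnames(ex) <- colnames(signatures)
    signatures <- rbind(signatures, ex)
  }
  manifest <- list(base_seed = config$base_seed, arms = arms,
                   baseline_config = unclass(config))
  study <- structure(list(censuses = censuses, runs = all_runs,
                          signatures = signatures, manifest = manifest,
                          errors = errors),
                     class = "trace_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mode in names(study$censuses)) {
    cen <- study$censuses[[mode]]
    utils::write.csv(cen$types,
                     file.path(out_dir, paste0("census_", mode, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(replicate = names(cen$membership),
                                type = unname(cen$membership)),
                     file.path(out_dir, paste0("membership_", mode, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(label = rownames(study$signatures),
                              study$signatures, check.names = FALSE),
                   file.path(out_dir, "pooled_signatures.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
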