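# Shared builders and a lazy cache for the acceptance-scale simulation arms.

# tiny deterministic trait table: `ev` / `an` are matrices of evolved /
# ancestral trait rows for a single genotype "G1"
tiny_table <- function(ev, an, genotype = "G1") {
  K <- ncol(ev)
  mk <- function(m, cond) {
    df <- data.frame(genotype = genotype,
                     replicate = paste0("r", seq_len(nrow(m))),
                     condition = cond)
    df[paste0("trait_", seq_len(K))] <- as.data.frame(m)
    df
  }
  as_trait_table(rbind(mk(ev, "evolved"), mk(an, "ancestral")))
}

# wrap a correlation matrix (final population) as a minimal trace_run
fake_run <- function(corr, fitness_series = c(0, 1), traits = NULL) {
  n <- nrow(corr)
  if (is.null(traits)) traits <- matrix(0, n, 2)
  structure(list(summary = data.frame(
                   generation = seq_along(fitness_series) - 1,
                   mean_fitness = fitness_series),
                 final = list(traits = traits, corr = corr,
                              fitness = rep(1, n)),
                 seed = 0L, mode = "mixed", config_hash = "x"),
            class = "trace_run")
}

# hclust-based independent oracle for UPGMA member sets
hclust_members <- function(hc, labels) {
  n <- length(labels)
  mm <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    mm[[s]] <- sort(unlist(lapply(hc$merge[s, ], function(id)
      if (id < 0) labels[-id] else mm[[id]])))
  }
  mm
}

# ---- acceptance-scale arms (computed once per test session) ----------------
# Standard scaled-down design: reference fixture, N = 250, 500 generations,
# 30 replicates, base seed 101.
ts_cache <- new.env(parent = emptyenv())

ref_fixture <- function() {
  if (is.null(ts_cache$fx)) {
    ts_cache$fx <- make_reference_fixture()
    ts_cache$scape <- fit_trait_scape(ts_cache$fx$table,
                                      focal_genotype = ts_cache$fx$focal_genotype)
  }
  list(fx = ts_cache$fx, scape = ts_cache$scape)
}

ref_runs <- function(arm) {
  key <- paste0("runs_", arm)
  if (is.null(ts_cache[[key]])) {
    rf <- ref_fixture()
    start <- if (arm == "equidistant") start_variants(rf$scape) else NULL
    mode <- switch(arm, uncorrelated = "uncorrelated", A4 = "A4", E4 = "E4",
                   "mixed")
    cfg <- sim_config(N = 250L, generations = 500L, replicates = 30L,
                      mode = mode, start_spec = start, base_seed = 101L)
    ts_cache[[key]] <- run_adaptive_walk(cfg, rf$scape, rf$fx$corr_table)
  }
  ts_cache[[key]]
}
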