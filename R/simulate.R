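#' Configuration for an adaptive-walk simulation
#'
#' Defaults follow the standard design: 1000 individuals, 2000 generations,
#' 100 replicates, the 90/10 update scheme (90% of individuals per generation
#' receive a correlation-propagated trait perturbation, 10% a joint trait +
#' correlation perturbation) and Gaussian perturbations with sd 0.05.
#'
#' @param N population size.
#' @param generations number of generations per replicate.
#' @param replicates number of replicate runs.
#' @param p_corr fraction of individuals per generation receiving the joint
#'   trait + correlation change (exact count `round(p_corr * N)`, sampled
#'   without replacement).
#' @param step_sd standard deviation of all Gaussian perturbations (trait and
#'   correlation), in standardized trait units.
#' @param propagation how a focal-trait change propagates through an
#'   individual's correlations: `"replace"` (trait_j <- r_kj * trait_k, the
#'   conditional-expectation update for standardized traits; default) or
#'   `"delta"` (trait_j <- trait_j + r_kj * delta).
#' @param mode initialization mode for standing correlations: `"mixed"` (iid
#'   Uniform(-1, 1)), `"A1"`..`"A4"` / `"E1"`..`"E4"` (the m most significant
#'   empirical ancestral/evolved correlations fixed across individuals, rest
#'   random), or `"uncorrelated"` (all correlations zero and propagation
#'   disabled -- the no-bias control).
#' @param start_spec optional list of `list(weight =, traits =)` starting
#'   phenotypes (standardized K-vectors); weights must sum to 1. Default: a
#'   single start at the trait-scape's `start_traits`.
#' @param base_seed integer; replicate r runs under seed `base_seed + r`.
#' @return a `sim_config` object.
#' @export
sim_config <- function(N = 1000L, generations = 2000L, replicates = 100L,
                       p_corr = 0.10, step_sd = 0.05,
                       propagation = c("replace", "delta"), mode = "mixed",
                       start_spec = NULL, base_seed = 1L) {
  propagation <- match.arg(propagation)
  modes <- c("mixed", "uncorrelated", paste0("A", 1:4), paste0("E", 1:4))
  if (!(is.character(mode) && length(mode) == 1L && mode %in% modes)) {
    stop("mode must be one of: ", paste(modes, collapse = ", "))
  }
  stopifnot(N >= 2, generations >= 0, replicates >= 1,
            p_corr >= 0, p_corr <= 1, step_sd >= 0)
  if (!is.null(start_spec)) {
    stopifnot(is.list(start_spec), length(start_spec) >= 1L)
    w <- vapply(start_spec, function(s) s$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-8) stop("start_spec weights must sum to 1")
  }
  structure(list(N = as.integer(N), generations = as.integer(generations),
                 replicates = as.integer(replicates), p_corr = p_corr,
                 step_sd = step_sd, propagation = propagation, mode = mode,
                 start_spec = start_spec, base_seed = as.integer(base_seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a flat JSON file
#'
#' Keys are the arguments of [sim_config()]; unknown keys are rejected.
#'
#' @param path JSON file path.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(sim_config)), "start_spec")
  unknown <- setdiff(names(x), c(known, "start_spec"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(x$start_spec)) {
    x$start_spec <- lapply(seq_len(nrow(x$start_spec)), function(i) {
      list(weight = x$start_spec$weight[i],
           traits = as.numeric(x$start_spec$traits[[i]]))
    })
  }
  do.call(sim_config, x)
}

# largest-remainder apportionment of N individuals over weights
apportion <- function(weights, N) {
  raw <- weights * N
  n <- floor(raw)
  left <- N - sum(n)
  if (left > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(left)]
    n[extra] <- n[extra] + 1
  }
  as.integer(n)
}

#' Initialize a population of individuals
#'
#' Every individual carries a standardized K-trait vector and a
#' K(K-1)/2-vector of heritable pairwise trait correlations in canonical pair
#' order. Trait values come from the configured start specification;
#' correlations are drawn according to the bias mode (see [sim_config()]).
#'
#' @param config a `sim_config`.
#' @param scape a `trait_scape` (supplies the default start and K).
#' @param corr_table a `correlation_table`; required for A/E modes.
#' @return a `trace_population`: list with matrices `traits` (N x K) and
#'   `corr` (N x P).
#' @export
init_population <- function(config, scape, corr_table = NULL) {
  K <- nrow(scape$loadings)
  P <- K * (K - 1L) / 2L
  N <- config$N
  starts <- config$start_spec
  if (is.null(starts)) starts <- list(list(weight = 1, traits = scape$start_traits))
  counts <- apportion(vapply(starts, function(s) s$weight, numeric(1)), N)
  traits <- matrix(0, N, K)
  at <- 1L
  for (i in seq_along(starts)) {
    tv <- as.numeric(starts[[i]]$traits)
    if (length(tv) != K) stop("start_spec trait vector must have length ", K)
    if (counts[i] > 0L) {
      traits[at:(at + counts[i] - 1L), ] <- matrix(tv, counts[i], K,
                                                   byrow = TRUE)
      at <- at + counts[i]
    }
  }

  mode <- config$mode
  if (mode == "uncorrelated") {
    corr <- matrix(0, N, P)
  } else {
    corr <- matrix(stats::runif(N * P, -1, 1), N, P)
    if (grepl("^[AE][1-4]$", mode)) {
      if (is.null(corr_table)) stop("mode ", mode, " requires a corr_table")
      m <- as.integer(substr(mode, 2L, 2L))
      cond <- if (substr(mode, 1L, 1L) == "A") "ancestral" else "evolved"
      rp <- ranked_pairs(corr_table, cond)
      if (nrow(rp) < m) {
        stop("mode ", mode, " needs ", m, " ranked significant ", cond,
             " pairs; found ", nrow(rp))
      }
      for (i in seq_len(m)) corr[, rp$pair_index[i]] <- rp$r[i]
    }
  }
  colnames(traits) <- paste0("trait_", seq_len(K))
  colnames(corr) <- pair_labels(K)
  structure(list(traits = traits, corr = corr), class = "trace_population")
}

#' Single-individual mutation kernels
#'
#' Deterministic forms of the two per-generation update rules, with every
#' random choice supplied by the caller. `apply_trait_change()` adds `delta`
#' to trait `k` and then propagates through the individual's stored
#' correlations: under `"replace"` every other trait j becomes
#' `corr(k, j) * trait_k`; under `"delta"` it gains `corr(k, j) * delta`.
#' With `correlated = FALSE` (the uncorrelated control) only the focal trait
#' moves. `apply_corr_change()` perturbs one stored correlation (clipped to
#' \[-1, 1\]), perturbs one endpoint trait of that pair, and rewrites the
#' other endpoint from the new correlation and the new first-trait value;
#' all remaining traits and correlations are untouched.
#'
#' @param traits K-vector of standardized trait values.
#' @param corr P-vector of pairwise correlations (canonical order).
#' @param k focal trait index.
#' @param delta Gaussian trait perturbation.
#' @param propagation `"replace"` or `"delta"`.
#' @param correlated propagate through correlations? (FALSE in the
#'   uncorrelated control.)
#' @return `apply_trait_change()`: the updated trait vector.
#'   `apply_corr_change()`: list(traits, corr).
#' @export
apply_trait_change <- function(traits, corr, k, delta,
                               propagation = c("replace", "delta"),
                               correlated = TRUE) {
  propagation <- match.arg(propagation)
  K <- length(traits)
  lut <- pair_lookup(K)
  traits[k] <- traits[k] + delta
  if (correlated) {
    for (j in seq_len(K)[-k]) {
      r <- corr[lut[k, j]]
      traits[j] <- if (propagation == "replace") r * traits[k]
                   else traits[j] + r * delta
    }
  }
  traits
}

#' @rdname apply_trait_change
#' @param pair flat index of the correlation pair to perturb.
#' @param corr_delta Gaussian perturbation of the stored correlation.
#' @param first which endpoint of the pair (1 or 2, in canonical a < b order)
#'   receives the trait perturbation.
#' @param trait_delta Gaussian perturbation of the first trait.
#' @export
apply_corr_change <- function(traits, corr, pair, corr_delta, first,
                              trait_delta,
                              propagation = c("replace", "delta")) {
  propagation <- match.arg(propagation)
  K <- length(traits)
  pr <- trait_pairs(K)
  corr[pair] <- clip_unit(corr[pair] + corr_delta)
  a <- pr[pair, first]
  b <- pr[pair, 3L - first]
  traits[a] <- traits[a] + trait_delta
  traits[b] <- if (propagation == "replace") corr[pair] * traits[a]
               else traits[b] + corr[pair] * trait_delta
  list(traits = traits, corr = corr)
}

# Vectorized trait-change over the rows `idx`.
# Draw order: focal trait indices, then deltas.
mutate_trait_group <- function(traits, corr, idx, step_sd, propagation,
                               correlated, lut) {
  n <- length(idx)
  if (n == 0L) return(traits)
  K <- ncol(traits)
  k <- sample.int(K, n, replace = TRUE)
  delta <- stats::rnorm(n, 0, step_sd)
  newv <- traits[cbind(idx, k)] + delta
  traits[cbind(idx, k)] <- newv
  if (correlated) {
    for (j in seq_len(K)) {
      sel <- k != j
      if (!any(sel)) next
      rows <- idx[sel]
      r <- corr[cbind(rows, lut[cbind(k[sel], j)])]
      traits[cbind(rows, j)] <- if (propagation == "replace") r * newv[sel]
                                else traits[cbind(rows, j)] + r * delta[sel]
    }
  }
  traits
}

# Vectorized joint trait+correlation change over the rows `idx`.
# Draw order: pair indices, correlation deltas, endpoint choices, trait deltas.
mutate_corr_group <- function(traits, corr, idx, step_sd, propagation, pairs) {
  n <- length(idx)
  if (n == 0L) return(list(traits = traits, corr = corr))
  P <- ncol(corr)
  pr <- sample.int(P, n, replace = TRUE)
  cd <- stats::rnorm(n, 0, step_sd)
  newc <- clip_unit(corr[cbind(idx, pr)] + cd)
  corr[cbind(idx, pr)] <- newc
  first <- sample.int(2L, n, replace = TRUE)
  a <- pairs[cbind(pr, first)]
  b <- pairs[cbind(pr, 3L - first)]
  td <- stats::rnorm(n, 0, step_sd)
  newa <- traits[cbind(idx, a)] + td
  traits[cbind(idx, a)] <- newa
  traits[cbind(idx, b)] <- if (propagation == "replace") newc * newa
                           else traits[cbind(idx, b)] + newc * td
  list(traits = traits, corr = corr)
}

# exact-count partition of the population into the corr-change subset
split_mutation_groups <- function(N, p_corr) {
  m <- as.integer(round(p_corr * N))
  if (m == 0L) integer(0) else sample.int(N, m)
}

#' Selection weight of individuals on the trait-scape
#'
#' An individual's fitness is `exp(-z^2 / 2)` where z is the Euclidean
#' distance, in retained-axis space, between its projected trait vector and
#' the evolutionary endpoint. Fitness is 1 exactly at the endpoint and
#' strictly decreasing in z.
#'
#' @param traits standardized K-trait vector or an N x K matrix.
#' @param scape a `trait_scape`.
#' @return fitness value(s) in (0, 1].
#' @export
compute_fitness <- function(traits, scape) {
  pc <- project_traits(scape, traits)
  if (is.matrix(pc)) {
    z2 <- rowSums(sweep(pc, 2L, scape$end)^2)
  } else {
    z2 <- sum((pc - scape$end)^2)
  }
  exp(-z2 / 2)
}

#' Fitness-weighted resampling of a population
#'
#' Draws N offspring with replacement, with probability proportional to the
#' supplied weights; offspring are exact copies of their parents (traits and
#' correlations are both heritable).
#'
#' @param population a `trace_population`.
#' @param weights non-negative fitness weights, at least one positive.
#' @return list(population, parents) where `parents` are the sampled row
#'   indices.
#' @export
select_population <- function(population, weights) {
  N <- nrow(population$traits)
  stopifnot(length(weights) == N)
  if (any(weights < 0) || all(weights == 0) || anyNA(weights)) {
    stop("selection weights must be non-negative with at least one > 0")
  }
  parents <- sample.int(N, N, replace = TRUE, prob = weights)
  structure(list(traits = population$traits[parents, , drop = FALSE],
                 corr = population$corr[parents, , drop = FALSE]),
            class = "trace_population")
}

#' Advance a population by one generation
#'
#' Exactly `round(p_corr * N)` individuals (sampled without replacement)
#' receive the joint trait + correlation change; the rest receive the
#' correlation-propagated trait change. Fitness is then evaluated on the
#' trait-scape and the population resampled by fitness weight. In
#' `"uncorrelated"` mode no correlations are touched and trait changes do not
#' propagate.
#'
#' @param population a `trace_population`.
#' @param config a `sim_config`.
#' @param scape a `trait_scape`.
#' @return list(population, fitness) -- the post-selection population and the
#'   fitness values of its (copied) individuals.
#' @export
step_generation <- function(population, config, scape) {
  traits <- population$traits
  corr <- population$corr
  N <- nrow(traits)
  K <- ncol(traits)
  uncorrelated <- config$mode == "uncorrelated"
  lut <- pair_lookup(K)
  pairs <- trait_pairs(K)

  idx_c <- if (uncorrelated) integer(0) else
    split_mutation_groups(N, config$p_corr)
  upd <- mutate_corr_group(traits, corr, idx_c, config$step_sd,
                           config$propagation, pairs)
  traits <- upd$traits
  corr <- upd$corr
  idx_t <- setdiff(seq_len(N), idx_c)
  traits <- mutate_trait_group(traits, corr, idx_t, config$step_sd,
                               config$propagation, !uncorrelated, lut)

  pop <- structure(list(traits = traits, corr = corr),
                   class = "trace_population")
  w <- compute_fitness(traits, scape)
  parents <- sample.int(N, N, replace = TRUE, prob = w)
  list(population = structure(list(traits = traits[parents, , drop = FALSE],
                                   corr = corr[parents, , drop = FALSE]),
                              class = "trace_population"),
       fitness = w[parents])
}

run_one_replicate <- function(config, scape, corr_table, seed) {
  with_seed(seed, {
    pop <- init_population(config, scape, corr_table)
    K <- ncol(pop$traits)
    P <- ncol(pop$corr)
    G <- config$generations
    nsum <- 3L + K + P + scape$n_axes
    S <- matrix(NA_real_, G + 1L, nsum)
    fit <- compute_fitness(pop$traits, scape)
    record <- function(g, pop, fit) {
      mt <- colMeans(pop$traits)
      c(g, mean(fit), stats::sd(fit), mt, colMeans(pop$corr),
        project_traits(scape, mt))
    }
    S[1L, ] <- record(0L, pop, fit)
    g <- 0L
    while (g < G) {
      st <- step_generation(pop, config, scape)
      pop <- st$population
      fit <- st$fitness
      g <- g + 1L
      S[g + 1L, ] <- record(g, pop, fit)
    }
    S <- as.data.frame(S)
    names(S) <- c("generation", "mean_fitness", "sd_fitness",
                  paste0("mean_", colnames(pop$traits)),
                  paste0("mean_corr_", seq_len(P)),
                  paste0("pc", seq_len(scape$n_axes)))
    structure(list(summary = S,
                   final = list(traits = pop$traits, corr = pop$corr,
                                fitness = fit),
                   seed = seed, mode = config$mode,
                   config_hash = config_hash(unclass(config))),
              class = "trace_run")
  })
}

#' Run an adaptive-walk simulation
#'
#' Executes `config$replicates` independent replicate walks; replicate r uses
#' RNG seed `base_seed + r`, so a rerun with the same configuration is
#' bit-identical. Each replicate records per-generation population summaries
#' (mean/sd fitness, mean traits, mean correlations, mean retained-axis
#' coordinates) including the initial state, plus a full final-population
#' snapshot.
#'
#' @param config a `sim_config`.
#' @param scape a `trait_scape`.
#' @param corr_table a `correlation_table` (required for A/E modes).
#' @return a `trace_runs` list of `trace_run` objects.
#' @export
run_adaptive_walk <- function(config, scape, corr_table = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(scape, "trait_scape"))
  runs <- lapply(seq_len(config$replicates), function(r) {
    run_one_replicate(config, scape, corr_table, config$base_seed + r)
  })
  structure(runs, class = "trace_runs")
}

#' @export
print.trace_run <- function(x, ...) {
  n <- nrow(x$summary)
  cat("trace_run (mode ", x$mode, "): ", n - 1L, " generations, ",
      nrow(x$final$traits), " individuals; final mean fitness ",
      sprintf("%.4f", x$summary$mean_fitness[n]), "\n", sep = "")
  invisible(x)
}
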