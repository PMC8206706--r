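test_that("configuration validates and round-trips through JSON", {
  expect_error(sim_config(mode = "Z9"), "mode")
  expect_error(sim_config(p_corr = 1.5))
  expect_error(sim_config(start_spec = list(list(weight = 0.6,
                                                 traits = c(0, 0)))),
               "sum to 1")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(N = 50, generations = 10, replicates = 2,
                            mode = "mixed"), f, auto_unbox = TRUE)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$N, 50L)
  jsonlite::write_json(list(N = 50, bogus_knob = 1), f, auto_unbox = TRUE)
  expect_error(read_sim_config(f), "bogus_knob")
})

test_that("initialization modes set traits and correlations as specified", {
  rf <- ref_fixture()
  scape <- rf$scape
  ct <- rf$fx$corr_table

  # mixed: every trait row at the fitted start; corr ~ Uniform(-1, 1)
  cfg <- sim_config(N = 4000L, mode = "mixed", base_seed = 1)
  set.seed(2)
  pop <- init_population(cfg, scape)
  expect_equal(unname(pop$traits[1, ]), unname(scape$start_traits))
  expect_equal(max(abs(sweep(pop$traits, 2, scape$start_traits))), 0)
  expect_lt(max(abs(colMeans(pop$corr))), 3 * sqrt(1 / 3 / 4000))
  expect_equal(unname(apply(pop$corr, 2, var)), rep(1 / 3, 6),
               tolerance = 0.1)

  # A2: top two ranked ancestral pairs fixed, others vary
  set.seed(3)
  popA <- init_population(sim_config(N = 200L, mode = "A2"), scape, ct)
  rp <- ct[order(ct$ancestral_rank), ]
  for (i in 1:2) {
    expect_equal(unname(popA$corr[, rp$pair[i]]),
                 rep(rp$ancestral_r[i], 200))
  }
  free <- setdiff(colnames(popA$corr), rp$pair[1:2])
  expect_true(all(apply(popA$corr[, free], 2, sd) > 0))

  # E-mode fixes evolved correlations instead
  set.seed(3)
  popE <- init_population(sim_config(N = 50L, mode = "E1"), scape, ct)
  top_e <- ct$pair[which(ct$evolved_rank == 1)]
  expect_equal(unname(popE$corr[, top_e]),
               rep(ct$evolved_r[ct$pair == top_e], 50))

  # uncorrelated: all-zero correlations
  popU <- init_population(sim_config(N = 20L, mode = "uncorrelated"), scape)
  expect_true(all(popU$corr == 0))

  # requesting more ranked pairs than exist is rejected
  ct2 <- ct
  ct2$ancestral_sig <- c(TRUE, rep(FALSE, 5))
  ct2$ancestral_rank <- c(1L, rep(NA_integer_, 5))
  expect_error(init_population(sim_config(N = 10L, mode = "A3"), scape, ct2),
               "ranked significant")
  expect_error(init_population(sim_config(N = 10L, mode = "A1"), scape, NULL),
               "corr_table")
})

test_that("multi-start specifications apportion individuals exactly", {
  rf <- ref_fixture()
  starts <- lapply(1:4, function(i) list(weight = 0.25,
                                         traits = rep(i, 4)))
  pop <- init_population(sim_config(N = 1000L, mode = "uncorrelated",
                                    start_spec = starts), rf$scape)
  counts <- table(pop$traits[, 1])
  expect_equal(unname(c(counts)), rep(250L, 4), ignore_attr = TRUE)
})

test_that("mutation kernels reproduce the update rules by hand", {
  # replace: trait 2 is rewritten from the correlation and the new trait 1
  tr <- apply_trait_change(c(0.5, 0), corr = 1, k = 1, delta = 0.1,
                           propagation = "replace")
  expect_equal(tr, c(0.6, 0.6))
  # delta: trait 2 gains corr * delta instead
  tr <- apply_trait_change(c(0.5, 0), corr = 1, k = 1, delta = 0.1,
                           propagation = "delta")
  expect_equal(tr, c(0.6, 0.1))
  # zero correlations under replace pull the other traits to the
  # standardized mean
  tr <- apply_trait_change(c(1, 2, 3, 4), corr = rep(0, 6), k = 2,
                           delta = 0.5, propagation = "replace")
  expect_equal(tr, c(0, 2.5, 0, 0))
  # uncorrelated control: only the focal trait moves
  tr <- apply_trait_change(c(1, 2, 3, 4), corr = rep(0.9, 6), k = 2,
                           delta = 0.5, correlated = FALSE)
  expect_equal(tr, c(1, 2.5, 3, 4))

  # correlation step is clipped to [-1, 1]
  up <- apply_corr_change(rep(0, 4), corr = c(0.98, rep(0, 5)), pair = 1,
                          corr_delta = 0.10, first = 1, trait_delta = 0)
  expect_equal(up$corr[1], 1)
  # joint change: corr(1v2) -> 0.5, trait1 += 0.2, trait2 <- 0.5 * 0.2
  up <- apply_corr_change(rep(0, 4), corr = c(0.3, rep(0, 5)), pair = 1,
                          corr_delta = 0.2, first = 1, trait_delta = 0.2)
  expect_equal(up$traits, c(0.2, 0.1, 0, 0))
  expect_equal(up$corr, c(0.5, rep(0, 5)))
  # the second endpoint can also be the perturbed one
  up <- apply_corr_change(rep(0, 4), corr = c(0.5, rep(0, 5)), pair = 1,
                          corr_delta = 0, first = 2, trait_delta = 0.2)
  expect_equal(up$traits, c(0.1, 0.2, 0, 0))
})

test_that("vectorized mutation matches the single-individual kernels", {
  K <- 4L
  n <- 60L
  lut <- pair_lookup(K)
  pairs <- trait_pairs(K)
  for (prop in c("replace", "delta")) {
    set.seed(91)
    traits <- matrix(rnorm(n * K), n, K)
    corr <- matrix(runif(n * 6, -1, 1), n, 6)
    idx <- seq_len(n)

    set.seed(77)
    got <- traitscape:::mutate_trait_group(traits, corr, idx, 0.3, prop,
                                           TRUE, lut)
    set.seed(77)  # replay the documented draw order: focal indices, deltas
    k <- sample.int(K, n, replace = TRUE)
    delta <- rnorm(n, 0, 0.3)
    want <- traits
    for (i in idx) {
      want[i, ] <- apply_trait_change(traits[i, ], corr[i, ], k[i], delta[i],
                                      prop)
    }
    expect_equal(got, want)

    set.seed(78)
    got2 <- traitscape:::mutate_corr_group(traits, corr, idx, 0.3, prop,
                                           pairs)
    set.seed(78)  # draw order: pairs, corr deltas, endpoints, trait deltas
    pr <- sample.int(6L, n, replace = TRUE)
    cd <- rnorm(n, 0, 0.3)
    first <- sample.int(2L, n, replace = TRUE)
    td <- rnorm(n, 0, 0.3)
    wt <- traits
    wc <- corr
    for (i in idx) {
      up <- apply_corr_change(traits[i, ], corr[i, ], pr[i], cd[i], first[i],
                              td[i], prop)
      wt[i, ] <- up$traits
      wc[i, ] <- up$corr
    }
    expect_equal(got2$traits, wt)
    expect_equal(got2$corr, wc)
  }
})

test_that("each joint change perturbs exactly one pair, uniformly", {
  n <- 20000L
  traits <- matrix(0, n, 4)
  corr <- matrix(0, n, 6)
  set.seed(13)
  up <- traitscape:::mutate_corr_group(traits, corr, seq_len(n), 0.5,
                                       "replace", trait_pairs(4))
  changed <- up$corr != 0
  expect_true(all(rowSums(changed) == 1))
  counts <- colSums(changed)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-6)
})

test_that("fitness follows the Gaussian distance weight on the scape", {
  rf <- ref_fixture()
  scape <- rf$scape
  W <- scape$loadings[, 1:2]
  at_end <- drop(W %*% scape$end)
  expect_equal(compute_fitness(at_end, scape), 1)
  # unit offset along pc1: z = 1
  expect_equal(compute_fitness(drop(W %*% (scape$end + c(1, 0))), scape),
               exp(-0.5))
  f10 <- compute_fitness(drop(W %*% (scape$end + c(10, 0))), scape)
  expect_gt(f10, 0)
  expect_equal(f10, exp(-50))
  # strictly decreasing in distance
  zs <- seq(0, 3, by = 0.25)
  fs <- vapply(zs, function(z)
    compute_fitness(drop(W %*% (scape$end + c(z, 0))), scape), numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("selection is weighted multinomial resampling with inheritance", {
  n <- 40000L
  pop <- structure(list(traits = matrix(rep(c(1, 2), each = n / 2), n, 2),
                        corr = matrix(rep(c(0.5, -0.5), each = n / 2), n, 1)),
                   class = "trace_population")
  expect_error(select_population(pop, rep(0, n)), "non-negative")
  w <- rep(c(4, 1), each = n / 2)
  set.seed(21)
  sel <- select_population(pop, w)
  share <- mean(sel$traits[, 1] == 1)
  expect_equal(share, 0.8, tolerance = 3 * sqrt(0.8 * 0.2 / n))
  # offspring inherit the parent's correlation vector exactly
  expect_true(all(sel$corr[sel$traits[, 1] == 1, 1] == 0.5))

  # monotone response: doubling a subgroup's weight raises its share
  set.seed(22)
  share2 <- mean(select_population(pop, rep(c(8, 1), each = n / 2))$traits[, 1] == 1)
  expect_gt(share2, share)
})

test_that("the 90/10 split is an exact count without replacement", {
  for (case in list(c(1000, 0.1, 100), c(250, 0.1, 25), c(11, 0.5, 6),
                    c(50, 0, 0), c(50, 1, 50))) {
    set.seed(4)
    idx <- traitscape:::split_mutation_groups(case[1], case[2])
    expect_length(idx, case[3])
    expect_false(anyDuplicated(idx) > 0)
    expect_true(all(idx >= 1 & idx <= case[1]))
  }
})

test_that("delta-mode mutation with step_sd = 0 leaves the state unchanged", {
  rf <- ref_fixture()
  cfg <- sim_config(N = 30L, step_sd = 0, propagation = "delta",
                    mode = "mixed", base_seed = 5)
  set.seed(6)
  pop <- init_population(cfg, rf$scape)
  st <- step_generation(pop, cfg, rf$scape)
  # selection may reshuffle copies, but every row equals the unique initial
  # state
  expect_equal(unique(st$population$traits), unique(pop$traits))
  expect_true(all(st$population$corr %in% pop$corr))
})

test_that("runs are bit-reproducible and respect the generation contract", {
  rf <- ref_fixture()
  cfg <- sim_config(N = 40L, generations = 30L, replicates = 2L,
                    mode = "mixed", base_seed = 17)
  r1 <- run_adaptive_walk(cfg, rf$scape, rf$fx$corr_table)
  r2 <- run_adaptive_walk(cfg, rf$scape, rf$fx$corr_table)
  expect_identical(r1[[1]]$summary, r2[[1]]$summary)
  expect_identical(r1[[2]]$final, r2[[2]]$final)
  expect_equal(nrow(r1[[1]]$summary), 31L)
  expect_equal(nrow(r1[[1]]$final$traits), 40L)
  expect_true(all(abs(r1[[1]]$final$corr) <= 1))
  expect_true(all(r1[[1]]$summary$mean_fitness > 0 &
                  r1[[1]]$summary$mean_fitness <= 1))
  # replicates differ from each other
  expect_false(identical(r1[[1]]$final, r1[[2]]$final))

  # generations = 0 records exactly the initial state
  cfg0 <- sim_config(N = 25L, generations = 0L, replicates = 1L,
                     mode = "uncorrelated", base_seed = 1)
  r0 <- run_adaptive_walk(cfg0, rf$scape)
  expect_equal(nrow(r0[[1]]$summary), 1L)
  expect_equal(unname(r0[[1]]$final$traits[1, ]),
               unname(rf$scape$start_traits))
})

test_that("with p_corr = 0 individual correlation vectors never change", {
  rf <- ref_fixture()
  cfg <- sim_config(N = 30L, generations = 40L, replicates = 1L,
                    p_corr = 0, mode = "mixed", base_seed = 9)
  run <- run_adaptive_walk(cfg, rf$scape)[[1]]
  # regenerate the initial population under the replicate seed
  init <- traitscape:::with_seed(cfg$base_seed + 1,
                                 init_population(cfg, rf$scape))
  key <- function(m) apply(round(m, 12), 1, paste, collapse = ",")
  expect_true(all(key(run$final$corr) %in% key(init$corr)))
})

test_that("run results survive a CSV round trip", {
  rf <- ref_fixture()
  cfg <- sim_config(N = 20L, generations = 10L, replicates = 2L,
                    mode = "mixed", base_seed = 31)
  runs <- run_adaptive_walk(cfg, rf$scape)
  d <- withr::local_tempdir()
  write_run_results(runs, d)
  back <- read_run_results(d)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$final$corr, runs[[1]]$final$corr,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(replicate_signature(back[[2]]), replicate_signature(runs[[2]]),
               ignore_attr = TRUE, tolerance = 1e-12)
})
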