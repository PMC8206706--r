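#' Nearest positive semi-definite correlation matrix
#'
#' Repairs a symmetric unit-diagonal target matrix by clipping negative
#' eigenvalues at zero and rescaling the reconstruction back to unit
#' diagonal. Already-PSD inputs are returned unchanged.
#'
#' @param C symmetric matrix with unit diagonal.
#' @param tol eigenvalues above `-tol` count as non-negative.
#' @return a PSD correlation matrix.
#' @export
nearest_psd_corr <- function(C, tol = 1e-10) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (max(abs(C - t(C))) > 1e-8) stop("correlation target is not symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8) stop("correlation target diagonal is not 1")
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= -tol) return(C)
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Specification for a synthetic multi-genotype trait table
#'
#' Describes a factorial design of `genotypes` x {ancestral, evolved} groups,
#' each sampled from a multivariate Gaussian with its own mean vector,
#' per-trait standard deviations and target trait correlation matrix.
#'
#' @param genotypes number of genotypes.
#' @param replicates replicate cultures per (genotype, condition) cell.
#' @param K number of traits.
#' @param means numeric array `[genotype, condition, trait]` of trait means
#'   (conditions ordered ancestral, evolved).
#' @param sds array of the same shape with per-trait standard deviations.
#' @param corrs list with elements `ancestral` and `evolved`; each either a
#'   single K x K correlation matrix (shared by all genotypes) or a list of
#'   one matrix per genotype.
#' @param seed RNG seed used by [make_trait_table()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(genotypes, replicates, K, means, sds, corrs,
                         seed = 1L) {
  stopifnot(genotypes >= 1, replicates >= 2, K >= 2)
  stopifnot(identical(dim(means), c(as.integer(genotypes), 2L, as.integer(K))))
  stopifnot(identical(dim(sds), dim(means)), all(sds > 0))
  stopifnot(is.list(corrs), all(c("ancestral", "evolved") %in% names(corrs)))
  structure(list(genotypes = as.integer(genotypes),
                 replicates = as.integer(replicates),
                 K = as.integer(K), means = means, sds = sds, corrs = corrs,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

spec_corr <- function(spec, condition, g) {
  cm <- spec$corrs[[condition]]
  if (is.list(cm)) cm <- cm[[g]]
  cm
}

#' Draw a synthetic trait table from a fixture specification
#'
#' Each (genotype, condition) cell is sampled from a multivariate Gaussian
#' whose correlation target is first repaired to the nearest PSD correlation
#' matrix ([nearest_psd_corr()]). Deterministic under `spec$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [fixture_spec()].
#' @return a `trait_table`.
#' @export
make_trait_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    rows <- list()
    conds <- c("ancestral", "evolved")
    for (g in seq_len(spec$genotypes)) {
      for (ci in 1:2) {
        C <- nearest_psd_corr(spec_corr(spec, conds[ci], g))
        L <- chol(C + diag(1e-10, spec$K))
        Z <- matrix(stats::rnorm(spec$replicates * spec$K),
                    spec$replicates, spec$K) %*% L
        X <- sweep(Z, 2L, spec$sds[g, ci, ], "*")
        X <- sweep(X, 2L, spec$means[g, ci, ], "+")
        colnames(X) <- paste0("trait_", seq_len(spec$K))
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = paste0("G", g),
          replicate = paste0("r", seq_len(spec$replicates)),
          condition = conds[ci], X,
          stringsAsFactors = FALSE)
      }
    }
    as_trait_table(do.call(rbind, rows))
  })
}

#' Ranked ancestral/evolved pairwise correlation table
#'
#' Assembles the per-pair correlation table consumed by the ancestral (A1-A4)
#' and evolved (E1-E4) bias initialization modes: for every canonical trait
#' pair, the ancestral and evolved correlation, a significance flag per
#' condition, and a significance rank (1 = most significant) that must be
#' unique among significant pairs within a condition.
#'
#' @param K number of traits.
#' @param ancestral_r,evolved_r numeric vectors in canonical pair order.
#' @param ancestral_sig,evolved_sig logical significance flags.
#' @param ancestral_rank,evolved_rank integer ranks (NA for non-significant
#'   pairs).
#' @return a `correlation_table` data frame.
#' @export
correlation_table <- function(K, ancestral_r, evolved_r, ancestral_sig,
                              evolved_sig, ancestral_rank, evolved_rank) {
  P <- K * (K - 1L) / 2L
  stopifnot(length(ancestral_r) == P, length(evolved_r) == P,
            length(ancestral_sig) == P, length(evolved_sig) == P,
            length(ancestral_rank) == P, length(evolved_rank) == P)
  stopifnot(all(abs(ancestral_r) <= 1), all(abs(evolved_r) <= 1))
  for (side in list(list(ancestral_sig, ancestral_rank, "ancestral"),
                    list(evolved_sig, evolved_rank, "evolved"))) {
    rk <- side[[2]][side[[1]]]
    if (anyNA(rk) || anyDuplicated(rk)) {
      stop("significant ", side[[3]],
           " pairs must carry unique non-missing ranks")
    }
  }
  structure(data.frame(pair = pair_labels(K),
                       ancestral_r = ancestral_r, ancestral_sig = ancestral_sig,
                       ancestral_rank = ancestral_rank,
                       evolved_r = evolved_r, evolved_sig = evolved_sig,
                       evolved_rank = evolved_rank,
                       stringsAsFactors = FALSE),
            class = c("correlation_table", "data.frame"))
}

# significant pairs of one condition, ordered most- to least-significant;
# returns data.frame(pair_index, r)
ranked_pairs <- function(corr_table, condition = c("ancestral", "evolved")) {
  condition <- match.arg(condition)
  sig <- corr_table[[paste0(condition, "_sig")]]
  rk <- corr_table[[paste0(condition, "_rank")]]
  r <- corr_table[[paste0(condition, "_r")]]
  idx <- which(sig)[order(rk[sig])]
  data.frame(pair_index = idx, r = r[idx])
}

corr_vec_to_matrix <- function(r, K) {
  p <- trait_pairs(K)
  C <- diag(K)
  C[p] <- r
  C[p[, 2:1, drop = FALSE]] <- r
  C
}

#' Packaged reference fixture: trait table plus ranked correlation tables
#'
#' A fully synthetic stand-in for a 4-trait, 5-genotype experimental
#' evolution design (ancestral and evolved cultures per genotype). By
#' construction the evolved PCA concentrates >= 80% of variance on the first
#' two axes, the focal genotype's ancestral and evolved centroids are
#' separated by >= 2 retained-axis units, and the ranked significant
#' ancestral correlations span r = -0.89 to 0.54. Ancestral and evolved
#' correlation structures are deliberately misaligned so that ancestral
#' standing bias opposes, and evolved bias matches, the direction of
#' adaptation.
#'
#' @param seed RNG seed for the sampled table.
#' @param replicates replicate cultures per (genotype, condition).
#' @return list with `table` (a `trait_table`), `corr_table` (a
#'   `correlation_table`), `spec` (the generating [fixture_spec()]) and
#'   `focal_genotype`.
#' @export
make_reference_fixture <- function(seed = 1234L, replicates = 6L) {
  K <- 4L
  G <- 5L
  # two orthonormal directions spanning the between-genotype spread
  u1 <- c(1, 1, 1, 1) / 2
  u2 <- c(1, -1, 1, -1) / 2
  u3 <- c(1, 1, -1, -1) / 2
  ab <- rbind(c(2.0, 0.3), c(-2.0, 0.6), c(0.2, 2.0), c(0.6, -2.0),
              c(-1.0, -1.6))
  cc <- c(0.25, -0.2, 0.15, -0.25, 0.1)
  means <- array(0, dim = c(G, 2L, K))
  for (g in seq_len(G)) {
    evolved <- ab[g, 1] * u1 + ab[g, 2] * u2 + cc[g] * u3
    means[g, 2L, ] <- evolved
    # ancestral phenotypes sit well away from the evolved cloud along -u1
    means[g, 1L, ] <- evolved - 4.5 * u1 + 0.8 * u2
  }
  sds <- array(0.4, dim = c(G, 2L, K))

  # canonical pair order: 1v2 1v3 1v4 2v3 2v4 3v4
  anc_r <- c(0.54, 0.10, 0.70, -0.05, -0.89, -0.62)
  anc_sig <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  anc_rank <- c(4L, NA, 2L, NA, 1L, 3L)
  evo_r <- c(0.80, 0.70, -0.60, 0.45, 0.02, -0.08)
  evo_sig <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  evo_rank <- c(1L, 2L, 3L, 4L, NA, NA)
  corr_table <- correlation_table(K, anc_r, evo_r, anc_sig, evo_sig,
                                  anc_rank, evo_rank)

  corrs <- list(ancestral = nearest_psd_corr(corr_vec_to_matrix(anc_r, K)),
                evolved = nearest_psd_corr(corr_vec_to_matrix(evo_r, K)))
  spec <- fixture_spec(G, replicates, K, means, sds, corrs, seed = seed)
  list(table = make_trait_table(spec), corr_table = corr_table, spec = spec,
       focal_genotype = "G1")
}
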