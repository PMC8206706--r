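#' Mean final correlation vector of a replicate run
#'
#' The clustering substrate for the phenotype census: the mean, over all
#' individuals of the final generation, of each pairwise trait correlation.
#'
#' @param run a `trace_run`.
#' @return a named P-vector.
#' @export
replicate_signature <- function(run) {
  stopifnot(inherits(run, "trace_run"))
  if (is.null(run$final$corr) || nrow(run$final$corr) == 0L) {
    stop("run has an empty final population")
  }
  colMeans(run$final$corr)
}

signature_matrix <- function(runs) {
  sig <- t(vapply(runs, replicate_signature,
                  numeric(ncol(runs[[1]]$final$corr))))
  rownames(sig) <- paste0("rep", seq_along(runs))
  sig
}

#' Rate of adaptation from a mean-fitness trajectory
#'
#' The plateau is the mean fitness over the final 10% of generations; t95 is
#' the first generation (0-based, the series includes generation 0) at which
#' mean fitness reaches 95% of the plateau. The rate is 1 / t95 in inverse
#' generations, guarded to 1 when the trajectory starts at or above the
#' plateau criterion (t95 = 0). The `"auc"` alternative reports mean fitness
#' as a fraction of the plateau -- a scale-free area-under-curve summary.
#'
#' @param fitness numeric mean-fitness series, generation 0 first.
#' @param method `"t95"` (default) or `"auc"`.
#' @return a scalar rate.
#' @export
adaptation_rate <- function(fitness, method = c("t95", "auc")) {
  method <- match.arg(method)
  if (length(fitness) < 2L || any(!is.finite(fitness))) {
    stop("fitness trajectory must be finite with length >= 2")
  }
  n <- length(fitness)
  plateau <- mean(fitness[seq.int(n - max(1L, ceiling(0.1 * n)) + 1L, n)])
  if (method == "auc") return(mean(fitness) / plateau)
  t95 <- which(fitness >= 0.95 * plateau)[1L] - 1L
  if (is.na(t95)) t95 <- n - 1L
  if (t95 == 0L) 1 else 1 / t95
}

# mean silhouette width of a hard clustering over a distance matrix
mean_silhouette <- function(D, cl) {
  n <- nrow(D)
  ks <- unique(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    if (sum(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != cl[i]], function(k) mean(D[i, cl == k]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Census of emergent population types across replicate runs
#'
#' Replicate signatures (mean final correlation vectors) are clustered by
#' UPGMA on Euclidean distance; the number of types k is chosen in
#' 2..`k_max` by maximum mean silhouette width, falling back to a single type
#' when the best silhouette is below `silhouette_min` (no structure) or when
#' all signatures coincide. Types are labelled Pop-A, Pop-B, ... by
#' decreasing accessibility (the fraction of replicates converging on the
#' type). When full runs are supplied, per-type trait means and adaptation
#' rates (mean over member replicates of [adaptation_rate()]) are included.
#'
#' @param x a `trace_runs` object, or a plain numeric matrix of replicate
#'   signatures (rows = replicates).
#' @param k_max largest number of types considered.
#' @param silhouette_min mean-silhouette threshold below which the replicate
#'   set is declared a single type.
#' @return a `phenotype_census`: list with `types` (data frame: `type`, `n`,
#'   `accessibility`, `rate`, `rate_auc`, `corr_mean_*`, `corr_sd_*`, and
#'   `trait_mean_*` when runs were given), `membership` (type label per
#'   replicate), `signatures`, and `k`.
#' @export
census <- function(x, k_max = 8L, silhouette_min = 0.25) {
  if (inherits(x, "trace_runs")) {
    runs <- x
    sig <- signature_matrix(runs)
  } else {
    runs <- NULL
    sig <- as.matrix(x)
    if (is.null(rownames(sig))) rownames(sig) <- paste0("rep", seq_len(nrow(sig)))
  }
  n <- nrow(sig)
  if (n < 2L) stop("census needs at least 2 replicates")

  D <- as.matrix(stats::dist(sig))
  if (max(D) == 0) {
    cl <- rep(1L, n)
  } else {
    dend <- upgma(sig)
    hc <- stats::as.hclust(dend)
    ks <- seq(2L, max(2L, min(k_max, n - 1L)))
    sil <- vapply(ks, function(k) mean_silhouette(D, stats::cutree(hc, k)),
                  numeric(1))
    if (max(sil) < silhouette_min) {
      cl <- rep(1L, n)
    } else {
      cl <- stats::cutree(hc, ks[which.max(sil)])
    }
  }

  sizes <- table(cl)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  type_of <- integer(max(cl))
  type_of[as.integer(names(sizes))[ord]] <- seq_along(ord)
  membership <- stats::setNames(paste0("Pop-", LETTERS[type_of[cl]]),
                                rownames(sig))
  P <- ncol(sig)

  rows <- lapply(seq_along(ord), function(t) {
    mem <- type_of[cl] == t
    row <- data.frame(type = paste0("Pop-", LETTERS[t]), n = sum(mem),
                      accessibility = sum(mem) / n)
    if (!is.null(runs)) {
      row$rate <- mean(vapply(runs[mem], function(r)
        adaptation_rate(r$summary$mean_fitness), numeric(1)))
      row$rate_auc <- mean(vapply(runs[mem], function(r)
        adaptation_rate(r$summary$mean_fitness, "auc"), numeric(1)))
    } else {
      row$rate <- NA_real_
      row$rate_auc <- NA_real_
    }
    cm <- colMeans(sig[mem, , drop = FALSE])
    cs <- apply(sig[mem, , drop = FALSE], 2L, stats::sd)
    cs[is.na(cs)] <- 0
    row[paste0("corr_mean_", seq_len(P))] <- as.list(cm)
    row[paste0("corr_sd_", seq_len(P))] <- as.list(cs)
    if (!is.null(runs)) {
      tm <- colMeans(do.call(rbind, lapply(runs[mem], function(r)
        colMeans(r$final$traits))))
      row[paste0("trait_mean_", seq_along(tm))] <- as.list(tm)
    }
    row
  })
  types <- do.call(rbind, rows)
  structure(list(types = types, membership = membership, signatures = sig,
                 k = length(ord)),
            class = "phenotype_census")
}

#' @export
print.phenotype_census <- function(x, ...) {
  cat("phenotype_census:", x$k, "type(s) over", nrow(x$signatures),
      "replicates\n")
  print(x$types[, c("type", "n", "accessibility", "rate")], row.names = FALSE)
  invisible(x)
}

#' Per-type mean correlation vectors of a census
#'
#' @param cen a `phenotype_census`.
#' @return matrix with one row per type (rownames = type labels).
#' @export
census_signatures <- function(cen) {
  P <- ncol(cen$signatures)
  m <- as.matrix(cen$types[, paste0("corr_mean_", seq_len(P)), drop = FALSE])
  rownames(m) <- cen$types$type
  colnames(m) <- colnames(cen$signatures)
  m
}
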