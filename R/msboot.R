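#' UPGMA (average-linkage) hierarchical clustering
#'
#' A from-scratch agglomerative UPGMA: at each step the two clusters with the
#' smallest mean pairwise (Euclidean) distance are merged at that height, and
#' distances to the merged cluster are size-weighted averages. Ties are broken
#' deterministically by the lexicographically smallest pair of canonical
#' (sorted) member tuples, so results are platform-reproducible.
#'
#' @param x an items x dims numeric matrix (Euclidean distances are computed
#'   over the columns), or a `dist` object / symmetric distance matrix.
#' @param labels optional item labels (default: rownames, else 1..n); must be
#'   unique.
#' @return a `trace_dendrogram`: list with hclust-compatible `merge`,
#'   `height`, `order`, `labels`, plus `members` (per internal node, the
#'   sorted member-label tuple). Convert with [stats::as.hclust()].
#' @export
upgma <- function(x, labels = NULL) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else {
    x <- as.matrix(x)
    D <- if (nrow(x) == ncol(x) && isSymmetric(unname(x)) &&
             all(diag(x) == 0) && is.null(labels) &&
             identical(rownames(x), colnames(x)) && !is.null(rownames(x))) {
      x
    } else {
      as.matrix(stats::dist(x))
    }
  }
  n <- nrow(D)
  if (n < 2L) stop("upgma needs at least 2 items")
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate item labels")

  id <- -seq_len(n)                  # hclust convention: leaves negative
  size <- rep(1L, n)
  members <- as.list(labels)
  keys <- labels
  alive <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  out_members <- vector("list", n - 1L)
  W <- D
  diag(W) <- Inf
  W[!alive, ] <- Inf

  for (s in seq_len(n - 1L)) {
    live <- which(alive)
    sub <- W[live, live, drop = FALSE]
    dmin <- min(sub)
    hits <- which(sub == dmin, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    if (nrow(hits) > 1L) {
      pk <- apply(hits, 1L, function(h) {
        paste(sort(c(keys[live[h[1L]]], keys[live[h[2L]]])), collapse = "||")
      })
      hits <- hits[order(pk)[1L], , drop = FALSE]
    }
    i <- live[hits[1L, 1L]]
    j <- live[hits[1L, 2L]]

    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- dmin
    newmem <- sort(c(members[[i]], members[[j]]))
    out_members[[s]] <- newmem

    for (k in which(alive)) {
      if (k == i || k == j) next
      W[i, k] <- W[k, i] <-
        (size[i] * W[i, k] + size[j] * W[j, k]) / (size[i] + size[j])
    }
    id[i] <- s
    size[i] <- size[i] + size[j]
    members[[i]] <- newmem
    keys[i] <- paste(newmem, collapse = ",")
    alive[j] <- FALSE
    W[j, ] <- Inf
    W[, j] <- Inf
  }

  ord <- local({
    rec <- function(node) {
      if (node < 0L) return(-node)
      c(rec(merge[node, 1L]), rec(merge[node, 2L]))
    }
    rec(n - 1L)
  })
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, members = out_members),
            class = "trace_dendrogram")
}

#' @export
as.hclust.trace_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 dist.method = "euclidean", call = match.call()),
            class = "hclust")
}

#' @export
print.trace_dendrogram <- function(x, ...) {
  cat("trace_dendrogram:", length(x$labels), "items,",
      length(x$height), "merges (UPGMA, Euclidean)\n")
  invisible(x)
}

node_keys <- function(dend) {
  vapply(dend$members, paste, character(1), collapse = ",")
}

#' Fit the two-parameter probit model of multiscale bootstrap counts
#'
#' The per-scale appearance probability of a cluster is modelled as
#' `BP_r = 1 - Phi(v * sqrt(r) + c / sqrt(r))`. (v, c) are estimated by
#' binomial maximum likelihood (a probit GLM on the miss counts); if that
#' fails to converge, a weighted-least-squares fit on probit-transformed
#' proportions is used, with counts of 0 or `nboot` pulled in by 0.5/nboot.
#' The approximately unbiased p-value is `AU = 1 - Phi(v - c)` and the
#' bias-corrected bootstrap probability is `BP_corrected = 1 - Phi(v + c)`.
#' Degenerate count vectors (all `nboot` or all 0) short-circuit to AU = 1
#' or 0 without fitting.
#'
#' @param counts per-scale appearance counts of one node.
#' @param nboot bootstrap replicates per scale.
#' @param scales the scale factors r.
#' @return list(AU, BP_corrected, v, c, flag) with flag one of
#'   `"degenerate"`, `"ml"`, `"wls"`.
#' @export
fit_au_model <- function(counts, nboot, scales) {
  stopifnot(length(counts) == length(scales), all(scales > 0),
            all(counts >= 0), all(counts <= nboot))
  if (all(counts == nboot)) {
    return(list(AU = 1, BP_corrected = 1, v = NA_real_, c = NA_real_,
                flag = "degenerate"))
  }
  if (all(counts == 0)) {
    return(list(AU = 0, BP_corrected = 0, v = NA_real_, c = NA_real_,
                flag = "degenerate"))
  }
  sr <- sqrt(scales)
  isr <- 1 / sr
  miss <- nboot - counts
  fit <- tryCatch(
    suppressWarnings(stats::glm(cbind(miss, counts) ~ 0 + sr + isr,
                                family = stats::binomial("probit"))),
    error = function(e) NULL)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    v <- unname(stats::coef(fit)[1L])
    cc <- unname(stats::coef(fit)[2L])
    flag <- "ml"
  } else {
    bp <- counts / nboot
    bp[bp == 0] <- 0.5 / nboot
    bp[bp == 1] <- 1 - 0.5 / nboot
    zval <- -stats::qnorm(bp)          # = v*sqrt(r) + c/sqrt(r)
    w <- nboot * stats::dnorm(stats::qnorm(bp))^2 / (bp * (1 - bp))
    X <- cbind(sr, isr)
    beta <- solve(crossprod(X, w * X), crossprod(X, w * zval))
    v <- beta[1L]
    cc <- beta[2L]
    flag <- "wls"
  }
  list(AU = 1 - stats::pnorm(v - cc),
       BP_corrected = 1 - stats::pnorm(v + cc),
       v = v, c = cc, flag = flag)
}

#' Multiscale bootstrap AU p-values for UPGMA clusters
#'
#' For each scale factor r, the P feature dimensions used to compute
#' inter-item distances are resampled with replacement at size
#' `round(r * P)`, the dendrogram is rebuilt, and each observed internal
#' node's appearance (exact member-set equality) is counted over `nboot`
#' resamples. Per-node counts across scales are then fed to [fit_au_model()].
#' With a single scale the probit fit is impossible: plain BP values are
#' reported with a warning and AU is NA.
#'
#' @param x items x P numeric matrix of signatures (rownames = item labels).
#' @param nboot bootstrap replicates per scale (>= 100).
#' @param scales positive scale factors (default 0.5..1.4 by 0.1).
#' @param seed optional seed making the resampling deterministic.
#' @return an `msboot` object: list with `dendrogram`, `scales`, `nboot`,
#'   `boot_size` (per-scale resample sizes), `counts` (node x scale), and
#'   `stats` -- a data frame with `members`, `AU`, `BP` (plain proportion at
#'   the scale nearest 1), `BP_corrected`, `v`, `c`, `flag`.
#' @export
multiscale_au <- function(x, nboot = 1000L, scales = seq(0.5, 1.4, by = 0.1),
                          seed = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L, all(scales > 0), nboot >= 100L)
  P <- ncol(x)
  dend <- upgma(x)
  keys <- node_keys(dend)
  nn <- length(keys)
  counts <- matrix(0L, nn, length(scales),
                   dimnames = list(keys, paste0("r", scales)))
  boot_size <- pmax(1L, as.integer(round(scales * P)))

  do_boot <- function() {
    for (si in seq_along(scales)) {
      m <- boot_size[si]
      for (b in seq_len(nboot)) {
        dims <- sample.int(P, m, replace = TRUE)
        bd <- upgma(x[, dims, drop = FALSE])
        hit <- keys %in% node_keys(bd)
        counts[hit, si] <<- counts[hit, si] + 1L
      }
    }
  }
  if (is.null(seed)) do_boot() else with_seed(seed, do_boot())

  if (length(scales) == 1L) {
    warning("a single scale cannot identify the (v, c) probit model; ",
            "reporting plain bootstrap proportions only")
    stats <- data.frame(members = keys, AU = NA_real_,
                        BP = counts[, 1L] / nboot, BP_corrected = NA_real_,
                        v = NA_real_, c = NA_real_, flag = "single-scale",
                        stringsAsFactors = FALSE, row.names = NULL)
  } else {
    near1 <- which.min(abs(scales - 1))
    fits <- lapply(seq_len(nn), function(i)
      fit_au_model(counts[i, ], nboot, scales))
    stats <- data.frame(
      members = keys,
      AU = vapply(fits, `[[`, numeric(1), "AU"),
      BP = counts[, near1] / nboot,
      BP_corrected = vapply(fits, `[[`, numeric(1), "BP_corrected"),
      v = vapply(fits, `[[`, numeric(1), "v"),
      c = vapply(fits, `[[`, numeric(1), "c"),
      flag = vapply(fits, `[[`, character(1), "flag"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(dendrogram = dend, scales = scales, nboot = as.integer(nboot),
                 boot_size = boot_size, counts = counts, stats = stats),
            class = "msboot")
}

#' @export
print.msboot <- function(x, ...) {
  cat("msboot:", nrow(x$stats), "internal nodes,", x$nboot,
      "bootstrap replicates x", length(x$scales), "scales\n")
  print(x$stats[, c("members", "AU", "BP", "flag")], row.names = FALSE)
  invisible(x)
}

#' Write an AU-annotated dendrogram to Newick
#'
#' Node labels carry AU support (as percentages, rounded to one decimal).
#' Requires the `ape` package.
#'
#' @param ms an `msboot` object.
#' @param path output file.
#' @export
write_msboot_newick <- function(ms, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("writing Newick output requires the 'ape' package")
  }
  phy <- ape::as.phylo(stats::as.hclust(ms$dendrogram))
  keys <- node_keys(ms$dendrogram)
  # ape numbers internal nodes in its own order; match by member sets
  phy_members <- lapply(seq_len(phy$Nnode) + length(phy$tip.label),
                        function(nd) {
    tips <- ape::extract.clade(phy, nd)$tip.label
    paste(sort(tips), collapse = ",")
  })
  au <- ms$stats$AU[match(unlist(phy_members), ms$stats$members)]
  phy$node.label <- ifelse(is.na(au), "", sprintf("%.1f", 100 * au))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' PCA of correlation signatures with per-cluster convex hulls
#'
#' Centred (not re-standardized: the dimensions share units) PCA over
#' correlation-vector signatures; clusters passing the AU confidence
#' threshold are summarized as convex hulls in the plane of the first two
#' components. Clusters with fewer than 3 points emit their point set as a
#' degenerate hull. Biplot loading vectors for the P correlation dimensions
#' are returned alongside.
#'
#' @param signatures items x P matrix (>= 3 rows, non-constant).
#' @param clusters cluster assignment per row.
#' @param cluster_au optional named vector of per-cluster AU values; clusters
#'   below `au_threshold` get no hull.
#' @param au_threshold minimum AU for a hull (default 0.75).
#' @return list with `scores` (n x 2), `var_explained`, `loadings` (P x 2),
#'   and `hulls` -- per qualifying cluster, its hull vertex coordinates (a
#'   matrix with rownames giving item labels).
#' @export
correlation_pca_hulls <- function(signatures, clusters, cluster_au = NULL,
                                  au_threshold = 0.75) {
  sig <- as.matrix(signatures)
  if (nrow(sig) < 3L) stop("need at least 3 signatures")
  stopifnot(length(clusters) == nrow(sig))
  if (max(stats::dist(sig)) == 0) stop("all signatures identical: no variance")
  p <- stats::prcomp(sig, center = TRUE, scale. = FALSE)
  scores <- p$x[, 1:2, drop = FALSE]
  ve <- p$sdev^2 / sum(p$sdev^2)
  cls <- unique(clusters)
  if (!is.null(cluster_au)) {
    cls <- cls[cls %in% names(cluster_au)[cluster_au >= au_threshold]]
  }
  hulls <- lapply(cls, function(cl) {
    pts <- scores[clusters == cl, , drop = FALSE]
    if (nrow(pts) < 3L) pts else pts[grDevices::chull(pts), , drop = FALSE]
  })
  names(hulls) <- as.character(cls)
  list(scores = scores, var_explained = ve,
       loadings = p$rotation[, 1:2, drop = FALSE], hulls = hulls)
}
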