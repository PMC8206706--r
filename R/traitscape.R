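#' Validate and normalize a long-format trait table
#'
#' A trait table has one row per biological population (culture) with columns
#' `genotype`, `replicate`, `condition` (one of `"ancestral"`/`"evolved"`,
#' matched case-insensitively) and K >= 2 numeric trait columns named
#' `trait_1` ... `trait_K`.
#'
#' @param df a data frame in the layout above.
#' @return the validated data frame with `condition` lower-cased, classed as
#'   `trait_table`.
#' @export
as_trait_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("genotype", "replicate", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trait table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tc <- grep("^trait_[0-9]+$", names(df), value = TRUE)
  if (length(tc) < 2L) {
    stop("trait table needs at least 2 trait_<k> columns, found ", length(tc))
  }
  tc <- tc[order(as.integer(sub("^trait_", "", tc)))]
  for (cl in tc) {
    if (!is.numeric(df[[cl]])) stop("trait column is not numeric: ", cl)
    if (anyNA(df[[cl]]) || any(!is.finite(df[[cl]]))) {
      stop("missing or non-finite values in trait column: ", cl)
    }
  }
  cond <- tolower(as.character(df$condition))
  bad <- setdiff(unique(cond), c("ancestral", "evolved"))
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected 'ancestral' or 'evolved')")
  }
  df$condition <- cond
  df <- df[, c(need, tc)]
  class(df) <- c("trait_table", "data.frame")
  df
}

#' @rdname as_trait_table
#' @param path path to a CSV file with header
#'   `genotype,replicate,condition,trait_1..trait_K`.
#' @export
read_trait_table <- function(path) {
  as_trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

trait_columns <- function(table) {
  grep("^trait_[0-9]+$", names(table), value = TRUE)
}

#' Standardize a trait table against its evolved rows
#'
#' Per-trait mean and standard deviation are computed from the *evolved* rows
#' only, and every row (ancestral rows included) is z-scored with them. This
#' places all traits on the common dimensionless scale in which the trait
#' landscape is defined and on which projection of ancestral phenotypes onto
#' evolved axes makes sense.
#'
#' @param table a `trait_table` (see [as_trait_table()]).
#' @param sd_method `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1).
#' @return a list with elements `table` (standardized trait table), `mu` and
#'   `sigma` (named per-trait vectors computed from the evolved rows).
#' @export
standardize_traits <- function(table, sd_method = c("population", "sample")) {
  table <- as_trait_table(table)
  sd_method <- match.arg(sd_method)
  tc <- trait_columns(table)
  ev <- table$condition == "evolved"
  if (sum(ev) < 2L) stop("need at least 2 evolved rows to standardize")
  X <- as.matrix(table[ev, tc, drop = FALSE])
  mu <- colMeans(X)
  ctr <- sweep(X, 2L, mu)
  sigma <- if (sd_method == "population") {
    sqrt(colMeans(ctr^2))
  } else {
    apply(X, 2L, stats::sd)
  }
  zero <- sigma <= 0 | !is.finite(sigma)
  if (any(zero)) {
    stop("zero variance over evolved rows in trait(s): ",
         paste(tc[zero], collapse = ", "))
  }
  names(mu) <- names(sigma) <- tc
  std <- sweep(sweep(as.matrix(table[, tc, drop = FALSE]), 2L, mu), 2L,
               sigma, "/")
  table[tc] <- std
  list(table = table, mu = mu, sigma = sigma)
}

#' Fit a 2-D trait landscape ("trait-scape") from a trait table
#'
#' Standardizes the table against its evolved rows, fits a PCA (SVD of the
#' standardized evolved matrix, equivalent to an eigen-decomposition of the
#' evolved trait correlation matrix), and projects the focal genotype's
#' ancestral and evolved centroids onto the retained axes to define the start
#' and end coordinates of an adaptive walk.
#'
#' Loading columns use a deterministic sign convention: each column is flipped
#' so that its largest-magnitude entry is positive, making fits
#' bit-reproducible across platforms.
#'
#' @param table a `trait_table` containing ancestral and evolved rows.
#' @param n_axes number of retained PC axes (default 2; the trait-scape and
#'   the fitness distance are defined in this space).
#' @param focal_genotype the genotype whose ancestral/evolved centroids define
#'   the walk start and end. Defaults to the first genotype with at least two
#'   rows in both conditions.
#' @param sd_method passed to [standardize_traits()].
#' @return a `trait_scape` object: list with `mu`, `sigma`, `loadings`
#'   (K x K orthonormal, variance-ordered columns), `var_explained`,
#'   `n_axes`, `start` (retained-axis coordinates of the ancestral focal
#'   centroid), `start_traits` (its standardized K-trait vector), `end`
#'   (retained-axis coordinates of the evolved focal centroid),
#'   `focal_genotype`, `trait_names`, `sd_method`.
#' @export
fit_trait_scape <- function(table, n_axes = 2L, focal_genotype = NULL,
                            sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  std <- standardize_traits(table, sd_method)
  table <- std$table
  tc <- trait_columns(table)
  K <- length(tc)
  if (n_axes < 1L || n_axes > K) {
    stop("n_axes must be between 1 and the number of traits (", K, ")")
  }
  ev <- table$condition == "evolved"
  X <- as.matrix(table[ev, tc, drop = FALSE])
  if (nrow(X) < K) stop("need at least K evolved rows for a full-rank PCA")

  if (is.null(focal_genotype)) {
    for (g in unique(table$genotype)) {
      if (sum(table$genotype == g & ev) >= 2L &&
          sum(table$genotype == g & !ev) >= 2L) {
        focal_genotype <- g
        break
      }
    }
    if (is.null(focal_genotype)) {
      stop("no genotype has >= 2 rows in both conditions")
    }
  }
  for (cond in c("ancestral", "evolved")) {
    nfg <- sum(table$genotype == focal_genotype & table$condition == cond)
    if (nfg < 2L) {
      stop("focal genotype '", focal_genotype, "' needs >= 2 ", cond,
           " rows, found ", nfg)
    }
  }

  sv <- svd(X, nu = 0L, nv = K)
  V <- sv$v
  for (j in seq_len(K)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  var_explained <- sv$d^2 / sum(sv$d^2)

  anc <- table$genotype == focal_genotype & table$condition == "ancestral"
  evo <- table$genotype == focal_genotype & ev
  start_traits <- colMeans(as.matrix(table[anc, tc, drop = FALSE]))
  end_traits <- colMeans(as.matrix(table[evo, tc, drop = FALSE]))
  W <- V[, seq_len(n_axes), drop = FALSE]

  structure(list(
    mu = std$mu,
    sigma = std$sigma,
    loadings = V,
    var_explained = var_explained,
    n_axes = as.integer(n_axes),
    start = drop(crossprod(W, start_traits)),
    start_traits = start_traits,
    end = drop(crossprod(W, end_traits)),
    focal_genotype = focal_genotype,
    trait_names = tc,
    sd_method = sd_method
  ), class = "trait_scape")
}

#' @export
print.trait_scape <- function(x, ...) {
  K <- length(x$trait_names)
  cat("trait_scape:", K, "traits,", x$n_axes, "retained axes\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  cat("  focal genotype:", x$focal_genotype, "\n")
  cat("  start:", paste(sprintf("%.3f", x$start), collapse = ", "),
      " end:", paste(sprintf("%.3f", x$end), collapse = ", "), "\n")
  invisible(x)
}

#' Project standardized trait vectors onto retained trait-scape axes
#'
#' @param scape a `trait_scape`.
#' @param traits a standardized K-trait vector, or an n x K matrix of such
#'   vectors (one per row).
#' @return a length-`n_axes` coordinate vector, or an n x `n_axes` matrix.
#' @export
project_traits <- function(scape, traits) {
  K <- nrow(scape$loadings)
  W <- scape$loadings[, seq_len(scape$n_axes), drop = FALSE]
  if (is.matrix(traits)) {
    if (ncol(traits) != K) {
      stop("trait matrix has ", ncol(traits), " columns, expected ", K)
    }
    traits %*% W
  } else {
    if (length(traits) != K) {
      stop("trait vector has length ", length(traits), ", expected ", K)
    }
    drop(crossprod(W, traits))
  }
}

#' Project every culture in a raw trait table into trait-scape coordinates
#'
#' Rows are standardized with the scape's evolved-row `mu`/`sigma` (ancestral
#' rows included) and projected onto the retained axes.
#'
#' @param scape a `trait_scape`.
#' @param table a raw (unstandardized) `trait_table`.
#' @return a data frame: `genotype`, `replicate`, `condition`, `pc1..pcn`.
#' @export
project_trait_table <- function(scape, table) {
  table <- as_trait_table(table)
  tc <- trait_columns(table)
  if (!identical(tc, scape$trait_names)) {
    stop("trait columns do not match the trait-scape: ",
         paste(tc, collapse = ", "))
  }
  std <- sweep(sweep(as.matrix(table[, tc, drop = FALSE]), 2L, scape$mu), 2L,
               scape$sigma, "/")
  pc <- project_traits(scape, std)
  colnames(pc) <- paste0("pc", seq_len(ncol(pc)))
  cbind(table[, c("genotype", "replicate", "condition")], as.data.frame(pc))
}

#' Serialize a trait-scape to/from JSON
#'
#' The JSON layout stores `loadings` row-major (a list of K rows of K
#' numbers) along with `mu`, `sigma`, `var_explained`, `n_axes`, `start`,
#' `start_traits` and `end`.
#'
#' @param scape a `trait_scape`.
#' @param path output/input file path.
#' @export
write_trait_scape <- function(scape, path) {
  obj <- unclass(scape)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trait_scape
#' @export
read_trait_scape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings <- matrix(as.numeric(obj$loadings), nrow = nrow(obj$loadings))
  obj$n_axes <- as.integer(obj$n_axes)
  names(obj$mu) <- names(obj$sigma) <- obj$trait_names
  names(obj$start_traits) <- obj$trait_names
  structure(obj, class = "trait_scape")
}
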