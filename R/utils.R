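#' Canonical trait-pair order
#'
#' Pairwise trait correlations are stored as flat vectors in a fixed canonical
#' order: all pairs (i, j) with i < j, sorted by i then j. For K = 4 this is
#' 1v2, 1v3, 1v4, 2v3, 2v4, 3v4.
#'
#' @param K number of traits (>= 2).
#' @return `trait_pairs()`: an integer matrix with one row per pair and
#'   columns `a`, `b` (a < b). `pair_labels()`: character labels like
#'   `"1v2"`. `pair_lookup()`: a K x K matrix mapping (i, j) to the flat
#'   pair index (diagonal is NA).
#' @export
trait_pairs <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 2)
  K <- as.integer(K)
  idx <- which(upper.tri(diag(K)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("a", "b")
  rownames(idx) <- NULL
  idx
}

#' @rdname trait_pairs
#' @export
pair_labels <- function(K) {
  p <- trait_pairs(K)
  paste0(p[, 1L], "v", p[, 2L])
}

#' @rdname trait_pairs
#' @export
pair_lookup <- function(K) {
  p <- trait_pairs(K)
  m <- matrix(NA_integer_, K, K)
  for (i in seq_len(nrow(p))) {
    m[p[i, 1L], p[i, 2L]] <- i
    m[p[i, 2L], p[i, 1L]] <- i
  }
  m
}

# clamp to the valid correlation range
clip_unit <- function(x) pmin(1, pmax(-1, x))

# Evaluate `code` under `set.seed(seed)` while leaving the caller's RNG
# state untouched.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Content hash of an R object (via its canonical JSON serialization).
config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
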