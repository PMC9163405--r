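#' Edge indexing for symmetric connectivity matrices
#'
#' Connectivity matrices over `n` networks are vectorized as the
#' `E = n*(n-1)/2` upper-triangle entries in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This order is fixed
#' across subjects, windows and files.
#'
#' @param n number of networks (nodes).
#' @return `edge_index()` returns a two-column integer matrix (`i`, `j`,
#'   `i < j`) with one row per edge, in the canonical order.
#' @export
edge_index <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' @rdname edge_index
#' @param m symmetric matrix to vectorize.
#' @return `mat_to_edges()` returns the edge vector of a symmetric matrix.
#' @export
mat_to_edges <- function(m) {
  # row-major upper triangle of a symmetric matrix == column-major lower
  m[lower.tri(m)]
}

#' @rdname edge_index
#' @param ev edge vector of length `n*(n-1)/2`.
#' @param diag_value value placed on the diagonal (default 0).
#' @return `edges_to_mat()` returns the symmetric matrix.
#' @export
edges_to_mat <- function(ev, n, diag_value = 0) {
  stopifnot(length(ev) == n * (n - 1) / 2)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- ev
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

# Evaluate an expression under a local RNG seed, restoring the caller's
# RNG state afterwards. All randomness in the package flows through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-subject seeds derived from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Fisher r-to-z with clipping so z stays finite.
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

stop_dynfc <- function(...) stop(sprintf(...), call. = FALSE)
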