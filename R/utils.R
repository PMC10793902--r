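#' @keywords internal
"_PACKAGE"

# Grouped softmax over a vector of logits, groups given by an integer index.
# A global max is subtracted before exponentiation (valid for every group).
softmax_by_group <- function(logits, group, n_groups) {
  e <- exp(logits - max(logits))
  denom <- rowsum_vec(e, group, n_groups)
  e / denom[group]
}

# rowsum() for a plain vector with a fixed number of groups; absent groups get 0.
rowsum_vec <- function(x, group, n_groups) {
  x <- as.numeric(x)
  out <- numeric(n_groups)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# rowsum() for a matrix, fixed group count, absent groups zero-filled.
rowsum_mat <- function(x, group, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  s <- rowsum(x, group)
  out[as.integer(rownames(s)), ] <- s
  out
}

# One-hot encode with clamping to the last level for out-of-range values.
one_hot <- function(value, levels) {
  v <- match(value, levels)
  v[is.na(v)] <- length(levels)
  m <- matrix(0, length(value), length(levels))
  m[cbind(seq_along(value), v)] <- 1
  m
}

# Pairwise Euclidean distances between two coordinate matrices (n x 3, m x 3).
cross_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Deterministic polynomial string hash modulo the Mersenne prime 2^31 - 1.
# Double arithmetic stays exact (values < 2^36 << 2^53).
hash32 <- function(s) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

# Combine non-negative integer invariants into one hash, order-sensitive.
hash_ints <- function(ints) {
  h <- 2166136261 %% 2147483647
  for (v in ints) h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lgn_warn <- function(...) warning(sprintf(...), call. = FALSE)
lgn_stop <- function(...) stop(sprintf(...), call. = FALSE)

# Seeded RNG scope: runs expr under a local seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
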