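# Shared small helpers: seed fan-out, partition agreement, softmax.

#' Derive a per-stage seed from a master seed
#'
#' A single master seed fans out to independent per-stage seeds through a
#' fixed affine scheme, so stages are independently rerunnable and every
#' derived seed stays inside R's 32-bit integer range.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (0, 1, 2, ...).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, offset) {
  master <- as.double(master) %% 1000003
  as.integer((master * 1009 + 7 * as.double(offset)) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 for identical
#' partitions (up to relabelling), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# row-wise softmax of a matrix, numerically stabilised
row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# stratified assignment of fold / split ids, seeded by the caller
stratified_split <- function(y, frac) {
  idx_test <- integer(0)
  for (cl in unique(y)) {
    members <- which(y == cl)
    n_take <- max(1L, round(frac * length(members)))
    if (n_take >= length(members)) n_take <- length(members) - 1L
    if (n_take > 0L)
      idx_test <- c(idx_test, sample(members, n_take))
  }
  sort(idx_test)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
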