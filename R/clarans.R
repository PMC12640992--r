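# CLARANS (Clustering Large Applications based on RANdomized Search,
# Ng & Han 2002): randomized k-medoid search. From a random medoid set,
# repeatedly examine a random (medoid, non-medoid) swap; accept any swap
# that lowers total within-cluster distance-to-medoid cost; declare a
# local optimum after `maxneighbor` consecutive non-improving examinations;
# restart `numlocal` times and keep the best local optimum.

#' CLARANS k-medoid clustering
#'
#' @param X numeric matrix, observations in rows (Euclidean metric), or a
#'   precomputed `dist` object.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param numlocal number of restarts.
#' @param maxneighbor non-improving examinations before declaring a local
#'   optimum; default `max(250, ceiling(0.0125 * k * (n - k)))`.
#' @return List with `labels`, `medoids` (row indices), `cost`.
#' @export
clarans_cluster <- function(X, k, seed = 1L, numlocal = 4L,
                            maxneighbor = NULL) {
  D <- if (inherits(X, "dist")) as.matrix(X) else as.matrix(dist(X))
  n <- nrow(D)
  if (k < 2L) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of observations")
  maxneighbor <- maxneighbor %||% max(250L, ceiling(0.0125 * k * (n - k)))
  set.seed(seed)

  cost_of <- function(medoids) sum(apply(D[, medoids, drop = FALSE], 1L, min))

  best_cost <- Inf
  best_medoids <- NULL
  for (rep in seq_len(numlocal)) {
    medoids <- sample.int(n, k)
    current_cost <- cost_of(medoids)
    fails <- 0L
    while (fails < maxneighbor) {
      swap_out <- sample.int(k, 1L)
      candidate <- sample(setdiff(seq_len(n), medoids), 1L)
      trial <- medoids
      trial[swap_out] <- candidate
      trial_cost <- cost_of(trial)
      if (trial_cost < current_cost) {
        medoids <- trial
        current_cost <- trial_cost
        fails <- 0L
      } else {
        fails <- fails + 1L
      }
    }
    if (current_cost < best_cost) {
      best_cost <- current_cost
      best_medoids <- medoids
    }
  }
  labels <- apply(D[, best_medoids, drop = FALSE], 1L, which.min)
  list(labels = as.integer(labels), medoids = best_medoids, cost = best_cost)
}
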