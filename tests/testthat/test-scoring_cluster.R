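# The five-voter scoring network: base algorithms, label alignment,
# majority vote, silhouette-guided k.

test_that("all five algorithms recover far-separated blobs exactly", {
  blobs <- make_blobs(c(20, 20), n_genes = 10, centers_scale = 10, seed = 2)
  base <- run_base_clusterers(blobs$x, k = 2, seed = 2, zscore = FALSE)
  for (r in base$results) {
    expect_equal(adjusted_rand_index(r$labels, blobs$labels), 1,
                 info = r$algorithm)
    expect_false(r$degenerate)
  }
})

test_that("clustering preconditions and determinism hold", {
  blobs <- make_blobs(c(5, 5), n_genes = 6, centers_scale = 8, seed = 3)
  expect_error(run_base_clusterers(blobs$x, k = 10, seed = 1), "smaller")
  expect_error(run_base_clusterers(blobs$x, k = 1, seed = 1), "at least 2")

  a <- run_base_clusterers(blobs$x, k = 2, seed = 7)
  b <- run_base_clusterers(blobs$x, k = 2, seed = 7)
  for (i in 1:5)
    expect_identical(a$results[[i]]$labels, b$results[[i]]$labels)
})

test_that("label alignment maps onto the reference by optimal assignment", {
  # a pure permutation aligns perfectly
  al <- align_labels(list(c(2L, 2L, 1L, 1L), c(1L, 1L, 2L, 2L)),
                     reference_index = 1L)
  expect_identical(al$aligned[, 2L], c(2L, 2L, 1L, 1L))
  # the reference maps by identity
  expect_identical(al$permutations[[1L]], 1:2)

  # brute force over all 3! permutations on random labelings
  perms3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  set.seed(11)
  for (rep in 1:10) {
    ref <- sample(1:3, 30, replace = TRUE)
    lab <- sample(1:3, 30, replace = TRUE)
    al <- align_labels(list(ref, lab), reference_index = 1L)
    got <- sum(al$aligned[, 2L] == ref)
    best <- max(apply(perms3, 1L, function(p) sum(p[lab] == ref)))
    expect_identical(got, as.integer(best))
  }
})

test_that("majority vote counts, agreement and errors follow the contract", {
  f <- matrix(rnorm(20), 10, 2)
  unan <- matrix(2L, 10, 5)
  v <- majority_vote(unan, f, k = 3)
  expect_true(all(v$consensus == 2L))
  expect_true(all(v$agreement == 1))
  expect_true(all(rowSums(v$votes) == 5L))

  mixed <- matrix(c(1L, 1L, 2L, 2L, 2L), 1, 5)
  v1 <- majority_vote(rbind(mixed, mixed), f[1:2, , drop = FALSE], k = 2)
  expect_identical(v1$consensus, c(2L, 2L))
  expect_equal(v1$agreement, c(0.6, 0.6))

  expect_error(majority_vote(unan[, 1:4], f, k = 3), "five voters")
})

test_that("a 2-2-1 tie resolves to the nearest consensus centroid", {
  # nine unambiguous samples anchor three centroids at (0,0), (10,0), (0,10);
  # sample 10 is tied 2-2 between clusters 1 and 2 and sits next to
  # centroid 2, so the vote must fall to cluster 2
  f <- rbind(matrix(rep(c(0, 0), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(10, 0), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(0, 10), 3), 3, 2, byrow = TRUE),
             c(9, 0.5))
  aligned <- rbind(do.call(rbind, lapply(rep(1:3, each = 3), function(c)
                     matrix(c, 1, 5))),
                   matrix(c(1L, 1L, 2L, 2L, 3L), 1, 5))
  storage.mode(aligned) <- "integer"
  v <- majority_vote(aligned, f, k = 3)
  expect_identical(v$consensus[10], 2L)
  expect_true(v$tied[10])
  expect_equal(v$agreement[10], 0.4)

  # same tie placed exactly on centroid 1 falls to cluster 1
  f2 <- f; f2[10, ] <- c(0, 0)
  v2 <- majority_vote(aligned, f2, k = 3)
  expect_identical(v2$consensus[10], 1L)
})

test_that("mean silhouette equals the O(n^2) definition", {
  blobs <- make_blobs(c(5, 5), n_genes = 4, centers_scale = 3, seed = 13)
  f <- t(blobs$x)
  labels <- blobs$labels
  got <- panfuse:::.mean_silhouette(labels, dist(f))

  # direct double-loop oracle
  n <- nrow(f)
  dmat <- as.matrix(dist(f))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    a <- mean(dmat[i, labels == own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), own), function(cl)
      mean(dmat[i, labels == cl]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  expect_equal(got, mean(sil), tolerance = 1e-9)
  expect_true(got >= -1 && got <= 1)
})

test_that("silhouette scan recovers the planted number of subtypes", {
  blobs <- make_blobs(c(15, 15, 15), n_genes = 12, centers_scale = 6,
                      seed = 17)
  rep <- silhouette_select_k(blobs$x, k_candidates = 2:4, seed = 17,
                             zscore = FALSE)
  expect_identical(rep$chosen_k, 3L)
  expect_true(all(rep$mean_silhouette >= -1 & rep$mean_silhouette <= 1))
  expect_error(silhouette_select_k(blobs$x, integer(0)), "empty")
})

test_that("consensus is invariant to sample order (as a partition)", {
  blobs <- make_blobs(c(12, 12, 12), n_genes = 9, centers_scale = 8,
                      seed = 19)
  fit <- consensus_subtypes(blobs$x, k = 3, seed = 19)
  perm <- sample(ncol(blobs$x))
  fit_p <- consensus_subtypes(blobs$x[, perm], k = 3, seed = 19)
  expect_equal(adjusted_rand_index(fit$labels[perm], fit_p$labels), 1)
  expect_true(all(rowSums(fit$votes) == 5L))
  expect_true(all(apply(fit$votes, 1L, max) >= ceiling(5 / 3)))
})

test_that("the full fit is reproducible under its master seed", {
  blobs <- make_blobs(c(10, 10, 10), n_genes = 9, centers_scale = 4,
                      seed = 23)
  a <- consensus_subtypes(blobs$x, k = 3, seed = 23)
  b <- consensus_subtypes(blobs$x, k = 3, seed = 23)
  expect_identical(a$labels, b$labels)
  expect_identical(a$votes, b$votes)
  expect_identical(a$per_algorithm, b$per_algorithm)
})
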