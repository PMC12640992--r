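# The pseudo-label "scoring network": five base clustering algorithms
# (k-means, full-covariance GMM, Ward agglomerative, CLARANS, PAM) run
# under a unified Euclidean metric on samples-as-units, label spaces
# aligned by optimal assignment to a reference, and consensus pseudo-labels
# assigned per sample by majority vote with a nearest-centroid tie-break.

# feature matrix for clustering: samples in rows, selected genes in columns
.cluster_features <- function(x, genes = NULL, top_var = 2000L,
                              zscore = TRUE) {
  validate_expression(x)
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(x))
    if (length(missing_g))
      stop("gene(s) not in expression matrix: ",
           paste(missing_g, collapse = ", "))
    x <- x[genes, , drop = FALSE]
  } else if (nrow(x) > top_var) {
    v <- apply(x, 1L, var)
    x <- x[order(v, decreasing = TRUE)[seq_len(top_var)], , drop = FALSE]
  }
  f <- t(x)
  if (zscore) {
    s <- apply(f, 2L, sd)
    s[s == 0] <- 1  # constant gene: centred to zero, not NaN
    f <- scale(f, center = TRUE, scale = s)
    attr(f, "scaled:center") <- NULL
    attr(f, "scaled:scale") <- NULL
  }
  f
}

.mean_silhouette <- function(labels, D) {
  if (length(unique(labels)) < 2L) return(-Inf)
  sil <- cluster::silhouette(labels, D)
  mean(sil[, "sil_width"])
}

#' Run the five base clustering algorithms
#'
#' All five cluster samples (columns of `x`) on gene features under the
#' Euclidean metric; the Gaussian mixture is the documented exception in
#' that it scores full-covariance Gaussian likelihood rather than raw
#' Euclidean distance. Each algorithm receives a deterministic seed
#' derived from `seed`.
#'
#' @param x genes-by-samples expression matrix.
#' @param k number of clusters (2 <= k < n_samples).
#' @param seed integer master seed.
#' @param zscore per-gene standardisation before clustering (default TRUE).
#' @param genes optional gene subset to cluster on (e.g. a pathway panel);
#'   when absent the `top_var` most variable genes are used.
#' @param top_var number of top-variance genes when `genes` is NULL.
#' @return List with `results` (five per-algorithm lists: `algorithm`,
#'   `labels`, `k`, `seed`, `degenerate`, `converged`), `features`
#'   (samples-by-genes matrix used), `dist` (its Euclidean `dist`).
#' @export
run_base_clusterers <- function(x, k, seed = 1L, zscore = TRUE,
                                genes = NULL, top_var = 2000L) {
  f <- .cluster_features(x, genes, top_var, zscore)
  n <- nrow(f)
  if (k < 2L) stop("k must be at least 2")
  if (k >= n) stop("k (", k, ") must be smaller than the number of samples (",
                   n, ")")
  D <- dist(f)

  res <- vector("list", 5L)
  algs <- c("kmeans", "gmm", "agglomerative", "clarans", "kmedoids")
  for (i in seq_along(algs)) {
    s_i <- derive_seed(seed, 10L + i)
    converged <- TRUE
    lab <- switch(algs[i],
      kmeans = {
        set.seed(s_i)
        km <- kmeans(f, centers = k, nstart = 10L, iter.max = 100L)
        converged <- isTRUE(km$ifault == 0L) || is.null(km$ifault)
        km$cluster
      },
      gmm = {
        fit <- gmm_cluster(f, k, seed = s_i)
        converged <- fit$converged
        fit$labels
      },
      agglomerative = cutree(hclust(D, method = "ward.D2"), k = k),
      clarans = clarans_cluster(D, k, seed = s_i)$labels,
      kmedoids = cluster::pam(D, k = k, diss = TRUE, cluster.only = TRUE)
    )
    lab <- as.integer(unname(lab))
    res[[i]] <- list(algorithm = algs[i], labels = lab, k = as.integer(k),
                     seed = s_i,
                     degenerate = length(unique(lab)) < k,
                     converged = converged)
  }
  list(results = res, features = f, dist = D)
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (sub in .permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
  out
}

# best permutation mapping labels of `lab` onto `ref`, maximising agreement
.best_permutation <- function(lab, ref, k) {
  tab <- table(factor(lab, levels = seq_len(k)),
               factor(ref, levels = seq_len(k)))
  if (k <= 7L) {
    best <- NULL
    best_score <- -1
    for (p in .permutations(k)) {
      score <- sum(tab[cbind(seq_len(k), p)])
      if (score > best_score) {
        best_score <- score
        best <- p
      }
    }
    best
  } else {
    # greedy fallback for large k: repeatedly take the biggest cell
    p <- integer(k)
    t2 <- tab
    for (step in seq_len(k)) {
      cell <- which(t2 == max(t2), arr.ind = TRUE)[1L, ]
      p[cell[1L]] <- cell[2L]
      t2[cell[1L], ] <- -1
      t2[, cell[2L]] <- -1
    }
    p
  }
}

#' Align cluster label spaces to a reference labeling
#'
#' Cluster labels are arbitrary names; before votes can be counted each
#' labeling is relabeled by the permutation of `1..k` that maximises total
#' agreement with the reference labeling (exact optimal assignment on the
#' k-by-k contingency table for k <= 7).
#'
#' @param labelings list of integer label vectors (values in 1..k) over
#'   identical samples.
#' @param reference_index which labeling is the reference (mapped by the
#'   identity).
#' @return List with `aligned` (matrix, samples by labelings) and
#'   `permutations` (list; `perm[[i]][old] = new`).
#' @export
align_labels <- function(labelings, reference_index = 1L) {
  ks <- vapply(labelings, max, integer(1L))
  ns <- lengths(labelings)
  if (length(unique(ns)) != 1L)
    stop("labelings cover different numbers of samples")
  k <- max(ks)
  if (any(vapply(labelings, function(l) any(l < 1L | l > k), logical(1L))))
    stop("labels must lie in 1..k")
  ref <- labelings[[reference_index]]
  perms <- vector("list", length(labelings))
  aligned <- matrix(0L, length(ref), length(labelings))
  for (i in seq_along(labelings)) {
    p <- if (i == reference_index) seq_len(k)
         else .best_permutation(labelings[[i]], ref, k)
    perms[[i]] <- p
    aligned[, i] <- p[labelings[[i]]]
  }
  list(aligned = aligned, permutations = perms)
}

#' Majority-vote consensus pseudo-labels
#'
#' Each sample's consensus label is the mode of its five aligned votes.
#' A vote tie is broken in favour of the tied cluster whose consensus
#' centroid (mean feature vector of samples with an unambiguous majority)
#' is nearest in Euclidean distance; an unresolvable tie falls to the
#' lowest label index.
#'
#' @param aligned samples-by-voters integer matrix of aligned labels (from
#'   [align_labels()]); exactly five voters.
#' @param features samples-by-genes feature matrix used for the
#'   centroid tie-break.
#' @param k number of clusters.
#' @return An object of class `consensus_labeling`: list with `votes`
#'   (samples by k), `consensus`, `agreement` (max votes / 5), `tied`
#'   (logical, tie-break applied).
#' @export
majority_vote <- function(aligned, features, k = max(aligned)) {
  if (ncol(aligned) != 5L)
    stop("the scoring network is defined with exactly five voters; got ",
         ncol(aligned))
  n <- nrow(aligned)
  votes <- t(apply(aligned, 1L, tabulate, nbins = k))
  top <- apply(votes, 1L, max)
  consensus <- integer(n)
  tied <- logical(n)
  unambiguous <- rowSums(votes == top) == 1L
  cons0 <- max.col(votes, ties.method = "first")
  centroids <- matrix(NA_real_, k, ncol(features))
  for (c in seq_len(k)) {
    members <- which(unambiguous & cons0 == c)
    if (length(members))
      centroids[c, ] <- colMeans(features[members, , drop = FALSE])
  }
  for (i in seq_len(n)) {
    cand <- which(votes[i, ] == top[i])
    if (length(cand) == 1L) {
      consensus[i] <- cand
    } else {
      tied[i] <- TRUE
      dd <- vapply(cand, function(c) {
        if (anyNA(centroids[c, ])) Inf
        else sum((features[i, ] - centroids[c, ])^2)
      }, numeric(1L))
      consensus[i] <- cand[which.min(dd)]  # which.min takes lowest index on ties
    }
  }
  structure(list(votes = votes, consensus = consensus,
                 agreement = top / 5, tied = tied, k = k),
            class = "consensus_labeling")
}

# full pipeline on a prepared feature matrix (internal reuse for the k scan)
.consensus_core <- function(f, D, k, seed) {
  n <- nrow(f)
  base <- run_base_clusterers(t(f), k, seed = seed, zscore = FALSE,
                              top_var = ncol(f))
  labelings <- lapply(base$results, `[[`, "labels")
  base_sil <- vapply(labelings, .mean_silhouette, numeric(1L), D = D)
  ref_idx <- which.max(base_sil)
  al <- align_labels(labelings, reference_index = ref_idx)
  vote <- majority_vote(al$aligned, f, k = k)
  list(base = base$results, base_silhouette = base_sil,
       reference_index = ref_idx, alignment = al$permutations,
       vote = vote,
       consensus_silhouette = .mean_silhouette(vote$consensus, D))
}

#' Choose the number of subtypes by mean silhouette of the consensus
#'
#' Runs the full five-voter consensus at every candidate k and picks the
#' k with the highest mean silhouette width (Euclidean); ties go to the
#' smaller k.
#'
#' @inheritParams run_base_clusterers
#' @param k_candidates integer vector of candidate cluster numbers.
#' @return List with `k_candidates`, `mean_silhouette`, `chosen_k`.
#' @export
silhouette_select_k <- function(x, k_candidates = 2:6, seed = 1L,
                                zscore = TRUE, genes = NULL,
                                top_var = 2000L) {
  if (!length(k_candidates)) stop("k_candidates is empty")
  f <- .cluster_features(x, genes, top_var, zscore)
  if (any(k_candidates < 2L) || any(k_candidates >= nrow(f)))
    stop("all k candidates must satisfy 2 <= k < n_samples")
  D <- dist(f)
  sil <- vapply(k_candidates, function(k)
    .consensus_core(f, D, k, seed)$consensus_silhouette, numeric(1L))
  chosen <- k_candidates[order(-sil, k_candidates)[1L]]
  list(k_candidates = as.integer(k_candidates), mean_silhouette = sil,
       chosen_k = as.integer(chosen))
}

#' Consensus molecular subtypes by five-algorithm voting
#'
#' The main subtype-discovery fit: five base clustering algorithms
#' (k-means, full-covariance GMM, Ward agglomerative, CLARANS, PAM) are
#' run on samples under a unified Euclidean metric, their label spaces
#' aligned to the base labeling with the highest mean silhouette, and each
#' sample assigned the majority-vote consensus pseudo-label. When `k` is
#' NULL the number of subtypes is chosen by the silhouette scan over
#' `k_candidates`.
#'
#' @inheritParams run_base_clusterers
#' @param k number of subtypes, or NULL to select by silhouette.
#' @param k_candidates candidates for the silhouette scan when `k` is NULL.
#' @return An object of class `consensus_subtypes` with elements `labels`
#'   (consensus pseudo-label per sample, named), `agreement`, `votes`,
#'   `per_algorithm` (samples by 5 matrix of aligned labels),
#'   `raw_per_algorithm`, `alignment`, `reference_index`, `k`,
#'   `silhouette` (mean silhouette of the consensus),
#'   `silhouette_report` (the k scan, when run), `base` (per-algorithm
#'   metadata), `seed`.
#' @examples
#' sim <- simulate_expression(sim_config(n_samples = 60, n_genes = 40,
#'                                       effect_size = 4, seed = 7))
#' fit <- consensus_subtypes(sim$expr, k = 3, seed = 7)
#' table(fit$labels, sim$labels)
#' @export
consensus_subtypes <- function(x, k = NULL, k_candidates = 2:6, seed = 1L,
                               zscore = TRUE, genes = NULL,
                               top_var = 2000L) {
  f <- .cluster_features(x, genes, top_var, zscore)
  D <- dist(f)
  report <- NULL
  if (is.null(k)) {
    report <- silhouette_select_k(x, k_candidates, seed = seed,
                                  zscore = zscore, genes = genes,
                                  top_var = top_var)
    k <- report$chosen_k
  }
  if (k < 2L) stop("k must be at least 2")
  if (k >= nrow(f)) stop("k must be smaller than the number of samples")
  core <- .consensus_core(f, D, k, seed)
  raw <- vapply(core$base, `[[`, integer(nrow(f)), "labels")
  aligned <- vapply(seq_len(5L), function(i)
    core$alignment[[i]][raw[, i]], integer(nrow(f)))
  colnames(raw) <- colnames(aligned) <-
    vapply(core$base, `[[`, character(1L), "algorithm")
  structure(list(
    labels = setNames(core$vote$consensus, rownames(f)),
    agreement = setNames(core$vote$agreement, rownames(f)),
    votes = core$vote$votes,
    per_algorithm = aligned,
    raw_per_algorithm = raw,
    alignment = core$alignment,
    reference_index = core$reference_index,
    base = lapply(core$base, function(b) b[c("algorithm", "k", "seed",
                                             "degenerate", "converged")]),
    base_silhouette = core$base_silhouette,
    k = as.integer(k),
    silhouette = core$consensus_silhouette,
    silhouette_report = report,
    n_genes_used = ncol(f),
    seed = seed), class = "consensus_subtypes")
}

#' @export
print.consensus_subtypes <- function(x, ...) {
  cat("Consensus subtypes (five-voter scoring network)\n")
  cat("  samples: ", length(x$labels), ", k = ", x$k,
      ", genes used: ", x$n_genes_used, "\n", sep = "")
  cat("  mean silhouette: ", round(x$silhouette, 3), "\n", sep = "")
  cat("  subtype sizes: ",
      paste(tabulate(x$labels, x$k), collapse = " / "), "\n", sep = "")
  cat("  mean voter agreement: ", round(mean(x$agreement), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.consensus_subtypes <- function(object, ...) {
  print(object)
  cat("  per-algorithm mean silhouette:\n")
  for (i in seq_along(object$base))
    cat(sprintf("    %-14s %.3f%s\n", object$base[[i]]$algorithm,
                object$base_silhouette[i],
                if (i == object$reference_index) "  (reference)" else ""))
  if (!is.null(object$silhouette_report)) {
    cat("  silhouette scan:\n")
    with(object$silhouette_report,
         for (j in seq_along(k_candidates))
           cat(sprintf("    k = %d: %.3f%s\n", k_candidates[j],
                       mean_silhouette[j],
                       if (k_candidates[j] == chosen_k) "  (chosen)" else "")))
  }
  invisible(object)
}

#' @export
plot.consensus_subtypes <- function(x, ...) {
  if (!is.null(x$silhouette_report)) {
    rep <- x$silhouette_report
    plot(rep$k_candidates, rep$mean_silhouette, type = "b",
         xlab = "number of subtypes k", ylab = "mean silhouette",
         main = "Consensus silhouette by k", ...)
    abline(v = rep$chosen_k, lty = 2)
  } else {
    graphics::barplot(table(factor(x$agreement,
                                   levels = seq(0.2, 1, by = 0.2))),
                      xlab = "voter agreement", ylab = "samples",
                      main = "Consensus agreement", ...)
  }
  invisible(x)
}
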