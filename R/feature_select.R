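# Dual hub-gene selection: cross-validated L1-regularised (multinomial)
# regression and random-forest permutation importance, intersected. The
# forest is the package's own C++ implementation (no RF package is part
# of this stack); glmnet supplies the penalised path.

.stratified_foldid <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    members <- sample(which(y == cl))
    fold[members] <- rep_len(seq_len(n_folds), length(members))
  }
  fold
}

#' L1-regularised gene selection
#'
#' Cross-validated lasso (binomial for two classes, grouped multinomial
#' otherwise) with stratified folds; the penalty is chosen by the
#' one-standard-error rule (default) or at the CV minimum. A gene is
#' selected if its coefficient is nonzero for any class at the chosen
#' penalty, and selected genes are ordered by the largest absolute
#' coefficient across classes.
#'
#' @param x genes-by-samples expression matrix.
#' @param y class labels (>= 2 classes), one per sample.
#' @param n_folds CV folds (default 10).
#' @param seed integer seed (fold assignment).
#' @param rule `"1se"` or `"min"`.
#' @return List with `genes`, `coefficients` (genes-by-classes matrix at
#'   the chosen penalty), `lambda_choice`, `fit` (the `cv.glmnet` object).
#' @export
lasso_select <- function(x, y, n_folds = 10L, seed = 1L,
                         rule = c("1se", "min")) {
  rule <- match.arg(rule)
  validate_expression(x)
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (ncol(x) < n_folds) stop("more folds than samples")
  set.seed(derive_seed(seed, 3L))
  foldid <- .stratified_foldid(y, n_folds)
  family <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  fit <- glmnet::cv.glmnet(t(x), y, family = family, foldid = foldid,
                           type.multinomial = "grouped")
  lambda <- if (rule == "1se") fit$lambda.1se else fit$lambda.min
  cf <- coef(fit, s = lambda)
  if (family == "binomial") cf <- list(cf)
  beta <- do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1L, 1L]))
  colnames(beta) <- if (family == "binomial") "class2" else levels(y)
  max_abs <- apply(abs(beta), 1L, max)
  genes <- names(sort(max_abs[max_abs > 0], decreasing = TRUE))
  list(genes = genes, coefficients = beta, lambda_choice = lambda,
       fit = fit)
}

#' Random-forest gene ranking by permutation importance
#'
#' Grows a bagged forest of CART trees (Gini splitting, `mtry` features
#' per node) and scores each gene by the mean out-of-bag accuracy drop
#' when that gene is permuted among a tree's OOB samples.
#'
#' @param x genes-by-samples expression matrix.
#' @param y class labels, one per sample.
#' @param n_trees number of trees (>= 100).
#' @param top_n how many top genes to return.
#' @param mtry features tried per split; default `floor(sqrt(n_genes))`.
#' @param min_node minimum node size.
#' @param seed integer seed.
#' @return List with `genes` (top `top_n`, decreasing importance),
#'   `importance` (full named vector), `oob_accuracy`.
#' @export
rf_select <- function(x, y, n_trees = 1000L, top_n = 30L, mtry = NULL,
                      min_node = 5L, seed = 1L) {
  validate_expression(x)
  if (n_trees < 100L) stop("n_trees must be at least 100")
  if (top_n > nrow(x))
    stop("top_n (", top_n, ") exceeds the number of genes (", nrow(x), ")")
  y <- as.factor(y)
  yi <- as.integer(y) - 1L
  mtry <- mtry %||% max(1L, floor(sqrt(nrow(x))))
  set.seed(derive_seed(seed, 4L))
  res <- cpp_class_forest(t(x), yi, nlevels(y), as.integer(n_trees),
                          as.integer(mtry), as.integer(min_node))
  imp <- setNames(res$importance, rownames(x))
  ord <- order(imp, decreasing = TRUE)
  oob_ok <- !is.na(res$oob_pred)
  list(genes = rownames(x)[ord[seq_len(top_n)]],
       importance = imp,
       oob_accuracy = mean(res$oob_pred[oob_ok] == yi[oob_ok]))
}

#' Hub-gene selection by LASSO / random-forest intersection
#'
#' Runs both selectors on the same gene universe and intersects them;
#' the intersection (ordered by forest importance) is the hub-gene set.
#' An empty intersection is allowed with a warning.
#'
#' @inheritParams lasso_select
#' @param n_trees,top_n forest parameters (see [rf_select()]).
#' @param ... passed on to [lasso_select()] (`n_folds`, `rule`).
#' @return An object of class `hub_selection`: `lasso_genes`, `rf_genes`,
#'   `rf_importances`, `lasso_coefficients`, `lambda_choice`,
#'   `intersection`.
#' @export
select_hub_genes <- function(x, y, n_trees = 1000L, top_n = 30L,
                             seed = 1L, ...) {
  las <- lasso_select(x, y, seed = seed, ...)
  rf <- rf_select(x, y, n_trees = n_trees, top_n = top_n, seed = seed)
  inter <- intersect_selections(las$genes, rf$genes, rf$importance)
  structure(list(lasso_genes = las$genes, rf_genes = rf$genes,
                 rf_importances = rf$importance,
                 lasso_coefficients = las$coefficients,
                 lambda_choice = las$lambda_choice,
                 intersection = inter), class = "hub_selection")
}

#' Intersect the two selector gene lists
#'
#' @param lasso_genes,rf_genes character vectors over the same universe.
#' @param rf_importances optional named importances used to order the
#'   intersection (decreasing); otherwise `rf_genes` order is kept.
#' @return Character vector (possibly empty, with a warning).
#' @export
intersect_selections <- function(lasso_genes, rf_genes,
                                 rf_importances = NULL) {
  inter <- intersect(rf_genes, lasso_genes)
  if (!length(inter)) {
    warning("LASSO and random-forest selections do not overlap")
    return(character(0))
  }
  if (!is.null(rf_importances))
    inter <- inter[order(rf_importances[inter], decreasing = TRUE)]
  inter
}

#' @export
print.hub_selection <- function(x, ...) {
  cat("Hub-gene selection (LASSO ∩ random forest)\n")
  cat("  lasso: ", length(x$lasso_genes), " genes (lambda = ",
      signif(x$lambda_choice, 3), ")\n", sep = "")
  cat("  forest top: ", length(x$rf_genes), " genes\n", sep = "")
  cat("  intersection (", length(x$intersection), "): ",
      paste(head(x$intersection, 10L), collapse = ", "),
      if (length(x$intersection) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
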