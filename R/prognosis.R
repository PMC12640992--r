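# Prognostic modelling: univariate Cox screen, random survival forest
# (C++ core, log-rank splitting, permutation importance, OOB error
# trajectory), a proportional-hazards risk function
# f(t|x) = f0(t) * exp(sum coef_i * gene_i) whose coefficients come from
# a multivariable Cox fit on the forest's top genes, stratification at
# the maximally selected rank-statistic cutoff, and Kaplan-Meier curves.

.join_expr_surv <- function(x, surv) {
  surv <- validate_survival(surv)
  common <- intersect(colnames(x), surv$sample_id)
  if (!length(common))
    stop("expression and survival tables share no samples")
  list(x = x[, common, drop = FALSE],
       surv = surv[match(common, surv$sample_id), ])
}

#' Univariate Cox screen over genes
#'
#' Per-gene proportional-hazards fit (Efron ties); genes with Wald
#' p < `alpha` are flagged significant. Constant genes yield an NA row
#' and are excluded from significance.
#'
#' @param x genes-by-samples expression matrix.
#' @param surv survival table (`sample_id`, `time`, `event`).
#' @param alpha significance level (default 0.05).
#' @return A data.frame of class `cox_screen` with columns `gene`, `coef`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `significant`.
#' @export
cox_screen <- function(x, surv, alpha = 0.05) {
  validate_expression(x)
  js <- .join_expr_surv(x, surv)
  x <- js$x; surv <- js$surv
  if (sum(surv$event) < 10L)
    stop("fewer than 10 events: the screen is not informative")
  ss <- survival::Surv(surv$time, surv$event)
  rows <- lapply(rownames(x), function(g) {
    v <- x[g, ]
    if (sd(v) == 0)
      return(data.frame(gene = g, coef = NA_real_, hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        significant = FALSE))
    fit <- survival::coxph(ss ~ v, ties = "efron")
    sm <- summary(fit)
    data.frame(gene = g, coef = unname(coef(fit)),
               hr = unname(sm$conf.int[1L, "exp(coef)"]),
               ci_low = unname(sm$conf.int[1L, "lower .95"]),
               ci_high = unname(sm$conf.int[1L, "upper .95"]),
               p = unname(sm$coefficients[1L, "Pr(>|z|)"]),
               significant = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  class(out) <- c("cox_screen", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Random survival forest
#'
#' Bagged survival trees split by the standardised log-rank statistic over
#' random candidate cutpoints; terminal nodes carry Nelson-Aalen
#' cumulative hazards on the cohort's event-time grid, and a sample's
#' predicted mortality is the sum of its ensemble CHF over that grid.
#' Out-of-bag error (1 - Harrell concordance of OOB mortality) is
#' recorded every `checkpoint_every` trees; the plateau flag is set when
#' the error range over the last quarter of checkpoints falls below
#' `plateau_tol`. Gene importance is the mean per-tree OOB concordance
#' drop under permutation.
#'
#' @param x genes-by-samples matrix (typically restricted to screened
#'   genes).
#' @param surv survival table.
#' @param n_trees number of trees.
#' @param mtry features tried per node; default `ceiling(sqrt(n_genes))`.
#' @param min_node minimum samples per daughter node.
#' @param nsplit random candidate cutpoints per feature per node.
#' @param checkpoint_every OOB-error checkpoint spacing in trees.
#' @param plateau_tol error range defining the plateau.
#' @param horizons time horizons for the truncated concordance trace;
#'   default quartiles of observed event times.
#' @param seed integer seed.
#' @return An object of class `rsf`: `importance` (named, decreasing),
#'   `oob_error` (data.frame trees/error), `plateau`, `oob_mortality`
#'   (named per sample), `cindex` (OOB), `cindex_time` (data.frame
#'   horizon/cindex), `n_trees`.
#' @export
rsf_fit <- function(x, surv, n_trees = 1000L, mtry = NULL, min_node = 15L,
                    nsplit = 10L, checkpoint_every = 25L,
                    plateau_tol = 0.02, horizons = NULL, seed = 1L) {
  validate_expression(x)
  if (nrow(x) < 2L) stop("need at least 2 genes for the survival forest")
  js <- .join_expr_surv(x, surv)
  x <- js$x; surv <- js$surv
  if (sum(surv$event) == 0L) stop("all samples censored")
  if (sum(surv$event) < 10L)
    stop("fewer than 10 events: forest would be unstable")
  mtry <- mtry %||% max(1L, ceiling(sqrt(nrow(x))))
  set.seed(derive_seed(seed, 5L))
  res <- cpp_surv_forest(t(x), surv$time, as.integer(surv$event),
                         as.integer(n_trees), as.integer(mtry),
                         as.integer(min_node), as.integer(nsplit),
                         as.integer(checkpoint_every))
  imp <- sort(setNames(res$importance, rownames(x)), decreasing = TRUE)
  err <- data.frame(trees = res$oob_trees, error = res$oob_error)
  tail_q <- err$error[err$trees > max(err$trees) * 0.75]
  plateau <- length(tail_q) >= 2L && diff(range(tail_q)) < plateau_tol
  mort <- setNames(res$oob_mortality, colnames(x))
  ok <- !is.na(mort)
  horizons <- horizons %||%
    unname(quantile(surv$time[surv$event == 1L], c(0.25, 0.5, 0.75, 1)))
  ct <- vapply(horizons, function(h)
    cindex_truncated(mort[ok], surv[ok, ], horizon = h), numeric(1L))
  structure(list(importance = imp,
                 oob_error = err, plateau = plateau,
                 oob_mortality = mort,
                 cindex = 1 - err$error[nrow(err)],
                 cindex_time = data.frame(horizon = horizons, cindex = ct),
                 n_trees = as.integer(n_trees), seed = seed),
            class = "rsf")
}

#' @export
print.rsf <- function(x, ...) {
  cat("Random survival forest: ", x$n_trees, " trees\n", sep = "")
  cat(sprintf("  OOB C-index %.3f (error %.3f), plateau: %s\n",
              x$cindex, 1 - x$cindex, x$plateau))
  cat("  top genes: ",
      paste(head(names(x$importance), 5L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Harrell concordance index
#'
#' Fraction of usable sample pairs whose risk ordering matches survival
#' ordering: a pair is usable when the smaller observed time is an event
#' (or the times are tied with exactly one event); score ties count 1/2.
#'
#' @param scores numeric risk scores (higher = worse).
#' @param surv survival table over the same samples, in order.
#' @return A number in `[0, 1]`; error if no pair is comparable.
#' @export
cindex <- function(scores, surv) {
  surv <- validate_survival(surv)
  if (length(scores) != nrow(surv))
    stop("scores and survival table differ in length")
  cpp_harrell_c(as.numeric(scores), surv$time, as.integer(surv$event))
}

#' Concordance truncated at a horizon
#'
#' Same statistic as [cindex()] but only pairs whose earlier (event) time
#' falls at or before `horizon` are usable — the "C-index over time" view.
#'
#' @inheritParams cindex
#' @param horizon follow-up truncation time.
#' @return A number in `[0, 1]`, or NA when no pair is usable by then.
#' @export
cindex_truncated <- function(scores, surv, horizon) {
  surv <- validate_survival(surv)
  n <- nrow(surv)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ii <- i; jj <- j
    if (surv$time[jj] < surv$time[ii]) { ii <- j; jj <- i }
    else if (surv$time[ii] == surv$time[jj]) {
      if (surv$event[i] + surv$event[j] != 1L) next
      ii <- if (surv$event[i] == 1L) i else j
      jj <- if (surv$event[i] == 1L) j else i
    }
    if (surv$event[ii] != 1L || surv$time[ii] > horizon) next
    usable <- usable + 1
    if (scores[ii] > scores[jj]) conc <- conc + 1
    else if (scores[ii] == scores[jj]) conc <- conc + 0.5
  }
  if (usable == 0) return(NA_real_)
  conc / usable
}

#' Risk scores from a fitted risk model
#'
#' The time-free factor of the risk function: `exp(sum coef_i * gene_i)`.
#' The full `f(t|x)` follows by composing with the model's baseline
#' cumulative hazard (see `baseline` element of [fit_risk_model()]).
#'
#' @param model a `risk_model` (or any list with `genes` and `coefs`).
#' @param x genes-by-samples matrix containing every model gene.
#' @return Named numeric vector of per-sample scores.
#' @export
risk_score <- function(model, x) {
  validate_expression(x)
  missing_g <- setdiff(model$genes, rownames(x))
  if (length(missing_g))
    stop("model gene(s) missing from expression: ",
         paste(missing_g, collapse = ", "))
  lp <- drop(crossprod(x[model$genes, , drop = FALSE], model$coefs))
  setNames(exp(lp), colnames(x))
}

# standardized two-group log-rank statistic; grp is logical (TRUE = high)
.logrank_z <- function(grp, time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; grp <- grp[ord]
  n <- length(time)
  U <- 0; V <- 0
  i <- 1L
  Y <- n; Y1 <- sum(grp)
  while (i <= n) {
    j <- i
    d <- 0; d1 <- 0; drop_all <- 0; drop1 <- 0
    tt <- time[i]
    while (j <= n && time[j] == tt) {
      if (event[j] == 1L) { d <- d + 1; d1 <- d1 + grp[j] }
      drop_all <- drop_all + 1; drop1 <- drop1 + grp[j]
      j <- j + 1L
    }
    if (d > 0 && Y > 1) {
      U <- U + (d1 - d * Y1 / Y)
      V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
    }
    Y <- Y - drop_all; Y1 <- Y1 - drop1
    i <- j
  }
  if (V <= 0) return(0)
  U / sqrt(V)
}

#' Maximally selected rank-statistic cutoff
#'
#' Scans every admissible cutpoint (midpoints of consecutive sorted
#' unique scores leaving at least `min_prop` of samples in each group)
#' and returns the one maximising the absolute standardised log-rank
#' statistic between the two induced groups. This selects a
#' stratification threshold; the selection is not a calibrated test.
#'
#' @param scores numeric risk scores.
#' @param surv survival table over the same samples, in order.
#' @param min_prop minimum group proportion (default 0.1).
#' @return List with `cutoff`, `statistic` (the max |z|), `candidates`
#'   (data.frame cutoff/statistic for every admissible cutpoint).
#' @export
maxstat_cutoff <- function(scores, surv, min_prop = 0.1) {
  surv <- validate_survival(surv)
  if (length(scores) != nrow(surv))
    stop("scores and survival table differ in length")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("scores are constant: no cutoff exists")
  mids <- (u[-length(u)] + u[-1L]) / 2
  n <- length(scores)
  n_min <- ceiling(min_prop * n)
  admissible <- vapply(mids, function(m) {
    hi <- sum(scores > m)
    hi >= n_min && (n - hi) >= n_min
  }, logical(1L))
  mids <- mids[admissible]
  if (!length(mids)) stop("no admissible cutpoint keeps both groups at ",
                          min_prop, " of samples")
  z <- vapply(mids, function(m)
    abs(.logrank_z(scores > m, surv$time, surv$event)), numeric(1L))
  best <- which.max(z)
  list(cutoff = mids[best], statistic = z[best],
       candidates = data.frame(cutoff = mids, statistic = z))
}

#' Kaplan-Meier stratification at a cutoff
#'
#' Splits samples into high (`score > cutoff`) and low risk groups,
#' estimates product-limit survival per group and tests the difference by
#' the two-group log-rank test. When the cutoff was chosen by
#' [maxstat_cutoff()] the p-value is post-selection and should be read as
#' descriptive.
#'
#' @param scores numeric risk scores (named or in `surv` order).
#' @param cutoff stratification threshold.
#' @param surv survival table over the same samples, in order.
#' @return An object of class `risk_stratification`: `table` (sample_id,
#'   score, group), `cutoff`, `logrank_p`, `logrank_chisq`, `km`
#'   (a `survfit` object), `curves` (per-group data.frames time/surv).
#' @export
km_stratify <- function(scores, cutoff, surv) {
  surv <- validate_survival(surv)
  if (length(scores) != nrow(surv))
    stop("scores and survival table differ in length")
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L))
    stop("a risk group is empty at cutoff ", cutoff)
  df <- data.frame(time = surv$time, event = surv$event, group = group)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  strata_names <- rep(names(km$strata), km$strata)
  curves <- lapply(split(data.frame(time = km$time, surv = km$surv,
                                    n_risk = km$n.risk, n_event = km$n.event),
                         strata_names), identity)
  structure(list(table = data.frame(sample_id = surv$sample_id,
                                    score = as.numeric(scores),
                                    group = as.character(group)),
                 cutoff = cutoff, logrank_p = p,
                 logrank_chisq = unname(sd_$chisq),
                 km = km, curves = curves),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  tab <- table(x$table$group)
  cat("Risk stratification at cutoff ", signif(x$cutoff, 4), "\n", sep = "")
  cat("  high: ", tab[["high"]], "  low: ", tab[["low"]], "\n", sep = "")
  cat(sprintf("  log-rank chisq %.2f, p = %.3g (post-selection)\n",
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' Fit the full prognostic risk model
#'
#' The screen-forest-score chain: (1) univariate Cox screen keeps genes
#' with p < `screen_alpha`; (2) a random survival forest over the
#' screened genes ranks them by permutation importance; (3) the top
#' `top_m` genes enter a multivariable Cox fit whose coefficients define
#' the risk function `f(t|x) = f0(t) * exp(sum coef_i * gene_i)` with a
#' Breslow baseline cumulative hazard; (4) training scores `exp(lp)` are
#' stratified at the maximally selected rank-statistic cutoff.
#'
#' @param x genes-by-samples expression matrix.
#' @param surv survival table.
#' @param screen_alpha univariate screen level (default 0.05).
#' @param top_m genes entering the final model (default 9).
#' @param n_trees forest size.
#' @param min_prop minimum group proportion for the cutoff scan.
#' @param seed integer seed.
#' @param ... passed to [rsf_fit()].
#' @return An object of class `risk_model`: `genes`, `coefs`, `baseline`
#'   (data.frame time/cumhaz, Breslow), `cutoff`, `importance`, `screen`,
#'   `rsf`, `scores` (training), `stratification`, `cindex` (training),
#'   `cox_fit`.
#' @export
fit_risk_model <- function(x, surv, screen_alpha = 0.05, top_m = 9L,
                           n_trees = 1000L, min_prop = 0.1, seed = 1L,
                           ...) {
  js <- .join_expr_surv(x, surv)
  x <- js$x; surv <- js$surv
  screen <- cox_screen(x, surv, alpha = screen_alpha)
  sig <- screen$gene[screen$significant]
  if (length(sig) < 2L)
    stop("fewer than 2 genes pass the univariate screen")
  forest <- rsf_fit(x[sig, , drop = FALSE], surv, n_trees = n_trees,
                    seed = seed, ...)
  top_m <- min(top_m, length(sig))
  genes <- names(forest$importance)[seq_len(top_m)]

  dfx <- as.data.frame(t(x[genes, , drop = FALSE]))
  dfx$time <- surv$time; dfx$event <- surv$event
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", genes),
                                       collapse = " + ")))
  cox_fit <- survival::coxph(fml, data = dfx, ties = "efron")
  coefs <- setNames(unname(coef(cox_fit)), genes)
  bh <- survival::basehaz(cox_fit, centered = FALSE)
  baseline <- data.frame(time = bh$time, cumhaz = bh$hazard)

  model <- list(genes = genes, coefs = coefs, baseline = baseline)
  scores <- risk_score(model, x)
  cut <- maxstat_cutoff(scores, surv, min_prop = min_prop)
  strat <- km_stratify(scores, cut$cutoff, surv)
  structure(c(model, list(
    cutoff = cut$cutoff, cutoff_statistic = cut$statistic,
    importance = forest$importance, screen = screen, rsf = forest,
    scores = scores, stratification = strat,
    cindex = cindex(scores, surv), cox_fit = cox_fit, seed = seed)),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Prognostic risk model: f(t|x) = f0(t) * exp(sum coef_i * gene_i)\n")
  cat("  genes (", length(x$genes), "): ",
      paste(x$genes, collapse = ", "), "\n", sep = "")
  cat("  training C-index: ", round(x$cindex, 3),
      ";  cutoff: ", signif(x$cutoff, 4), "\n", sep = "")
  cat(sprintf("  stratification log-rank p = %.3g (post-selection)\n",
              x$stratification$logrank_p))
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  print(object)
  cat("  coefficients:\n")
  for (g in object$genes)
    cat(sprintf("    %-10s coef %+.3f  HR %.3f\n", g, object$coefs[g],
                exp(object$coefs[g])))
  cat("  forest OOB C-index: ", round(object$rsf$cindex, 3),
      "; plateau: ", object$rsf$plateau, "\n", sep = "")
  invisible(object)
}

#' @export
coef.risk_model <- function(object, ...) object$coefs

#' Predict risk for new samples
#'
#' @param object a fitted `risk_model`.
#' @param newdata genes-by-samples matrix with every model gene.
#' @param type `"score"` (`exp(lp)`), `"group"` (high/low at the trained
#'   cutoff), or `"cumhaz"` (matrix of per-sample cumulative hazard
#'   `H0(t) * score` over the baseline grid).
#' @param ... unused.
#' @export
predict.risk_model <- function(object, newdata,
                               type = c("score", "group", "cumhaz"), ...) {
  type <- match.arg(type)
  s <- risk_score(object, newdata)
  switch(type,
    score = s,
    group = setNames(ifelse(s > object$cutoff, "high", "low"), names(s)),
    cumhaz = outer(object$baseline$cumhaz, s))
}

#' @export
plot.risk_model <- function(x, ...) {
  plot(x$stratification$km, col = c("darkblue", "firebrick"),
       xlab = "time", ylab = "survival probability",
       main = "Risk-group Kaplan-Meier", ...)
  legend("bottomleft", c("low risk", "high risk"),
         col = c("darkblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
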