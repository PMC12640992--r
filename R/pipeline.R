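# End-to-end orchestration: (simulate | load) -> consensus clustering ->
# cross-fusion classifier -> hub-gene selection -> prognosis, driven by
# one JSON config and one master seed that fans out to per-stage seeds.
# Every stage writes its outputs before the next starts, so a failure
# retains partial results; the run manifest records the config snapshot,
# seeds, input digests and produced files.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.read_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  known <- c("data", "simulate", "cluster", "classifier", "select",
             "prognosis", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  if (is.null(config$data) && is.null(config$simulate))
    stop("config needs either a 'data' or a 'simulate' block")
  config
}

#' Run the full subtype-and-prognosis pipeline
#'
#' Stages, in order: data (load TSVs or simulate), cluster (consensus
#' pseudo-labels, always run), classifier, select and prognosis (each run
#' when its block is present; a missing block skips the stage with a
#' logged notice). Any stage failure halts with a stage-named error;
#' outputs already written are retained.
#'
#' Config blocks (JSON file or R list): `simulate` (any [sim_config()]
#' field) or `data` (`expr`, optional `surv`, optional `orientation`);
#' `cluster` (`k` or `k_candidates`, `zscore`, `genes`, `top_var`);
#' `classifier` (`test_frac` plus any [crossfusion_config()] field);
#' `select` (`n_trees`, `top_n`); `prognosis` (`screen_alpha`, `top_m`,
#' `n_trees`, `min_prop`). A top-level `seed` is overridden by the
#' `seed` argument when given.
#'
#' @param config JSON path or list.
#' @param out_dir output directory.
#' @param seed master seed (fans out per stage via [derive_seed()]).
#' @return Invisibly, a list with the fitted objects (`subtypes`,
#'   `classifier`, `selection`, `risk_model`) and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- .read_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg)
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  cat("", file = log_path)

  manifest <- list(config = config, master_seed = seed,
                   stage_seeds = list(), inputs = list(), outputs = list())
  results <- list()

  # ---- data ----
  surv <- NULL
  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, c(config$simulate,
                                list(seed = derive_seed(seed, 100L))))
    manifest$stage_seeds$data <- sc$seed
    sim <- .stage("data", simulate_dataset(sc, out_dir))
    x <- sim$expr; surv <- sim$surv
    manifest$outputs$data <- c("expr.tsv", "truth_labels.tsv", "surv.tsv",
                               "manifest.json")
    logf("data", sprintf("simulated %d genes x %d samples, k = %d",
                         nrow(x), ncol(x), sc$k_subtypes))
  } else {
    d <- config$data
    x <- .stage("data", load_expression(
      d$expr, orientation = d$orientation %||% "genes_by_samples"))
    manifest$inputs$expr <- unname(tools::md5sum(d$expr))
    if (!is.null(d$surv)) {
      surv <- .stage("data", load_survival(d$surv))
      manifest$inputs$surv <- unname(tools::md5sum(d$surv))
    }
    logf("data", sprintf("loaded %d genes x %d samples", nrow(x), ncol(x)))
  }

  # ---- cluster (always) ----
  cl <- config$cluster %||% list()
  seed_cl <- derive_seed(seed, 200L)
  manifest$stage_seeds$cluster <- seed_cl
  subtypes <- .stage("cluster", consensus_subtypes(
    x, k = cl$k, k_candidates = cl$k_candidates %||% 2:6,
    seed = seed_cl, zscore = cl$zscore %||% TRUE,
    genes = cl$genes, top_var = cl$top_var %||% 2000L))
  lab_df <- data.frame(sample_id = names(subtypes$labels),
                       consensus = unname(subtypes$labels),
                       agreement = unname(subtypes$agreement),
                       subtypes$per_algorithm)
  write_labels(lab_df, file.path(out_dir, "labels.tsv"))
  if (!is.null(subtypes$silhouette_report))
    write.table(with(subtypes$silhouette_report,
                     data.frame(k = k_candidates,
                                mean_silhouette = mean_silhouette)),
                file.path(out_dir, "silhouette.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  manifest$outputs$cluster <- c("labels.tsv",
                                if (!is.null(subtypes$silhouette_report))
                                  "silhouette.tsv")
  results$subtypes <- subtypes
  logf("cluster", sprintf("k = %d, mean silhouette %.3f", subtypes$k,
                          subtypes$silhouette))

  # ---- classifier ----
  if (!is.null(config$classifier)) {
    cc <- config$classifier
    seed_cf <- derive_seed(seed, 300L)
    manifest$stage_seeds$classifier <- seed_cf
    res_cf <- .stage("classifier", {
      set.seed(seed_cf)
      test_idx <- stratified_split(subtypes$labels,
                                   cc$test_frac %||% 0.2)
      tr_idx <- setdiff(seq_len(ncol(x)), test_idx)
      cfg_fields <- setdiff(names(cc), "test_frac")
      cfg <- do.call(crossfusion_config,
                     c(list(n_genes = nrow(x), k_classes = subtypes$k),
                       cc[cfg_fields]))
      fit <- crossfusion(x[, tr_idx, drop = FALSE],
                         subtypes$labels[tr_idx], config = cfg,
                         seed = seed_cf)
      ev <- evaluate_classifier(fit, x[, test_idx, drop = FALSE],
                                subtypes$labels[test_idx])
      probs <- predict(fit, x, type = "prob")
      write.table(data.frame(sample_id = colnames(x), probs,
                             predicted = max.col(probs, "first"),
                             check.names = FALSE),
                  file.path(out_dir, "probs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(fit$history, file.path(out_dir, "history.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      metrics <- data.frame(metric = c("test_accuracy",
                                       names(ev$auc)),
                            value = c(ev$accuracy, unname(ev$auc)))
      write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      saveRDS(fit, file.path(out_dir, "model.rds"))
      list(fit = fit, eval = ev, test_idx = test_idx)
    })
    manifest$outputs$classifier <- c("probs.tsv", "history.tsv",
                                     "metrics.tsv", "model.rds")
    results$classifier <- res_cf$fit
    results$classifier_eval <- res_cf$eval
    logf("classifier", sprintf("test accuracy %.3f", res_cf$eval$accuracy))
  } else logf("classifier", "skipped (no config block)")

  # ---- select ----
  if (!is.null(config$select)) {
    sl <- config$select
    seed_sel <- derive_seed(seed, 400L)
    manifest$stage_seeds$select <- seed_sel
    selection <- .stage("select", select_hub_genes(
      x, subtypes$labels, n_trees = sl$n_trees %||% 1000L,
      top_n = sl$top_n %||% 30L, seed = seed_sel))
    sel_df <- data.frame(
      gene = rownames(x),
      lasso_coef = apply(abs(selection$lasso_coefficients), 1L, max),
      rf_importance = selection$rf_importances[rownames(x)],
      in_intersection = rownames(x) %in% selection$intersection)
    write.table(sel_df, file.path(out_dir, "selection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$outputs$select <- "selection.tsv"
    results$selection <- selection
    logf("select", sprintf("%d hub genes", length(selection$intersection)))
  } else logf("select", "skipped (no config block)")

  # ---- prognosis ----
  if (!is.null(config$prognosis) && !is.null(surv)) {
    pg <- config$prognosis
    seed_pg <- derive_seed(seed, 500L)
    manifest$stage_seeds$prognosis <- seed_pg
    rm_ <- .stage("prognosis", fit_risk_model(
      x, surv, screen_alpha = pg$screen_alpha %||% 0.05,
      top_m = pg$top_m %||% 9L, n_trees = pg$n_trees %||% 1000L,
      min_prop = pg$min_prop %||% 0.1, seed = seed_pg))
    write.table(rm_$screen, file.path(out_dir, "screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = names(rm_$importance),
                           importance = unname(rm_$importance)),
                file.path(out_dir, "importance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(genes = rm_$genes,
                              coefs = unname(rm_$coefs),
                              cutoff = rm_$cutoff,
                              baseline = rm_$baseline),
                         file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(rm_$stratification$table, file.path(out_dir, "scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(rm_$stratification$curves))
      write.table(rm_$stratification$curves[[g]],
                  file.path(out_dir, paste0("km_", sub("^group=", "", g),
                                            ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$prognosis <- c("screen.tsv", "importance.tsv",
                                    "model.json", "scores.tsv")
    results$risk_model <- rm_
    logf("prognosis", sprintf("C-index %.3f, cutoff %.4g", rm_$cindex,
                              rm_$cutoff))
  } else logf("prognosis",
              if (is.null(surv)) "skipped (no survival data)"
              else "skipped (no config block)")

  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
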