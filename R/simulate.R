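# Synthetic bulk-expression and survival generator. The stated world:
# k latent subtypes as Gaussian mean shifts on disjoint blocks of
# informative genes over unit-variance noise, and survival times drawn
# from an exponential proportional-hazards model on a linear risk score
# with independent uniform censoring calibrated to a target rate.

#' Simulation configuration
#'
#' Defaults describe the reference synthetic world used throughout the
#' package's tests: 300 samples by 200 genes, three balanced subtypes,
#' 40 informative genes shifted by 3 noise-SD units, exponential survival
#' on a time scale of days (baseline rate 0.001/day, i.e. mean ~1000 days)
#' with 30% censoring.
#'
#' @param n_samples,n_genes,k_subtypes,n_informative integers.
#' @param effect_size subtype mean shift in units of the noise SD.
#' @param mixing subtype proportions (length `k_subtypes`, sums to 1);
#'   default balanced.
#' @param surv_coefs named numeric vector of per-gene log-hazard
#'   coefficients for [simulate_survival()]; default `log(2)` on the first
#'   three informative genes.
#' @param censor_rate target censoring fraction in `[0, 1)`.
#' @param baseline_rate baseline exponential event rate (> 0), per day.
#' @param seed integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_genes = 200L, k_subtypes = 3L,
                       n_informative = 40L, effect_size = 3,
                       mixing = NULL, surv_coefs = NULL,
                       censor_rate = 0.3, baseline_rate = 0.001,
                       seed = 1L) {
  if (k_subtypes < 2L) stop("k_subtypes must be at least 2")
  if (n_informative > n_genes) stop("n_informative exceeds n_genes")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  mixing <- mixing %||% rep(1 / k_subtypes, k_subtypes)
  if (length(mixing) != k_subtypes || abs(sum(mixing) - 1) > 1e-9)
    stop("mixing must have length k_subtypes and sum to 1")
  if (is.null(surv_coefs)) {
    # default prognostic genes sit outside the subtype-informative block
    # (pure noise genes), so survival effects are not confounded with the
    # planted subtype shifts
    n_prog <- min(3L, n_genes - n_informative)
    gn <- if (n_prog > 0L) sprintf("g%04d", n_genes - seq_len(n_prog) + 1L)
          else character(0)
    surv_coefs <- setNames(rep(log(2), length(gn)), gn)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 k_subtypes = as.integer(k_subtypes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, mixing = mixing,
                 surv_coefs = surv_coefs, censor_rate = censor_rate,
                 baseline_rate = baseline_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an expression matrix with planted subtypes
#'
#' Informative genes are assigned round-robin to subtypes; a gene assigned
#' to subtype s has mean `effect_size` in samples of subtype s and 0
#' elsewhere (orthogonal block shift patterns, so pairwise subtype
#' separation grows with `effect_size`). All other genes are standard
#' Gaussian noise. Genes are `g0001...`, samples `s0001...`.
#'
#' @param config a [sim_config()] object.
#' @return List with `expr` (genes-by-samples matrix), `labels` (integer
#'   subtype 1..k per sample, named by sample), and `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n_samples; p <- config$n_genes; k <- config$k_subtypes
  labels <- sample(seq_len(k), n, replace = TRUE, prob = config$mixing)
  # guarantee every subtype occupied
  for (s in seq_len(k)) if (!any(labels == s)) labels[s] <- s

  genes <- sprintf("g%04d", seq_len(p))
  samples <- sprintf("s%04d", seq_len(n))
  x <- matrix(rnorm(p * n), p, n, dimnames = list(genes, samples))
  info <- seq_len(config$n_informative)
  block <- ((info - 1L) %% k) + 1L           # round-robin gene -> subtype
  for (j in seq_along(info)) {
    hit <- labels == block[j]
    x[info[j], hit] <- x[info[j], hit] + config$effect_size
  }
  list(expr = x, labels = setNames(as.integer(labels), samples),
       config = config)
}

#' Simulate survival outcomes linked to expression
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum(coef * expression))` per sample (a
#' proportional-hazards world), and censoring times are uniform on
#' `(0, u)` with `u` calibrated by root finding so the expected censoring
#' fraction matches `censor_rate`.
#'
#' @param x genes-by-samples expression matrix.
#' @param prognostic_genes character vector of genes carrying effects.
#' @param surv_coefs numeric vector of log-hazard coefficients, one per
#'   prognostic gene.
#' @param baseline_rate baseline exponential rate (> 0).
#' @param censor_rate target censoring fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return A survival `data.frame` (`sample_id`, `time`, `event`).
#' @export
simulate_survival <- function(x, prognostic_genes, surv_coefs,
                              baseline_rate = 0.001, censor_rate = 0.3,
                              seed = 1L) {
  validate_expression(x)
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  missing_g <- setdiff(prognostic_genes, rownames(x))
  if (length(missing_g))
    stop("prognostic gene(s) absent from expression: ",
         paste(missing_g, collapse = ", "))
  if (length(surv_coefs) != length(prognostic_genes))
    stop("surv_coefs and prognostic_genes differ in length")

  set.seed(derive_seed(seed, 1L))
  lp <- if (length(prognostic_genes))
    drop(crossprod(x[prognostic_genes, , drop = FALSE], surv_coefs))
  else rep(0, ncol(x))
  rate <- baseline_rate * exp(lp)
  t_event <- rexp(ncol(x), rate = rate)

  if (censor_rate == 0) {
    time <- t_event
    event <- rep(1L, ncol(x))
  } else {
    # P(C < t) for C ~ U(0, u) is min(t/u, 1); calibrate u on the drawn times
    f <- function(u) mean(pmin(t_event / u, 1)) - censor_rate
    u_hi <- max(t_event) / censor_rate + 1
    u <- uniroot(f, lower = min(t_event) * 1e-6 + 1e-12, upper = u_hi,
                 tol = 1e-8)$root
    c_time <- runif(ncol(x), 0, u)
    event <- as.integer(t_event <= c_time)
    time <- pmin(t_event, c_time)
  }
  data.frame(sample_id = colnames(x), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Run the full generator and write a reconstructible fixture directory
#'
#' Writes `expr.tsv`, `truth_labels.tsv`, `surv.tsv` and a `manifest.json`
#' echoing every generator parameter, so any fixture can be rebuilt from
#' its manifest alone.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list returned by [simulate_expression()] plus
#'   `surv`.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config)
  surv <- simulate_survival(sim$expr, names(config$surv_coefs),
                            unname(config$surv_coefs),
                            baseline_rate = config$baseline_rate,
                            censor_rate = config$censor_rate,
                            seed = config$seed)
  save_expression(sim$expr, file.path(out_dir, "expr.tsv"))
  write_labels(data.frame(sample_id = names(sim$labels),
                          label = unname(sim$labels)),
               file.path(out_dir, "truth_labels.tsv"))
  save_survival(surv, file.path(out_dir, "surv.tsv"))
  jsonlite::write_json(unclass(config), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(surv = surv)))
}
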