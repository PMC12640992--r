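# Cox screen, survival forest, risk function, maxstat cutoff, KM and
# concordance.

test_that("the Cox screen flags effects and handles degenerate genes", {
  sim <- simulate_expression(sim_config(n_samples = 300, n_genes = 20,
                                        n_informative = 0, seed = 31))
  x <- sim$expr
  x["g0020", ] <- 3
  surv <- simulate_survival(x, "g0001", log(2), baseline_rate = 0.01,
                            censor_rate = 0.2, seed = 31)
  scr <- cox_screen(x, surv)
  expect_true(scr$significant[scr$gene == "g0001"])
  row20 <- scr[scr$gene == "g0020", ]
  expect_true(is.na(row20$coef) && !row20$significant)
  expect_equal(scr$hr, exp(scr$coef), tolerance = 1e-12)

  bad <- surv; bad$sample_id <- paste0("zz", seq_len(nrow(bad)))
  expect_error(cox_screen(x, bad), "share no samples")
})

test_that("risk scores follow the printed exponential form exactly", {
  x <- matrix(c(1, 0, 2, 1), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  m0 <- list(genes = c("gA", "gB"), coefs = c(gA = 0, gB = 0))
  expect_equal(unname(risk_score(m0, x)), c(1, 1))

  m1 <- list(genes = "gA", coefs = c(gA = log(2)))
  s <- risk_score(m1, x)
  expect_equal(unname(s["s1"] / s["s2"]), 2 ^ (1 - 2))
  x2 <- x; x2["gA", ] <- c(1, 0)
  expect_equal(unname(risk_score(m1, x2)), c(2, 1))

  # dot-product-then-exponentiate oracle on random fixtures
  set.seed(33)
  for (rep in 1:5) {
    p <- 6; n <- 9
    xr <- matrix(rnorm(p * n), p, n,
                 dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
    cf <- rnorm(p)
    m <- list(genes = paste0("g", 1:p), coefs = setNames(cf, paste0("g", 1:p)))
    want <- exp(as.numeric(t(xr) %*% cf))
    expect_equal(unname(risk_score(m, xr)), want, tolerance = 1e-9)
  }
  expect_error(risk_score(m1, x[2, , drop = FALSE]), "gA")
})

test_that("maxstat equals exhaustive enumeration via survdiff", {
  surv <- random_surv(60, seed = 35)
  set.seed(35)
  scores <- rnorm(60) - surv$time / 20  # mildly informative
  got <- maxstat_cutoff(scores, surv, min_prop = 0.1)

  # oracle: standardized statistic per admissible midpoint from survdiff
  u <- sort(unique(scores))
  mids <- (u[-length(u)] + u[-1]) / 2
  keep <- vapply(mids, function(m) {
    hi <- sum(scores > m)
    hi >= 6 && (60 - hi) >= 6
  }, logical(1))
  mids <- mids[keep]
  zs <- vapply(mids, function(m) {
    g <- factor(scores > m)
    sqrt(survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)$chisq)
  }, numeric(1))
  expect_equal(got$statistic, max(zs), tolerance = 1e-9)
  expect_equal(got$cutoff, mids[which.max(zs)], tolerance = 1e-12)
  expect_equal(got$candidates$statistic, zs, tolerance = 1e-9)

  expect_error(maxstat_cutoff(rep(1, 60), surv), "constant")
})

test_that("maxstat recovers a planted threshold within one grid step", {
  set.seed(36)
  n <- 200
  scores <- runif(n, 0, 20)
  grp <- scores > 10
  t_ev <- rexp(n, rate = ifelse(grp, 0.4, 0.1))  # hazard ratio 4 at 10
  surv <- data.frame(sample_id = paste0("s", 1:n),
                     time = pmin(t_ev, 30),
                     event = as.integer(t_ev <= 30))
  got <- maxstat_cutoff(scores, surv)
  ss <- sort(unique(scores))
  step <- max(diff(ss[abs(ss - 10) < 1]))
  expect_lt(abs(got$cutoff - 10), 2 * step + 0.2)
})

test_that("Kaplan-Meier steps match the hand product-limit computation", {
  # four uncensored events in the low group: S = 0.75, 0.50, 0.25, 0
  surv <- data.frame(sample_id = paste0("s", 1:8),
                     time = c(1, 2, 3, 4, 5, 6, 7, 8),
                     event = rep(1L, 8))
  scores <- c(rep(0, 4), rep(10, 4))
  strat <- km_stratify(scores, 5, surv)
  low <- strat$curves[["group=low"]]
  expect_equal(low$surv, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)

  # all-censored group: survival never drops
  surv2 <- surv; surv2$event <- c(rep(1L, 4), rep(0L, 4))
  strat2 <- km_stratify(scores, 5, surv2)
  expect_true(all(strat2$curves[["group=high"]]$surv == 1))

  # censored 10-sample fixture against the independent product-limit oracle
  s10 <- surv_fixture_10()
  sc10 <- c(rep(0, 5), rep(1, 5))
  strat3 <- km_stratify(sc10, 0.5, s10)
  for (g in c("low", "high")) {
    members <- if (g == "low") 1:5 else 6:10
    want <- product_limit(s10$time[members], s10$event[members])
    gotc <- strat3$curves[[paste0("group=", g)]]
    gotc <- gotc[gotc$n_event > 0, ]
    expect_equal(gotc$surv, want$surv, tolerance = 1e-12)
  }
  # two-group log-rank agrees with survdiff
  z <- panfuse:::.logrank_z(sc10 > 0.5, s10$time, s10$event)
  chisq <- survival::survdiff(survival::Surv(s10$time, s10$event) ~
                                (sc10 > 0.5))$chisq
  expect_equal(z^2, chisq, tolerance = 1e-9)
  expect_error(km_stratify(rep(1, 10), 5, s10), "empty")
})

test_that("KM curves are proper survival functions", {
  surv <- random_surv(80, seed = 37)
  set.seed(37)
  strat <- km_stratify(rnorm(80), 0, surv)
  for (cv in strat$curves) {
    expect_true(all(diff(cv$surv) <= 1e-12))
    expect_true(all(cv$surv >= 0 & cv$surv <= 1))
  }
})

test_that("concordance equals the double-loop oracle and its invariances", {
  surv <- random_surv(200, seed = 38)
  set.seed(38)
  scores <- rnorm(200) + surv$time / 30
  got <- cindex(scores, surv)
  want <- cindex_bruteforce(scores, surv$time, surv$event)
  expect_equal(got, want, tolerance = 1e-12)

  # strictly increasing transforms leave the statistic unchanged
  expect_equal(cindex(exp(scores / 2), surv), got, tolerance = 1e-12)

  # perfect ordering, no censoring
  s4 <- data.frame(sample_id = paste0("s", 1:4), time = 1:4,
                   event = rep(1L, 4))
  expect_equal(cindex(c(4, 3, 2, 1), s4), 1)
  # chance level for uninformative scores
  big <- random_surv(1000, seed = 39)
  set.seed(40)
  expect_lt(abs(cindex(rnorm(1000), big) - 0.5), 0.05)
  # no comparable pair
  s_cens <- data.frame(sample_id = c("a", "b"), time = c(1, 2),
                       event = c(0L, 0L))
  expect_error(cindex(c(1, 2), s_cens), "comparable")
})

test_that("truncated concordance uses only pairs decided by the horizon", {
  s10 <- surv_fixture_10()
  set.seed(41)
  sc <- rnorm(10)
  # beyond the last time the truncated and plain statistics coincide
  expect_equal(cindex_truncated(sc, s10, horizon = 100), cindex(sc, s10),
               tolerance = 1e-12)
  # before the first event no pair is usable
  expect_true(is.na(cindex_truncated(sc, s10, horizon = 1)))
})

test_that("the survival forest finds planted prognostic genes", {
  sim <- simulate_expression(sim_config(n_samples = 250, n_genes = 50,
                                        n_informative = 0, seed = 42))
  pg <- c("g0010", "g0020", "g0030")
  surv <- simulate_survival(sim$expr, pg, c(0.9, 0.9, -0.9),
                            baseline_rate = 0.01, censor_rate = 0.2,
                            seed = 42)
  rsf <- rsf_fit(sim$expr, surv, n_trees = 300, seed = 42)
  expect_true(all(pg %in% names(rsf$importance)[1:10]))

  # the error trajectory must not end above its start (plus tolerance)
  err <- rsf$oob_error$error
  expect_lte(err[length(err)], err[1] + 0.02)

  rsf2 <- rsf_fit(sim$expr, surv, n_trees = 300, seed = 42)
  expect_identical(rsf$importance, rsf2$importance)

  allc <- surv; allc$event <- 0L
  expect_error(rsf_fit(sim$expr, allc, n_trees = 100), "censored|events")
})

test_that("the fitted risk model respects the screen-forest-score chain", {
  sim <- simulate_expression(sim_config(n_samples = 250, n_genes = 40,
                                        n_informative = 0, seed = 43))
  pg <- c("g0005", "g0015")
  surv <- simulate_survival(sim$expr, pg, c(0.9, -0.9),
                            baseline_rate = 0.01, censor_rate = 0.2,
                            seed = 43)
  rm_ <- fit_risk_model(sim$expr, surv, n_trees = 200, top_m = 5, seed = 43)
  screened <- rm_$screen$gene[rm_$screen$significant]
  expect_true(all(rm_$genes %in% screened))
  expect_true(all(pg %in% rm_$genes))
  expect_true(rm_$cutoff > min(rm_$scores) && rm_$cutoff < max(rm_$scores))
  expect_identical(names(rm_$coefs), rm_$genes)

  # baseline cumulative hazard is a nondecreasing step function
  expect_true(all(diff(rm_$baseline$cumhaz) >= -1e-12))

  # prediction on the training matrix reproduces the stored scores
  expect_equal(predict(rm_, sim$expr), rm_$scores, tolerance = 1e-12)
  grp <- predict(rm_, sim$expr, type = "group")
  expect_identical(unname(grp == "high"), unname(rm_$scores > rm_$cutoff))
})

test_that("high-risk groups carry the planted excess hazard", {
  hits <- 0L
  for (r in 1:20) {
    sim <- simulate_expression(sim_config(n_samples = 150, n_genes = 10,
                                          n_informative = 0,
                                          seed = 500 + r))
    surv <- simulate_survival(sim$expr, "g0001", log(3),
                              baseline_rate = 0.01, censor_rate = 0.2,
                              seed = 500 + r)
    m <- list(genes = "g0001", coefs = c(g0001 = log(3)))
    sc <- risk_score(m, sim$expr)
    cut <- maxstat_cutoff(sc, surv)$cutoff
    strat <- km_stratify(sc, cut, surv)
    tab <- strat$table
    rate_high <- mean(surv$event[tab$group == "high"])
    rate_low <- mean(surv$event[tab$group == "low"])
    if (rate_high > rate_low) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
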