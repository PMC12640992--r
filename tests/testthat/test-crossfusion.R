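# The CNN+BiLSTM cross-attention classifier: fusion algebra, gradients,
# training behaviour and evaluation metrics.

test_that("branch outputs share the configured token/feature shape", {
  cfg <- crossfusion_config(n_genes = 64, k_classes = 2, window = 4,
                            stride = 4, conv_channels = c(4L, 4L, 4L),
                            hidden = 4L, d = 8L, dropout = 0)
  expect_identical(cfg$L, 16L)
  set.seed(1)
  x <- matrix(rnorm(64 * 6), 64, 6,
              dimnames = list(sprintf("g%02d", 1:64), sprintf("s%d", 1:6)))
  y <- rep(1:2, 3)
  fit <- crossfusion(x, y, config = modifyList(cfg, list(max_epochs = 1L)),
                     seed = 1)
  bf <- branch_features(fit, x[fit$gene_order, 1])
  expect_identical(dim(bf$Fc), c(16L, 8L))
  expect_identical(dim(bf$Fg), c(16L, 8L))
  expect_identical(dim(bf$attention), c(16L, 16L))
  expect_equal(rowSums(bf$attention), rep(1, 16), tolerance = 1e-6)
  expect_error(branch_features(fit, rnorm(10)), "length")
})

test_that("cross-fusion collapses analytically at L = 1 and Fc = 0", {
  Fc <- matrix(rnorm(3), 1, 3)
  Fg <- matrix(rnorm(3), 1, 3)
  out <- cross_fusion(Fc, Fg)
  expect_identical(out$attention[1, 1], 1)
  expect_equal(out$Fcg, Fc + Fg)

  # zero Fc: uniform attention, every fused row is the column mean of Fg
  L <- 5; d <- 3
  Fg2 <- matrix(rnorm(L * d), L, d)
  out2 <- cross_fusion(matrix(0, L, d), Fg2)
  expect_equal(out2$attention, matrix(1 / L, L, L), tolerance = 1e-12)
  expect_equal(out2$Fcg,
               matrix(rep(colMeans(Fg2), each = L), L, d),
               tolerance = 1e-12)
  expect_error(cross_fusion(matrix(0, 2, 3), matrix(0, 3, 2)), "shape")
})

test_that("cross-fusion matches a scalar-loop evaluation on random inputs", {
  # independent oracle: nested loops, no matrix algebra
  fuse_loops <- function(Fc, Fg, scale) {
    L <- nrow(Fc); d <- ncol(Fc)
    A <- matrix(0, L, L)
    for (i in 1:L) {
      s <- numeric(L)
      for (j in 1:L) {
        acc <- 0
        for (m in 1:d) acc <- acc + Fc[i, m] * Fg[j, m]
        s[j] <- acc / scale
      }
      e <- exp(s - max(s))
      A[i, ] <- e / sum(e)
    }
    out <- matrix(0, L, d)
    for (i in 1:L) for (m in 1:d) {
      acc <- 0
      for (j in 1:L) acc <- acc + A[i, j] * (Fc[j, m] + Fg[j, m])
      out[i, m] <- acc
    }
    list(Fcg = out, attention = A)
  }
  set.seed(31)
  for (rep in 1:100) {
    L <- sample(1:5, 1); d <- sample(1:4, 1)
    Fc <- matrix(rnorm(L * d, sd = 2), L, d)
    Fg <- matrix(rnorm(L * d, sd = 2), L, d)
    for (sc in c("sqrt_d", "d")) {
      got <- cross_fusion(Fc, Fg, attn_scale = sc)
      want <- fuse_loops(Fc, Fg, if (sc == "sqrt_d") sqrt(d) else d)
      expect_lt(max(abs(got$Fcg - want$Fcg)), 1e-6)
      expect_lt(max(abs(got$attention - want$attention)), 1e-6)
    }
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- crossfusion_config(n_genes = 8, k_classes = 2, window = 2,
                            stride = 2, conv_channels = c(3L, 3L, 2L),
                            hidden = 2L, d = 3L, dropout = 0)
  set.seed(42)
  P <- panfuse:::.init_params(cfg)
  # nudge biases off exact ReLU kinks so the numeric derivative is clean
  for (nm in names(P)) P[[nm]] <- P[[nm]] + rnorm(length(P[[nm]]), 0, 0.05)
  idx <- panfuse:::.token_index(cfg)
  X <- matrix(rnorm(3 * 8), 3, 8)
  y <- c(1L, 2L, 1L)
  loss_fn <- function(P)
    panfuse:::.ce_loss(panfuse:::.forward(P, X, cfg, idx)$probs, y)
  fw <- panfuse:::.forward(P, X, cfg, idx)
  G <- panfuse:::.backward(P, X, y, cfg, idx, fw)
  eps <- 1e-6
  for (nm in names(P)) {
    num <- G[[nm]]
    for (i in seq_along(P[[nm]])) {
      Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
      Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
      num[i] <- (loss_fn(Pp) - loss_fn(Pm)) / (2 * eps)
    }
    expect_lt(max(abs(num - G[[nm]])) / max(1e-8, max(abs(num))), 1e-5)
  }
})

test_that("predictions are distributions; a zeroed head is uniform", {
  blobs <- make_blobs(c(10, 10), n_genes = 12, centers_scale = 5, seed = 5)
  fit <- crossfusion(blobs$x, blobs$labels,
                     config = tiny_cf_config(12, 2), seed = 5)
  probs <- predict(fit, blobs$x, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, 20), tolerance = 1e-6)
  expect_true(all(probs >= 0))

  fit0 <- fit
  fit0$params$Wfc[] <- 0
  fit0$params$bfc[] <- 0
  probs0 <- predict(fit0, blobs$x, type = "prob")
  expect_equal(unname(probs0), matrix(0.5, 20, 2), tolerance = 1e-12)
})

test_that("training is deterministic and its loss decreases when separable", {
  blobs <- make_blobs(c(12, 12), n_genes = 12, centers_scale = 5, seed = 6)
  a <- crossfusion(blobs$x, blobs$labels, config = tiny_cf_config(12, 2),
                   seed = 9)
  b <- crossfusion(blobs$x, blobs$labels, config = tiny_cf_config(12, 2),
                   seed = 9)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)

  # monotone trend over the first five epochs
  first5 <- a$history$train_loss[1:5]
  expect_lt(first5[5], first5[1])
  expect_lt(mean(diff(first5)), 0)
})

test_that("label and panel contracts are enforced", {
  blobs <- make_blobs(c(8, 8), n_genes = 10, centers_scale = 5, seed = 7)
  y_missing <- ifelse(blobs$labels == 2, 3L, 1L)  # class 2 absent
  expect_error(crossfusion(blobs$x, y_missing,
                           config = tiny_cf_config(10, 3)), "absent")
  fit <- crossfusion(blobs$x, blobs$labels, config = tiny_cf_config(10, 2),
                     seed = 7)
  expect_error(predict(fit, blobs$x[1:5, ]), "missing")
  expect_error(evaluate_classifier(fit, blobs$x, rep(1L, 16)),
               "single-class")
})

test_that("per-class AUC equals brute-force pair counting", {
  blobs <- make_blobs(c(10, 10), n_genes = 10, centers_scale = 2, seed = 8)
  fit <- crossfusion(blobs$x, blobs$labels, config = tiny_cf_config(10, 2),
                     seed = 8)
  ev <- evaluate_classifier(fit, blobs$x, blobs$labels)
  probs <- predict(fit, blobs$x, type = "prob")
  for (cl in 1:2) {
    pos <- which(blobs$labels == cl)
    neg <- which(blobs$labels != cl)
    acc <- 0
    for (i in pos) for (j in neg)
      acc <- acc + (probs[i, cl] > probs[j, cl]) +
        0.5 * (probs[i, cl] == probs[j, cl])
    expect_equal(unname(ev$auc[cl]), acc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("labels independent of the features give chance-level AUC", {
  blobs <- make_blobs(c(15, 15), n_genes = 10, centers_scale = 4, seed = 10)
  fit <- crossfusion(blobs$x, blobs$labels, config = tiny_cf_config(10, 2),
                     seed = 10)
  set.seed(99)
  big <- matrix(rnorm(10 * 400), 10, 400,
                dimnames = list(rownames(blobs$x), sprintf("t%03d", 1:400)))
  y_rand <- sample(1:2, 400, replace = TRUE)
  ev <- evaluate_classifier(fit, big, y_rand)
  expect_lt(abs(ev$auc[1] - 0.5), 0.05)
})

test_that("the ablation table covers all variants deterministically", {
  blobs <- make_blobs(c(10, 10), n_genes = 8, centers_scale = 6, seed = 12)
  cfg <- tiny_cf_config(8, 2)
  cfg$max_epochs <- 6L
  tab <- ablate_crossfusion(blobs$x, blobs$labels, test_idx = c(1:3, 11:13),
                            config = cfg, seeds = 1L)
  expect_identical(nrow(tab), 3L)
  expect_setequal(tab$variant, c("cnn", "bilstm", "fusion"))
  tab2 <- ablate_crossfusion(blobs$x, blobs$labels, test_idx = c(1:3, 11:13),
                             config = cfg, seeds = 1L)
  expect_identical(tab, tab2)
})
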