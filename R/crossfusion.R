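# Parallel CNN + BiLSTM classifier fused by scaled dot-product
# cross-attention, trained with cross-entropy against consensus
# pseudo-labels. No deep-learning runtime is available to R in this
# stack, so the forward and backward passes are written out here in
# vectorised base R (gradients are validated against finite differences
# in the test suite) with Adam and early stopping on validation loss.
#
# Shapes. One sample's expression vector over a frozen gene order
# (descending training-set variance) is windowed into L tokens of width
# `window` (zero-padded tail). Both branches preserve the token axis:
# the conv branch stacks three 1-D convolutions along tokens (kernel 3,
# same padding, ReLU) and projects to [L x d]; the BiLSTM runs over
# tokens with `hidden` units per direction, concatenates both directions
# and projects to [L x d]. Fusion per sample:
#   A   = row-softmax(Fc %*% t(Fg) / scale),  scale = sqrt(d) or d
#   Fcg = A %*% (Fc + Fg)
# Mean-pooling over tokens, a fully connected layer and softmax give the
# class distribution.

#' Classifier configuration
#'
#' @param n_genes length of the input gene panel.
#' @param k_classes number of subtype classes.
#' @param window,stride tokenisation of the gene sequence; the default
#'   window 4 / stride 4 partitions the panel (zero-padded tail), giving
#'   `L = ceiling(n_genes / stride)` tokens.
#' @param conv_channels channels of the three convolutional layers.
#' @param hidden BiLSTM hidden units per direction.
#' @param d shared feature dimension after projection.
#' @param attn_scale `"sqrt_d"` (scaled dot-product attention, default) or
#'   `"d"` (the literal printed scaling).
#' @param variant `"fusion"` (both branches + cross-attention), `"cnn"` or
#'   `"bilstm"` (single-branch ablations).
#' @param dropout dropout rate on the pooled feature during training.
#' @param lr,batch_size,max_epochs,patience,val_frac Adam learning rate,
#'   minibatch size, epoch cap, early-stopping patience on validation
#'   loss, and validation fraction (stratified).
#' @return A list of class `crossfusion_config`.
#' @export
crossfusion_config <- function(n_genes, k_classes, window = 4L, stride = 4L,
                               conv_channels = c(32L, 64L, 64L),
                               hidden = 32L, d = 64L,
                               attn_scale = c("sqrt_d", "d"),
                               variant = c("fusion", "cnn", "bilstm"),
                               dropout = 0.2, lr = 1e-3, batch_size = 32L,
                               max_epochs = 200L, patience = 20L,
                               val_frac = 0.2) {
  attn_scale <- match.arg(attn_scale)
  variant <- match.arg(variant)
  if (length(conv_channels) != 3L) stop("exactly three conv layers expected")
  if (n_genes < 1L) stop("empty gene panel")
  L <- as.integer(ceiling(n_genes / stride))
  structure(list(n_genes = as.integer(n_genes),
                 k_classes = as.integer(k_classes),
                 window = as.integer(window), stride = as.integer(stride),
                 L = L, conv_channels = as.integer(conv_channels),
                 hidden = as.integer(hidden), d = as.integer(d),
                 attn_scale = attn_scale, variant = variant,
                 dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_frac = val_frac),
            class = "crossfusion_config")
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

.init_params <- function(cfg) {
  w <- cfg$window; cc <- cfg$conv_channels; h <- cfg$hidden; d <- cfg$d
  p <- list(
    Wc1 = .glorot(3L * w, cc[1L]), bc1 = numeric(cc[1L]),
    Wc2 = .glorot(3L * cc[1L], cc[2L]), bc2 = numeric(cc[2L]),
    Wc3 = .glorot(3L * cc[2L], cc[3L]), bc3 = numeric(cc[3L]),
    Pc = .glorot(cc[3L], d), pcb = numeric(d),
    Wxf = .glorot(w, 4L * h), Whf = .glorot(h, 4L * h), bfv = numeric(4L * h),
    Wxb = .glorot(w, 4L * h), Whb = .glorot(h, 4L * h), bbv = numeric(4L * h),
    Pg = .glorot(2L * h, d), pgb = numeric(d),
    Wfc = .glorot(d, cfg$k_classes), bfc = numeric(cfg$k_classes)
  )
  # forget-gate bias starts open, the usual LSTM trick
  p$bfv[(h + 1L):(2L * h)] <- 1
  p$bbv[(h + 1L):(2L * h)] <- 1
  p
}

# token index map: L x window matrix of gene positions, 0 = zero pad
.token_index <- function(cfg) {
  starts <- seq(1L, cfg$n_genes, by = cfg$stride)
  idx <- outer(starts, 0:(cfg$window - 1L), `+`)
  idx[idx > cfg$n_genes] <- 0L
  idx
}

# X: B x n -> big token matrix [L*B x w], rows blocked by token
.tokenize <- function(X, cfg, idx) {
  B <- nrow(X); L <- nrow(idx); w <- ncol(idx)
  Tm <- matrix(0, L * B, w)
  for (l in seq_len(L)) {
    rows <- ((l - 1L) * B + 1L):(l * B)
    for (j in seq_len(w)) if (idx[l, j] > 0L) Tm[rows, j] <- X[, idx[l, j]]
  }
  Tm
}

# shift a token-blocked [L*B x c] matrix by one token (dir = -1 prev, +1 next)
.tok_shift <- function(M, B, L, dir) {
  out <- matrix(0, nrow(M), ncol(M))
  if (dir == -1L && L > 1L)
    out[(B + 1L):(L * B), ] <- M[1L:((L - 1L) * B), ]
  if (dir == +1L && L > 1L)
    out[1L:((L - 1L) * B), ] <- M[(B + 1L):(L * B), ]
  out
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- forward ----------------------------------------------------------

# returns loss-ready activations and caches for backprop
.forward <- function(P, X, cfg, idx, dropout_mask = NULL) {
  B <- nrow(X); L <- cfg$L; h <- cfg$hidden; d <- cfg$d
  Tm <- .tokenize(X, cfg, idx)                      # [L*B x w]
  cache <- list(Tm = Tm, B = B)

  Fc <- NULL
  if (cfg$variant != "bilstm") {
    A1in <- cbind(.tok_shift(Tm, B, L, -1L), Tm, .tok_shift(Tm, B, L, 1L))
    Z1 <- sweep(A1in %*% P$Wc1, 2L, P$bc1, `+`); H1 <- pmax(Z1, 0)
    A2in <- cbind(.tok_shift(H1, B, L, -1L), H1, .tok_shift(H1, B, L, 1L))
    Z2 <- sweep(A2in %*% P$Wc2, 2L, P$bc2, `+`); H2 <- pmax(Z2, 0)
    A3in <- cbind(.tok_shift(H2, B, L, -1L), H2, .tok_shift(H2, B, L, 1L))
    Z3 <- sweep(A3in %*% P$Wc3, 2L, P$bc3, `+`); H3 <- pmax(Z3, 0)
    Fc <- sweep(H3 %*% P$Pc, 2L, P$pcb, `+`)        # [L*B x d]
    cache <- c(cache, list(A1in = A1in, Z1 = Z1, H1 = H1, A2in = A2in,
                           Z2 = Z2, H2 = H2, A3in = A3in, Z3 = Z3, H3 = H3))
  }

  Fg <- NULL
  if (cfg$variant != "cnn") {
    run_lstm <- function(Wx, Wh, b, reverse) {
      hs <- vector("list", L); cs <- vector("list", L)
      gates <- vector("list", L)
      hprev <- matrix(0, B, h); cprev <- matrix(0, B, h)
      order_l <- if (reverse) rev(seq_len(L)) else seq_len(L)
      for (l in order_l) {
        xt <- Tm[((l - 1L) * B + 1L):(l * B), , drop = FALSE]
        G <- sweep(xt %*% Wx + hprev %*% Wh, 2L, b, `+`)
        i_g <- .sigmoid(G[, 1:h, drop = FALSE])
        f_g <- .sigmoid(G[, (h + 1L):(2L * h), drop = FALSE])
        g_g <- tanh(G[, (2L * h + 1L):(3L * h), drop = FALSE])
        o_g <- .sigmoid(G[, (3L * h + 1L):(4L * h), drop = FALSE])
        ct <- f_g * cprev + i_g * g_g
        ht <- o_g * tanh(ct)
        gates[[l]] <- list(i = i_g, f = f_g, g = g_g, o = o_g,
                           cprev = cprev, hprev = hprev, c = ct)
        hs[[l]] <- ht; cs[[l]] <- ct
        hprev <- ht; cprev <- ct
      }
      list(hs = hs, gates = gates)
    }
    fwd <- run_lstm(P$Wxf, P$Whf, P$bfv, reverse = FALSE)
    bwd <- run_lstm(P$Wxb, P$Whb, P$bbv, reverse = TRUE)
    Hcat <- matrix(0, L * B, 2L * h)
    for (l in seq_len(L)) {
      rows <- ((l - 1L) * B + 1L):(l * B)
      Hcat[rows, ] <- cbind(fwd$hs[[l]], bwd$hs[[l]])
    }
    Fg <- sweep(Hcat %*% P$Pg, 2L, P$pgb, `+`)      # [L*B x d]
    cache <- c(cache, list(lstm_f = fwd, lstm_b = bwd, Hcat = Hcat))
  }

  scale <- if (cfg$attn_scale == "sqrt_d") sqrt(d) else d
  pooled <- matrix(0, B, d)
  attn <- vector("list", B)
  if (cfg$variant == "fusion") {
    for (bi in seq_len(B)) {
      rows <- seq(bi, by = B, length.out = L)
      Fcb <- Fc[rows, , drop = FALSE]; Fgb <- Fg[rows, , drop = FALSE]
      S <- Fcb %*% t(Fgb) / scale
      A <- row_softmax(S)
      Fcg <- A %*% (Fcb + Fgb)
      attn[[bi]] <- A
      pooled[bi, ] <- colMeans(Fcg)
    }
  } else {
    Fb <- if (cfg$variant == "cnn") Fc else Fg
    for (bi in seq_len(B)) {
      rows <- seq(bi, by = B, length.out = L)
      pooled[bi, ] <- colMeans(Fb[rows, , drop = FALSE])
    }
  }
  if (!is.null(dropout_mask)) pooled_d <- pooled * dropout_mask
  else pooled_d <- pooled
  logits <- sweep(pooled_d %*% P$Wfc, 2L, P$bfc, `+`)
  probs <- row_softmax(logits)
  c(cache, list(Fc = Fc, Fg = Fg, attn = attn, pooled = pooled,
                pooled_d = pooled_d, probs = probs, scale = scale,
                dropout_mask = dropout_mask))
}

# ---- backward ---------------------------------------------------------

# mean cross-entropy gradient for all parameters; y in 1..k
.backward <- function(P, X, y, cfg, idx, fw) {
  B <- nrow(X); L <- cfg$L; h <- cfg$hidden; d <- cfg$d
  G <- lapply(P, function(m) array(0, dim = dim(m) %||% length(m)))
  names(G) <- names(P)

  dlogits <- fw$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  G$Wfc <- t(fw$pooled_d) %*% dlogits
  G$bfc <- colSums(dlogits)
  dpooled <- dlogits %*% t(P$Wfc)
  if (!is.null(fw$dropout_mask)) dpooled <- dpooled * fw$dropout_mask

  dFc <- if (!is.null(fw$Fc)) matrix(0, L * B, d)
  dFg <- if (!is.null(fw$Fg)) matrix(0, L * B, d)
  if (cfg$variant == "fusion") {
    for (bi in seq_len(B)) {
      rows <- seq(bi, by = B, length.out = L)
      Fcb <- fw$Fc[rows, , drop = FALSE]; Fgb <- fw$Fg[rows, , drop = FALSE]
      A <- fw$attn[[bi]]
      dFcg <- matrix(rep(dpooled[bi, ] / L, each = L), L, d)
      Fs <- Fcb + Fgb
      dA <- dFcg %*% t(Fs)
      dFs <- t(A) %*% dFcg
      dS <- A * (dA - rowSums(dA * A))   # softmax rows
      dFc[rows, ] <- dFs + (dS %*% Fgb) / fw$scale
      dFg[rows, ] <- dFs + (t(dS) %*% Fcb) / fw$scale
    }
  } else if (cfg$variant == "cnn") {
    for (bi in seq_len(B)) {
      rows <- seq(bi, by = B, length.out = L)
      dFc[rows, ] <- matrix(rep(dpooled[bi, ] / L, each = L), L, d)
    }
  } else {
    for (bi in seq_len(B)) {
      rows <- seq(bi, by = B, length.out = L)
      dFg[rows, ] <- matrix(rep(dpooled[bi, ] / L, each = L), L, d)
    }
  }

  if (!is.null(dFc)) {
    G$Pc <- t(fw$H3) %*% dFc
    G$pcb <- colSums(dFc)
    dH3 <- dFc %*% t(P$Pc)
    dZ3 <- dH3 * (fw$Z3 > 0)
    G$Wc3 <- t(fw$A3in) %*% dZ3
    G$bc3 <- colSums(dZ3)
    dA3 <- dZ3 %*% t(P$Wc3)
    cc <- cfg$conv_channels
    dH2 <- .tok_shift(dA3[, 1:cc[2L], drop = FALSE], B, L, 1L) +
      dA3[, (cc[2L] + 1L):(2L * cc[2L]), drop = FALSE] +
      .tok_shift(dA3[, (2L * cc[2L] + 1L):(3L * cc[2L]), drop = FALSE],
                 B, L, -1L)
    dZ2 <- dH2 * (fw$Z2 > 0)
    G$Wc2 <- t(fw$A2in) %*% dZ2
    G$bc2 <- colSums(dZ2)
    dA2 <- dZ2 %*% t(P$Wc2)
    dH1 <- .tok_shift(dA2[, 1:cc[1L], drop = FALSE], B, L, 1L) +
      dA2[, (cc[1L] + 1L):(2L * cc[1L]), drop = FALSE] +
      .tok_shift(dA2[, (2L * cc[1L] + 1L):(3L * cc[1L]), drop = FALSE],
                 B, L, -1L)
    dZ1 <- dH1 * (fw$Z1 > 0)
    G$Wc1 <- t(fw$A1in) %*% dZ1
    G$bc1 <- colSums(dZ1)
  }

  if (!is.null(dFg)) {
    G$Pg <- t(fw$Hcat) %*% dFg
    G$pgb <- colSums(dFg)
    dHcat <- dFg %*% t(P$Pg)

    bptt <- function(Wx, Wh, lstm, dh_slice, reverse) {
      dWx <- array(0, dim = dim(Wx)); dWh <- array(0, dim = dim(Wh))
      db <- numeric(4L * h)
      dh_next <- matrix(0, B, h); dc_next <- matrix(0, B, h)
      order_l <- if (reverse) seq_len(L) else rev(seq_len(L))
      for (l in order_l) {
        gt <- lstm$gates[[l]]
        dh <- dh_slice[[l]] + dh_next
        tc <- tanh(gt$c)
        do_ <- dh * tc
        dc <- dh * gt$o * (1 - tc^2) + dc_next
        di <- dc * gt$g
        dg <- dc * gt$i
        df <- dc * gt$cprev
        dc_next <- dc * gt$f
        dG <- cbind(di * gt$i * (1 - gt$i),
                    df * gt$f * (1 - gt$f),
                    dg * (1 - gt$g^2),
                    do_ * gt$o * (1 - gt$o))
        xt <- fw$Tm[((l - 1L) * B + 1L):(l * B), , drop = FALSE]
        dWx <- dWx + t(xt) %*% dG
        dWh <- dWh + t(gt$hprev) %*% dG
        db <- db + colSums(dG)
        dh_next <- dG %*% t(Wh)
      }
      list(dWx = dWx, dWh = dWh, db = db)
    }
    dh_f <- lapply(seq_len(L), function(l)
      dHcat[((l - 1L) * B + 1L):(l * B), 1:h, drop = FALSE])
    dh_b <- lapply(seq_len(L), function(l)
      dHcat[((l - 1L) * B + 1L):(l * B), (h + 1L):(2L * h), drop = FALSE])
    gf <- bptt(P$Wxf, P$Whf, fw$lstm_f, dh_f, reverse = FALSE)
    gb <- bptt(P$Wxb, P$Whb, fw$lstm_b, dh_b, reverse = TRUE)
    G$Wxf <- gf$dWx; G$Whf <- gf$dWh; G$bfv <- gf$db
    G$Wxb <- gb$dWx; G$Whb <- gb$dWh; G$bbv <- gb$db
  }
  G
}

.ce_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y)], 1e-12)))
}

#' Cross-attention fusion of two branch feature matrices
#'
#' The fusion step in isolation: given spatial features `Fc` and temporal
#' features `Fg` of identical shape `[L x d]`, computes
#' `A = row-softmax(Fc %*% t(Fg) / scale)` and `Fcg = A %*% (Fc + Fg)`,
#' with `scale = sqrt(d)` (scaled dot-product attention, default) or the
#' literal `d`.
#'
#' @param Fc,Fg numeric matrices `[L x d]`.
#' @param attn_scale `"sqrt_d"` or `"d"`.
#' @return List with `Fcg` `[L x d]` and `attention` `[L x L]` (rows sum
#'   to 1).
#' @export
cross_fusion <- function(Fc, Fg, attn_scale = c("sqrt_d", "d")) {
  attn_scale <- match.arg(attn_scale)
  if (!all(dim(Fc) == dim(Fg)))
    stop("Fc and Fg must have identical [L x d] shapes")
  d <- ncol(Fc)
  scale <- if (attn_scale == "sqrt_d") sqrt(d) else d
  A <- row_softmax(Fc %*% t(Fg) / scale)
  list(Fcg = A %*% (Fc + Fg), attention = A)
}

#' Branch features for one sample
#'
#' Exposes the two branch outputs (and the fused tensor for the fusion
#' variant) for a single expression vector, mainly for inspection and
#' testing of shapes.
#'
#' @param object a fitted or initialised `crossfusion` model.
#' @param x_vec numeric vector over the model's gene order.
#' @return List with `Fc`, `Fg` (each `[L x d]` or NULL for ablated
#'   branches), `attention`, `Fcg`.
#' @export
branch_features <- function(object, x_vec) {
  stopifnot(inherits(object, "crossfusion"))
  cfg <- object$config
  if (length(x_vec) != cfg$n_genes)
    stop("expected an expression vector of length ", cfg$n_genes)
  fw <- .forward(object$params, matrix(x_vec, 1L), cfg, object$token_index)
  pick <- function(Fm) if (is.null(Fm)) NULL else {
    rows <- seq(1L, by = 1L, length.out = cfg$L)
    Fm[rows, , drop = FALSE]  # B = 1: token blocks are single rows
  }
  out <- list(Fc = pick(fw$Fc), Fg = pick(fw$Fg), attention = fw$attn[[1L]],
              Fcg = NULL)
  if (cfg$variant == "fusion")
    out$Fcg <- out$attention %*% (out$Fc + out$Fg)
  out
}

# ---- training ---------------------------------------------------------

.adam_step <- function(P, G, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(P)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * G[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * G[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    P[[nm]] <- P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(P = P, state = state)
}

#' Fit the cross-fusion classifier
#'
#' Trains the CNN + BiLSTM cross-attention model (or a single-branch
#' ablation) on expression profiles against integer class labels —
#' typically consensus pseudo-labels from [consensus_subtypes()]. The
#' gene order is frozen into the model as descending training-set
#' variance. Minimises mean cross-entropy with Adam; early stopping on
#' validation loss with best-weight restore.
#'
#' @param x genes-by-samples expression matrix.
#' @param y integer class labels in 1..k, one per sample (vector or the
#'   `labels` element of a `consensus_subtypes` fit).
#' @param config a [crossfusion_config()]; NULL for defaults inferred
#'   from the data.
#' @param seed integer seed (initialisation, shuffling, dropout, split).
#' @param verbose print per-epoch losses.
#' @return An object of class `crossfusion`: `params`, `config`,
#'   `gene_order`, `history` (per-epoch data.frame), `best_epoch`,
#'   `classes`, `seed`.
#' @export
crossfusion <- function(x, y, config = NULL, seed = 1L, verbose = FALSE) {
  validate_expression(x)
  y <- as.integer(y)
  if (length(y) != ncol(x)) stop("one label per sample required")
  k <- max(y)
  if (min(y) < 1L) stop("labels must be positive integers 1..k")
  counts <- tabulate(y, k)
  if (any(counts == 0L))
    stop("class(es) absent from training data: ",
         paste(which(counts == 0L), collapse = ", "))
  if (any(counts < 2L))
    stop("each class needs at least 2 samples")

  gene_order <- rownames(x)[order(apply(x, 1L, var), decreasing = TRUE)]
  cfg <- config %||% crossfusion_config(n_genes = nrow(x), k_classes = k)
  if (cfg$k_classes != k)
    stop("config k_classes (", cfg$k_classes, ") does not match labels (",
         k, ")")
  if (cfg$n_genes != nrow(x))
    stop("config n_genes (", cfg$n_genes, ") does not match expression (",
         nrow(x), ")")

  Xall <- t(x[gene_order, , drop = FALSE])   # samples x genes
  idx <- .token_index(cfg)

  set.seed(derive_seed(seed, 2L))
  P <- .init_params(cfg)
  state <- list(m = lapply(P, function(m) array(0, dim = dim(m) %||%
                                                  length(m))),
                v = lapply(P, function(m) array(0, dim = dim(m) %||%
                                                  length(m))))

  val_idx <- if (cfg$val_frac > 0 && ncol(x) >= 5L * k)
    stratified_split(y, cfg$val_frac) else integer(0)
  tr_idx <- setdiff(seq_len(ncol(x)), val_idx)
  Xtr <- Xall[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- Xall[val_idx, , drop = FALSE]; yva <- y[val_idx]

  eval_split <- function(Pcur, X, yy) {
    if (!nrow(X)) return(c(NA_real_, NA_real_))
    fw <- .forward(Pcur, X, cfg, idx)
    c(.ce_loss(fw$probs, yy),
      mean(max.col(fw$probs, ties.method = "first") == yy))
  }

  history <- data.frame()
  best_loss <- Inf; best_P <- P; best_epoch <- 0L; stall <- 0L
  t_adam <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(nrow(Xtr))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (b in batches) {
      Xb <- Xtr[b, , drop = FALSE]; yb <- ytr[b]
      mask <- if (cfg$dropout > 0)
        matrix(stats::rbinom(length(b) * cfg$d, 1L, 1 - cfg$dropout) /
                 (1 - cfg$dropout), length(b), cfg$d)
      else NULL
      fw <- .forward(P, Xb, cfg, idx, dropout_mask = mask)
      G <- .backward(P, Xb, yb, cfg, idx, fw)
      t_adam <- t_adam + 1L
      upd <- .adam_step(P, G, state, cfg$lr, t_adam)
      P <- upd$P; state <- upd$state
    }
    tr <- eval_split(P, Xtr, ytr)
    va <- eval_split(P, Xva, yva)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr[1L], train_acc = tr[2L],
      val_loss = va[1L], val_acc = va[2L]))
    monitor <- if (is.na(va[1L])) tr[1L] else va[1L]
    if (verbose)
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                      epoch, tr[1L], tr[2L], va[1L], va[2L]))
    if (monitor < best_loss - 1e-6) {
      best_loss <- monitor; best_P <- P; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }

  structure(list(params = best_P, config = cfg, gene_order = gene_order,
                 token_index = idx, history = history,
                 best_epoch = best_epoch, classes = seq_len(k),
                 seed = seed), class = "crossfusion")
}

#' @export
print.crossfusion <- function(x, ...) {
  cfg <- x$config
  cat("Cross-fusion classifier (", cfg$variant, " variant)\n", sep = "")
  cat("  genes: ", cfg$n_genes, " -> ", cfg$L, " tokens of width ",
      cfg$window, "; d = ", cfg$d, "; classes: ", cfg$k_classes, "\n",
      sep = "")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epochs (best %d): train loss %.4f, acc %.3f\n",
              nrow(x$history), x$best_epoch, last$train_loss,
              last$train_acc))
  if (!is.na(last$val_loss))
    cat(sprintf("  validation: loss %.4f, acc %.3f\n", last$val_loss,
                last$val_acc))
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' @param object a fitted `crossfusion` model.
#' @param newdata genes-by-samples matrix; must contain every gene of the
#'   frozen panel (missing genes are an error, never imputed).
#' @param type `"prob"` (samples-by-classes matrix) or `"class"`.
#' @param ... unused.
#' @export
predict.crossfusion <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  validate_expression(newdata)
  missing_g <- setdiff(object$gene_order, rownames(newdata))
  if (length(missing_g))
    stop("gene(s) missing from newdata: ",
         paste(head(missing_g, 5L), collapse = ", "),
         if (length(missing_g) > 5L) ", ...")
  X <- t(newdata[object$gene_order, , drop = FALSE])
  fw <- .forward(object$params, X, object$config, object$token_index)
  if (type == "prob") {
    dimnames(fw$probs) <- list(colnames(newdata),
                               paste0("class", object$classes))
    fw$probs
  } else {
    setNames(max.col(fw$probs, ties.method = "first"), colnames(newdata))
  }
}

#' @export
plot.crossfusion <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Training history",
       ylim = range(c(h$train_loss, h$val_loss), na.rm = TRUE), ...)
  if (any(!is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, lty = 2)
    legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Accuracy and per-class one-vs-rest ROC AUC
#'
#' AUC is the rank statistic (Mann-Whitney) of the predicted probability
#' of each class against the rest; ties contribute 1/2.
#'
#' @param object a fitted `crossfusion` model.
#' @param x genes-by-samples test matrix.
#' @param y integer test labels in 1..k.
#' @return List with `accuracy` and `auc` (named per class; NA with a
#'   warning for a class absent from the test set).
#' @export
evaluate_classifier <- function(object, x, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("single-class test set: AUC undefined")
  probs <- predict(object, x, type = "prob")
  acc <- mean(max.col(probs, ties.method = "first") == y)
  auc <- vapply(object$classes, function(cl) {
    pos <- y == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(probs[, cl])
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
  }, numeric(1L))
  names(auc) <- paste0("class", object$classes)
  if (anyNA(auc))
    warning("AUC undefined for class(es) absent from the test set: ",
            paste(names(auc)[is.na(auc)], collapse = ", "))
  list(accuracy = acc, auc = auc)
}

#' Ablation study over model variants
#'
#' Trains the CNN-only, BiLSTM-only and full fusion variants under the
#' same data, seeds and budget, and tabulates train/test accuracy.
#'
#' @param x genes-by-samples matrix.
#' @param y integer labels in 1..k.
#' @param test_idx column indices held out for testing.
#' @param config base [crossfusion_config()] (variant is overridden).
#' @param seeds integer vector of seeds; results are averaged over them.
#' @return A data.frame with one row per (variant, seed) plus attribute
#'   `summary`, the per-variant mean accuracies.
#' @export
ablate_crossfusion <- function(x, y, test_idx, config = NULL, seeds = 1L) {
  y <- as.integer(y)
  tr <- setdiff(seq_len(ncol(x)), test_idx)
  rows <- list()
  for (variant in c("cnn", "bilstm", "fusion")) {
    for (s in seeds) {
      cfg <- config %||% crossfusion_config(n_genes = nrow(x),
                                            k_classes = max(y))
      cfg$variant <- variant
      fit <- crossfusion(x[, tr, drop = FALSE], y[tr], config = cfg,
                         seed = s)
      acc_tr <- mean(predict(fit, x[, tr, drop = FALSE],
                             type = "class") == y[tr])
      acc_te <- mean(predict(fit, x[, test_idx, drop = FALSE],
                             type = "class") == y[test_idx])
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, seed = s, train_acc = acc_tr, test_acc = acc_te)
    }
  }
  out <- do.call(rbind, rows)
  summ <- aggregate(cbind(train_acc, test_acc) ~ variant, out, mean)
  attr(out, "summary") <- summ
  out
}
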