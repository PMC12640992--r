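# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# genes x samples matrix of k Gaussian blobs (samples as columns)
make_blobs <- function(n_per, n_genes, centers_scale, k = length(n_per),
                       seed = 1) {
  set.seed(seed)
  n <- sum(n_per)
  labels <- rep(seq_len(k), n_per)
  # blob centers: orthogonal corners scaled by centers_scale
  centers <- matrix(0, k, n_genes)
  for (c in seq_len(k)) {
    idx <- seq(c, n_genes, by = k)
    centers[c, idx] <- centers_scale
  }
  x <- matrix(rnorm(n_genes * n), n_genes, n)
  for (i in seq_len(n)) x[, i] <- x[, i] + centers[labels[i], ]
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n)))
  list(x = x, labels = labels)
}

# small censored survival fixture with hand-checkable structure
surv_fixture_10 <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:10),
    time = c(2, 3, 3, 5, 7, 8, 10, 12, 14, 15),
    event = c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
}

# random survival table (exponential, uniform censoring), vectors aligned
random_surv <- function(n, seed, rate = 0.05, cens_max = 40) {
  set.seed(seed)
  t_ev <- rexp(n, rate)
  t_c <- runif(n, 0, cens_max)
  data.frame(sample_id = sprintf("r%04d", seq_len(n)),
             time = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c),
             stringsAsFactors = FALSE)
}

# independent product-limit estimator (brute force, for KM oracles)
product_limit <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- numeric(length(ut))
  cur <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    cur <- cur * (1 - d / at_risk)
    s[i] <- cur
  }
  data.frame(time = ut, surv = s)
}

# brute-force Harrell C (literal double loop; the independent oracle)
cindex_bruteforce <- function(scores, time, event) {
  conc <- 0; usable <- 0
  n <- length(scores)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- i; b <- j
    if (time[b] < time[a]) { a <- j; b <- i }
    if (time[a] == time[b]) {
      if (event[i] + event[j] != 1) next
      a <- if (event[i] == 1) i else j
      b <- if (event[i] == 1) j else i
    } else if (event[a] != 1) next
    usable <- usable + 1
    if (scores[a] > scores[b]) conc <- conc + 1
    else if (scores[a] == scores[b]) conc <- conc + 0.5
  }
  conc / usable
}

# tiny classifier config so training tests stay fast
tiny_cf_config <- function(n_genes, k, ...) {
  crossfusion_config(n_genes = n_genes, k_classes = k, window = 2L,
                     stride = 2L, conv_channels = c(4L, 4L, 4L),
                     hidden = 4L, d = 8L, dropout = 0, lr = 5e-3,
                     batch_size = 16L, max_epochs = 15L, patience = 15L,
                     ...)
}
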