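# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense normal-equations solve instead of the SVD
# pseudoinverse, pairwise tallies instead of vectorized counting.

# ridge-limit normal equations: W = Y H' (H H' + lambda I)^{-1}. Forming
# H H' squares cond(H), so this oracle is only accurate to ~cond(H)^2 * eps:
# compare it at 1e-8 only on instances with cond(H) well below sqrt(1e8).
lsq_oracle <- function(H, Y, lambda = 0) {
  Y %*% t(H) %*% solve(tcrossprod(H) + diag(lambda, nrow(H)))
}

# dense QR least-squares oracle on the transposed system H' W' = Y';
# numerically stable for any full-rank H, independent of the SVD route
lsq_oracle_qr <- function(H, Y) {
  t(qr.solve(t(H), t(Y)))
}

cond_number <- function(H) {
  d <- svd(H)$d
  max(d) / min(d)
}

# rebuild the training matrices of a seeded FLN instance outside fln_solve
build_instance <- function(N, n, m, seed, l = 2L) {
  set.seed(seed)
  x <- matrix(runif(N * n), nrow = N)
  labels <- c(1L, 2L, sample(1:l, N - 2L, replace = TRUE))
  cfg <- fln_config(hidden_count = m, seed = seed + 1L,
                    scale_features = FALSE)
  w <- fln_init_weights(cfg, n)
  G <- fln_hidden_output(w$W_in, w$b, t(x))
  list(x = x, labels = labels, cfg = cfg,
       H = rbind(t(x), G), Y = encode_targets(labels, l))
}

# brute-force pairwise confusion tally
confusion_oracle <- function(truth, pred, positive = 1L) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive) {
      if (pred[i] == positive) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred[i] == positive) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# Mann-Whitney AUC: concordant pairs / (P * N), ties counted half
auc_oracle <- function(scores, truth, positive = 1L) {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# held-out accuracy of a single seeded fit on a synthetic dataset
holdout_accuracy <- function(data, hidden_count, split_seed, fit_seed) {
  s <- stratified_split(data, 0.3, seed = split_seed)
  m <- fln_fit(s$train, fln_config(hidden_count, seed = fit_seed))
  mean(predict(m, s$test$features) == s$test$labels)
}

# in-memory WBCD-dialect fixture (one row carries a missing value)
wbcd_fixture_lines <- function() {
  c("1000025,5,1,1,1,2,1,3,1,1,2",
    "1002945,5,4,4,5,7,10,3,2,1,2",
    "1015425,3,1,1,1,2,2,3,1,1,2",
    "1016277,6,8,8,1,3,4,3,7,1,4",
    "1057013,8,4,5,1,2,?,7,3,1,4")
}

wdbc_fixture_lines <- function() {
  row <- function(start)
    paste(sprintf("%.4f", seq(start, start + 2.9, length.out = 30)),
          collapse = ",")
  paste0(c("842302,M,", "842517,M,", "8510426,B,"),
         c(row(0.10), row(0.20), row(0.15)))
}
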