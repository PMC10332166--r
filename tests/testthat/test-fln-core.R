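test_that("random initialization respects the documented ranges and seed", {
  cfg <- fln_config(hidden_count = 2, seed = 7)
  w <- fln_init_weights(cfg, n_features = 3)
  expect_equal(dim(w$W_in), c(2L, 3L))
  expect_length(w$b, 2L)
  expect_true(all(w$W_in >= -1 & w$W_in <= 1))
  expect_true(all(w$b >= 0 & w$b <= 1))

  # determinism of the seeded stream
  w1 <- fln_init_weights(fln_config(1, seed = 42), 1)
  w2 <- fln_init_weights(fln_config(1, seed = 42), 1)
  expect_identical(w1, w2)

  # uniform-distribution moments at 450 weight / 50 bias draws
  w3 <- fln_init_weights(fln_config(50, seed = 0), 9)
  expect_lt(abs(mean(w3$W_in)), 0.15)
  expect_lt(abs(mean(w3$b) - 0.5), 0.15)

  expect_error(fln_config(hidden_count = 0), "positive")
  expect_error(fln_init_weights(cfg, 0), "positive")
})

test_that("hidden-layer output applies g row-wise with the right shape", {
  # g(0) = 0.5 everywhere
  G0 <- fln_hidden_output(matrix(0, 2, 3), c(0, 0), matrix(1:6 / 6, 3, 2))
  expect_true(all(G0 == 0.5))

  # hand evaluation of 1/(1+exp(-1))
  G1 <- fln_hidden_output(matrix(1), 0, matrix(1))
  expect_equal(G1[1, 1], 0.73106, tolerance = 1e-4)

  # m x N shape
  set.seed(1)
  G <- fln_hidden_output(matrix(runif(3 * 4), 3, 4), runif(3),
                         matrix(runif(4 * 5), 4, 5))
  expect_equal(dim(G), c(3L, 5L))
  expect_true(all(G > 0 & G < 1))

  expect_error(fln_hidden_output(matrix(0, 2, 3), c(0, 0), matrix(0, 2, 5)),
               "shape")
})

test_that("one-hot encoding partitions unity per column", {
  expect_equal(encode_targets(c(1, 2, 2), 2),
               matrix(c(1, 0, 0, 1, 0, 1), nrow = 2))
  expect_equal(encode_targets(2, 2), matrix(c(0, 1), nrow = 2))
  expect_error(encode_targets(c(1, 3), 2), "invalid label")
  for (seed in 1:5) {
    set.seed(seed)
    lab <- sample(1:4, 30, replace = TRUE)
    expect_equal(colSums(encode_targets(lab, 4)), rep(1, 30))
  }
})

test_that("closed-form solve matches independent least-squares oracles", {
  # tiny instance plus larger seeded ones, all N <= 50; the QR oracle is
  # checked everywhere, the normal-equations oracle wherever its own
  # conditioning keeps it meaningful at this tolerance
  cases <- list(c(N = 8, n = 3, m = 4), c(N = 30, n = 9, m = 6),
                c(N = 40, n = 10, m = 8), c(N = 50, n = 5, m = 20))
  ne_checked <- 0L
  for (cs in cases) {
    for (seed in 1:3) {
      inst <- build_instance(cs["N"], cs["n"], cs["m"], seed = seed * 17L)
      sol <- fln_solve(inst$x, t(inst$Y), inst$cfg)
      W_hat <- cbind(sol$W_oi, sol$W_oh)
      expect_lt(max(abs(W_hat - lsq_oracle_qr(inst$H, inst$Y))), 1e-8)
      if (cond_number(inst$H) < 3e3) {
        expect_lt(max(abs(W_hat - lsq_oracle(inst$H, inst$Y))), 1e-8)
        expect_lt(max(abs(W_hat - lsq_oracle(inst$H, inst$Y, 1e-15))), 1e-8)
        ne_checked <- ne_checked + 1L
      }
    }
  }
  expect_gte(ne_checked, 6L)
})

test_that("a linear target map is fitted with vanishing residual", {
  probe <- generate_linear_probe(n = 10, n_features = 2, seed = 3)
  expect_equal(probe$targets, probe$features %*% t(probe$A))
  sol <- fln_solve(probe$features, probe$targets,
                   fln_config(hidden_count = 4, seed = 9,
                              scale_features = FALSE))
  expect_lt(sol$residual, 1e-6)
  # same seed twice -> identical fixture
  expect_identical(probe, generate_linear_probe(10, 2, seed = 3))
})

test_that("full-rank H interpolates the targets exactly", {
  for (seed in c(2, 11, 23)) {
    inst <- build_instance(N = 10, n = 3, m = 12, seed = seed)
    expect_equal(qr(inst$H)$rank, 10L)
    sol <- fln_solve(inst$x, t(inst$Y), inst$cfg)
    W_hat <- cbind(sol$W_oi, sol$W_oh)
    expect_lt(max(abs(W_hat %*% inst$H - inst$Y)), 1e-6)
    # predictions through the fitted classifier reproduce the one-hot targets
    d <- fln_dataset(inst$x, inst$labels)
    model <- fln_fit(d, inst$cfg)
    scores <- predict(model, inst$x, type = "score")
    expect_lt(max(abs(t(scores) - inst$Y)), 1e-6)
    expect_equal(predict(model, inst$x), inst$labels)
  }
})

test_that("the solved weights are the least-squares optimum", {
  inst <- build_instance(N = 30, n = 4, m = 8, seed = 5)
  sol <- fln_solve(inst$x, t(inst$Y), inst$cfg)
  W_hat <- cbind(sol$W_oi, sol$W_oh)
  base_err <- sum((W_hat %*% inst$H - inst$Y)^2)
  set.seed(99)
  for (i in 1:100) {
    delta <- matrix(rnorm(length(W_hat)), nrow(W_hat))
    delta <- delta / sqrt(sum(delta^2)) * runif(1, 1e-3, 1)
    pert_err <- sum(((W_hat + delta) %*% inst$H - inst$Y)^2)
    expect_lte(base_err, pert_err)
  }
})

test_that("fitting is deterministic and rejects degenerate inputs", {
  d <- synth_dataset("wbcd_like", 30, 50, separation = 2, seed = 1)
  cfg <- fln_config(hidden_count = 10, seed = 4)
  m1 <- fln_fit(d, cfg)
  m2 <- fln_fit(d, cfg)
  expect_identical(m1[c("W_in", "b", "W_oi", "W_oh", "c", "scaler")],
                   m2[c("W_in", "b", "W_oi", "W_oh", "c", "scaler")])
  expect_identical(m1$c, c(0, 0))

  single <- fln_dataset(d$features[d$labels == 1L, ],
                        d$labels[d$labels == 1L])
  expect_error(fln_fit(single, cfg), "two classes")

  # constant feature maps to 0 under scaling, no error
  feats <- cbind(d$features, constant = 5)
  dc <- fln_dataset(feats, d$labels)
  expect_s3_class(fln_fit(dc, cfg), "fln")
})

test_that("prediction is a row-wise argmax with documented tie-break", {
  d <- synth_dataset("wbcd_like", 25, 40, separation = 3, seed = 2)
  model <- fln_fit(d, fln_config(hidden_count = 8, seed = 3))

  # score rows decide by maximum; ties go to the smallest class index
  expect_equal(max.col(matrix(c(0.9, 0.1), 1), "first"), 1L)
  expect_equal(max.col(matrix(c(0.5, 0.5), 1), "first"), 1L)
  set.seed(8)
  S <- matrix(rnorm(1000 * 3), ncol = 3)
  scan <- apply(S, 1L, function(r) which(r == max(r))[1])
  expect_equal(max.col(S, "first"), as.integer(scan))

  # permutation equivariance of the row-wise map
  idx <- sample(nrow(d$features))
  expect_equal(predict(model, d$features, type = "score")[idx, ],
               predict(model, d$features[idx, ], type = "score"))

  # all-zero output weights give all-zero scores
  zero <- model
  zero$W_oi[] <- 0
  zero$W_oh[] <- 0
  expect_true(all(predict(zero, d$features, type = "score") == 0))

  expect_error(predict(model, d$features[, 1:3]), "shape")
})

test_that("model serialization round-trips bit-exactly", {
  d <- synth_dataset("wdbc_like", 20, 30, separation = 2, seed = 6)
  model <- fln_fit(d, fln_config(hidden_count = 7, seed = 11))
  path <- withr::local_tempfile(fileext = ".json")
  write_fln(model, path)
  back <- read_fln(path)
  expect_identical(model[c("W_in", "b", "W_oi", "W_oh", "c")],
                   back[c("W_in", "b", "W_oi", "W_oh", "c")])
  expect_identical(model$scaler$min, back$scaler$min)
  expect_identical(model$scaler$max, back$scaler$max)
  expect_identical(unclass(model$config), unclass(back$config))
  expect_identical(predict(model, d$features, type = "score"),
                   predict(back, d$features, type = "score"))
})
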