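test_that("squash matches the closed forms of both variants", {
  expect_equal(squash(rep(0, 5)), rep(0, 5))

  u <- c(3, 4) / 5                    # unit vector
  expect_equal(sqrt(sum(squash(u, "sabour")^2)), 0.5)
  expect_equal(sqrt(sum(squash(u, "as_printed")^2)), 0.5)

  s3 <- 3 * u                         # norm 3
  expect_equal(sqrt(sum(squash(s3, "sabour")^2)), 0.9)
  expect_equal(sqrt(sum(squash(s3, "as_printed")^2)), 0.3)
})

test_that("squash preserves direction and respects norm bounds", {
  set.seed(3)
  for (i in 1:50) {
    s <- rnorm(8, sd = runif(1, 0.1, 10))
    for (variant in c("sabour", "as_printed")) {
      v <- squash(s, variant)
      expect_equal(v, oracle_squash(s, variant), tolerance = 1e-12)
      ## nonnegative multiple of s: cosine similarity 1
      expect_gte(sum(v * s), 0)
      expect_equal(sum(v * s) / sqrt(sum(v^2) * sum(s^2)), 1,
                   tolerance = 1e-10)
      nv <- sqrt(sum(v^2))
      if (variant == "sabour") expect_lt(nv, 1) else expect_lte(nv, 0.5)
    }
  }
  ## matrix form agrees with rowwise application
  m <- matrix(rnorm(30), 5, 6)
  expect_equal(squash(m), t(apply(m, 1, oracle_squash)), tolerance = 1e-12)
})

test_that("conv_lane is a 'same'-padded stride-1 cross-correlation with ReLU", {
  cfg <- lane_config(3, n_conv_filters = 4, dropout_rate = 0)
  set.seed(5)
  w <- list(Wc = matrix(rnorm(3 * 20 * 4), 60, 4), bc = numeric(4))

  expect_equal(conv_lane(matrix(0, 15, 20), cfg, w), matrix(0, 15, 4))

  ## kernel size 1 with a delta kernel reproduces a scaled input channel
  cfg1 <- lane_config(1, n_conv_filters = 1, dropout_rate = 0)
  wd <- list(Wc = matrix(0, 20, 1), bc = 0)
  wd$Wc[7, 1] <- 2
  x <- matrix(abs(rnorm(200)), 10, 20)
  expect_equal(conv_lane(x, cfg1, wd)[, 1], 2 * x[, 7])

  ## random instance against the triple-loop oracle
  x20 <- matrix(rnorm(400), 20, 20)
  w$bc <- rnorm(4)
  expect_equal(conv_lane(x20, cfg, w), oracle_conv(x20, w$Wc, w$bc, 3),
               tolerance = 1e-12)
})

test_that("primary_caps yields one squashed capsule per position and channel", {
  cfg <- lane_config(3, n_conv_filters = 4, primary_channels = 2,
                     capsule_dim = 3, dropout_rate = 0)
  set.seed(6)
  w <- list(Wp = matrix(rnorm(4 * 6), 4, 6), bp = rnorm(6))
  feat <- matrix(rnorm(40), 10, 4)
  caps <- primary_caps(feat, cfg, w)
  expect_equal(dim(caps), c(10L, 2L, 3L))
  expect_equal(caps, oracle_primary(feat, w$Wp, w$bp, 2, 3),
               tolerance = 1e-12)
  norms <- apply(caps, c(1, 2), function(v) sqrt(sum(v^2)))
  expect_true(all(norms < 1))

  expect_equal(primary_caps(matrix(0, 10, 4), cfg,
                            list(Wp = w$Wp, bp = numeric(6))),
               array(0, c(10, 2, 3)))

  ## the deployed geometry: 1000 positions x 8 channels of 16D capsules
  cfg_full <- lane_config(3)
  wf <- list(Wp = matrix(rnorm(10 * 128, sd = 0.1), 10, 128),
             bp = numeric(128))
  expect_equal(dim(primary_caps(matrix(rnorm(10000), 1000, 10), cfg_full, wf)),
               c(1000L, 8L, 16L))
})

test_that("dynamic_routing handles degenerate cases analytically", {
  set.seed(7)
  ## one input, one output: V = squash(u_hat), coupling 1
  u <- array(rnorm(4), c(1, 1, 4))
  r <- dynamic_routing(u, iterations = 4)
  expect_equal(as.vector(r$v), oracle_squash(u[1, 1, ]), tolerance = 1e-12)
  expect_equal(as.vector(r$couplings), 1)

  ## one iteration: couplings are the uniform softmax of zero logits
  u2 <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
  r2 <- dynamic_routing(u2, iterations = 1)
  expect_equal(r2$couplings, matrix(1 / 5, 3, 5), ignore_attr = TRUE)
})

test_that("dynamic_routing agrees with the straight-line oracle", {
  set.seed(8)
  for (rep in 1:5) {
    u <- array(rnorm(3 * 2 * 4, sd = 2), c(3, 2, 4))
    for (variant in c("sabour", "as_printed")) {
      got <- dynamic_routing(u, iterations = 5, variant = variant)
      want <- oracle_routing(u, 5, variant)
      expect_equal(got$v, want$v, tolerance = 1e-10)
      expect_equal(got$couplings, want$couplings, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("coupling coefficients are a probability distribution at every iteration", {
  set.seed(9)
  u <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  hist <- oracle_routing(u, 5, keep_history = TRUE)$history
  for (cc in hist) {
    expect_true(all(cc >= 0))
    expect_true(all(abs(rowSums(cc) - 1) < 1e-6))
  }
  ## the package path reports the final couplings; same invariant
  got <- dynamic_routing(u, iterations = 5)$couplings
  expect_true(all(got >= 0))
  expect_true(all(abs(rowSums(got) - 1) < 1e-6))
})

test_that("routing is equivariant under permutation of input capsules", {
  set.seed(10)
  u <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  perm <- c(4, 1, 5, 3, 2)
  r1 <- dynamic_routing(u, iterations = 5)
  r2 <- dynamic_routing(u[perm, , , drop = FALSE], iterations = 5)
  expect_equal(r2$v, r1$v, tolerance = 1e-12)
  expect_equal(r2$couplings, r1$couplings[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("hidden_caps shares routing weights across the positional grid", {
  cfg <- lane_config(3, primary_channels = 2, capsule_dim = 3,
                     hidden_capsules = 2, routing_iterations = 3,
                     dropout_rate = 0)
  set.seed(11)
  w <- list(Wr = array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2)))

  expect_equal(hidden_caps(array(0, c(6, 2, 3)), cfg, w)$v,
               matrix(0, 2, 3))

  prim <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  h <- hidden_caps(prim, cfg, w)
  expect_equal(dim(h$v), c(2L, 3L))
  ho <- oracle_hidden(prim, w$Wr, 2, 3)
  expect_equal(h$v, ho$v, tolerance = 1e-10)

  ## permuting positions leaves the routed output unchanged (shared weights)
  h2 <- hidden_caps(prim[c(3, 1, 6, 2, 5, 4), , , drop = FALSE], cfg, w)
  expect_equal(h2$v, h$v, tolerance = 1e-12)

  expect_error(hidden_caps(prim, cfg, list(Wr = array(0, c(3, 3, 2, 5)))),
               "shape")

  ## the deployed geometry: eight 16D hidden capsules per lane
  cfg_full <- lane_config(3)
  set.seed(12)
  wf <- list(Wr = array(rnorm(16 * 16 * 8 * 8, sd = 0.05), c(16, 16, 8, 8)))
  hf <- hidden_caps(array(rnorm(20 * 8 * 16), c(20, 8, 16)), cfg_full, wf)
  expect_equal(dim(hf$v), c(8L, 16L))
})

test_that("forward produces a softmax distribution deterministically", {
  tn <- tiny_net(input_len = 12L, input_channels = 6L)
  set.seed(13)
  x <- matrix(runif(12 * 6), 12, 6)
  p1 <- capsnet_forward(x, tn$cfg, tn$w)
  p2 <- capsnet_forward(x, tn$cfg, tn$w)
  expect_equal(rowSums(p1), 1, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(p1 >= 0))
  expect_identical(p1, p2)
  expect_error(capsnet_forward(matrix(0, 5, 6), tn$cfg, tn$w), "input")
})

test_that("forward agrees with the composed brute-force oracle", {
  lanes <- list(lane_config(3, n_conv_filters = 3, primary_channels = 2,
                            capsule_dim = 3, hidden_capsules = 2,
                            routing_iterations = 4, dropout_rate = 0),
                lane_config(1, n_conv_filters = 2, primary_channels = 2,
                            capsule_dim = 2, hidden_capsules = 3,
                            routing_iterations = 2, dropout_rate = 0))
  for (variant in c("sabour", "as_printed")) {
    cfg <- network_config(lanes = lanes, input_len = 5L, input_channels = 4L,
                          dense_units = 6L, squash_variant = variant,
                          l2_coefficient = 0)
    set.seed(14)
    w <- capsnet_init(cfg)
    for (rep in 1:3) {
      x <- matrix(rnorm(20), 5, 4)
      got <- as.vector(capsnet_forward(x, cfg, w))
      want <- oracle_forward(x, cfg, w)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("batched forward equals sample-by-sample forward", {
  tn <- tiny_net(input_len = 8L, input_channels = 5L)
  set.seed(15)
  xs <- lapply(1:4, function(i) matrix(rnorm(40), 8, 5))
  pb <- capsnet_forward(xs, tn$cfg, tn$w)
  ps <- do.call(rbind, lapply(xs, capsnet_forward, cfg = tn$cfg, weights = tn$w))
  expect_equal(pb, ps, ignore_attr = TRUE, tolerance = 1e-12)
})
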