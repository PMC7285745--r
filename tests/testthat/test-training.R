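# small, quickly separable synthetic problem: class 1 activates channel 1,
# class 0 activates channel 2
toy_problem <- function(n = 40, len = 10L, chans = 4L, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  inputs <- lapply(labels, function(y) {
    x <- matrix(runif(len * chans, 0, 0.1), len, chans)
    x[, y + 1L] <- x[, y + 1L] + 0.8
    pad_or_truncate(x, len)
  })
  list(inputs = inputs, labels = labels)
}

toy_net <- function(...) {
  network_config(lanes = list(lane_config(3, n_conv_filters = 3,
                                          primary_channels = 2,
                                          capsule_dim = 2, hidden_capsules = 2,
                                          routing_iterations = 2,
                                          dropout_rate = 0)),
                 input_len = 10L, input_channels = 4L, dense_units = 4L, ...)
}

test_that("make_bags builds balanced bags from an imbalanced pool", {
  pos <- sprintf("P%03d", 1:350)
  neg <- sprintf("N%04d", 1:1750)
  cfg <- bagging_config(iterations = 10L, bag_size = 350L, seed = 3L)
  bags <- make_bags(pos, neg, cfg)
  expect_length(bags, 10)
  for (b in bags) {
    expect_equal(length(b$positives) + length(b$negatives), 700L)
    expect_setequal(b$positives, pos)              # all positives, every bag
    expect_length(b$negatives, 350L)
    expect_false(anyDuplicated(b$negatives) > 0)   # without replacement
    expect_true(all(b$negatives %in% neg))
  }
  ## negatives re-drawn per bag
  expect_false(identical(bags[[1]]$negatives, bags[[2]]$negatives))

  ## reproducible under the same seed
  bags2 <- make_bags(pos, neg, cfg)
  expect_identical(bags, bags2)

  ## n = |negatives|: every bag holds the full negative set
  cfg_all <- bagging_config(iterations = 3L, bag_size = 30L, seed = 1L)
  bags3 <- make_bags(pos[1:10], neg[1:30], cfg_all)
  for (b in bags3) expect_setequal(b$negatives, neg[1:30])

  expect_error(make_bags(pos, neg[1:100], cfg), "exceeds")
})

test_that("kfold_split is a stratified partition", {
  labels <- rep(c(1L, 0L), each = 350)
  folds <- kfold_split(labels, k = 10L, seed = 2L)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 70))
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_along(labels))         # disjoint and exhaustive
  for (f in folds) {
    expect_equal(sum(labels[f]), 35)               # stratified
  }
  expect_identical(folds, kfold_split(labels, k = 10L, seed = 2L))
  expect_error(kfold_split(labels, k = 1000L), "exceeds")
  expect_error(kfold_split(c(1L, 1L, 1L, 0L), k = 3L), "class")
})

test_that("train_member reduces the loss on separable data, reproducibly", {
  toy <- toy_problem()
  cfg <- train_config(batch_size = 8L, max_epochs = 8L,
                      early_stop_patience = 8L, validation_fraction = 0.2,
                      l2_coefficient = 1e-4)
  m <- train_member(toy$inputs, toy$labels, toy_net(), cfg, seed = 5L)
  expect_s3_class(m, "capsnet_model")
  expect_lt(min(m$history$train_loss), m$history$train_loss[1])
  expect_lt(m$history$val_loss[nrow(m$history)], log(2))  # better than chance

  ## bit-stable under the same seed
  m2 <- train_member(toy$inputs, toy$labels, toy_net(), cfg, seed = 5L)
  expect_identical(m$weights, m2$weights)

  expect_error(train_member(toy$inputs, rep(1L, 40), toy_net(), cfg),
               "both classes")
})

test_that("early stopping halts before the epoch budget on noise", {
  set.seed(6)
  toy <- toy_problem()
  noise_labels <- sample(toy$labels)               # destroy the signal
  cfg <- train_config(batch_size = 8L, max_epochs = 40L,
                      early_stop_patience = 1L, validation_fraction = 0.2)
  m <- train_member(toy$inputs, noise_labels, toy_net(), cfg, seed = 7L)
  expect_lt(nrow(m$history), 40)
  expect_lte(m$best_epoch, nrow(m$history))
})

test_that("stronger L2 yields smaller weights, all else equal", {
  toy <- toy_problem()
  norm_of <- function(l2) {
    cfg <- train_config(batch_size = 8L, max_epochs = 6L,
                        early_stop_patience = 6L, validation_fraction = 0.2,
                        l2_coefficient = l2)
    m <- train_member(toy$inputs, toy$labels, toy_net(), cfg, seed = 8L)
    sqrt(sum(unlist(lapply(rapply(m$weights, identity, how = "unlist"),
                           function(x) x))^2))
  }
  expect_lt(norm_of(0.3), norm_of(0))
})

test_that("ensemble_predict is the arithmetic mean of member outputs", {
  net <- toy_net()
  members <- lapply(1:3, function(s) {
    set.seed(100 + s)
    structure(list(weights = capsnet_init(net), net = net),
              class = "capsnet_model")
  })
  ens <- structure(list(members = members, net = net),
                   class = "capsnet_ensemble")
  toy <- toy_problem(n = 5)
  pm <- ensemble_predict(ens, toy$inputs)
  indiv <- lapply(members, function(m) predict(m, toy$inputs))
  expect_equal(pm, (indiv[[1]] + indiv[[2]] + indiv[[3]]) / 3,
               tolerance = 1e-12)
  expect_equal(rowSums(pm), rep(1, 5), ignore_attr = TRUE, tolerance = 1e-12)
  ## identical members: the mean is each member's output
  ens1 <- structure(list(members = members[c(1, 1)], net = net),
                    class = "capsnet_ensemble")
  expect_equal(ensemble_predict(ens1, toy$inputs), indiv[[1]],
               tolerance = 1e-12)
  expect_error(ensemble_predict(structure(list(members = list()),
                                          class = "capsnet_ensemble"),
                                toy$inputs), "empty")
})

test_that("the full bagging pipeline is reproducible under a fixed seed", {
  toy <- toy_problem(n = 30)
  cfg <- bagging_config(iterations = 2L, bag_size = 10L, seed = 9L,
                        train = train_config(batch_size = 8L, max_epochs = 3L,
                                             early_stop_patience = 3L,
                                             validation_fraction = 0.2))
  e1 <- train_ensemble(toy$inputs, toy$labels, toy_net(), cfg)
  e2 <- train_ensemble(toy$inputs, toy$labels, toy_net(), cfg)
  expect_identical(lapply(e1$members, `[[`, "weights"),
                   lapply(e2$members, `[[`, "weights"))
  expect_identical(e1$bags, e2$bags)
  p1 <- ensemble_predict(e1, toy$inputs[1:4])
  p2 <- ensemble_predict(e2, toy$inputs[1:4])
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip through save and load", {
  toy <- toy_problem(n = 20)
  cfg <- train_config(batch_size = 8L, max_epochs = 2L,
                      early_stop_patience = 2L, validation_fraction = 0.2)
  m <- train_member(toy$inputs, toy$labels, toy_net(), cfg, seed = 10L)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(predict(m, toy$inputs[1:2]), predict(m2, toy$inputs[1:2]))
  saveRDS(list(1), f)
  expect_error(load_checkpoint(f), "checkpoint")
})
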