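#' Optimizer and regularization settings
#'
#' Adam constants follow the published training protocol (learning rate
#' 0.001, first/second-moment decay 0.9/0.999); the remaining knobs are
#' conventional defaults, exposed so scaled-down runs can shrink them.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam first/second-moment decay rates.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Stop when validation cross-entropy has not
#'   improved for this many epochs.
#' @param validation_fraction Fraction of the bag held out to monitor
#'   validation loss.
#' @param l2_coefficient L2 penalty on weight matrices.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 32L, max_epochs = 100L,
                         early_stop_patience = 10L, validation_fraction = 0.1,
                         l2_coefficient = 1e-4) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1, max_epochs >= 1, early_stop_patience >= 1,
            validation_fraction > 0, validation_fraction < 1,
            l2_coefficient >= 0)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 l2_coefficient = l2_coefficient),
            class = "train_config")
}

#' Bagging configuration
#'
#' The deployed protocol uses `iterations = 10` balanced bags of
#' `bag_size = 350` negatives (each joined with all positives).
#'
#' @param iterations Number of bagging iterations T.
#' @param bag_size Number of negatives drawn (without replacement) per bag.
#' @param seed Integer seed controlling bag composition and member training.
#' @param train A [train_config()].
#' @return A `bagging_config` object.
#' @export
bagging_config <- function(iterations = 10L, bag_size = 350L, seed = 1L,
                           train = train_config()) {
  stopifnot(iterations >= 1, bag_size >= 1, inherits(train, "train_config"))
  structure(list(iterations = as.integer(iterations),
                 bag_size = as.integer(bag_size),
                 seed = as.integer(seed), train = train),
            class = "bagging_config")
}

## deterministic fan-out of one user seed into per-component seeds
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + 7919 * index) %% 2147483563)
}

#' Build balanced bags from an imbalanced dataset
#'
#' Every bag contains all positives (or `bag_size` positives when more are
#' available) plus `bag_size` negatives sampled without replacement within
#' the bag; negatives are re-drawn independently for each bag.
#'
#' @param positives Vector of positive identifiers (or indices).
#' @param negatives Vector of negative identifiers (or indices).
#' @param cfg A [bagging_config()].
#' @return List of `iterations` bags, each a list with `positives` and
#'   `negatives`.
#' @export
make_bags <- function(positives, negatives, cfg = bagging_config()) {
  n <- cfg$bag_size
  if (length(positives) < 1) stop("need at least one positive sample")
  if (length(negatives) < n) {
    stop("bag_size (", n, ") exceeds the number of negatives (",
         length(negatives), ")")
  }
  lapply(seq_len(cfg$iterations), function(t) {
    set.seed(.derive_seed(cfg$seed, t))
    pos <- if (length(positives) > n) sample(positives, n) else positives
    neg <- sample(negatives, n)
    list(positives = pos, negatives = neg)
  })
}

#' Stratified k-fold split
#'
#' Partitions sample indices into `k` label-stratified folds: disjoint,
#' jointly exhaustive, reproducible under `seed`.
#'
#' @param labels Vector of 0/1 labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `k` integer vectors of fold (validation) indices.
#' @export
kfold_split <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k > length(labels)) stop("k exceeds dataset size")
  tab <- table(labels)
  if (any(tab < k)) {
    stop("k (", k, ") exceeds the size of class ",
         names(tab)[which.min(tab)], " (", min(tab), ")")
  }
  set.seed(.derive_seed(seed, 0L))
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_of <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[fold_of == f])
    }
  }
  lapply(folds, sort)
}

## -------------------------------------------------------------------------
## backward pass

.squash_backward <- function(Sblock, n, dVblock, variant) {
  h <- .squash_scale(n, variant)
  hp <- .squash_scale_deriv(n, variant)
  sdv <- rowSums(Sblock * dVblock)
  dVblock * h + Sblock * (hp * sdv / (n + .EPS))
}

.lane_backward <- function(lf, dV, B, P, lc, lw, variant, training) {
  C <- lc$primary_channels; D <- lc$capsule_dim; J <- lc$hidden_capsules
  Pp <- lf$Pp

  ## hidden-capsule squash backward
  dS <- matrix(0, B, J * D)
  for (j in seq_len(J)) {
    cols <- ((j - 1L) * D + 1L):(j * D)
    dS[, cols] <- .squash_backward(lf$S[, cols, drop = FALSE], lf$hid_n[, j],
                                   dV[, cols, drop = FALSE], variant)
  }

  ## routing backward with couplings treated as constants; the J affine
  ## maps of a channel are handled as one fused (D x J*D) block
  dU <- .routing_bwd_cpp(lf$cc, dS, Pp, D)
  dMu <- matrix(0, B * Pp, C * D)
  dWr <- array(0, dim(lw$Wr))
  for (c in seq_len(C)) {
    dUc <- matrix(dU[, , c], B * Pp, J * D)
    mcols <- ((c - 1L) * D + 1L):(c * D)
    Mu_c <- lf$Mu[, mcols, drop = FALSE]
    Wbig <- matrix(lw$Wr[, , c, ], D, D * J)
    dWr[, , c, ] <- array(crossprod(Mu_c, dUc), c(D, D, J))
    dMu[, mcols] <- dUc %*% t(Wbig)
  }

  ## primary-capsule squash backward
  dZp <- matrix(0, B * Pp, C * D)
  for (c in seq_len(C)) {
    cols <- ((c - 1L) * D + 1L):(c * D)
    dZp[, cols] <- .squash_backward(lf$Zp[, cols, drop = FALSE], lf$prim_n[, c],
                                    dMu[, cols, drop = FALSE], variant)
  }
  dWp <- crossprod(lf$R, dZp)
  dbp <- colSums(dZp)
  dR <- dZp %*% t(lw$Wp)

  ## un-stride, dropout, ReLU
  dA1 <- matrix(0, B * P, lc$n_conv_filters)
  dA1[lf$keep, ] <- dR
  if (training && lc$dropout_rate > 0 && !is.null(lf$drop_mask)) {
    dA1 <- dA1 * lf$drop_mask / (1 - lc$dropout_rate)
  }
  dZ1 <- dA1 * (lf$Z1 > 0)
  dWc <- crossprod(lf$Xcol, dZ1)
  dbc <- colSums(dZ1)

  list(Wc = dWc, bc = dbc, Wp = dWp, bp = dbp, Wr = dWr)
}

## loss and full gradient for one batch; Y is (B x 2) one-hot
.capsnet_backward <- function(fw, Y, cfg, weights, training = TRUE) {
  B <- nrow(Y)
  P <- fw$head$P
  loss <- -mean(rowSums(Y * log(P + .EPS)))

  dw <- weights$dense
  dZo <- (P - Y) / B
  dWo <- crossprod(fw$head$Ad, dZo)
  dbo <- colSums(dZo)
  dAd <- dZo %*% t(dw$Wo)
  dZd <- dAd * (fw$head$Zd > 0)
  dWd <- crossprod(fw$H, dZd)
  dbd <- colSums(dZd)
  dH <- dZd %*% t(dw$Wd)

  off <- 0L
  lane_grads <- vector("list", length(cfg$lanes))
  for (l in seq_along(cfg$lanes)) {
    lc <- cfg$lanes[[l]]
    w_l <- lc$hidden_capsules * lc$capsule_dim
    dV <- dH[, (off + 1L):(off + w_l), drop = FALSE]
    off <- off + w_l
    lane_grads[[l]] <- .lane_backward(fw$lanes[[l]], dV, B, cfg$input_len,
                                      lc, weights$lanes[[l]],
                                      cfg$squash_variant, training)
  }

  grads <- list(lanes = lane_grads,
                dense = list(Wd = dWd, bd = dbd, Wo = dWo, bo = dbo))

  ## L2 penalty on weight matrices (not biases)
  l2 <- cfg$l2_coefficient
  if (l2 > 0) {
    for (l in seq_along(grads$lanes)) {
      for (nm in c("Wc", "Wp", "Wr")) {
        grads$lanes[[l]][[nm]] <- grads$lanes[[l]][[nm]] + l2 * weights$lanes[[l]][[nm]]
        loss <- loss + l2 / 2 * sum(weights$lanes[[l]][[nm]]^2)
      }
    }
    for (nm in c("Wd", "Wo")) {
      grads$dense[[nm]] <- grads$dense[[nm]] + l2 * weights$dense[[nm]]
      loss <- loss + l2 / 2 * sum(weights$dense[[nm]]^2)
    }
  }
  list(loss = loss, grads = grads)
}

## -------------------------------------------------------------------------
## Adam over the nested weight structure

.tree_zeros <- function(w) {
  if (is.list(w)) lapply(w, .tree_zeros) else w * 0
}

.adam_step <- function(w, g, st, lr, b1, b2, t, eps = 1e-8) {
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      out_w <- w; out_m <- m; out_v <- v
      for (i in seq_along(w)) {
        r <- walk(w[[i]], g[[i]], m[[i]], v[[i]])
        out_w[[i]] <- r$w; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(w = out_w, m = out_m, v = out_v)
    } else {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g^2
      mhat <- m2 / (1 - b1^t)
      vhat <- v2 / (1 - b2^t)
      list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  r <- walk(w, g, st$m, st$v)
  list(w = r$w, state = list(m = r$m, v = r$v))
}

.stack_inputs <- function(inputs) {
  mats <- lapply(inputs, function(x) if (inherits(x, "encoded_input")) x$values else as.matrix(x))
  do.call(rbind, mats)
}

.batch_ce <- function(Pm, y) {
  -mean(log(Pm[cbind(seq_along(y), y + 1L)] + .EPS))
}

#' Train one network on a (balanced) bag
#'
#' Minibatch Adam on the cross-entropy loss with L2 regularization, dropout
#' after the first convolution of each lane, and early stopping on the
#' cross-entropy of a held-out validation split of the bag. The best
#' validation-loss weights are restored at the end.
#'
#' @param inputs List of `encoded_input` objects (or matrices).
#' @param labels Integer 0/1 labels, 1 = saliva-secretory.
#' @param net A [network_config()].
#' @param cfg A [train_config()].
#' @param seed Integer seed (weight init, shuffling, dropout).
#' @param verbose Print per-epoch losses.
#' @return A `capsnet_model`: list with `weights`, `net`, `history`, `seed`.
#' @export
train_member <- function(inputs, labels, net, cfg = train_config(),
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "network_config"), inherits(cfg, "train_config"))
  labels <- as.integer(labels)
  if (length(inputs) != length(labels)) stop("inputs/labels length mismatch")
  if (length(unique(labels)) < 2) stop("training bag must contain both classes")

  net$l2_coefficient <- cfg$l2_coefficient   # training-time L2 wins
  set.seed(seed)
  weights <- capsnet_init(net)

  ## stratified validation split
  val_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(cfg$validation_fraction * length(idx)))
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  tr_idx <- setdiff(seq_along(labels), val_idx)

  Xtr <- .stack_inputs(inputs[tr_idx]); ytr <- labels[tr_idx]
  Xva <- .stack_inputs(inputs[val_idx]); yva <- labels[val_idx]
  n_tr <- length(ytr); n_va <- length(yva)
  P <- net$input_len

  st <- list(m = .tree_zeros(weights), v = .tree_zeros(weights))
  step <- 0L
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  stall <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(n_tr)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n_tr, by = cfg$batch_size)) {
      bi <- perm[start:min(start + cfg$batch_size - 1L, n_tr)]
      B <- length(bi)
      rows <- as.vector(outer(seq_len(P), (bi - 1L) * P, "+"))
      Xb <- Xtr[rows, , drop = FALSE]
      Yb <- matrix(0, B, 2L); Yb[cbind(seq_len(B), ytr[bi] + 1L)] <- 1
      fw <- .capsnet_forward_batch(Xb, B, net, weights, training = TRUE)
      bw <- .capsnet_backward(fw, Yb, net, weights, training = TRUE)
      step <- step + 1L
      upd <- .adam_step(weights, bw$grads, st, cfg$learning_rate,
                        cfg$beta1, cfg$beta2, step)
      weights <- upd$w; st <- upd$state
      ep_loss <- ep_loss + bw$loss; n_batches <- n_batches + 1L
    }
    fw_va <- .capsnet_forward_batch(Xva, n_va, net, weights, training = FALSE)
    val_loss <- .batch_ce(fw_va$P, yva)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_batches,
                                   val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / n_batches, val_loss))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, weights = weights, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }

  structure(list(weights = best$weights, net = net, history = hist,
                 seed = seed, best_epoch = best$epoch),
            class = "capsnet_model")
}

#' @export
predict.capsnet_model <- function(object, inputs, ...) {
  capsnet_forward(inputs, object$net, object$weights)
}

#' Train a bagging ensemble
#'
#' Draws balanced bags with [make_bags()] and trains one member per bag,
#' each with its own derived seed.
#'
#' @param inputs List of `encoded_input` objects.
#' @param labels Integer 0/1 labels.
#' @param net A [network_config()].
#' @param cfg A [bagging_config()].
#' @param verbose Print training progress.
#' @return A `capsnet_ensemble`: members, bag compositions, seeds.
#' @export
train_ensemble <- function(inputs, labels, net, cfg = bagging_config(),
                           verbose = FALSE) {
  labels <- as.integer(labels)
  bags <- make_bags(which(labels == 1L), which(labels == 0L), cfg)
  members <- vector("list", length(bags))
  seeds <- integer(length(bags))
  for (t in seq_along(bags)) {
    idx <- c(bags[[t]]$positives, bags[[t]]$negatives)
    seeds[t] <- .derive_seed(cfg$seed, 1000L + t)
    if (verbose) message("training ensemble member ", t, "/", length(bags))
    members[[t]] <- train_member(inputs[idx], labels[idx], net, cfg$train,
                                 seed = seeds[t], verbose = verbose)
  }
  structure(list(members = members, bags = bags, seeds = seeds, net = net,
                 config = cfg),
            class = "capsnet_ensemble")
}

#' Ensemble prediction by probability averaging
#'
#' @param model A `capsnet_ensemble`.
#' @param inputs List of `encoded_input` objects (or a single one).
#' @return Matrix `(n_inputs x 2)`: the arithmetic mean of the members'
#'   softmax outputs (rows still sum to 1).
#' @export
ensemble_predict <- function(model, inputs) {
  if (!inherits(model, "capsnet_ensemble")) stop("not a capsnet_ensemble")
  if (length(model$members) == 0) stop("empty ensemble")
  preds <- lapply(model$members, function(m) predict(m, inputs))
  Reduce(`+`, preds) / length(preds)
}

#' @export
predict.capsnet_ensemble <- function(object, inputs, ...) {
  ensemble_predict(object, inputs)
}

#' Save / load a trained model or ensemble
#'
#' Checkpoints are single-file containers holding the weights together with
#' the network configuration, so a checkpoint is self-describing.
#'
#' @param model A `capsnet_model` or `capsnet_ensemble`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("capsnet_model", "capsnet_ensemble")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("capsnet_model", "capsnet_ensemble"))) {
    stop("not a model checkpoint: ", path)
  }
  m
}
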