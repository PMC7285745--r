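#' Configuration of one capsule-network lane
#'
#' A lane is one parallel branch of the network: a 1D convolution of a fixed
#' kernel size (capturing motifs at one length scale), followed by a
#' convolutional capsule layer and agreement-routed hidden capsules.
#'
#' @param kernel_size Odd positive integer; width of the lane's convolution.
#' @param n_conv_filters Number of convolution kernels (default 10).
#' @param primary_channels Number of primary-capsule channels (default 8).
#' @param capsule_dim Dimension of every capsule vector (default 16).
#' @param primary_stride Stride of the primary-capsule convolution
#'   (default 1, which keeps one capsule per sequence position).
#' @param hidden_capsules Number of hidden capsules the lane routes into
#'   (default 8).
#' @param routing_iterations Number of dynamic-routing iterations (default 5).
#' @param dropout_rate Dropout rate applied after the first convolution
#'   during training (default 0.5).
#' @return A `lane_config` object.
#' @export
lane_config <- function(kernel_size, n_conv_filters = 10L, primary_channels = 8L,
                        capsule_dim = 16L, primary_stride = 1L,
                        hidden_capsules = 8L, routing_iterations = 5L,
                        dropout_rate = 0.5) {
  kernel_size <- as.integer(kernel_size)
  stopifnot(kernel_size >= 1L, kernel_size %% 2L == 1L,
            n_conv_filters >= 1L, primary_channels >= 1L, capsule_dim >= 1L,
            primary_stride >= 1L, hidden_capsules >= 1L,
            routing_iterations >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(kernel_size = kernel_size,
                 n_conv_filters = as.integer(n_conv_filters),
                 primary_channels = as.integer(primary_channels),
                 capsule_dim = as.integer(capsule_dim),
                 primary_stride = as.integer(primary_stride),
                 hidden_capsules = as.integer(hidden_capsules),
                 routing_iterations = as.integer(routing_iterations),
                 dropout_rate = dropout_rate),
            class = "lane_config")
}

#' Configuration of the full multilane network
#'
#' Defaults reproduce the deployed architecture: eight lanes with kernel
#' sizes 1, 3, 5, 9, 15, 21, 27 and 33 over a 1000 x 20 profile, a 128-unit
#' dense layer and a two-class softmax head.
#'
#' @param lanes List of [lane_config()] objects.
#' @param input_len Fixed input length (rows of the encoded profile).
#' @param input_channels Number of input channels (20 amino acids).
#' @param dense_units Width of the dense layer before the softmax.
#' @param n_classes Number of output classes (2: secretory vs not).
#' @param squash_variant `"sabour"` (default) for the original squash
#'   `(|s|^2/(1+|s|^2)) s/|s|`; `"as_printed"` for the variant
#'   `(|s|/(1+|s|^2)) s/|s|`, which is bounded by 1/2 and non-monotone.
#' @param l2_coefficient L2 penalty coefficient on weight matrices.
#' @return A `network_config` object.
#' @export
network_config <- function(lanes = lapply(c(1L, 3L, 5L, 9L, 15L, 21L, 27L, 33L),
                                          lane_config),
                           input_len = 1000L, input_channels = 20L,
                           dense_units = 128L, n_classes = 2L,
                           squash_variant = c("sabour", "as_printed"),
                           l2_coefficient = 1e-4) {
  squash_variant <- match.arg(squash_variant)
  if (inherits(lanes, "lane_config")) lanes <- list(lanes)
  stopifnot(length(lanes) >= 1, all(vapply(lanes, inherits, TRUE, "lane_config")),
            input_len >= 2, input_channels >= 1, dense_units >= 1,
            n_classes == 2L, l2_coefficient >= 0)
  structure(list(lanes = lanes, input_len = as.integer(input_len),
                 input_channels = as.integer(input_channels),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 squash_variant = squash_variant,
                 l2_coefficient = l2_coefficient),
            class = "network_config")
}

.EPS <- 1e-8

## squash scale h(n) such that v = h(||s||) * s, and its derivative h'(n)
.squash_scale <- function(n, variant) {
  switch(variant,
         sabour = n / (1 + n^2),
         as_printed = 1 / (1 + n^2),
         stop("unknown squash variant: ", variant))
}

.squash_scale_deriv <- function(n, variant) {
  switch(variant,
         sabour = (1 - n^2) / (1 + n^2)^2,
         as_printed = -2 * n / (1 + n^2)^2,
         stop("unknown squash variant: ", variant))
}

#' Squashing nonlinearity for capsule vectors
#'
#' Rescales a capsule vector's length into a probability-like range while
#' preserving its direction. The `"sabour"` variant maps a vector of norm `n`
#' to norm `n^2/(1+n^2)` (approaching 1 for long vectors); the
#' `"as_printed"` variant maps it to norm `n/(1+n^2)` (bounded by 1/2).
#' A zero vector maps to the zero vector.
#'
#' @param s Numeric vector (one capsule) or matrix (one capsule per row).
#' @param variant `"sabour"` or `"as_printed"`.
#' @return Same shape as `s`.
#' @export
squash <- function(s, variant = c("sabour", "as_printed")) {
  variant <- match.arg(variant)
  if (is.matrix(s)) {
    if (!all(is.finite(s))) stop("squash: non-finite input")
    n <- sqrt(rowSums(s^2))
    s * .squash_scale(n, variant)
  } else {
    if (!all(is.finite(s))) stop("squash: non-finite input")
    n <- sqrt(sum(s^2))
    s * .squash_scale(n, variant)
  }
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.softmax_rows <- function(x) {
  mx <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) mx <- pmax(mx, x[, j])
  e <- exp(x - mx)
  e / rowSums(e)
}

## -------------------------------------------------------------------------
## im2col: unfold a stacked batch (B*P x Cin) into (B*P x k*Cin) with 'same'
## zero padding, never crossing sample boundaries. Column blocks are ordered
## by kernel offset, channels within an offset.
.im2col <- function(Xstack, B, P, k) {
  Cin <- ncol(Xstack)
  if (k == 1L) return(Xstack)
  half <- (k - 1L) %/% 2L
  n <- B * P
  pos <- rep(seq_len(P), times = B)               # position within sample
  out <- matrix(0, nrow = n, ncol = k * Cin)
  for (oi in seq_len(k)) {
    off <- oi - 1L - half
    src_pos <- pos + off
    ok <- src_pos >= 1L & src_pos <= P
    cols <- ((oi - 1L) * Cin + 1L):(oi * Cin)
    out[ok, cols] <- Xstack[which(ok) + off, , drop = FALSE]
  }
  out
}

## Glorot-uniform initializer
.glorot <- function(nr, nc, extra_dims = NULL) {
  fan_in <- nr; fan_out <- nc
  lim <- sqrt(6 / (fan_in + fan_out))
  n <- nr * nc * prod(extra_dims %||% 1)
  a <- stats::runif(n, -lim, lim)
  if (is.null(extra_dims)) matrix(a, nr, nc) else array(a, c(nr, nc, extra_dims))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize network weights
#'
#' Glorot-uniform initialization of every layer, driven by the current RNG
#' state (call `set.seed()` first for reproducibility).
#'
#' @param cfg A [network_config()].
#' @return A nested list of weight arrays (class `capsnet_weights`).
#' @export
capsnet_init <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  Cin <- cfg$input_channels
  lanes <- lapply(cfg$lanes, function(lc) {
    D <- lc$capsule_dim
    list(
      Wc = .glorot(lc$kernel_size * Cin, lc$n_conv_filters),
      bc = numeric(lc$n_conv_filters),
      Wp = .glorot(lc$n_conv_filters, lc$primary_channels * D),
      bp = numeric(lc$primary_channels * D),
      Wr = .glorot(D, D, c(lc$primary_channels, lc$hidden_capsules))
    )
  })
  concat_dim <- sum(vapply(cfg$lanes, function(lc)
    lc$hidden_capsules * lc$capsule_dim, numeric(1)))
  structure(list(
    lanes = lanes,
    dense = list(Wd = .glorot(concat_dim, cfg$dense_units),
                 bd = numeric(cfg$dense_units),
                 Wo = .glorot(cfg$dense_units, cfg$n_classes),
                 bo = numeric(cfg$n_classes))
  ), class = "capsnet_weights")
}

## -------------------------------------------------------------------------
## Batched lane forward. Xcol: (B*P x k*Cin) unfolded input. Returns the
## activations needed for the backward pass alongside the lane output.
.lane_forward <- function(Xcol, B, P, lc, lw, variant,
                          training = FALSE, drop_mask = NULL) {
  Fn <- lc$n_conv_filters
  C <- lc$primary_channels
  D <- lc$capsule_dim
  J <- lc$hidden_capsules

  Z1 <- sweep(Xcol %*% lw$Wc, 2, lw$bc, "+")
  A1 <- .relu(Z1)
  if (training && lc$dropout_rate > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(stats::rbinom(length(A1), 1, 1 - lc$dropout_rate),
                          nrow(A1), ncol(A1))
    }
    A1 <- A1 * drop_mask / (1 - lc$dropout_rate)
  }

  pos <- seq(1L, P, by = lc$primary_stride)
  Pp <- length(pos)
  keep <- as.vector(outer(pos, (seq_len(B) - 1L) * P, "+"))  # rows, b-major
  R <- A1[keep, , drop = FALSE]                      # (B*Pp x Fn)

  Zp <- sweep(R %*% lw$Wp, 2, lw$bp, "+")            # (B*Pp x C*D)
  Mu <- matrix(0, nrow(Zp), ncol(Zp))
  prim_n <- matrix(0, nrow(Zp), C)                   # capsule norms, per channel
  for (c in seq_len(C)) {
    cols <- ((c - 1L) * D + 1L):(c * D)
    S <- Zp[, cols, drop = FALSE]
    n <- sqrt(rowSums(S^2))
    prim_n[, c] <- n
    Mu[, cols] <- S * .squash_scale(n, variant)
  }

  ## predictions u_hat, one (B*Pp x J*D) slice per primary channel;
  ## the J affine maps of a channel are fused into one (D x J*D) multiply
  U <- array(0, c(nrow(Mu), J * D, C))
  for (c in seq_len(C)) {
    mcols <- ((c - 1L) * D + 1L):(c * D)
    Wbig <- matrix(lw$Wr[, , c, ], D, D * J)   # cols: j-major, d within
    U[, , c] <- Mu[, mcols, drop = FALSE] %*% Wbig
  }

  rt <- .routing_batched(U, B, Pp, J, D, lc$routing_iterations, variant)

  list(Z1 = Z1, drop_mask = drop_mask, keep = keep, R = R, Zp = Zp,
       prim_n = prim_n, Mu = Mu, U = U,
       S = rt$S, hid_n = rt$hid_n, V = rt$V, cc = rt$cc,
       pos = pos, Pp = Pp)
}

## Dynamic routing over a batch. U: (B*Pp x J*D x C) array of prediction
## vectors, one slice per primary channel; rows are sample-major. Thin
## wrapper over the compiled routing loop.
.routing_batched <- function(U, B, Pp, J, D, iterations, variant) {
  .routing_fwd_cpp(U, B, Pp, J, D, iterations,
                   if (variant == "sabour") 0L else 1L)
}

.head_forward <- function(H, dw) {
  Zd <- sweep(H %*% dw$Wd, 2, dw$bd, "+")
  Ad <- .relu(Zd)
  Zo <- sweep(Ad %*% dw$Wo, 2, dw$bo, "+")
  P <- .softmax_rows(Zo)
  list(Zd = Zd, Ad = Ad, P = P)
}

## Full batched forward; inputs_mat: (B*P x Cin) stacked encoded profiles.
.capsnet_forward_batch <- function(inputs_mat, B, cfg, weights,
                                   training = FALSE, drop_masks = NULL,
                                   Xcols = NULL) {
  P <- cfg$input_len
  lanes <- vector("list", length(cfg$lanes))
  H <- NULL
  for (l in seq_along(cfg$lanes)) {
    lc <- cfg$lanes[[l]]
    Xcol <- if (!is.null(Xcols)) Xcols[[l]] else .im2col(inputs_mat, B, P, lc$kernel_size)
    lf <- .lane_forward(Xcol, B, P, lc, weights$lanes[[l]], cfg$squash_variant,
                        training = training,
                        drop_mask = if (is.null(drop_masks)) NULL else drop_masks[[l]])
    lf$Xcol <- Xcol
    lanes[[l]] <- lf
    H <- if (is.null(H)) lf$V else cbind(H, lf$V)
  }
  hd <- .head_forward(H, weights$dense)
  list(lanes = lanes, H = H, head = hd, P = hd$P)
}

#' Single-lane convolution
#'
#' 1D cross-correlation of an encoded profile with the lane's kernels:
#' stride 1, zero ('same') padding, ReLU activation. Dropout is applied only
#' when `training = TRUE`.
#'
#' @param input `input_len x input_channels` numeric matrix (an
#'   [pad_or_truncate()] `values` field).
#' @param cfg A [lane_config()].
#' @param weights Lane weight list with elements `Wc` (`kernel_size *
#'   input_channels` x `n_conv_filters`) and `bc`.
#' @param training Apply dropout if `TRUE`.
#' @return `input_len x n_conv_filters` feature matrix.
#' @export
conv_lane <- function(input, cfg, weights, training = FALSE) {
  input <- as.matrix(input)
  stopifnot(inherits(cfg, "lane_config"), cfg$kernel_size <= nrow(input))
  Xcol <- .im2col(input, 1L, nrow(input), cfg$kernel_size)
  Z <- sweep(Xcol %*% weights$Wc, 2, weights$bc, "+")
  A <- .relu(Z)
  if (training && cfg$dropout_rate > 0) {
    mask <- matrix(stats::rbinom(length(A), 1, 1 - cfg$dropout_rate),
                   nrow(A), ncol(A))
    A <- A * mask / (1 - cfg$dropout_rate)
  }
  A
}

#' Primary capsule layer of one lane
#'
#' Applies `capsule_dim` size-1 convolutional units per channel to the lane's
#' feature map, then squashes each capsule vector. With stride 1 this yields
#' one capsule per sequence position and channel.
#'
#' @param features Feature matrix from [conv_lane()].
#' @param cfg A [lane_config()].
#' @param weights Lane weight list with elements `Wp`, `bp`.
#' @param variant Squash variant.
#' @return 3-d array `(positions, primary_channels, capsule_dim)` of squashed
#'   capsule vectors.
#' @export
primary_caps <- function(features, cfg, weights,
                         variant = c("sabour", "as_printed")) {
  variant <- match.arg(variant)
  features <- as.matrix(features)
  pos <- seq(1L, nrow(features), by = cfg$primary_stride)
  Zp <- sweep(features[pos, , drop = FALSE] %*% weights$Wp, 2, weights$bp, "+")
  C <- cfg$primary_channels; D <- cfg$capsule_dim
  out <- array(0, c(length(pos), C, D))
  for (c in seq_len(C)) {
    cols <- ((c - 1L) * D + 1L):(c * D)
    out[, c, ] <- squash(Zp[, cols, drop = FALSE], variant)
  }
  out
}

#' Dynamic routing between capsule layers
#'
#' Iterative agreement routing: coupling coefficients are the softmax (over
#' output capsules) of logits that start at zero and accumulate the dot
#' product between each prediction vector and the current output capsule.
#' The agreement update is skipped after the final iteration.
#'
#' @param u_hat 3-d array `(n_input_capsules, n_output_capsules,
#'   capsule_dim)` of prediction vectors.
#' @param iterations Number of routing iterations (>= 1).
#' @param variant Squash variant applied to the weighted sums.
#' @return List with `v` (`n_output_capsules x capsule_dim` output capsules)
#'   and `couplings` (`n_input_capsules x n_output_capsules`, rows summing
#'   to 1).
#' @export
dynamic_routing <- function(u_hat, iterations = 5L,
                            variant = c("sabour", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(length(dim(u_hat)) == 3, iterations >= 1, all(is.finite(u_hat)))
  I <- dim(u_hat)[1]; J <- dim(u_hat)[2]; D <- dim(u_hat)[3]
  U <- array(aperm(u_hat, c(1, 3, 2)), c(I, J * D, 1L))  # cols: j-major blocks
  rt <- .routing_batched(U, B = 1L, Pp = I, J = J, D = D,
                         iterations = iterations, variant = variant)
  v <- matrix(rt$V, nrow = J, ncol = D, byrow = TRUE)
  list(v = v, couplings = matrix(rt$cc[, , 1], nrow = I, ncol = J))
}

#' Hidden capsule layer of one lane
#'
#' Each primary capsule predicts every hidden capsule through an affine map
#' shared across the positional grid within a channel; predictions are
#' combined by [dynamic_routing()].
#'
#' @param primary 3-d array from [primary_caps()].
#' @param cfg A [lane_config()].
#' @param weights Lane weight list with element `Wr`
#'   (`capsule_dim x capsule_dim x primary_channels x hidden_capsules`).
#' @param variant Squash variant.
#' @return List with `v` (`hidden_capsules x capsule_dim`) and `couplings`.
#' @export
hidden_caps <- function(primary, cfg, weights,
                        variant = c("sabour", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(length(dim(primary)) == 3)
  Pp <- dim(primary)[1]; C <- dim(primary)[2]; D <- dim(primary)[3]
  J <- cfg$hidden_capsules
  if (!all(dim(weights$Wr) == c(D, D, C, J))) {
    stop("routing weight shape ", paste(dim(weights$Wr), collapse = "x"),
         " does not match config (expected ",
         paste(c(D, D, C, J), collapse = "x"), ")")
  }
  u_hat <- array(0, c(Pp * C, J, D))
  for (c in seq_len(C)) {
    Mu_c <- matrix(primary[, c, ], nrow = Pp, ncol = D)
    for (j in seq_len(J)) {
      u_hat[((c - 1L) * Pp + 1L):(c * Pp), j, ] <- Mu_c %*% weights$Wr[, , c, j]
    }
  }
  dynamic_routing(u_hat, cfg$routing_iterations, variant)
}

#' Forward pass of the multilane capsule network
#'
#' Runs every lane, concatenates the hidden capsules, and applies the dense
#' softmax head. Class index 2 of the output is the positive
#' (saliva-secretory) class.
#'
#' @param inputs A single `encoded_input`, a bare `input_len x 20` matrix, or
#'   a list of either.
#' @param cfg A [network_config()].
#' @param weights Weights from [capsnet_init()] (or a trained model).
#' @return Numeric matrix `(n_inputs x 2)` of class probabilities; each row
#'   sums to 1.
#' @export
capsnet_forward <- function(inputs, cfg, weights) {
  stopifnot(inherits(cfg, "network_config"))
  if (inherits(inputs, "encoded_input") || is.matrix(inputs)) inputs <- list(inputs)
  mats <- lapply(inputs, function(x) {
    if (inherits(x, "encoded_input")) x <- x$values
    x <- as.matrix(x)
    if (nrow(x) != cfg$input_len || ncol(x) != cfg$input_channels) {
      stop("input must be ", cfg$input_len, " x ", cfg$input_channels)
    }
    x
  })
  B <- length(mats)
  stacked <- do.call(rbind, mats)
  fw <- .capsnet_forward_batch(stacked, B, cfg, weights, training = FALSE)
  if (!all(is.finite(fw$P))) stop("non-finite activations in forward pass")
  p <- fw$P
  rownames(p) <- names(inputs)
  colnames(p) <- c("other", "secretory")
  p
}
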