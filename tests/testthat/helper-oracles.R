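# Straight-line reference implementations, kept deliberately loop-based and
# independent of the package's vectorized/compiled code paths.

oracle_squash <- function(s, variant = "sabour") {
  n <- sqrt(sum(s^2))
  if (n == 0) return(s * 0)
  vn <- if (variant == "sabour") n^2 / (1 + n^2) else n / (1 + n^2)
  vn * s / n
}

# 1D cross-correlation, 'same' zero padding, stride 1, ReLU.
# W: (k*Cin x F) with rows ordered offset-major, channel within offset.
oracle_conv <- function(X, W, b, k) {
  P <- nrow(X); Cin <- ncol(X); Fn <- ncol(W)
  half <- (k - 1) / 2
  out <- matrix(0, P, Fn)
  for (p in 1:P) {
    for (f in 1:Fn) {
      acc <- b[f]
      for (oi in 1:k) {
        q <- p + oi - 1 - half
        if (q >= 1 && q <= P) {
          for (ch in 1:Cin) {
            acc <- acc + X[q, ch] * W[(oi - 1) * Cin + ch, f]
          }
        }
      }
      out[p, f] <- max(0, acc)
    }
  }
  out
}

# dynamic routing exactly as specified: logits start at 0; per iteration
# couplings = row softmax of logits, s_j = sum_i c_ij u_hat_ij,
# v_j = squash(s_j), logits += u_hat . v (skipped after the last iteration)
oracle_routing <- function(u_hat, iterations, variant = "sabour",
                           keep_history = FALSE) {
  I <- dim(u_hat)[1]; J <- dim(u_hat)[2]; D <- dim(u_hat)[3]
  b <- matrix(0, I, J)
  v <- matrix(0, J, D)
  cc <- NULL
  history <- list()
  for (it in 1:iterations) {
    cc <- t(apply(b, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    if (I == 1) cc <- matrix(cc, 1, J)
    for (j in 1:J) {
      s <- numeric(D)
      for (i in 1:I) s <- s + cc[i, j] * u_hat[i, j, ]
      v[j, ] <- oracle_squash(s, variant)
    }
    if (keep_history) history[[it]] <- cc
    if (it < iterations) {
      for (i in 1:I) for (j in 1:J) {
        b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
      }
    }
  }
  list(v = v, couplings = cc, history = history)
}

# primary capsules by explicit loops: size-1 convolution into C*D units,
# squash per capsule
oracle_primary <- function(features, Wp, bp, C, D, stride = 1,
                           variant = "sabour") {
  pos <- seq(1, nrow(features), by = stride)
  out <- array(0, c(length(pos), C, D))
  for (pi in seq_along(pos)) {
    for (c in 1:C) {
      s <- numeric(D)
      for (d in 1:D) {
        col <- (c - 1) * D + d
        s[d] <- sum(features[pos[pi], ] * Wp[, col]) + bp[col]
      }
      out[pi, c, ] <- oracle_squash(s, variant)
    }
  }
  out
}

oracle_hidden <- function(primary, Wr, J, iterations, variant = "sabour") {
  Pp <- dim(primary)[1]; C <- dim(primary)[2]; D <- dim(primary)[3]
  u_hat <- array(0, c(Pp * C, J, D))
  for (c in 1:C) for (p in 1:Pp) for (j in 1:J) {
    u_hat[(c - 1) * Pp + p, j, ] <- primary[p, c, ] %*% Wr[, , c, j]
  }
  oracle_routing(u_hat, iterations, variant)
}

# full forward pass composed from the loop oracles
oracle_forward <- function(x, cfg, weights) {
  H <- NULL
  for (l in seq_along(cfg$lanes)) {
    lc <- cfg$lanes[[l]]; lw <- weights$lanes[[l]]
    feat <- oracle_conv(x, lw$Wc, lw$bc, lc$kernel_size)
    prim <- oracle_primary(feat, lw$Wp, lw$bp, lc$primary_channels,
                           lc$capsule_dim, lc$primary_stride,
                           cfg$squash_variant)
    hid <- oracle_hidden(prim, lw$Wr, lc$hidden_capsules,
                         lc$routing_iterations, cfg$squash_variant)
    H <- c(H, as.vector(t(hid$v)))
  }
  zd <- as.vector(H %*% weights$dense$Wd) + weights$dense$bd
  ad <- pmax(zd, 0)
  zo <- as.vector(ad %*% weights$dense$Wo) + weights$dense$bo
  e <- exp(zo - max(zo))
  e / sum(e)
}

# metric formulas transcribed directly
oracle_metrics <- function(TP, TN, FP, FN) {
  N <- TP + TN + FP + FN
  c(accuracy = (TP + TN) / N,
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    precision = TP / (TP + FP),
    f_score = 2 * (TP / (TP + FP)) * (TP / (TP + FN)) /
      (TP / (TP + FP) + TP / (TP + FN)),
    mcc = (TP * TN - FP * FN) /
      sqrt((TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)))
}

# AUC as the Mann-Whitney pair-counting statistic
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
oracle_hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d <= K))
  mean(hits >= k)
}

# small helper: write a BLAST-style ASCII PSSM file
write_fake_pssm <- function(path, scores, letters = NULL,
                            residues = NULL) {
  ab <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  if (is.null(letters)) letters <- ab
  if (is.null(residues)) residues <- rep("A", nrow(scores))
  lines <- c("", "Last position-specific scoring matrix computed",
             paste("   ", paste(letters, collapse = "  ")))
  for (i in seq_len(nrow(scores))) {
    lines <- c(lines, paste(i, residues[i],
                            paste(scores[i, ], collapse = " ")))
  }
  writeLines(lines, path)
}

tiny_net <- function(lanes = list(lane_config(3, n_conv_filters = 4,
                                              primary_channels = 2,
                                              capsule_dim = 3,
                                              hidden_capsules = 2,
                                              routing_iterations = 3,
                                              dropout_rate = 0)),
                     input_len = 10L, input_channels = 4L,
                     dense_units = 5L, seed = 1) {
  cfg <- network_config(lanes = lanes, input_len = input_len,
                        input_channels = input_channels,
                        dense_units = dense_units, l2_coefficient = 0)
  set.seed(seed)
  list(cfg = cfg, w = capsnet_init(cfg))
}
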