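#' Configuration of the synthetic sequence generator
#'
#' The generator emulates the statistical structure the classifier relies
#' on: positives carry a terminal sorting-signal-like motif (with
#' per-position substitution noise), negatives come from protein families
#' with family-specific composition biases, and every sequence has a
#' simulated profile built from per-position Dirichlet draws concentrated on
#' the true residue.
#'
#' @param n_positives,n_negatives Class sizes (defaults 100 / 500).
#' @param n_families Number of negative families (default 25).
#' @param family_size Integer pair: min/max family size used when building
#'   the family map (default c(10, 30)).
#' @param motif Optional motif string; when `NULL` a random motif of
#'   `motif_length` residues is drawn from the seed.
#' @param motif_length Length of the implanted motif (default 12).
#' @param motif_position `"n_terminal"` (default), `"c_terminal"` or
#'   `"internal"`.
#' @param motif_noise Per-position substitution probability within the
#'   implanted motif (default 0.1).
#' @param background 20-vector of amino-acid frequencies summing to 1
#'   (default uniform).
#' @param profile_concentration Dirichlet concentration of simulated profile
#'   rows; larger = less noisy (default 50).
#' @param seq_len Integer pair: min/max sequence length (default c(50, 300)).
#' @param seed Integer seed.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_positives = 100L, n_negatives = 500L,
                             n_families = 25L, family_size = c(10L, 30L),
                             motif = NULL, motif_length = 12L,
                             motif_position = c("n_terminal", "c_terminal",
                                                "internal"),
                             motif_noise = 0.1,
                             background = rep(1 / 20, 20),
                             profile_concentration = 50,
                             seq_len = c(50L, 300L), seed = 1L) {
  motif_position <- match.arg(motif_position)
  stopifnot(n_positives >= 1, n_negatives >= 1, n_families >= 1,
            length(family_size) == 2, family_size[1] >= 1,
            family_size[1] <= family_size[2],
            motif_length >= 1, motif_noise >= 0, motif_noise < 1,
            length(background) == 20, abs(sum(background) - 1) < 1e-8,
            all(background >= 0), profile_concentration > 0,
            length(seq_len) == 2, seq_len[1] >= 1, seq_len[1] <= seq_len[2])
  if (!is.null(motif)) motif_length <- nchar(motif)
  if (motif_length > seq_len[1]) {
    stop("motif longer than the minimum sequence length")
  }
  structure(list(n_positives = as.integer(n_positives),
                 n_negatives = as.integer(n_negatives),
                 n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 motif = motif, motif_length = as.integer(motif_length),
                 motif_position = motif_position, motif_noise = motif_noise,
                 background = background,
                 profile_concentration = profile_concentration,
                 seq_len = as.integer(seq_len), seed = as.integer(seed)),
            class = "synthetic_config")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

.sample_seq <- function(len, comp) {
  paste(sample(aa_alphabet(), len, replace = TRUE, prob = comp), collapse = "")
}

.implant <- function(sequence, motif, position, noise) {
  chars <- strsplit(sequence, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  sub <- stats::runif(length(m)) < noise
  if (any(sub)) {
    m[sub] <- vapply(which(sub), function(i)
      sample(setdiff(aa_alphabet(), m[i]), 1), character(1))
  }
  L <- length(chars); ml <- length(m)
  start <- switch(position,
                  n_terminal = 1L,
                  c_terminal = L - ml + 1L,
                  internal = sample(seq_len(L - ml + 1L), 1))
  chars[start:(start + ml - 1L)] <- m
  paste(chars, collapse = "")
}

## simulated profile: each row is a Dirichlet draw concentrated on the
## true residue, mixed with the background composition
.simulate_profile <- function(sequence, background, concentration) {
  idx <- match(strsplit(sequence, "")[[1]], aa_alphabet())
  L <- length(idx)
  vals <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    q <- 0.2 * background
    q[idx[i]] <- q[idx[i]] + 0.8
    vals[i, ] <- .rdirichlet1(concentration * q)
  }
  profile_matrix(vals, source = "pssm")
}

#' Generate a labeled synthetic dataset
#'
#' Positives are background sequences with the motif implanted at the
#' configured terminus (noisy copies); negatives are drawn from families
#' with family-specific composition biases and are guaranteed not to contain
#' the motif. Each record gets a simulated profile. Fully reproducible under
#' the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_dataset`: `records` (data.frame id,
#'   sequence), `profiles` (named list of [profile_matrix()]), `labels`
#'   (named 0/1 integer vector), `family_of` (named vector, NA for
#'   positives), `motif`.
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  motif <- cfg$motif %||%
    paste(sample(aa_alphabet(), cfg$motif_length, replace = TRUE),
          collapse = "")

  ids <- character(0); seqs <- character(0); labels <- integer(0)
  family_of <- character(0)

  for (i in seq_len(cfg$n_positives)) {
    len <- sample(cfg$seq_len[1]:cfg$seq_len[2], 1)
    s <- .sample_seq(len, cfg$background)
    s <- .implant(s, motif, cfg$motif_position, cfg$motif_noise)
    ids <- c(ids, sprintf("POS%04d", i)); seqs <- c(seqs, s)
    labels <- c(labels, 1L); family_of <- c(family_of, NA_character_)
  }

  ## family assignment: draw family sizes, trim to the requested count
  sizes <- sample(cfg$family_size[1]:cfg$family_size[2], cfg$n_families,
                  replace = TRUE)
  fam_ids <- rep(seq_len(cfg$n_families), times = sizes)
  fam_ids <- rep_len(fam_ids, cfg$n_negatives)
  fam_comp <- lapply(seq_len(cfg$n_families), function(f)
    .rdirichlet1(30 * cfg$background))

  for (i in seq_len(cfg$n_negatives)) {
    f <- fam_ids[i]
    len <- sample(cfg$seq_len[1]:cfg$seq_len[2], 1)
    repeat {
      s <- .sample_seq(len, fam_comp[[f]])
      if (!grepl(motif, s, fixed = TRUE)) break
    }
    ids <- c(ids, sprintf("NEG%04d", i)); seqs <- c(seqs, s)
    labels <- c(labels, 0L)
    family_of <- c(family_of, sprintf("FAM%03d", f))
  }

  profiles <- lapply(seqs, .simulate_profile, background = cfg$background,
                     concentration = cfg$profile_concentration)
  names(profiles) <- ids
  names(labels) <- ids
  names(family_of) <- ids

  structure(list(records = data.frame(id = ids, sequence = seqs,
                                      stringsAsFactors = FALSE),
                 profiles = profiles, labels = labels, family_of = family_of,
                 motif = motif, config = cfg),
            class = "synthetic_dataset")
}

#' Sample negatives from sufficiently large families
#'
#' Families with fewer than `min_size` members are excluded; from each
#' retained family, `per_family` members are sampled without replacement
#' (the whole family when it has exactly `per_family` members).
#'
#' @param families Named list mapping family name to a vector of member IDs.
#' @param min_size Minimum family size to retain (default 10).
#' @param per_family Members sampled per retained family (default 3).
#' @param seed Integer seed.
#' @return Character vector of sampled member IDs.
#' @export
sample_negative_families <- function(families, min_size = 10L,
                                     per_family = 3L, seed = 1L) {
  stopifnot(length(families) >= 1, min_size >= 1, per_family >= 1)
  keep <- families[vapply(families, length, integer(1)) >= min_size]
  if (length(keep) == 0) {
    warning("no family has at least ", min_size, " members")
    return(character(0))
  }
  set.seed(.derive_seed(seed, 42L))
  unlist(lapply(keep, function(members) {
    if (length(members) <= per_family) members
    else sample(members, per_family)
  }), use.names = FALSE)
}

## containment identity estimate: shared k-mers over the k-mers of the
## shorter sequence
.kmer_set <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(s)
  unique(substring(s, 1:(L - k + 1), k:L))
}

#' Remove redundant sequences by approximate identity
#'
#' Greedy longest-first clustering: sequences are visited in decreasing
#' length order and dropped when their estimated identity to an already
#' retained representative exceeds the threshold. Identity is estimated as
#' the shared-k-mer fraction over the shorter sequence (k = 3), a fast
#' containment proxy for alignment identity; this is a deliberately simple
#' stand-in for full clustering tools, adequate for building
#' low-redundancy benchmark sets.
#'
#' @param records data.frame with columns `id`, `sequence`.
#' @param identity_threshold Drop sequences above this estimated identity
#'   (default 0.30).
#' @param k k-mer size of the containment estimate.
#' @return The retained subset of `records` (original order preserved).
#' @export
redundancy_filter <- function(records, identity_threshold = 0.30, k = 3L) {
  stopifnot(identity_threshold > 0, identity_threshold < 1)
  ord <- order(-nchar(records$sequence))
  kmers <- lapply(records$sequence, .kmer_set, k = k)
  retained <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (r in retained) {
      shorter <- if (nchar(records$sequence[i]) <= nchar(records$sequence[r])) i else r
      shared <- length(intersect(kmers[[i]], kmers[[r]]))
      if (shared / length(kmers[[shorter]]) > identity_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) retained <- c(retained, i)
  }
  records[sort(retained), , drop = FALSE]
}

#' Motif-presence score
#'
#' The best sliding-window agreement between a sequence and a motif: the
#' maximum over alignments of the fraction of matching positions. A direct,
#' model-free baseline classifier for motif-implanted data.
#'
#' @param sequences Character vector.
#' @param motif Motif string.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
motif_presence_score <- function(sequences, motif) {
  m <- strsplit(motif, "")[[1]]
  ml <- length(m)
  vapply(sequences, function(s) {
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    if (L < ml) return(mean(chars == m[seq_len(L)]))
    best <- 0
    for (start in 1:(L - ml + 1)) {
      best <- max(best, mean(chars[start:(start + ml - 1)] == m))
      if (best == 1) break
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
}
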