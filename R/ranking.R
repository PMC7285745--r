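#' Signed confidence score (S-value) from a softmax pair
#'
#' `S = 2 * (argmax(p) - 0.5) * max(p)` with classes indexed 0 (other) and
#' 1 (saliva-secretory): S is positive iff the predicted class is the
#' secretory one, and `|S|` is the winning probability. At the exact tie
#' `p = (0.5, 0.5)` the first maximum (class 0) wins, giving `S = -0.5`;
#' such ties carry a `tie` attribute.
#'
#' @param p Numeric pair of class probabilities (sums to 1), or a two-column
#'   matrix of pairs.
#' @return Numeric S-value(s) in `[-1, 1]`; attribute `tie` is a logical
#'   marking exact ties.
#' @export
s_value <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2) stop("p must have two columns")
    return(structure(vapply(seq_len(nrow(p)),
                            function(i) as.numeric(s_value(p[i, ])),
                            numeric(1)),
                     tie = apply(p, 1, function(r) r[1] == r[2])))
  }
  if (length(p) != 2 || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("p must be a nonnegative probability pair summing to 1")
  }
  am <- which.max(p) - 1L          # first maximum: tie resolves to class 0
  structure(2 * (am - 0.5) * max(p), tie = p[1] == p[2])
}

#' Rank candidates by S-value
#'
#' Descending S-value; ties break by lexicographic ID for determinism.
#'
#' @param ids Character vector of unique protein IDs.
#' @param s Numeric S-values, parallel to `ids`.
#' @return data.frame with columns `id`, `S`, `rank`, sorted by rank.
#' @export
rank_candidates <- function(ids, s) {
  stopifnot(length(ids) == length(s))
  if (anyDuplicated(ids)) {
    stop("duplicate IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ord <- order(-s, ids)
  data.frame(id = ids[ord], S = s[ord], rank = seq_along(ids),
             stringsAsFactors = FALSE)
}

.log_hyper_pmf <- function(x, N, K, n) {
  lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
}

.check_enrichment_query <- function(N, K, n, k) {
  stopifnot(N >= 1, K >= 0, n >= 0, k >= 0)
  if (K > N) stop("marker-set size K exceeds population N")
  if (n > N) stop("top-list size n exceeds population N")
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
}

#' Hypergeometric point probability
#'
#' `P(X = k) = choose(K, k) * choose(N - K, n - k) / choose(N, n)`: the
#' probability of exactly `k` marker proteins among `n` drawn from a
#' population of `N` containing `K` markers. Evaluated through log binomial
#' coefficients so population sizes in the tens of thousands do not
#' overflow.
#'
#' @param N Population size (e.g. number of reviewed human proteins).
#' @param K Marker-set size within the population.
#' @param n Size of the top-ranked list.
#' @param k Observed overlap.
#' @return `P(X = k)`.
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  .check_enrichment_query(N, K, n, k)
  exp(.log_hyper_pmf(k, N, K, n))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)`: the probability of at least `k` marker proteins in the top
#' `n`, summed in log space over the support `k..min(K, n)`.
#'
#' @inheritParams hypergeom_pmf
#' @return `P(X >= k)`; equals 1 at `k = 0`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  .check_enrichment_query(N, K, n, k)
  hi <- min(K, n)
  if (k > hi) return(0)
  lp <- .log_hyper_pmf(k:hi, N, K, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Overlap of a ranked list's top n with a marker set
#'
#' Marker IDs absent from the ranked population are dropped with a warning
#' (they cannot contribute to either K or k).
#'
#' @param ranked data.frame from [rank_candidates()] (or any data.frame with
#'   an `id` column in rank order).
#' @param markers Character vector of marker IDs.
#' @param n Top-list size.
#' @param N Population size; defaults to the number of ranked proteins.
#' @return List of class `enrichment_query`: `N`, `K`, `n`, `k`.
#' @export
overlap_at_top <- function(ranked, markers, n, N = nrow(ranked)) {
  ids <- ranked$id
  missing <- setdiff(markers, ids)
  if (length(missing) > 0) {
    warning("dropping ", length(missing),
            " marker ID(s) absent from the ranked population: ",
            paste(utils::head(missing, 5), collapse = ", "))
    markers <- setdiff(markers, missing)
  }
  k <- length(intersect(utils::head(ids, n), markers))
  structure(list(N = as.integer(N), K = length(markers), n = as.integer(n),
                 k = as.integer(k)),
            class = "enrichment_query")
}

#' Enrichment of a ranked list against a marker set
#'
#' For each top-list size, counts the overlap with the marker set and
#' reports both the hypergeometric point probability `P(X = k)` (the
#' quantity conventionally quoted alongside such rankings) and the
#' upper-tail probability `P(X >= k)`.
#'
#' @inheritParams overlap_at_top
#' @param tops Integer vector of top-list sizes.
#' @return data.frame with columns `n`, `k`, `K`, `N`, `p_point`, `p_tail`.
#' @export
enrichment_table <- function(ranked, markers, N = nrow(ranked),
                             tops = c(1000L, 2000L, 3000L, 4000L)) {
  out <- lapply(tops, function(n) {
    q <- suppressWarnings(overlap_at_top(ranked, markers, n, N))
    data.frame(n = q$n, k = q$k, K = q$K, N = q$N,
               p_point = hypergeom_pmf(q$N, q$K, q$n, q$k),
               p_tail = hypergeom_tail(q$N, q$K, q$n, q$k))
  })
  do.call(rbind, out)
}
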