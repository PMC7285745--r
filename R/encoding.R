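#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the column order used throughout the
#' package: `ARNDCQEGHILKMFPSTWYV`, the ordering of BLAST ASCII PSSM files.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
}

#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into a list of protein records. Identifiers are taken
#' from the header up to the first whitespace; sequences are upper-cased.
#' Duplicate identifiers are an error, as downstream containers are keyed by
#' protein ID.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per entry,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      ## locate the first offending line for a usable message
      lines <- readLines(path, warn = FALSE)
      first_bad <- which(!grepl("^>", lines) & grepl("[^A-Za-z*\\-\\s]", lines))
      hint <- if (length(first_bad)) paste0(" (near line ", first_bad[1], ")") else ""
      stop("malformed FASTA", hint, ": ", conditionMessage(e))
    }
  )
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("malformed FASTA: empty header identifier")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("malformed FASTA: zero-length sequence for ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Parse a BLAST-style ASCII PSSM
#'
#' Reads the first 20-column score block of a BLAST/PSI-BLAST ASCII position
#' -specific scoring matrix. The column header line names the amino-acid
#' order used by the file; scores are reordered to the canonical alphabet of
#' [aa_alphabet()].
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional protein sequence; when supplied the row count and
#'   per-row residue letters are checked against it.
#' @return Numeric matrix with one row per residue and 20 columns in
#'   canonical order. The residue letters are attached as attribute
#'   `residues`.
#' @export
parse_pssm <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  ## header line: 20 (or 40) single-letter columns
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_header <- vapply(toks, function(t) {
    length(t) >= 20 && all(t[1:20] %in% aa_alphabet()) &&
      all(nchar(t) == 1)
  }, logical(1))
  if (!any(is_header)) stop("malformed PSSM: no amino-acid column header found")
  h <- which(is_header)[1]
  file_order <- toks[[h]][1:20]
  if (anyDuplicated(file_order)) stop("malformed PSSM: duplicated column letters")

  if (h >= length(lines)) stop("malformed PSSM: no score rows found")
  rows <- list(); residues <- character(0)
  for (i in seq(h + 1, length(lines))) {
    t <- toks[[i]]
    if (length(t) == 0) break                     # blank line ends the block
    if (is.na(suppressWarnings(as.integer(t[1])))) break  # trailing stats block
    if (length(t) < 22) {
      stop("malformed PSSM: row at line ", i, " has fewer than 20 score columns")
    }
    sc <- suppressWarnings(as.numeric(t[3:22]))
    if (anyNA(sc)) stop("malformed PSSM: non-numeric score at line ", i)
    rows[[length(rows) + 1L]] <- sc
    residues <- c(residues, t[2])
  }
  if (length(rows) == 0) stop("malformed PSSM: no score rows found")
  raw <- do.call(rbind, rows)
  colnames(raw) <- file_order
  raw <- raw[, aa_alphabet(), drop = FALSE]

  if (!is.null(sequence)) {
    if (nrow(raw) != nchar(sequence)) {
      stop("PSSM/sequence length mismatch: ", nrow(raw), " rows vs ",
           nchar(sequence), " residues")
    }
  }
  attr(raw, "residues") <- residues
  raw
}

#' Construct a profile matrix
#'
#' A profile matrix is an L x 20 real matrix with entries in `[0, 1]`,
#' columns in canonical alphabet order, either a normalized PSSM or a one-hot
#' encoding.
#'
#' @param values L x 20 numeric matrix with entries in `[0, 1]`.
#' @param source Either `"pssm"` or `"one_hot"`.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, source = c("pssm", "one_hot")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (ncol(values) != 20) stop("profile must have exactly 20 columns")
  if (!all(is.finite(values))) stop("profile contains non-finite entries")
  if (min(values) < 0 || max(values) > 1) {
    stop("profile entries must lie in [0, 1]")
  }
  if (source == "one_hot") {
    rs <- rowSums(values)
    if (!all(abs(rs) < 1e-9 | abs(rs - 1) < 1e-9)) {
      stop("one-hot profile rows must sum to 0 or 1")
    }
  }
  colnames(values) <- aa_alphabet()
  structure(list(values = values, source = source), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix: %d x 20, source=%s>\n", nrow(x$values), x$source))
  invisible(x)
}

#' Normalize a raw PSSM into a profile matrix
#'
#' Applies an elementwise squashing transform mapping raw log-odds scores
#' into `(0, 1)`. The default is the logistic function `1 / (1 + exp(-x))`,
#' the usual choice when PSSMs feed a neural network: bounded, monotone and
#' order-preserving. The transform is configurable for other profile
#' dialects.
#'
#' @param raw L x 20 numeric matrix of raw scores (finite).
#' @param transform Elementwise normalizing function; must map the reals into
#'   `[0, 1]`.
#' @return A [profile_matrix()] with `source = "pssm"`.
#' @export
normalize_profile <- function(raw, transform = stats::plogis) {
  raw <- as.matrix(raw)
  if (!all(is.finite(raw))) stop("raw PSSM contains non-finite entries")
  if (ncol(raw) != 20) stop("raw PSSM must have exactly 20 columns")
  profile_matrix(transform(raw), source = "pssm")
}

#' One-hot encode a protein sequence
#'
#' Row i carries a single 1 in the column of residue i. Ambiguous or
#' non-standard letters (B, J, O, U, X, Z, ...) give an all-zero row: a
#' neutral signal rather than an invented composition.
#'
#' @param sequence Character scalar over amino-acid letters.
#' @return A [profile_matrix()] with `source = "one_hot"`.
#' @export
one_hot <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("sequence must have length >= 1")
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, aa_alphabet())
  m <- matrix(0, nrow = length(chars), ncol = 20)
  known <- !is.na(idx)
  m[cbind(which(known), idx[known])] <- 1
  profile_matrix(m, source = "one_hot")
}

#' Pad or truncate a profile to the fixed network input length
#'
#' Profiles shorter than `max_len` keep all rows and are zero-padded at the
#' end. Profiles longer than `max_len` keep the first `max_len/2` rows (the
#' N-terminus) and the last `max_len/2` rows (the C-terminus), preserving the
#' sequence segments that carry sorting signals.
#'
#' @param profile A [profile_matrix()] or bare L x 20 matrix.
#' @param max_len Even integer >= 2; the fixed input length (default 1000).
#' @return An object of class `encoded_input` with fields `values`
#'   (`max_len` x 20), `true_length` and `truncated`.
#' @export
pad_or_truncate <- function(profile, max_len = 1000L) {
  if (inherits(profile, "profile_matrix")) profile <- profile$values
  profile <- as.matrix(profile)
  max_len <- as.integer(max_len)
  if (max_len < 2L || max_len %% 2L != 0L) stop("max_len must be even and >= 2")
  L <- nrow(profile)
  if (L > max_len) {
    half <- max_len %/% 2L
    values <- rbind(profile[seq_len(half), , drop = FALSE],
                    profile[seq(L - half + 1L, L), , drop = FALSE])
    truncated <- TRUE
    true_length <- max_len
  } else {
    values <- rbind(profile,
                    matrix(0, nrow = max_len - L, ncol = ncol(profile)))
    truncated <- FALSE
    true_length <- L
  }
  structure(list(values = values, true_length = as.integer(true_length),
                 truncated = truncated),
            class = "encoded_input")
}

#' @export
print.encoded_input <- function(x, ...) {
  cat(sprintf("<encoded_input: %d x %d, true_length=%d%s>\n",
              nrow(x$values), ncol(x$values), x$true_length,
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Encode a set of records into fixed-size network inputs
#'
#' Convenience wrapper: each record is encoded from its profile when one is
#' supplied (keyed by ID), falling back to one-hot encoding of the sequence,
#' then padded or truncated to `max_len`.
#'
#' @param records data.frame from [read_fasta()].
#' @param profiles Optional named list of [profile_matrix()] objects keyed by
#'   protein ID.
#' @param max_len Fixed input length.
#' @return Named list of `encoded_input` objects, in record order.
#' @export
encode_records <- function(records, profiles = NULL, max_len = 1000L) {
  out <- vector("list", nrow(records))
  names(out) <- records$id
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    prof <- if (!is.null(profiles) && !is.null(profiles[[id]])) {
      profiles[[id]]
    } else {
      one_hot(records$sequence[i])
    }
    out[[i]] <- pad_or_truncate(prof, max_len)
  }
  out
}
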