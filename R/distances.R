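#' Path-overlap difference between two answer sequences
#'
#' The core disagreement measure between two annotations: one minus the number
#' of positionally matching answers divided by the total number of answer
#' pairs, where the total is the length of the longer sequence. Positions past
#' the end of the shorter sequence count as mismatches, so the no-change path
#' (length 1) is maximally different from every change path (length 3).
#' Because the decision graph constrains which tokens can appear at each
#' depth, positional matching coincides with unordered token-overlap counting
#' for paths of the same graph.
#'
#' @param a,b answer sequences: character vectors of tokens or single
#'   `"|"`-joined path strings.
#' @return difference in \eqn{[0, 1]}; 0 for identical sequences.
#' @examples
#' sequence_difference("Yes|Effort|Light", "Yes|Effort|Strong")  # 1/3
#' @export
sequence_difference <- function(a, b) {
  a <- split_path(a); b <- split_path(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty answer sequence")
  n <- max(length(a), length(b))
  k <- min(length(a), length(b))
  1 - sum(a[seq_len(k)] == b[seq_len(k)]) / n
}

#' Overlap similarity between two answer sequences
#'
#' Matching answer pairs over total pairs: the exact complement of
#' [sequence_difference()]. Used to score each rater's annotation against the
#' modal annotation of a unit.
#'
#' @param reference,candidate answer sequences (token vectors or path strings).
#' @return similarity in \eqn{[0, 1]}; 1 for identical sequences.
#' @export
similarity <- function(reference, candidate) {
  1 - sequence_difference(reference, candidate)
}

#' Order-dependent difference between two-round annotation pairs
#'
#' Treats the pair (round 1, round 2) as a single annotation in the product
#' space of paths: the two sequences of each pair are concatenated and the
#' positional overlap difference is applied to the concatenations, with the
#' total pair count the longer concatenated length. Swapping the rounds of one
#' rater but not the other therefore counts as disagreement.
#'
#' @param p,q length-2 lists (or character vectors of two path strings):
#'   the round-1 and round-2 answer sequences of one rater.
#' @return difference in \eqn{[0, 1]}.
#' @export
composite_difference_ordered <- function(p, q) {
  p <- as_round_pair(p); q <- as_round_pair(q)
  sequence_difference(c(split_path(p[[1]]), split_path(p[[2]])),
                      c(split_path(q[[1]]), split_path(q[[2]])))
}

#' Order-independent difference between two-round annotation pairs
#'
#' Aligns the two rounds so as to maximize overlap: the minimum over the two
#' possible pairings — (p1,q1),(p2,q2) and (p1,q2),(p2,q1) — of the mean of
#' the two single-sequence differences. Two raters who saw the same two
#' changes but prioritized them differently are at distance 0.
#'
#' @inheritParams composite_difference_ordered
#' @return difference in \eqn{[0, 1]}.
#' @export
composite_difference_unordered <- function(p, q) {
  p <- as_round_pair(p); q <- as_round_pair(q)
  d11 <- sequence_difference(p[[1]], q[[1]])
  d22 <- sequence_difference(p[[2]], q[[2]])
  d12 <- sequence_difference(p[[1]], q[[2]])
  d21 <- sequence_difference(p[[2]], q[[1]])
  min((d11 + d22) / 2, (d12 + d21) / 2)
}

as_round_pair <- function(p) {
  if (is.character(p) && length(p) == 1L && grepl("::", p, fixed = TRUE)) {
    p <- strsplit(p, "::", fixed = TRUE)[[1]]
  }
  if (length(p) != 2L) stop("a round pair must hold exactly two sequences")
  list(p[[1]], p[[2]])
}

#' Pairwise distance matrix over a value inventory
#'
#' @param values character vector of distinct value keys: path strings for
#'   single sequences, or `"r1::r2"` strings for round pairs.
#' @param d a symmetric distance function taking two value keys, e.g.
#'   [sequence_difference()] (the default), [composite_difference_ordered()]
#'   or [composite_difference_unordered()].
#' @return symmetric numeric matrix with zero diagonal, dimnames `values`.
#' @export
distance_matrix <- function(values, d = sequence_difference) {
  values <- as.character(values)
  if (anyDuplicated(values)) stop("values must be distinct")
  v <- length(values)
  m <- matrix(0, v, v, dimnames = list(values, values))
  if (v < 2L) return(m)
  for (i in seq_len(v - 1L)) {
    for (j in seq.int(i + 1L, v)) {
      m[i, j] <- m[j, i] <- d(values[[i]], values[[j]])
    }
  }
  m
}

# ---- vectorized distance-matrix builders used by the alpha pipeline ----
# (agree with the scalar functions above; asserted in the test suite)

# token matrix (rows = sequences, NA-padded) + lengths
pad_tokens <- function(token_lists) {
  lens <- lengths(token_lists)
  w <- max(lens, 1L)
  mat <- matrix(NA_character_, length(token_lists), w)
  for (i in seq_along(token_lists)) {
    if (lens[[i]]) mat[i, seq_len(lens[[i]])] <- token_lists[[i]]
  }
  list(tokens = mat, lens = lens)
}

# positional-overlap distance matrix from a padded token matrix
dmat_positional <- function(padded) {
  n <- nrow(padded$tokens)
  matches <- matrix(0, n, n)
  for (col in seq_len(ncol(padded$tokens))) {
    x <- padded$tokens[, col]
    eq <- outer(x, x, "==")
    eq[is.na(eq)] <- FALSE
    matches <- matches + eq
  }
  total <- outer(padded$lens, padded$lens, pmax)
  d <- 1 - matches / total
  diag(d) <- 0
  d
}

# distance matrix for an inventory of value keys under a named strategy
strategy_distance_matrix <- function(values, kind = c("simple", "ordered", "unordered")) {
  kind <- match.arg(kind)
  values <- as.character(values)
  if (kind == "simple") {
    d <- dmat_positional(pad_tokens(strsplit(values, "|", fixed = TRUE)))
    dimnames(d) <- list(values, values)
    return(d)
  }
  pairs <- strsplit(values, "::", fixed = TRUE)
  bad <- lengths(pairs) != 2L
  if (any(bad)) stop("malformed round-pair value key: ", values[bad][1])
  r1 <- vapply(pairs, `[[`, character(1), 1L)
  r2 <- vapply(pairs, `[[`, character(1), 2L)
  if (kind == "ordered") {
    concat <- Map(c, strsplit(r1, "|", fixed = TRUE), strsplit(r2, "|", fixed = TRUE))
    d <- dmat_positional(pad_tokens(concat))
  } else {
    seqs <- unique(c(r1, r2))
    ds <- dmat_positional(pad_tokens(strsplit(seqs, "|", fixed = TRUE)))
    i1 <- match(r1, seqs); i2 <- match(r2, seqs)
    identity_mean <- (ds[i1, i1, drop = FALSE] + ds[i2, i2, drop = FALSE]) / 2
    swapped_mean  <- (ds[i1, i2, drop = FALSE] + ds[i2, i1, drop = FALSE]) / 2
    d <- pmin(identity_mean, swapped_mean)
    diag(d) <- 0
  }
  dimnames(d) <- list(values, values)
  d
}
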