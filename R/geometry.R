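# True-structure geometry: representative-atom distance maps and sequence
# separation classes.

#' True distance map of a parsed structure
#'
#' Euclidean distances between representative atoms (C-beta; C-alpha for
#' glycine) for every pair of valid residues; rows/columns of invalid
#' residues and the diagonal are masked.
#'
#' @param rec A [protein_record()] with at least two valid residues.
#' @return A [distance_map()].
#' @export
true_distance_map <- function(rec) {
  stopifnot(inherits(rec, "protein_record"))
  if (sum(rec$valid) < 2)
    stop("degenerate structure: fewer than 2 valid residues")
  co <- rec$coords
  co[!rec$valid, ] <- 0  # masked anyway; keep dist() finite
  d <- as.matrix(stats::dist(co))
  dimnames(d) <- NULL
  mask <- outer(rec$valid, rec$valid, "&")
  diag(mask) <- FALSE
  distance_map(d, mask)
}

#' Sequence-separation class of a residue pair
#'
#' With s = |i - j|: s < 6 is `local`, 6 <= s < 12 `short`,
#' 12 <= s < 24 `medium`, s >= 24 `long`.
#'
#' @param i,j Residue indices (vectors allowed, i != j elementwise).
#' @return Character vector of class labels.
#' @export
separation_class <- function(i, j) {
  if (any(i == j)) stop("separation class undefined for i = j")
  s <- abs(i - j)
  c("local", "short", "medium", "long")[
    findInterval(s, c(0, 6, 12, 24))]
}

#' Effective sequence length L
#'
#' The smaller of the sequence length and the number of valid residues in
#' the native structure; this L is what top-L and top-L/5 contact counts
#' are based on.
#'
#' @param seq_len Sequence length.
#' @param n_valid Number of valid residues.
#' @return Integer L.
#' @export
effective_length <- function(seq_len, n_valid) {
  if (seq_len < 1 || n_valid < 1)
    stop("lengths must be positive, got ", seq_len, " and ", n_valid)
  as.integer(min(seq_len, n_valid))
}
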