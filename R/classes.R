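# Core S3 containers shared by every module. All residue indices are 1-based
# and every stored pair satisfies i < j; only the upper triangle of any
# distance matrix is ever consulted downstream.

#' Parsed protein chain
#'
#' Holds the per-residue state extracted from a structure: one-letter
#' sequence, representative-atom coordinates (C-beta, falling back to
#' C-alpha for glycine or when C-beta is absent) and a validity mask for
#' residues that carry neither atom.
#'
#' @param sequence One-letter amino-acid string of length L.
#' @param coords Numeric L x 3 matrix of representative-atom coordinates
#'   in Angstrom. Rows for invalid residues may be `NA`.
#' @param valid Logical vector of length L; `TRUE` where a representative
#'   atom exists.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(sequence, coords, valid) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != L)
    stop("coords must be a numeric L x 3 matrix matching the sequence length")
  valid <- as.logical(valid)
  if (length(valid) != L)
    stop("valid mask length (", length(valid), ") != sequence length (", L, ")")
  if (any(valid & !stats::complete.cases(coords)))
    stop("valid residues must have finite coordinates")
  structure(list(sequence = sequence, coords = coords, valid = valid),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %d residues (%d valid)\n",
              nchar(x$sequence), sum(x$valid)))
  cat("  ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Square inter-residue distance map
#'
#' @param values Numeric L x L matrix of distances in Angstrom.
#' @param mask Logical L x L matrix, `TRUE` where the cell is usable.
#'   Defaults to all cells off the diagonal that are finite and positive.
#' @return An object of class `distance_map` with a masked diagonal.
#' @export
distance_map <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("distance map must be square, got ", nrow(values), " x ", ncol(values))
  L <- nrow(values)
  if (is.null(mask)) mask <- is.finite(values) & values > 0
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(values))) stop("mask shape differs from values")
  mask <- mask & is.finite(values)
  diag(mask) <- FALSE
  structure(list(values = values, mask = mask), class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d x %d, %d unmasked cells\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Ranked contact prediction
#'
#' @param pairs Data frame with columns `i`, `j` (1-based residue indices,
#'   i < j after normalization) and `confidence`.
#' @param target_length Integer sequence length if known, else `NA`.
#' @return An object of class `contact_prediction`.
#' @export
contact_prediction <- function(pairs, target_length = NA_integer_) {
  pairs <- as.data.frame(pairs)
  need <- c("i", "j", "confidence")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns i, j, confidence")
  pairs <- pairs[, need]
  if (nrow(pairs)) {
    swap <- pairs$i > pairs$j
    if (any(swap)) pairs[swap, c("i", "j")] <- pairs[swap, c("j", "i")]
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    if (anyDuplicated(pairs[c("i", "j")]))
      stop("duplicate (i, j) pairs in contact prediction")
    if (!all(is.finite(pairs$confidence)))
      stop("non-finite confidence values")
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, target_length = as.integer(target_length)),
            class = "contact_prediction")
}

#' @export
print.contact_prediction <- function(x, ...) {
  cat(sprintf("<contact_prediction> %d pairs, target length %s\n",
              nrow(x$pairs),
              ifelse(is.na(x$target_length), "unknown", x$target_length)))
  invisible(x)
}

#' Binned distance distribution per residue pair
#'
#' Bin b spans `[edges[b], edges[b + 1])`; the final bin is open above
#' `edges[B]`, so there are as many edges as bins.
#'
#' @param i,j Integer vectors of 1-based residue indices with `i < j`.
#' @param probs Numeric matrix, one row per pair, one column per bin.
#' @param edges Strictly increasing numeric vector of bin lower edges
#'   (Angstrom), one per bin.
#' @param target_length Integer sequence length if known, else `NA`.
#' @param normalize Renormalize rows whose sum is in [0.5, 1.5] (with a
#'   warning); rows outside that window are an error.
#' @return An object of class `distogram`.
#' @export
distogram <- function(i, j, probs, edges, target_length = NA_integer_,
                      normalize = TRUE) {
  probs <- as.matrix(probs)
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (ncol(probs) != length(edges))
    stop("number of probability columns (", ncol(probs),
         ") != number of bins (", length(edges), ")")
  if (length(i) != nrow(probs) || length(j) != nrow(probs))
    stop("pair index length differs from probability rows")
  if (any(i >= j)) stop("distogram pairs must satisfy i < j")
  if (any(probs < -1e-9) || !all(is.finite(probs)))
    stop("bin probabilities must be finite and nonnegative")
  probs[probs < 0] <- 0
  sums <- rowSums(probs)
  # all-zero rows are tolerated here: they mark absent predictions and are
  # masked (with a warning) when the distogram is flattened
  off <- abs(sums - 1) > 1e-3 & sums > 0
  if (any(off)) {
    if (!normalize || any(sums[off] < 0.5 | sums[off] > 1.5))
      stop("distogram row sums outside tolerance: e.g. ",
           format(sums[off][1], digits = 4))
    warning(sum(off), " distogram row(s) renormalized (sums in [0.5, 1.5])")
    probs[off, ] <- probs[off, , drop = FALSE] / sums[off]
  }
  ord <- order(i, j)
  structure(list(i = as.integer(i)[ord], j = as.integer(j)[ord],
                 probs = probs[ord, , drop = FALSE], edges = edges,
                 target_length = as.integer(target_length)),
            class = "distogram")
}

#' @export
print.distogram <- function(x, ...) {
  cat(sprintf("<distogram> %d pairs x %d bins, edges %.1f..%.1f+ Angstrom\n",
              length(x$i), ncol(x$probs), x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' Distance-bin midpoints
#'
#' The final, open bin is represented by 21 Angstrom: every distance above
#' the 20 Angstrom visualization cap is treated identically, so only its
#' "beyond cap" semantics matter.
#'
#' @param edges Bin lower edges as in [distogram()].
#' @return Numeric vector of representative distances, one per bin.
#' @export
bin_midpoints <- function(edges) {
  B <- length(edges)
  c((edges[-B] + edges[-1]) / 2, edges[B] + 1)
}

#' CASP14 standard distance bins
#'
#' The ten bins used by RMODE 2 submissions:
#' \[0,4), \[4,6), ..., \[18,20), \[20, Inf).
#'
#' @return Numeric vector of the ten bin lower edges.
#' @export
casp14_bin_edges <- function() c(0, 4, 6, 8, 10, 12, 14, 16, 18, 20)

# internal: upper-triangle pair list (i < j) of an L x L matrix
upper_pairs <- function(L) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  list(i = idx[ord, 1], j = idx[ord, 2])
}
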