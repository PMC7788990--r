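# Converting binned distograms into real-valued maps and contact
# predictions.

#' Flatten a distogram to a real-valued distance map
#'
#' Each pair gets the midpoint of its highest-probability bin; argmax ties
#' break toward the lower-distance bin, and the open final bin maps to its
#' lower edge + 1 (anything above the 20 Angstrom cap is masked by
#' standardization downstream, so only "beyond cap" matters). Flattening
#' discards multi-peak information by design. All-zero probability rows are
#' masked with a warning.
#'
#' @param dg A [distogram()].
#' @param L Matrix dimension; defaults to the distogram's target length or
#'   the largest pair index.
#' @return A [distance_map()] with cells only where the distogram has pairs.
#' @export
flatten_distogram <- function(dg, L = NULL) {
  stopifnot(inherits(dg, "distogram"))
  if (is.null(L)) L <- if (!is.na(dg$target_length)) dg$target_length
                       else max(dg$j)
  mid <- bin_midpoints(dg$edges)
  best <- apply(dg$probs, 1, which.max)  # which.max = first max: low-bin ties
  dead <- rowSums(dg$probs) == 0
  if (any(dead)) warning(sum(dead), " all-zero distogram row(s) masked")
  v <- matrix(NA_real_, L, L)
  msk <- matrix(FALSE, L, L)
  idx <- cbind(dg$i, dg$j)
  v[idx] <- mid[best]
  msk[idx] <- !dead
  v[idx[, 2:1]] <- v[idx]
  msk[idx[, 2:1]] <- msk[idx]
  distance_map(v, msk)
}

#' Extract contact confidences from a distogram
#'
#' The confidence of a pair is its total probability mass in bins lying
#' entirely below 8 Angstrom (bins whose upper edge is <= 8). The bin set
#' must place an edge exactly at 8; there is no partial-bin interpolation.
#'
#' @param dg A [distogram()].
#' @return A [contact_prediction()].
#' @export
distogram_to_contacts <- function(dg) {
  stopifnot(inherits(dg, "distogram"))
  uppers <- c(dg$edges[-1], Inf)
  if (!any(abs(dg$edges - 8) < 1e-9))
    stop("bin edges incompatible with the 8 Angstrom contact threshold ",
         "(no edge at 8): ", paste(dg$edges, collapse = ", "))
  below <- uppers <= 8 + 1e-9
  conf <- rowSums(dg$probs[, below, drop = FALSE])
  conf <- pmin(pmax(conf, 0), 1)
  contact_prediction(data.frame(i = dg$i, j = dg$j, confidence = conf),
                     dg$target_length)
}
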