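# Quantitative evaluation of predicted distances and contacts against the
# true structure. Every metric reads the upper triangle (i < j) only, and
# pairs touching an invalid residue are excluded from every denominator
# rather than imputed. Metrics with an empty pair set report NA, never 0.

LDDT_INCLUSION_RADIUS <- 15   # Angstrom, on true distances
LDDT_TOLERANCES <- c(0.5, 1, 2, 4)
CONTACT_THRESHOLD <- 8        # Angstrom, true Cb-Cb distance
DIST_CAP <- 20                # Angstrom, standardization / "below 20 A" filter
DIST_FLOOR <- 3.5

#' Standardize a distance map for comparison
#'
#' Values below 3.5 Angstrom are ceiled to 3.5; values above 20 Angstrom
#' are masked (ignored). The transform is idempotent and makes maps from
#' different proteins share one numeric range.
#'
#' @param map A [distance_map()].
#' @return A [distance_map()] whose unmasked values lie in [3.5, 20].
#' @export
standardize <- function(map) {
  stopifnot(inherits(map, "distance_map"))
  v <- map$values
  msk <- map$mask
  msk[msk & v > DIST_CAP] <- FALSE
  v[msk & v < DIST_FLOOR] <- DIST_FLOOR
  distance_map(v, msk)
}

# Upper-triangle pairs unmasked in both maps, with separation class.
eligible_pairs <- function(pred, true, classes,
                           true_cap = DIST_CAP, min_sep = NULL) {
  stopifnot(inherits(pred, "distance_map"), inherits(true, "distance_map"))
  if (!all(dim(pred$values) == dim(true$values)))
    stop("prediction is ", nrow(pred$values), " x ", ncol(pred$values),
         " but true map is ", nrow(true$values), " x ", ncol(true$values))
  L <- nrow(true$values)
  up <- upper_pairs(L)
  idx <- cbind(up$i, up$j)
  keep <- pred$mask[idx] & true$mask[idx]
  if (!is.null(true_cap)) keep <- keep & true$values[idx] <= true_cap
  s <- up$j - up$i
  if (!is.null(classes))
    keep <- keep & separation_class(up$i, up$j) %in% classes
  if (!is.null(min_sep)) keep <- keep & s >= min_sep
  data.frame(i = up$i[keep], j = up$j[keep],
             pred = pred$values[idx][keep], true = true$values[idx][keep])
}

metric_value <- function(value, n) list(value = value, n = as.integer(n))

#' Mean absolute error of predicted distances
#'
#' Averaged over upper-triangle pairs unmasked in both maps, within the
#' requested separation classes, whose TRUE distance is <= 20 Angstrom
#' (the reference set is fixed by the native structure, independent of the
#' predictor).
#'
#' @param pred,true [distance_map()] objects of equal dimension.
#' @param classes Character vector of separation classes, e.g.
#'   `c("medium", "long")`.
#' @return `list(value =, n =)`; value is `NA` when no pair is eligible.
#' @export
mae <- function(pred, true, classes = c("medium", "long")) {
  e <- eligible_pairs(pred, true, classes)
  if (!nrow(e)) return(metric_value(NA_real_, 0))
  metric_value(mean(abs(e$pred - e$true)), nrow(e))
}

#' Root mean squared error of predicted distances
#'
#' Same pair set as [mae()].
#' @inheritParams mae
#' @return `list(value =, n =)`.
#' @export
rmse <- function(pred, true, classes = c("medium", "long")) {
  e <- eligible_pairs(pred, true, classes)
  if (!nrow(e)) return(metric_value(NA_real_, 0))
  metric_value(sqrt(mean((e$pred - e$true)^2)), nrow(e))
}

#' Pearson correlation of predicted vs true distances
#'
#' Same pair set as [mae()]; undefined (NA) below 3 pairs or under zero
#' variance on either side.
#' @inheritParams mae
#' @return `list(value =, n =)`.
#' @export
pcc_distances <- function(pred, true, classes = c("medium", "long")) {
  e <- eligible_pairs(pred, true, classes)
  if (nrow(e) < 3 || stats::sd(e$pred) == 0 || stats::sd(e$true) == 0)
    return(metric_value(NA_real_, nrow(e)))
  metric_value(stats::cor(e$pred, e$true), nrow(e))
}

#' Cb-LDDT of a predicted distance map
#'
#' Local distance difference test, superposition-free, in a symmetric
#' single-reference form: reference pairs are unmasked true pairs with
#' sequence separation >= `min_sep` and true distance below the 15
#' Angstrom inclusion radius. The score is the fraction of reference pairs
#' whose absolute error is within tolerance, averaged over the tolerances
#' 0.5, 1, 2 and 4 Angstrom. Reference pairs with a masked prediction
#' count as not preserved.
#'
#' @param pred,true [distance_map()] objects of equal dimension.
#' @param min_sep Minimum sequence separation (6, 12 or 24 in reports).
#' @return `list(value =, n =)`; value in [0, 1] or `NA` with no
#'   reference pairs.
#' @export
lddt <- function(pred, true, min_sep = 12) {
  stopifnot(inherits(pred, "distance_map"), inherits(true, "distance_map"))
  if (!all(dim(pred$values) == dim(true$values)))
    stop("prediction and true map dimensions differ")
  L <- nrow(true$values)
  up <- upper_pairs(L)
  idx <- cbind(up$i, up$j)
  ref <- true$mask[idx] & (up$j - up$i) >= min_sep &
    true$values[idx] < LDDT_INCLUSION_RADIUS
  n <- sum(ref)
  if (!n) return(metric_value(NA_real_, 0))
  err <- abs(pred$values[idx][ref] - true$values[idx][ref])
  err[!pred$mask[idx][ref]] <- Inf  # masked prediction: not preserved
  score <- mean(vapply(LDDT_TOLERANCES,
                       function(t) mean(err <= t), numeric(1)))
  metric_value(score, n)
}

#' Rank a distance map as a contact prediction
#'
#' Pairs are ranked by ascending predicted distance (ties broken by
#' lexicographic (i, j)); the stored confidence is the monotone display
#' transform (20 - clamp(d, 3.5, 20)) / 16.5, landing in [0, 1]. Masked
#' pairs are excluded.
#'
#' @param pred A [distance_map()].
#' @return A [contact_prediction()].
#' @export
distances_to_contact_ranking <- function(pred) {
  stopifnot(inherits(pred, "distance_map"))
  L <- nrow(pred$values)
  up <- upper_pairs(L)
  idx <- cbind(up$i, up$j)
  keep <- pred$mask[idx]
  d <- pred$values[idx][keep]
  conf <- (DIST_CAP - pmin(pmax(d, DIST_FLOOR), DIST_CAP)) /
    (DIST_CAP - DIST_FLOOR)
  contact_prediction(
    data.frame(i = up$i[keep], j = up$j[keep], confidence = conf),
    target_length = L)
}

#' Top-k contact precision
#'
#' Predicted pairs are filtered to the requested separation classes,
#' sorted by descending confidence (ties by lexicographic (i, j)), pairs
#' without an evaluable true distance are skipped (they consume no top-k
#' slot), and precision is the fraction of the top k whose true distance
#' is below 8 Angstrom. k is `max(1, floor(L / 5))` for `"topL5"` and `L`
#' for `"topL"`.
#'
#' @param pred A [contact_prediction()].
#' @param true The true [distance_map()].
#' @param classes Separation classes to keep (`"long"` or
#'   `c("medium", "long")`).
#' @param k_mode `"topL5"` or `"topL"`.
#' @param L Effective length from [effective_length()].
#' @return `list(value =, n =)` with n the number of predictions actually
#'   evaluated (min(k, available)); value `NA` when none are evaluable.
#' @export
precision_topk <- function(pred, true, classes = "long",
                           k_mode = c("topL5", "topL"), L) {
  stopifnot(inherits(pred, "contact_prediction"),
            inherits(true, "distance_map"))
  k_mode <- match.arg(k_mode)
  k <- if (k_mode == "topL5") max(1L, floor(L / 5)) else as.integer(L)
  p <- pred$pairs
  if (nrow(p)) {
    p <- p[separation_class(p$i, p$j) %in% classes, , drop = FALSE]
    Lmat <- nrow(true$values)
    p <- p[p$i <= Lmat & p$j <= Lmat, , drop = FALSE]
    if (nrow(p)) p <- p[true$mask[cbind(p$i, p$j)], , drop = FALSE]
  }
  if (!nrow(p)) return(metric_value(NA_real_, 0))
  p <- p[order(-p$confidence, p$i, p$j), , drop = FALSE]
  p <- utils::head(p, k)
  hits <- true$values[cbind(p$i, p$j)] < CONTACT_THRESHOLD
  metric_value(mean(hits), nrow(p))
}
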