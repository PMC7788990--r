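# Whole-report evaluation: dispatches on prediction kind, computes every
# metric the report defines and records the pair count behind each value.

REPORT_FIELDS <- c("mae_long", "mae_medium_long", "rmse_long",
                   "rmse_medium_long", "pcc_medium_long",
                   "lddt_sep6", "lddt_sep12", "lddt_sep24",
                   "precision_topL5_long", "precision_topL_long",
                   "precision_topL5_medlong", "precision_topL_medlong")

#' Evaluate a prediction against a true structure
#'
#' Distance maps produce all report fields; contact predictions produce
#' only the four precision fields; distograms are first flattened to a
#' distance map (for MAE/RMSE/PCC/LDDT) and reduced to contact
#' confidences by their sub-8-Angstrom bin mass (for precision). L is the
#' smaller of the sequence length and the number of valid residues.
#'
#' @param pred A [distance_map()], [contact_prediction()] or
#'   [distogram()].
#' @param structure A [protein_record()], or a precomputed true
#'   [distance_map()] together with `L`.
#' @param L Effective length override (needed only when `structure` is
#'   already a distance map).
#' @return An `evaluation_report`: a list of `list(value =, n =)` entries
#'   per metric plus `L` and the input `kind`.
#' @export
evaluate <- function(pred, structure, L = NULL) {
  if (inherits(structure, "protein_record")) {
    true <- true_distance_map(structure)
    L <- effective_length(nchar(structure$sequence), sum(structure$valid))
  } else if (inherits(structure, "distance_map")) {
    true <- structure
    if (is.null(L)) L <- nrow(true$values)
  } else stop("structure must be a protein_record or distance_map")

  Lmat <- nrow(true$values)
  na <- metric_value(NA_real_, 0)
  rep <- stats::setNames(vector("list", length(REPORT_FIELDS)), REPORT_FIELDS)
  for (f in REPORT_FIELDS) rep[[f]] <- na

  kind <- if (inherits(pred, "distogram")) "distogram"
          else if (inherits(pred, "distance_map")) "distance"
          else if (inherits(pred, "contact_prediction")) "contact"
          else stop("unsupported prediction type: ", class(pred)[1])

  dist_pred <- NULL
  contact_pred <- NULL
  if (kind == "distogram") {
    plen <- if (!is.na(pred$target_length)) pred$target_length else max(pred$j)
    if (plen > Lmat)
      stop("prediction indexes ", plen, " residues but structure has ", Lmat)
    dist_pred <- flatten_distogram(pred, L = Lmat)
    contact_pred <- distogram_to_contacts(pred)
  } else if (kind == "distance") {
    if (nrow(pred$values) != Lmat)
      stop("prediction is ", nrow(pred$values), " x ", ncol(pred$values),
           " but structure has ", Lmat, " residues")
    dist_pred <- pred
    contact_pred <- distances_to_contact_ranking(pred)
  } else {
    if (nrow(pred$pairs) && max(pred$pairs$j) > Lmat)
      stop("prediction indexes residue ", max(pred$pairs$j),
           " but structure has ", Lmat)
    contact_pred <- pred
  }

  if (!is.null(dist_pred)) {
    rep$mae_long <- mae(dist_pred, true, "long")
    rep$mae_medium_long <- mae(dist_pred, true, c("medium", "long"))
    rep$rmse_long <- rmse(dist_pred, true, "long")
    rep$rmse_medium_long <- rmse(dist_pred, true, c("medium", "long"))
    rep$pcc_medium_long <- pcc_distances(dist_pred, true, c("medium", "long"))
    rep$lddt_sep6 <- lddt(dist_pred, true, 6)
    rep$lddt_sep12 <- lddt(dist_pred, true, 12)
    rep$lddt_sep24 <- lddt(dist_pred, true, 24)
  }
  rep$precision_topL5_long <-
    precision_topk(contact_pred, true, "long", "topL5", L)
  rep$precision_topL_long <-
    precision_topk(contact_pred, true, "long", "topL", L)
  rep$precision_topL5_medlong <-
    precision_topk(contact_pred, true, c("medium", "long"), "topL5", L)
  rep$precision_topL_medlong <-
    precision_topk(contact_pred, true, c("medium", "long"), "topL", L)

  rep$L <- as.integer(L)
  rep$kind <- kind
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.evaluation_report <- function(x, ...) {
  c(sprintf("# evaluation report (input: %s, L = %d)", x$kind, x$L),
    vapply(REPORT_FIELDS, function(f) {
      m <- x[[f]]
      v <- if (is.na(m$value)) "NA" else sprintf("%.4f", m$value)
      sprintf("%-24s %8s  (n = %d)", f, v, m$n)
    }, character(1)))
}

#' Serialize an evaluation report
#'
#' @param rep An `evaluation_report`.
#' @param path Output path; `format = "json"` writes structured JSON with
#'   value and pair count per metric, `"txt"` the flat key-value table.
#' @param format `"json"` or `"txt"`.
#' @return The path, invisibly.
#' @export
write_report <- function(rep, path, format = c("json", "txt")) {
  stopifnot(inherits(rep, "evaluation_report"))
  format <- match.arg(format)
  if (format == "json") {
    out <- c(list(kind = rep$kind, L = rep$L),
             lapply(stats::setNames(REPORT_FIELDS, REPORT_FIELDS),
                    function(f) rep[[f]]))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    writeLines(format(rep), path)
  }
  invisible(path)
}
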