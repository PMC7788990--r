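# Heatmap and chord-diagram data products. build_* functions produce pure
# spec objects (testable without a device); render() rasterizes them to
# PNG or SVG. Exact colors are configuration, not contract: the contracts
# are the monotone value->bin mapping per scheme, the 8/12 Angstrom
# discontinuities of the threshold scheme, the triangle roles and the
# chord width/transparency laws.

#' Residue index gradient colors
#'
#' The shared "red through green to blue" gradient used for the heatmap
#' diagonal, chord arcs and chord colors, so the visualizations can be
#' cross-referenced by residue.
#'
#' @param L Number of residues.
#' @return Character vector of L colors.
#' @export
residue_gradient <- function(L) grDevices::rainbow(L, end = 2 / 3)

SS_COLORS <- c(H = "#d62728", E = "#2ca02c", C = "#ffffff")

#' Map a value to its color bin under a scheme
#'
#' For the `threshold` scheme there are exactly three bins with
#' discontinuities at 8 and 12 Angstrom; `gradient` and `uniform` use 64
#' monotone bins over the standardized range [3.5, 20] (distances) or
#' [0, 1] (confidences).
#'
#' @param value Numeric vector.
#' @param scheme `"gradient"`, `"threshold"` or `"uniform"`.
#' @param kind `"distance"`, `"confidence"` or `"error"`.
#' @return Integer bin indices (NA for NA input).
#' @export
color_bin <- function(value, scheme = c("gradient", "threshold", "uniform"),
                      kind = c("distance", "confidence", "error")) {
  scheme <- match.arg(scheme)
  kind <- match.arg(kind)
  if (scheme == "threshold" && kind == "distance")
    return(ifelse(is.na(value), NA_integer_,
                  ifelse(value < 8, 1L, ifelse(value < 12, 2L, 3L))))
  rng <- switch(kind, distance = c(3.5, 20), confidence = c(0, 1),
                error = c(0, 16.5))
  v <- pmin(pmax(value, rng[1]), rng[2])
  out <- findInterval(v, seq(rng[1], rng[2], length.out = 65),
                      rightmost.closed = TRUE)
  out[is.na(value)] <- NA_integer_
  as.integer(out)
}

scheme_palette <- function(scheme, kind, n = 64) {
  if (scheme == "threshold" && kind == "distance")
    return(c("#b2182b", "#fddbc7", "#f7f7f7"))
  if (scheme == "uniform") return(grDevices::hcl.colors(n, "viridis"))
  if (kind == "confidence")
    return(grDevices::colorRampPalette(c("#f7f7f7", "#08306b"))(n))
  if (kind == "error")
    return(grDevices::colorRampPalette(c("#f7f7f7", "#67000d"))(n))
  grDevices::colorRampPalette(
    c("#67001f", "#ef8a62", "#fddbc7", "#f7f7f7", "#d1e5f0", "#2166ac"))(n)
}

diag_band <- function(L, ss = NULL) {
  if (is.null(ss)) return(list(type = "gradient", colors = residue_gradient(L)))
  ss <- toupper(gsub("\\s", "", paste(ss, collapse = "")))
  if (nchar(ss) != L)
    stop("secondary-structure string length ", nchar(ss), " != L = ", L)
  cls <- strsplit(chartr("GITSB-", "HHHCEC", ss), "")[[1]]
  if (!all(cls %in% c("H", "E", "C")))
    stop("secondary structure must use H/E/C (or DSSP letters)")
  list(type = "ss", classes = cls, colors = unname(SS_COLORS[cls]))
}

contact_cells <- function(pred, L) {
  m <- matrix(NA_real_, L, L)
  if (nrow(pred$pairs))
    m[cbind(pred$pairs$i, pred$pairs$j)] <- pred$pairs$confidence
  m
}

#' Build a combined predicted/true heatmap spec
#'
#' The upper triangle carries the prediction (standardized distances, or
#' confidences in [0, 1] for contact input) and the lower triangle the
#' true standardized distance map (empty when absent). The diagonal shows
#' per-residue secondary-structure bands (helix red, strand green, coil
#' white) when `ss` is given, else the residue-index gradient. With
#' `rotated = TRUE` the cell-to-canvas transform turns the diagonal
#' vertical (the canvas becomes wider than tall).
#'
#' @param pred A [distance_map()] or [contact_prediction()].
#' @param true Optional true [distance_map()].
#' @param ss Optional secondary-structure string (H/E/C per residue).
#' @param scheme Coloring scheme (see [color_bin()]).
#' @param rotated Rotate 45 degrees so the diagonal is vertical.
#' @return A `heatmap_spec` object.
#' @export
build_heatmap <- function(pred, true = NULL, ss = NULL,
                          scheme = c("gradient", "threshold", "uniform"),
                          rotated = FALSE) {
  scheme <- match.arg(scheme)
  if (inherits(pred, "contact_prediction")) {
    L <- if (!is.na(pred$target_length)) pred$target_length
         else if (!is.null(true)) nrow(true$values)
         else max(pred$pairs$j, 2L)
    upper <- contact_cells(pred, L)
    upper_kind <- "confidence"
  } else if (inherits(pred, "distance_map")) {
    sp <- standardize(pred)
    L <- nrow(sp$values)
    upper <- sp$values
    upper[!sp$mask] <- NA_real_
    upper_kind <- "distance"
  } else stop("pred must be a distance_map or contact_prediction")

  cells <- matrix(NA_real_, L, L)
  cells[upper.tri(cells)] <- upper[upper.tri(upper)]
  lower_kind <- NULL
  if (!is.null(true)) {
    if (nrow(true$values) != L)
      stop("true map is ", nrow(true$values), " x ", ncol(true$values),
           " but prediction has L = ", L)
    st <- standardize(true)
    tv <- st$values
    tv[!st$mask] <- NA_real_
    cells[lower.tri(cells)] <- t(tv)[lower.tri(cells)]
    lower_kind <- "distance"
  }
  structure(list(cells = cells, L = L, upper_kind = upper_kind,
                 lower_kind = lower_kind, diag = diag_band(L, ss),
                 scheme = scheme, rotated = rotated),
            class = "heatmap_spec")
}

#' Build an absolute-error heatmap spec
#'
#' Cell value = |pred - true| on standardized maps where both cells are
#' unmasked, masked elsewhere; both triangles carry the error.
#'
#' @param pred,true [distance_map()] objects of equal dimension.
#' @param scheme Coloring scheme.
#' @param rotated Rotate 45 degrees.
#' @return A `heatmap_spec` with `upper_kind = lower_kind = "error"`.
#' @export
build_error_heatmap <- function(pred, true,
                                scheme = c("gradient", "threshold", "uniform"),
                                rotated = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(pred, "distance_map"), inherits(true, "distance_map"))
  if (!all(dim(pred$values) == dim(true$values)))
    stop("prediction and true map dimensions differ")
  sp <- standardize(pred); st <- standardize(true)
  err <- abs(sp$values - st$values)
  err[!(sp$mask & st$mask)] <- NA_real_
  L <- nrow(err)
  structure(list(cells = err, L = L, upper_kind = "error",
                 lower_kind = "error", diag = diag_band(L, NULL),
                 scheme = scheme, rotated = rotated),
            class = "heatmap_spec")
}

#' Chord width for a standardized distance
#'
#' Linear in the standardized distance: maximal (`w_max`) at 3.5
#' Angstrom, zero at 20 Angstrom; strictly decreasing in between.
#'
#' @param d Distances in Angstrom (clamped to [3.5, 20]).
#' @param w_max Maximum line width.
#' @return Numeric widths.
#' @export
chord_width_distance <- function(d, w_max = 10) {
  d <- pmin(pmax(d, DIST_FLOOR), DIST_CAP)
  w_max * (DIST_CAP - d) / (DIST_CAP - DIST_FLOOR)
}

#' Build a chord-diagram spec
#'
#' Arcs are the residues around a circle, colored by secondary structure
#' (if `ss` given) or by the residue-index gradient — the same coloring
#' as the corresponding heatmap's diagonal. Each displayed pair becomes a
#' chord whose color is the arc color of the lower-index residue. For
#' distance input, width decreases and transparency increases linearly
#' with the standardized distance, and only pairs with standardized value
#' below 12 Angstrom and separation >= 6 are drawn; for contact input,
#' width and opacity are proportional to confidence and the top 2L pairs
#' are drawn.
#'
#' @param x A [distance_map()] (standardized internally) or a
#'   [contact_prediction()].
#' @param ss Optional secondary-structure string.
#' @param L Residue count override (needed for contact input with unknown
#'   target length).
#' @param w_max Maximum chord width.
#' @param max_dist Display filter for distance input, Angstrom.
#' @param min_sep Display filter on |i - j| for distance input.
#' @return A `chord_spec` object.
#' @export
build_chord <- function(x, ss = NULL, L = NULL, w_max = 10,
                        max_dist = 12, min_sep = 6) {
  if (inherits(x, "distance_map")) {
    sm <- standardize(x)
    L <- L %||% nrow(sm$values)
    up <- upper_pairs(L)
    idx <- cbind(up$i, up$j)
    keep <- sm$mask[idx] & sm$values[idx] < max_dist &
      (up$j - up$i) >= min_sep
    d <- sm$values[idx][keep]
    chords <- data.frame(i = up$i[keep], j = up$j[keep],
                         width = chord_width_distance(d, w_max),
                         alpha = (DIST_CAP - d) / (DIST_CAP - DIST_FLOOR))
  } else if (inherits(x, "contact_prediction")) {
    L <- L %||% (if (!is.na(x$target_length)) x$target_length
                 else max(x$pairs$j, 2L))
    p <- x$pairs[order(-x$pairs$confidence, x$pairs$i, x$pairs$j), ,
                 drop = FALSE]
    p <- utils::head(p, 2L * L)
    chords <- data.frame(i = p$i, j = p$j,
                         width = w_max * p$confidence,
                         alpha = pmin(pmax(p$confidence, 0), 1))
  } else stop("x must be a distance_map or contact_prediction")
  chords <- chords[chords$width > 0, , drop = FALSE]
  band <- diag_band(L, ss)
  chords$color <- band$colors[pmin(chords$i, chords$j)]
  structure(list(arcs = band, chords = chords, L = L), class = "chord_spec")
}

#' Render a heatmap or chord spec to an image file
#'
#' @param spec A `heatmap_spec` or `chord_spec`.
#' @param path Output path; extension selects the device (`.png` or
#'   `.svg`).
#' @param width,height Canvas size in pixels (png) or inches (svg).
#' @return The path, invisibly.
#' @export
render <- function(spec, path, width = NULL, height = NULL) {
  UseMethod("render")
}

open_device <- function(path, width, height) {
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    grDevices::svg(path, width = width %||% 7, height = height %||% 7)
  } else {
    grDevices::png(path, width = width %||% 700, height = height %||% 700,
                   type = "cairo")
  }
}

#' @export
render.heatmap_spec <- function(spec, path, width = NULL, height = NULL) {
  L <- spec$L
  rot <- isTRUE(spec$rotated)
  if (rot && is.null(width) && is.null(height)) {
    # the 45-degree transform maps the L x L square onto a 2L-wide,
    # L-tall diamond: default to a wider-than-tall canvas
    width <- if (grepl("\\.svg$", path, ignore.case = TRUE)) 10 else 1000
    height <- if (grepl("\\.svg$", path, ignore.case = TRUE)) 5 else 500
  }
  open_device(path, width, height)
  on.exit(grDevices::dev.off())
  tr <- function(x, y) {
    if (!rot) return(list(x = x, y = y))
    list(x = (x + y) / sqrt(2), y = (y - x) / sqrt(2))
  }
  corners <- tr(c(0, L, 0, L), c(0, 0, L, L))
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(NA, xlim = range(corners$x), ylim = range(corners$y),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  draw_cell <- function(i, j, col) {
    # cell (i, j): column j, row i, y flipped so residue 1 is top-left
    p <- tr(c(j - 1, j, j, j - 1), L - c(i - 1, i - 1, i, i))
    graphics::polygon(p$x, p$y, col = col, border = NA)
  }
  pal_for <- function(kind) scheme_palette(spec$scheme, kind)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) { draw_cell(i, j, spec$diag$colors[i]); next }
    kind <- if (i < j) spec$upper_kind else spec$lower_kind
    if (is.null(kind)) next
    v <- spec$cells[i, j]
    if (is.na(v)) next
    pal <- pal_for(kind)
    draw_cell(i, j, pal[min(color_bin(v, spec$scheme, kind), length(pal))])
  }
  invisible(path)
}

#' @export
render.chord_spec <- function(spec, path, width = NULL, height = NULL) {
  open_device(path, width, height)
  on.exit(grDevices::dev.off())
  L <- spec$L
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  ang <- function(r) pi / 2 - 2 * pi * (r - 0.5) / L  # residue r center
  # arcs: one thick segment per residue along the circumference
  for (r in seq_len(L)) {
    th <- seq(pi / 2 - 2 * pi * (r - 1) / L, pi / 2 - 2 * pi * r / L,
              length.out = 8)
    graphics::lines(1.05 * cos(th), 1.05 * sin(th), lwd = 6,
                    col = spec$arcs$colors[r])
  }
  ch <- spec$chords
  if (nrow(ch)) for (k in seq_len(nrow(ch))) {
    a1 <- ang(ch$i[k]); a2 <- ang(ch$j[k])
    col <- grDevices::adjustcolor(ch$color[k], alpha.f = ch$alpha[k])
    # quadratic bezier through the origin-side control point
    t <- seq(0, 1, length.out = 32)
    cx <- (1 - t)^2 * cos(a1) + t^2 * cos(a2)
    cy <- (1 - t)^2 * sin(a1) + t^2 * sin(a2)
    graphics::lines(cx, cy, lwd = max(ch$width[k], 0.1), col = col)
  }
  invisible(path)
}
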