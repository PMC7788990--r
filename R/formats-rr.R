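# CASP RR text formats. Three dialects are accepted: the classic 5-column
# format (i j lower upper probability), the newer header-declared RMODE 1
# contact variant and the RMODE 2 distance-bin variant over the ten
# standardized bins of casp14_bin_edges().

RR_HEADER_KEYWORDS <- c("PFRMAT", "TARGET", "AUTHOR", "REMARK", "METHOD",
                        "MODEL", "RMODE", "SEQUENCE", "END")

#' Detect the RR dialect of a prediction file
#'
#' Detection is a pure function of header lines: a line declaring
#' `RMODE 1` or `RMODE 2` selects the corresponding CASP14 variant;
#' anything else is the classic format.
#'
#' @param text RR file content as a single string or a character vector of
#'   lines.
#' @return One of `"classic"`, `"rmode1"`, `"rmode2"`.
#' @export
detect_rr_dialect <- function(text) {
  lines <- rr_lines(text)
  if (!length(lines)) stop("empty RR content")
  rmode <- grep("^\\s*RMODE\\s+[0-9]", lines, value = TRUE)
  if (length(rmode)) {
    mode <- sub("^\\s*RMODE\\s+([0-9]+).*$", "\\1", rmode[1])
    if (mode == "1") return("rmode1")
    if (mode == "2") return("rmode2")
    stop("unsupported RMODE declaration: ", trimws(rmode[1]))
  }
  "classic"
}

rr_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  bad <- grepl("[^\t\r\n\033\040-\176]", text)
  if (any(bad))
    stop("unreadable (non-text) content at line ", which(bad)[1])
  text <- sub("\r$", "", text)
  text[nzchar(trimws(text))]
}

rr_is_header <- function(line) {
  first <- sub("^\\s*(\\S+).*$", "\\1", line)
  toupper(first) %in% RR_HEADER_KEYWORDS ||
    grepl("^[A-Za-z]+$", first)  # bare sequence continuation lines
}

#' Parse a CASP RR prediction file
#'
#' Classic and RMODE 1 content yields a [contact_prediction()]; RMODE 2
#' content yields a [distogram()] over the ten CASP14 bins. Pairs given as
#' i > j are transposed, self-pairs are dropped, and on duplicate pairs the
#' last occurrence wins with a warning (tolerant of concatenated
#' submissions).
#'
#' @param text RR content (string or lines).
#' @param dialect One of `"classic"`, `"rmode1"`, `"rmode2"`; by default
#'   detected with [detect_rr_dialect()].
#' @return A `contact_prediction` or `distogram`.
#' @export
parse_rr <- function(text, dialect = detect_rr_dialect(text)) {
  dialect <- match.arg(dialect, c("classic", "rmode1", "rmode2"))
  lines <- rr_lines(text)
  target_length <- NA_integer_
  seq_lines <- character()
  in_seq <- FALSE
  rows <- list()
  for (k in seq_along(lines)) {
    line <- lines[k]
    first <- toupper(sub("^\\s*(\\S+).*$", "\\1", line))
    if (first %in% RR_HEADER_KEYWORDS) {
      in_seq <- first == "SEQUENCE"
      next
    }
    if (grepl("^\\s*[A-Za-z]+\\s*$", line)) {  # raw sequence line
      seq_lines <- c(seq_lines, trimws(line))
      next
    }
    in_seq <- FALSE
    fields <- strsplit(trimws(line), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop("non-numeric pair fields at line ", k, ": '", trimws(line), "'")
    rows[[length(rows) + 1L]] <- list(line = k, vals = vals)
  }
  if (length(seq_lines)) target_length <- nchar(paste(seq_lines, collapse = ""))

  parse_pair <- function(r, nmin, what) {
    if (length(r$vals) < nmin)
      stop(what, " line needs >= ", nmin, " fields, got ", length(r$vals),
           " at line ", r$line)
    ij <- r$vals[1:2]
    if (any(ij != round(ij)) || any(ij < 1))
      stop("residue indices must be positive integers at line ", r$line)
    ij
  }

  if (dialect %in% c("classic", "rmode1")) {
    conf_col <- if (dialect == "classic") 5L else 3L
    nmin <- if (dialect == "classic") 5L else 3L
    out <- lapply(rows, function(r) {
      ij <- parse_pair(r, nmin, dialect)
      p <- r$vals[conf_col]
      if (!is.finite(p) || p < 0 || p > 1)
        stop("probability outside [0, 1] at line ", r$line, ": ", p)
      c(ij, p)
    })
    tab <- do.call(rbind, out)
    if (is.null(tab)) tab <- matrix(numeric(), 0, 3)
    df <- data.frame(i = tab[, 1], j = tab[, 2], confidence = tab[, 3])
    df <- normalize_pairs(df)
    contact_prediction(df, target_length)
  } else {
    edges <- casp14_bin_edges()
    B <- length(edges)
    out <- lapply(rows, function(r) {
      ij <- parse_pair(r, 2L + B, "rmode2")
      p <- r$vals[3:(2 + B)]
      if (any(p < 0 | p > 1))
        stop("probability outside [0, 1] at line ", r$line)
      c(ij, p)
    })
    tab <- do.call(rbind, out)
    if (is.null(tab)) stop("RMODE 2 file contains no pair lines")
    df <- data.frame(i = tab[, 1], j = tab[, 2])
    keep <- normalize_pairs_idx(df)
    distogram(i = pmin(df$i, df$j)[keep], j = pmax(df$i, df$j)[keep],
              probs = tab[keep, -(1:2), drop = FALSE], edges = edges,
              target_length = target_length)
  }
}

# transpose i>j, drop self-pairs, dedupe last-wins with a warning
normalize_pairs <- function(df) {
  keep <- normalize_pairs_idx(df)
  df <- df[keep, , drop = FALSE]
  ij <- data.frame(i = pmin(df$i, df$j), j = pmax(df$i, df$j))
  df$i <- ij$i; df$j <- ij$j
  df
}

normalize_pairs_idx <- function(df) {
  i <- pmin(df$i, df$j); j <- pmax(df$i, df$j)
  keep <- which(i != j)
  if (length(keep) < nrow(df))
    warning(nrow(df) - length(keep), " self-pair line(s) dropped")
  key <- paste(i[keep], j[keep])
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s): last occurrence wins")
    keep <- keep[!dup]
  }
  keep
}

#' Write a classic-format RR file
#'
#' Only the classic 5-column dialect is supported for writing; a parse of
#' the output reproduces the pair set exactly (confidences to 1e-6).
#'
#' @param pred A [contact_prediction()].
#' @param dialect Must be `"classic"`.
#' @param target Target name for the header line.
#' @return RR content as a single string.
#' @export
write_rr <- function(pred, dialect = "classic", target = "T0000") {
  if (!identical(dialect, "classic"))
    stop("writing is supported for the classic dialect only")
  stopifnot(inherits(pred, "contact_prediction"))
  header <- c("PFRMAT RR", paste("TARGET", target), "MODEL 1")
  body <- if (nrow(pred$pairs)) {
    sprintf("%d %d 0 8 %.6f", pred$pairs$i, pred$pairs$j,
            pred$pairs$confidence)
  } else character()
  paste(c(header, body, "END", ""), collapse = "\n")
}
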