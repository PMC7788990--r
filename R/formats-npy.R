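# Minimal reader/writer for the single-array '.npy' binary layout (version
# 1.0/2.0 headers, little-endian numeric dtypes, C or Fortran order) plus a
# whitespace/CSV text fallback, feeding read_distance_matrix(). No R npy
# package is available in the supported environment, and the format is a
# fixed 10-byte magic + python-literal header + raw buffer.

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an npy file (bad magic): ", path)
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))

  get <- function(key, rx) {
    m <- regmatches(header, regexec(paste0("'", key, "':\\s*", rx), header))[[1]]
    if (length(m) < 2) stop("npy header missing '", key, "': ", header)
    m[2]
  }
  descr <- get("descr", "'([^']+)'")
  fortran <- get("fortran_order", "(True|False)") == "True"
  shape_s <- get("shape", "\\(([^)]*)\\)")
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]

  dt <- regmatches(descr, regexec("^([<>|=])?([a-z])([0-9]+)$", descr))[[1]]
  if (length(dt) < 4) stop("unsupported npy dtype: ", descr)
  endian <- if (dt[2] == ">") "big" else "little"
  kind <- dt[3]; size <- as.integer(dt[4])
  n <- prod(shape)
  data <- switch(kind,
    f = readBin(con, "numeric", n, size = size, endian = endian),
    i = readBin(con, "integer", n, size = size, endian = endian),
    u = readBin(con, "integer", n, size = size, signed = FALSE,
                endian = endian),
    b = as.numeric(readBin(con, "integer", n, size = 1)),
    stop("unsupported npy dtype: ", descr))
  if (length(data) != n) stop("truncated npy payload in ", path)

  if (length(shape) <= 1) return(as.numeric(data))
  if (fortran) array(data, dim = shape)
  else aperm(array(data, dim = rev(shape)), rev(seq_along(shape)))
}

write_npy <- function(x, path) {
  x <- if (is.null(dim(x))) as.numeric(x) else x
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  shape_s <- if (length(shape) == 1) paste0("(", shape, ",)")
             else paste0("(", paste(shape, collapse = ", "), ")")
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }",
                    shape_s)
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a real-valued distance map
#'
#' Accepts the single-array '.npy' binary layout or a plain-text matrix
#' (whitespace-, comma- or tab-separated). If the two triangles disagree by
#' at most 1e-3 Angstrom they are averaged; on larger disagreement only the
#' upper triangle is trusted (all evaluation is upper-triangle based
#' anyway). Nonpositive and non-finite cells are masked.
#'
#' @param path Path to the matrix file.
#' @return A [distance_map()].
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  magic <- readBin(path, "raw", 6)
  m <- if (identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    read_npy(path)
  } else {
    first <- readLines(path, n = 1, warn = FALSE)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  }
  if (length(dim(m)) != 2)
    stop("distance matrix file must hold a 2D array, got ",
         length(dim(m)) %||% 1, "D")
  if (nrow(m) != ncol(m))
    stop("distance matrix must be square, got ", nrow(m), " x ", ncol(m))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL

  up <- upper.tri(m)
  finite_both <- is.finite(m) & is.finite(t(m))
  dev <- abs(m - t(m))
  if (any(up & finite_both & dev > 1e-3)) {
    # asymmetric beyond tolerance: trust the upper triangle
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  } else {
    avg <- (m + t(m)) / 2
    m[up & finite_both] <- avg[up & finite_both]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  mask <- is.finite(m) & m > 0
  distance_map(m, mask)
}

#' Write a distance map
#'
#' @param map A [distance_map()]; masked cells are written as -1.
#' @param path Output path; a `.npy` extension selects the binary layout,
#'   anything else a whitespace-separated text matrix.
#' @return The path, invisibly.
#' @export
write_distance_matrix <- function(map, path) {
  stopifnot(inherits(map, "distance_map"))
  v <- map$values
  v[!map$mask] <- -1
  diag(v) <- 0
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    write_npy(v, path)
  } else {
    utils::write.table(format(v, trim = TRUE, digits = 8), path,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
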