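# PDB ATOM-record parsing. Only the first MODEL is read; HETATM records are
# ignored; altloc blank or 'A'; insertion-coded residues are kept in file
# order. The representative atom is CB, with CA as fallback (always for
# glycine); residues carrying neither are flagged invalid.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

#' Parse a PDB file into a protein record
#'
#' @param text PDB content (single string, character vector of lines, or a
#'   file path to an existing file).
#' @param chain Optional one-character chain identifier; by default the
#'   first chain encountered is used.
#' @return A [protein_record()] with one entry per residue in file order.
#' @export
parse_pdb <- function(text, chain = NULL) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  end_model <- grep("^ENDMDL", text)
  if (length(end_model)) text <- text[seq_len(end_model[1] - 1L)]
  atom <- text[startsWith(text, "ATOM ") | startsWith(text, "ATOM\t")]
  if (!length(atom)) stop("no ATOM records found in PDB content")

  fx <- function(lines, from, to) substr(lines, from, to)
  name <- trimws(fx(atom, 13, 16))
  altloc <- fx(atom, 17, 17)
  resname <- trimws(fx(atom, 18, 20))
  chains <- fx(atom, 22, 22)
  resseq <- trimws(fx(atom, 23, 26))
  icode <- fx(atom, 27, 27)
  xyz <- cbind(as.numeric(fx(atom, 31, 38)),
               as.numeric(fx(atom, 39, 46)),
               as.numeric(fx(atom, 47, 54)))
  if (anyNA(xyz)) stop("malformed ATOM coordinates in PDB content")

  if (is.null(chain)) chain <- chains[1]
  keep <- chains == chain & altloc %in% c(" ", "A", "")
  if (!any(keep)) stop("no ATOM records in chain '", chain, "'")
  name <- name[keep]; resname <- resname[keep]
  resseq <- resseq[keep]; icode <- icode[keep]; xyz <- xyz[keep, , drop = FALSE]

  resid <- paste0(resseq, icode)
  resid <- factor(resid, levels = unique(resid))  # file order
  L <- nlevels(resid)
  coords <- matrix(NA_real_, L, 3)
  valid <- logical(L)
  aa <- character(L)
  for (r in seq_len(L)) {
    sel <- as.integer(resid) == r
    rn <- resname[sel][1]
    one <- AA3TO1[rn]
    if (is.na(one)) {
      warning("unknown residue name '", rn, "' mapped to 'X'")
      one <- "X"
    }
    aa[r] <- one
    nm <- name[sel]
    pick <- if (one != "G" && any(nm == "CB")) which(nm == "CB")[1]
            else if (any(nm == "CA")) which(nm == "CA")[1]
            else if (any(nm == "CB")) which(nm == "CB")[1]
            else NA_integer_
    if (!is.na(pick)) {
      coords[r, ] <- xyz[sel, , drop = FALSE][pick, ]
      valid[r] <- TRUE
    }
  }
  protein_record(paste(aa, collapse = ""), coords, valid)
}

AA1TO3 <- stats::setNames(names(AA3TO1)[1:20], AA3TO1[1:20])

#' Write a minimal PDB file for a protein record
#'
#' Emits CA and CB records per residue (CA only for glycine or invalid
#' residues with no coordinates are skipped). The representative-atom
#' coordinate of the record is written as the CB atom (CA for glycine), so
#' [parse_pdb()] round-trips the record to coordinate precision (1e-3).
#'
#' @param rec A [protein_record()].
#' @param chain Chain identifier to write.
#' @return PDB content as a single string.
#' @export
write_pdb <- function(rec, chain = "A") {
  stopifnot(inherits(rec, "protein_record"))
  aa <- strsplit(rec$sequence, "")[[1]]
  lines <- character()
  serial <- 0L
  for (r in seq_along(aa)) {
    if (!rec$valid[r]) next
    res3 <- AA1TO3[aa[r]]
    if (is.na(res3)) res3 <- "UNK"
    p <- rec$coords[r, ]
    emit <- function(name, xyz) {
      serial <<- serial + 1L
      sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
              serial, name, res3, chain, r, xyz[1], xyz[2], xyz[3])
    }
    if (aa[r] == "G") {
      lines <- c(lines, emit("CA", p))
    } else {
      # place a CA 1.53 Angstrom away so the file has a backbone atom too
      lines <- c(lines, emit("CA", p + c(1.53, 0, 0)), emit("CB", p))
    }
  }
  paste(c(lines, "TER", "END", ""), collapse = "\n")
}
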