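# Archived distogram tensor bundles: a tar (.tgz/.tar.gz) or zip (.npz)
# archive holding '.npy' members, one of which is an L x L x B pair
# probability tensor. Bin edges are resolved from an 'edges'-like 1-D
# member when present, else from the channel-count convention.

DISTOGRAM_TENSOR_KEYS <- c("dist", "distance", "distogram", "probs", "p_dist")
DISTOGRAM_EDGE_KEYS <- c("bin_edges", "edges", "bins")

#' Read a distogram tensor bundle
#'
#' Supported conventions for `B` channels when the bundle does not carry
#' explicit edges:
#' * `B = 37`: the trRosetta layout — first channel is the no-contact bin
#'   (> 20 Angstrom), followed by 36 half-Angstrom bins spanning 2 to 20
#'   Angstrom. Channels are reordered so bins ascend in distance with the
#'   no-contact bin last (open above 20).
#' * `B = 10`: the CASP14 standard bins ([casp14_bin_edges()]).
#'
#' Only the upper triangle of the tensor is used. Rows whose probabilities
#' sum to a value in [0.5, 1.5] but not 1 are renormalized with a warning;
#' rows further off are an error.
#'
#' @param path Path to the archive.
#' @param edges Optional explicit bin lower edges overriding the
#'   conventions above (length must equal the number of channels).
#' @return A [distogram()].
#' @export
read_distogram_bundle <- function(path, edges = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tmp <- tempfile("distogram_bundle_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  magic <- readBin(path, "raw", 4)
  if (identical(magic[1:2], as.raw(c(0x50, 0x4b)))) {         # zip / npz
    utils::unzip(path, exdir = tmp)
  } else if (identical(magic[1:2], as.raw(c(0x1f, 0x8b))) ||  # gzip tar
             grepl("\\.(tar|tgz|tar\\.gz)$", path, ignore.case = TRUE)) {
    utils::untar(path, exdir = tmp)
  } else stop("unrecognized bundle type (expected tar/tgz or zip/npz): ", path)

  members <- list.files(tmp, recursive = TRUE, full.names = TRUE)
  members <- members[grepl("\\.npy$", members)]
  if (!length(members)) stop("bundle contains no '.npy' members")
  arrays <- lapply(members, read_npy)
  keys <- sub("\\.npy$", "", basename(members))
  names(arrays) <- keys

  nd <- vapply(arrays, function(a) length(dim(a) %||% integer()), 1L)
  want <- which(tolower(keys) %in% DISTOGRAM_TENSOR_KEYS & nd == 3L)
  if (!length(want)) want <- which(nd == 3L)
  if (!length(want))
    stop("no L x L x B distance tensor in bundle; members: ",
         paste(keys, collapse = ", "))
  tensor <- arrays[[want[1]]]
  d <- dim(tensor)
  if (d[1] != d[2]) stop("tensor first two dims must match, got ",
                         paste(d, collapse = " x "))
  L <- d[1]; B <- d[3]

  if (is.null(edges)) {
    ek <- which(tolower(keys) %in% DISTOGRAM_EDGE_KEYS & nd <= 1L)
    if (length(ek)) {
      e <- as.numeric(arrays[[ek[1]]])
      edges <- if (length(e) == B + 1L) e[seq_len(B)] else e
      if (length(edges) != B)
        stop("bundle edges length ", length(e), " incompatible with ", B,
             " channels")
    } else if (B == 37L) {
      # trRosetta convention: channel 1 = no contact, then 36 half-A bins
      tensor <- tensor[, , c(2:37, 1), drop = FALSE]
      edges <- c(seq(2, 19.5, by = 0.5), 20)
    } else if (B == 10L) {
      edges <- casp14_bin_edges()
    } else {
      stop("cannot resolve bin edges for ", B,
           " channels; pass `edges` explicitly")
    }
  } else if (length(edges) != B) {
    stop("edges length ", length(edges), " != number of channels ", B)
  }

  up <- upper_pairs(L)
  probs <- t(vapply(seq_along(up$i),
                    function(k) tensor[up$i[k], up$j[k], ],
                    numeric(B)))
  distogram(up$i, up$j, probs, edges, target_length = L)
}
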