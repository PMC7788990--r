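# Shared fixture builders: tiny maps and structures built in code.

# distance_map from an upper-triangle pair list on an L x L grid
pair_map <- function(L, i, j, d) {
  v <- matrix(NA_real_, L, L)
  m <- matrix(FALSE, L, L)
  v[cbind(i, j)] <- d; v[cbind(j, i)] <- d
  m[cbind(i, j)] <- TRUE; m[cbind(j, i)] <- TRUE
  distance_map(v, m)
}

# fully dense symmetric map with constant fill and selected overrides
dense_map <- function(L, fill = 10, i = integer(), j = integer(),
                      d = numeric()) {
  v <- matrix(fill, L, L)
  diag(v) <- 0
  if (length(i)) { v[cbind(i, j)] <- d; v[cbind(j, i)] <- d }
  distance_map(v)
}

classic_rr_text <- function(pairs, header = c("PFRMAT RR", "MODEL 1"),
                            seq_lines = character()) {
  body <- sprintf("%d %d 0 8 %s", pairs$i, pairs$j,
                  formatC(pairs$confidence, format = "f", digits = 6))
  paste(c(header, seq_lines, body, "END"), collapse = "\n")
}

# random compact structure cached per (n, seed) to keep the suite fast
.structure_cache <- new.env(parent = emptyenv())
cached_structure <- function(n, seed) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.structure_cache[[key]]))
    .structure_cache[[key]] <- make_structure(synthetic_spec(n, seed = seed))
  .structure_cache[[key]]
}
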