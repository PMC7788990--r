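# Independent brute-force oracles, deliberately written as plain loops
# over all pairs so they share no code path with the package internals.

oracle_sep_class <- function(i, j) {
  s <- abs(i - j)
  if (s < 6) "local" else if (s < 12) "short"
  else if (s < 24) "medium" else "long"
}

# LDDT: loop over every i<j pair, apply the reference-set rules, count
# preserved distances per tolerance.
oracle_lddt <- function(pred_v, pred_m, true_v, true_m, min_sep,
                        r0 = 15, tols = c(0.5, 1, 2, 4)) {
  L <- nrow(true_v)
  per_tol <- numeric(length(tols))
  n_ref <- 0
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    if (!true_m[i, j]) next
    if (j - i < min_sep) next
    if (true_v[i, j] >= r0) next
    n_ref <- n_ref + 1
    for (t in seq_along(tols)) {
      ok <- pred_m[i, j] && abs(pred_v[i, j] - true_v[i, j]) <= tols[t]
      per_tol[t] <- per_tol[t] + ok
    }
  }
  if (n_ref == 0) return(list(value = NA_real_, n = 0))
  list(value = mean(per_tol / n_ref), n = n_ref)
}

# top-k precision from an explicit confidence table, sorting and counting
# by hand
oracle_precision <- function(pairs, true_v, true_m, classes, k) {
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    keep[r] <- oracle_sep_class(i, j) %in% classes &&
      i <= nrow(true_v) && j <= nrow(true_v) && true_m[i, j]
  }
  p <- pairs[keep, , drop = FALSE]
  if (!nrow(p)) return(list(value = NA_real_, n = 0))
  p <- p[order(-p$confidence, p$i, p$j), , drop = FALSE]
  p <- p[seq_len(min(k, nrow(p))), , drop = FALSE]
  hits <- 0
  for (r in seq_len(nrow(p)))
    hits <- hits + (true_v[p$i[r], p$j[r]] < 8)
  list(value = hits / nrow(p), n = nrow(p))
}
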