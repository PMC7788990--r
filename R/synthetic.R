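# Seeded synthetic fixtures: compact self-avoiding chains standing in for
# native structures, Gaussian-noise distance predictions and sharpened
# distograms. All randomness flows from the single seed in the spec, and
# generation is a pure function of the spec (the caller's RNG state is
# left untouched).

#' Parameters of the synthetic world
#'
#' @param n_residues Chain length (>= 2).
#' @param noise_sigma Std. dev. of the Gaussian distance noise, Angstrom.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param distogram_edges Bin lower edges for synthetic distograms.
#' @param glycine_fraction Fraction of glycines (written CA-only in PDB).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_residues, noise_sigma = 1, seed = 1,
                           distogram_edges = casp14_bin_edges(),
                           glycine_fraction = 0.08) {
  stopifnot(n_residues >= 2, noise_sigma >= 0,
            glycine_fraction >= 0, glycine_fraction <= 1)
  structure(list(n_residues = as.integer(n_residues),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 distogram_edges = distogram_edges,
                 glycine_fraction = glycine_fraction),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

runif_sphere <- function() {
  repeat {
    v <- stats::runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-6 && n2 <= 1) return(v / sqrt(n2))
  }
}

#' Generate a compact self-avoiding synthetic chain
#'
#' A biased random walk with fixed 3.8 Angstrom steps between consecutive
#' representative atoms, a 3.5 Angstrom clearance between non-consecutive
#' residues and a confining sphere of radius `2.6 * n^(1/3)` Angstrom
#' (floor 6). The confinement collapses the chain so every separation
#' class contains sub-8-Angstrom contacts, which the precision metrics
#' need. Residue identities are random with the requested glycine
#' fraction; glycines carry only a CA atom in the emitted PDB.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with the `record` ([protein_record()]) and `pdb_text`
#'   (well-formed PDB content that [parse_pdb()] round-trips).
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_residues
  step <- 3.8; clearance <- 3.5
  radius <- max(6, 2.6 * n^(1/3))
  with_seed(spec$seed, {
    aa_pool <- setdiff(unname(AA3TO1[1:20]), "G")
    seq_chars <- ifelse(stats::runif(n) < spec$glycine_fraction, "G",
                        sample(aa_pool, n, replace = TRUE))
    coords <- NULL
    for (restart in 1:50) {
      cand_coords <- matrix(NA_real_, n, 3)
      cand_coords[1, ] <- c(0, 0, 0)
      k <- 2L
      backtracks <- 0L
      while (k <= n) {
        placed <- FALSE
        for (try in 1:300) {
          cand <- cand_coords[k - 1L, ] + step * runif_sphere()
          if (sqrt(sum(cand^2)) > radius) next
          if (k > 2L) {
            prev <- cand_coords[seq_len(k - 2L), , drop = FALSE]
            d2 <- rowSums(sweep(prev, 2, cand)^2)
            if (min(d2) < clearance^2) next
          }
          cand_coords[k, ] <- cand
          placed <- TRUE
          break
        }
        if (placed) {
          k <- k + 1L
        } else {
          backtracks <- backtracks + 1L
          if (backtracks > 10L * n) break  # give up, restart fresh
          k <- max(2L, k - 3L)             # back up a few residues
          cand_coords[k:n, ] <- NA_real_
        }
      }
      if (!anyNA(cand_coords)) { coords <- cand_coords; break }
    }
    if (is.null(coords))
      stop("chain placement failed after bounded retries; ",
           "try fewer residues or a larger confinement box")
    rec <- protein_record(paste(seq_chars, collapse = ""), coords,
                          rep(TRUE, n))
    list(record = rec, pdb_text = write_pdb(rec))
  })
}

#' Perturb a true distance map into a synthetic prediction
#'
#' Zero-mean Gaussian noise with `spec$noise_sigma` is added to the upper
#' triangle and mirrored, then values are floored at 1 Angstrom. Masked
#' cells stay masked. `sigma = 0` returns the true map unchanged.
#'
#' @param true A [distance_map()].
#' @param spec A [synthetic_spec()] (fields used: `noise_sigma`, `seed`).
#' @return A [distance_map()].
#' @export
make_prediction <- function(true, spec) {
  stopifnot(inherits(true, "distance_map"), inherits(spec, "synthetic_spec"))
  L <- nrow(true$values)
  with_seed(spec$seed + 1L, {
    v <- true$values
    up <- upper.tri(v)
    noise <- matrix(0, L, L)
    noise[up] <- stats::rnorm(sum(up), 0, spec$noise_sigma)
    v[up] <- pmax(v[up] + noise[up], 1)
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    distance_map(v, true$mask)
  })
}

#' Build a distogram around a true distance map
#'
#' Each pair's probability vector is the Gaussian
#' `N(true distance, sharpness^2)` mass falling in each bin (the final
#' bin is open), renormalized. Small sharpness concentrates mass in the
#' bin containing the true distance.
#'
#' @param true A [distance_map()].
#' @param edges Bin lower edges.
#' @param sharpness Gaussian sigma in Angstrom (> 0).
#' @return A [distogram()] over the unmasked upper-triangle pairs.
#' @export
make_distogram <- function(true, edges = casp14_bin_edges(),
                           sharpness = 0.5) {
  stopifnot(inherits(true, "distance_map"), sharpness > 0)
  L <- nrow(true$values)
  up <- upper_pairs(L)
  keep <- true$mask[cbind(up$i, up$j)]
  i <- up$i[keep]; j <- up$j[keep]
  d <- true$values[cbind(i, j)]
  B <- length(edges)
  hi <- c(edges[-1], Inf)
  probs <- vapply(seq_len(B), function(b) {
    stats::pnorm(hi[b], d, sharpness) - stats::pnorm(edges[b], d, sharpness)
  }, numeric(length(d)))
  probs <- matrix(probs, nrow = length(d))
  probs <- probs / rowSums(probs)
  distogram(i, j, probs, edges, target_length = L)
}
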