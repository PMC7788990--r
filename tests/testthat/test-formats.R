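# RR dialects, PDB parsing, matrix files and distogram bundles.

test_that("RR dialect detection is driven by header lines only", {
  expect_equal(detect_rr_dialect("PFRMAT RR\nRMODE 2\n1 9 0.1 0.2 0.3"),
               "rmode2")
  expect_equal(detect_rr_dialect("PFRMAT RR\nRMODE 1\n1 9 0.9"), "rmode1")
  expect_equal(detect_rr_dialect("PFRMAT RR\n5 27 0 8 0.93"), "classic")
  # RMODE must be a header keyword, not a substring of data
  expect_equal(detect_rr_dialect("PFRMAT RR\nMODEL 1\n1 9 0 8 0.5"),
               "classic")
  expect_error(detect_rr_dialect(rawToChar(as.raw(c(80, 1, 2, 3)))),
               "line 1")
  expect_error(detect_rr_dialect(character()), "empty")
})

test_that("classic RR pair lines parse with confidence in column 5", {
  txt <- paste("PFRMAT RR", "TARGET T1", "MODEL 1",
               "5 27 0 8 0.93", "2 40 0 8 0.10", sep = "\n")
  cp <- parse_rr(txt)
  expect_s3_class(cp, "contact_prediction")
  expect_equal(cp$pairs$i, c(2, 5))
  expect_equal(cp$pairs$j, c(40, 27))
  expect_equal(cp$pairs$confidence, c(0.10, 0.93))
})

test_that("sequence lines set the target length and are not pair lines", {
  txt <- classic_rr_text(data.frame(i = 1, j = 30, confidence = 0.5),
                         seq_lines = c("ACDEFGHIKL", "MNPQRSTVWY"))
  cp <- parse_rr(txt)
  expect_equal(cp$target_length, 20L)
})

test_that("pair normalization: transposed, self and duplicate pairs", {
  txt <- paste("PFRMAT RR", "27 5 0 8 0.93", sep = "\n")
  cp <- parse_rr(txt)
  expect_equal(cp$pairs[, c("i", "j")], data.frame(i = 5, j = 27))

  expect_warning(cp <- parse_rr("PFRMAT RR\n7 7 0 8 0.5\n1 9 0 8 0.2"),
                 "self-pair")
  expect_equal(nrow(cp$pairs), 1L)

  expect_warning(
    cp <- parse_rr("PFRMAT RR\n5 27 0 8 0.10\n5 27 0 8 0.90"),
    "last occurrence wins")
  expect_equal(cp$pairs$confidence, 0.90)
})

test_that("malformed RR content raises located errors", {
  expect_error(parse_rr("PFRMAT RR\n5 x 0 8 0.9"), "line 2")
  expect_error(parse_rr("PFRMAT RR\n5 27 0 8 1.7"), "\\[0, 1\\]")
  expect_error(parse_rr("PFRMAT RR\n5 27 0 8"), ">= 5 fields")
})

test_that("RMODE 1 parses as contacts from the third column", {
  cp <- parse_rr("PFRMAT RR\nRMODE 1\n3 40 0.75 0.1 0.2\n1 30 0.20")
  expect_s3_class(cp, "contact_prediction")
  expect_equal(cp$pairs$confidence, c(0.20, 0.75))
})

test_that("RMODE 2 parses to a distogram over the ten CASP14 bins", {
  probs <- c(0, 1, rep(0, 8))
  txt <- paste("PFRMAT RR", "RMODE 2",
               paste(c(4, 30, probs), collapse = " "), sep = "\n")
  dg <- parse_rr(txt)
  expect_s3_class(dg, "distogram")
  expect_equal(dg$edges, casp14_bin_edges())
  expect_equal(dg$probs[1, ], probs)  # unit mass in bin 2 = [4, 6)
  expect_error(parse_rr("PFRMAT RR\nRMODE 2\n4 30 0.5 0.5"), "12 fields")
})

test_that("distogram rows must sum to 1 within tolerance after parsing", {
  # sum 0.9: renormalized with a warning (float-truncation tolerance)
  half <- c(0.45, 0.45, rep(0, 8))
  txt <- paste("PFRMAT RR", "RMODE 2",
               paste(c(1, 30, half), collapse = " "), sep = "\n")
  expect_warning(dg <- parse_rr(txt), "renormalized")
  expect_equal(sum(dg$probs[1, ]), 1, tolerance = 1e-9)
  # sum 0.3: corrupt, rejected
  bad <- c(0.3, rep(0, 9))
  txt <- paste("PFRMAT RR", "RMODE 2",
               paste(c(1, 30, bad), collapse = " "), sep = "\n")
  expect_error(suppressWarnings(parse_rr(txt)), "row sums")
})

test_that("classic RR write -> parse is the identity on pair sets", {
  set.seed(11)
  n <- 50
  prs <- unique(data.frame(i = sample(1:40, n, TRUE),
                           j = sample(41:80, n, TRUE)))
  prs$confidence <- round(runif(nrow(prs)), 4)
  cp <- contact_prediction(prs)
  back <- parse_rr(write_rr(cp))
  expect_equal(back$pairs$i, cp$pairs$i)
  expect_equal(back$pairs$j, cp$pairs$j)
  expect_equal(back$pairs$confidence, cp$pairs$confidence, tolerance = 1e-6)

  empty <- contact_prediction(data.frame(i = integer(), j = integer(),
                                         confidence = numeric()))
  expect_equal(nrow(parse_rr(write_rr(empty))$pairs), 0L)
  expect_error(write_rr(cp, dialect = "rmode2"), "classic")
})

test_that("parse_pdb follows the CB-with-CA-fallback convention", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       2.000   0.000   0.000  1.00  0.00",
    "ATOM      3  CB  ALA A   2       2.000   1.000   0.000  1.00  0.00",
    "ATOM      4  N   SER A   3       3.000   0.000   0.000  1.00  0.00",
    "ATOM      5  CA  VAL A   4       4.000   0.000   0.000  1.00  0.00",
    "TER", "END")
  rec <- parse_pdb(paste(lines, collapse = "\n"))
  expect_equal(rec$sequence, "GASV")
  expect_equal(rec$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(rec$coords[1, ], c(1, 0, 0))  # Gly: CA is representative
  expect_equal(rec$coords[2, ], c(2, 1, 0))  # CB preferred over CA
  expect_equal(rec$coords[4, ], c(4, 0, 0))  # CB absent: CA fallback
})

test_that("parse_pdb chain selection, HETATM, altloc and unknowns", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  1.00  0.00",
    "HETATM    3  O   HOH A   2       5.000   5.000   5.000  1.00  0.00",
    "ATOM      4  CA  XYZ A   2       1.000   1.000   1.000  1.00  0.00",
    "ATOM      5  CA  TRP B   1       7.000   0.000   0.000  1.00  0.00",
    "END")
  expect_warning(rec <- parse_pdb(paste(lines, collapse = "\n")),
                 "unknown residue")
  expect_equal(rec$sequence, "AX")          # first chain, altloc B skipped
  expect_equal(rec$coords[1, ], c(0, 0, 0))
  recB <- parse_pdb(paste(lines[-4], collapse = "\n"), chain = "B")
  expect_equal(recB$sequence, "W")
  expect_error(parse_pdb("REMARK nothing here\nEND"), "no ATOM")
  expect_error(parse_pdb(paste(lines, collapse = "\n"), chain = "Z"),
               "chain 'Z'")
})

test_that("read_distance_matrix handles npy, text, masking and shape", {
  d <- tempfile(fileext = ".npy")
  m <- matrix(c(0, 5, 9, 5, 0, 4, 9, 4, 0), 3, 3)
  distval:::write_npy(m, d)
  dm <- read_distance_matrix(d)
  expect_equal(dm$values[1, 2], 5)
  expect_equal(dm$mask, !diag(3) == 1)  # only the diagonal masked

  m2 <- m; m2[1, 3] <- -1; m2[3, 1] <- -1
  t2 <- tempfile(fileext = ".txt")
  write.table(m2, t2, row.names = FALSE, col.names = FALSE)
  dm2 <- read_distance_matrix(t2)
  expect_false(dm2$mask[1, 3])
  expect_true(dm2$mask[1, 2])

  d3 <- tempfile(fileext = ".npy")
  distval:::write_npy(matrix(1, 3, 4), d3)
  expect_error(read_distance_matrix(d3), "square")
})

test_that("asymmetric matrices beyond 1e-3 trust the upper triangle", {
  m <- matrix(c(0, 7, 5, 0), 2, 2)  # [1,2] = 5 (upper), [2,1] = 7 (lower)
  f <- tempfile(fileext = ".npy")
  distval:::write_npy(m, f)
  dm <- read_distance_matrix(f)
  expect_equal(dm$values[1, 2], 5)
  expect_equal(dm$values[2, 1], 5)
  # within tolerance: averaged
  m2 <- matrix(c(0, 5.0004, 5.0, 0), 2, 2)
  distval:::write_npy(m2, f)
  expect_equal(read_distance_matrix(f)$values[1, 2], 5.0002)
})

test_that("npy io round-trips and agrees with the numpy reference", {
  m <- matrix(rnorm(12), 3, 4)
  f <- tempfile(fileext = ".npy")
  distval:::write_npy(m, f)
  expect_equal(distval:::read_npy(f), m)

  py <- Sys.which("python")
  if (nzchar(py)) {
    # cross-check against numpy itself on the same file
    f2 <- tempfile(fileext = ".npy")
    script <- sprintf(paste0(
      "import numpy as np; a = np.load('%s'); ",
      "np.save('%s', np.asarray(a, order='C') * 2)"), f, f2)
    res <- system2(py, c("-c", shQuote(script)))
    if (res == 0L) expect_equal(distval:::read_npy(f2), 2 * m)
  } else succeed("python unavailable; binary layout checked by round-trip")
})

test_that("distogram bundles: tensor lookup, edges and renormalization", {
  L <- 4
  edges <- casp14_bin_edges()
  tensor <- array(0, c(L, L, 10))
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    tensor[i, j, 3] <- 0.9   # [6, 8)
    tensor[i, j, 4] <- 0.1
    tensor[j, i, ] <- tensor[i, j, ]
  }
  dir <- tempfile(); dir.create(dir)
  distval:::write_npy(tensor, file.path(dir, "dist.npy"))
  distval:::write_npy(edges, file.path(dir, "bin_edges.npy"))
  tgz <- tempfile(fileext = ".tgz")
  old <- setwd(dir); on.exit(setwd(old))
  tar(tgz, files = c("dist.npy", "bin_edges.npy"), compression = "gzip",
      tar = "internal")
  setwd(old)
  dg <- read_distogram_bundle(tgz)
  expect_equal(length(dg$i), L * (L - 1) / 2)
  expect_equal(dg$edges, edges)
  expect_equal(unname(dg$probs[1, 3]), 0.9)

  # row summing to 0.90 is renormalized with a warning
  tensor2 <- tensor * 0.9
  distval:::write_npy(tensor2, file.path(dir, "dist.npy"))
  setwd(dir)
  tar(tgz, files = c("dist.npy", "bin_edges.npy"), compression = "gzip",
      tar = "internal")
  setwd(old)
  expect_warning(dg2 <- read_distogram_bundle(tgz), "renormalized")
  expect_equal(rowSums(dg2$probs), rep(1, L * (L - 1) / 2))

  # bundle with no 3D tensor lists its members
  distval:::write_npy(1:3, file.path(dir, "other.npy"))
  file.remove(file.path(dir, "dist.npy"))
  setwd(dir)
  tar(tgz, files = c("other.npy", "bin_edges.npy"), compression = "gzip",
      tar = "internal")
  setwd(old)
  expect_error(read_distogram_bundle(tgz), "other")
})

test_that("37-channel bundles use the trRosetta layout (no-contact first)", {
  L <- 3
  tensor <- array(0, c(L, L, 37))
  # true distance ~5.1: mass in channel for [5.0, 5.5) = index 1 + 7
  tensor[1, 2, 8] <- 1; tensor[2, 1, 8] <- 1
  tensor[1, 3, 1] <- 1; tensor[3, 1, 1] <- 1  # no-contact channel
  tensor[2, 3, 37] <- 1; tensor[3, 2, 37] <- 1
  dir <- tempfile(); dir.create(dir)
  distval:::write_npy(tensor, file.path(dir, "dist.npy"))
  tgz <- tempfile(fileext = ".tgz")
  old <- setwd(dir)
  tar(tgz, files = "dist.npy", compression = "gzip", tar = "internal")
  setwd(old)
  dg <- read_distogram_bundle(tgz)
  expect_equal(dg$edges[1], 2)
  dm <- flatten_distogram(dg)
  expect_equal(dm$values[1, 2], 5.25)   # midpoint of [5.0, 5.5)
  expect_equal(dm$values[1, 3], 21)     # no-contact bin, beyond the cap
  expect_equal(dm$values[2, 3], 19.75)  # [19.5, 20)
})
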