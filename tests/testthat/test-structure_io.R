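test_that("parse -> write -> parse preserves residues and coordinates", {
  h <- make_helix(12)
  txt <- write_pdb(h)
  h2 <- parse_structure(paste(txt, collapse = "\n"))
  expect_equal(nrow(structure_residues(h2)), 12)
  expect_equal(h2$atoms$resid, h$atoms$resid)
  expect_equal(h2$atoms$elety, h$atoms$elety)
  # PDB precision is 3 decimals
  expect_equal(as.matrix(h2$atoms[, c("x", "y", "z")]),
               as.matrix(h$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)

  txt2 <- write_pdb(h2)
  h3 <- parse_structure(paste(txt2, collapse = "\n"))
  expect_equal(h3$atoms[, c("x", "y", "z")], h2$atoms[, c("x", "y", "z")])
})

test_that("altloc conformers resolve to highest occupancy, ties by letter", {
  mk <- function(occ_a, occ_b) c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.500   2.400   0.000  1.00  0.00           O",
    sprintf("ATOM      5  CB AALA A   1       1.000   1.000   1.000%6.2f  0.00           C", occ_a),
    sprintf("ATOM      6  CB BALA A   1       9.000   9.000   9.000%6.2f  0.00           C", occ_b),
    "END")
  st <- parse_structure(mk(0.60, 0.40))
  cb <- residue_atoms(st, "A", 1)$CB
  expect_equal(cb, c(1, 1, 1))
  expect_equal(sum(st$atoms$elety == "CB"), 1L)
  # tie: altloc A (letter order) wins
  st2 <- parse_structure(mk(0.50, 0.50))
  expect_equal(residue_atoms(st2, "A", 1)$CB, c(1, 1, 1))
})

test_that("degenerate inputs raise named parse errors", {
  waters <- c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END")
  expect_error(parse_structure(waters), class = "ssf_empty_structure")

  bad <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       xxxxx   0.000   0.000  1.00  0.00           C",
    "END")
  expect_error(parse_structure(bad), "line 2", class = "ssf_parse_error")
})

test_that("native disulfide detection applies the cutoff and greedy matching", {
  st <- make_cystine_structure(sg_sg = 2.05)
  expect_equal(nrow(detect_native_disulfides(st)), 1L)

  far <- make_cystine_structure(sg_sg = 5.0)
  expect_equal(nrow(detect_native_disulfides(far)), 0L)

  # three cysteines: A-B 2.05, B-C 2.2 -> only A-B survives (B consumed
  # by its closer partner). Oracle: greedy matching over all 3 pairwise
  # distances computed directly.
  base <- make_cystine_structure(sg_sg = 2.05)          # residues 2, 10
  third <- make_cystine_structure(sg_sg = 2.05)$atoms
  third <- third[third$resno == 2, ]
  third$resno <- 20L
  sg_b <- residue_atoms(base, "A", 10)$SG
  shift <- (sg_b + c(2.2, 0, 0)) - as.numeric(
    third[third$elety == "SG", c("x", "y", "z")])
  third[, c("x", "y", "z")] <- sweep(third[, c("x", "y", "z")], 2, shift, "+")
  st3 <- new_structure("three_cys", rbind(base$atoms, third))

  sg <- st3$atoms[st3$atoms$elety == "SG", ]
  d <- as.matrix(dist(sg[, c("x", "y", "z")]))
  cand <- which(upper.tri(d) & d <= 2.3, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used <- logical(3); oracle <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    oracle[[length(oracle) + 1]] <- sort(sg$resno[c(i, j)])
  }
  det <- detect_native_disulfides(st3)
  expect_equal(nrow(det), length(oracle))
  expect_equal(sort(c(det$resno_a, det$resno_b)), sort(unlist(oracle)))
  expect_equal(sort(c(det$resno_a[1], det$resno_b[1])), c(2, 10))

  # symmetry: residue order on input must not matter
  perm <- st3
  perm$atoms <- perm$atoms[rev(seq_len(nrow(perm$atoms))), ]
  det2 <- detect_native_disulfides(perm)
  expect_equal(det2[order(det2$resno_a), c("resno_a", "resno_b")],
               det[order(det$resno_a), c("resno_a", "resno_b")],
               ignore_attr = TRUE)
  # every residue in a returned pair is a cysteine
  for (r in seq_len(nrow(det))) {
    expect_equal(ssforge:::residue_resid(st3, det$chain_a[r], det$resno_a[r]), "CYS")
    expect_equal(ssforge:::residue_resid(st3, det$chain_b[r], det$resno_b[r]), "CYS")
  }
})

test_that("SSBOND records disagreeing with geometry are logged", {
  st <- make_cystine_structure(sg_sg = 2.05)
  txt <- write_pdb(st)
  ss <- "SSBOND   1 CYS A    2    CYS A   99"
  expect_message(parse_structure(paste(c(ss, txt), collapse = "\n")),
                 "not confirmed")
  expect_silent(parse_structure(paste(
    c("SSBOND   1 CYS A    2    CYS A   10", txt), collapse = "\n")))
})

test_that("candidate tables round-trip through TSV", {
  lib <- shared$library
  cand <- rank_candidates(shared$bundle, lib)
  f <- tempfile(fileext = ".tsv")
  write_candidates(cand, f)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(cand) + 1L)
  back <- read_candidates(f)
  expect_equal(back$p_geom, cand$p_geom, tolerance = 1e-6)
  expect_equal(back$p_rmsd, cand$p_rmsd, tolerance = 1e-6)
  expect_equal(back$delta_s, cand$delta_s, tolerance = 1e-6)

  # empty record list: header only
  empty <- cand[0, , drop = FALSE]
  write_candidates(empty, f)
  expect_equal(length(readLines(f)), 1L)
})
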