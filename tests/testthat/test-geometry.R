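test_that("dihedral reproduces reference configurations and sign convention", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  # +90 under the IUPAC convention (hand evaluation of the cross-product
  # formula: n1 = z, n2 = x, so cos = 0 and the signed sine is +1)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "ssf_degenerate_geometry")
})

test_that("dihedral is rigid-invariant and flips sign under reflection", {
  set.seed(11)
  for (rep in 1:20) {
    pts <- lapply(1:4, function(i) rnorm(3) * 3)
    d0 <- tryCatch(do.call(dihedral, pts), ssf_degenerate_geometry = function(e) NULL)
    if (is.null(d0)) next
    R <- ssforge:::random_rotation(); tr <- rnorm(3)
    moved <- lapply(pts, function(p) as.numeric(R %*% p) + tr)
    expect_equal(do.call(dihedral, moved), d0, tolerance = 1e-9)
    mirrored <- lapply(pts, function(p) p * c(1, 1, -1))
    expect_equal(do.call(dihedral, mirrored), -d0, tolerance = 1e-9)
  }
})

test_that("place_atom round-trips its internal coordinates", {
  set.seed(21)
  for (rep in 1:20) {
    a <- rnorm(3); b <- a + rnorm(3); c <- b + rnorm(3)
    if (ssforge:::vnorm(ssforge:::vcross(b - a, c - b)) < 0.1) next
    bond <- runif(1, 1, 2); ang <- runif(1, 60, 150); tor <- runif(1, -179, 180)
    d <- place_atom(a, b, c, bond, ang, tor)
    expect_equal(ssforge:::vnorm(d - c), bond, tolerance = 1e-9)
    v1 <- b - c; v2 <- d - c
    got_ang <- acos(sum(v1 * v2) / (ssforge:::vnorm(v1) * ssforge:::vnorm(v2))) * 180 / pi
    expect_equal(got_ang, ang, tolerance = 1e-7)
    expect_equal(dihedral(a, b, c, d), tor, tolerance = 1e-7)
  }
})

test_that("plane_dihedral handles parallel, antiparallel and orthogonal planes", {
  a1 <- c(0, 0, 0); a2 <- c(1, 0, 0); a3 <- c(0, 1, 0)
  expect_equal(plane_dihedral(a1, a2, a3, a1, a2, a3), 0)
  # reversed winding makes the normal antiparallel
  expect_equal(plane_dihedral(a1, a2, a3, a1, a3, a2), 180)
  b1 <- c(0, 0, 0); b2 <- c(0, 1, 0); b3 <- c(0, 0, 1)  # x = 0 plane
  expect_equal(plane_dihedral(a1, a2, a3, b1, b2, b3), 90)
  expect_error(plane_dihedral(a1, a2, a3, c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "ssf_degenerate_geometry")
})

test_that("superpose solves exact rigid copies and honours its contract", {
  set.seed(31)
  x <- matrix(rnorm(15), 5)
  s <- superpose(x, x)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)

  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  y <- sweep(x %*% t(R), 2, c(1, 2, 3), "+")
  expect_lt(superpose(x, y)$rmsd, 1e-8)
  expect_equal(det(superpose(x, y)$rotation), 1, tolerance = 1e-9)

  # a mirrored target must still be fit with a proper rotation
  ymir <- x %*% diag(c(1, 1, -1))
  expect_equal(det(superpose(x, ymir)$rotation), 1, tolerance = 1e-9)

  expect_error(superpose(x, x[1:4, ]), class = "ssf_contract_error")
  expect_error(superpose(x[1:2, ], x[1:2, ]), class = "ssf_contract_error")
})

test_that("superpose is symmetric and matches the rotation-grid oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    a <- matrix(rnorm(3 * n, sd = 2), n)
    b <- a + matrix(rnorm(3 * n, sd = 0.4), n)
    expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd, tolerance = 1e-9)
    expect_equal(superpose(a, b)$rmsd, oracle_rmsd(a, b), tolerance = 1e-3)
  }
  # distorted unit square: one corner pushed 1 A out of plane
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sq2 <- sq; sq2[3, 3] <- 1
  expect_equal(superpose(sq, sq2)$rmsd, oracle_rmsd(sq, sq2), tolerance = 1e-3)
})

test_that("superpose agrees with the bio3d reference implementation", {
  set.seed(51)
  a <- matrix(rnorm(24, sd = 2), 8)
  b <- a + matrix(rnorm(24, sd = 0.3), 8)
  ref <- bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a)),
                        fixed.inds = 1:24, mobile.inds = 1:24)
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(superpose(a, b)$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("model_cystine reproduces experimental side chains and rotamer grids", {
  st <- make_cystine_structure()
  pr <- residue_pair(st, "A", 2, "A", 10)
  at_a <- residue_atoms(st, "A", 2); at_b <- residue_atoms(st, "A", 10)
  obs_chi1 <- dihedral(at_a$N, at_a$CA, at_a$CB, at_a$SG)
  mc <- model_cystine(st, pr, rotamer_set = obs_chi1)
  expect_length(mc, 1)
  expect_lt(ssforge:::vnorm(mc[[1]]$coords$SG_a - at_a$SG), 0.1)
  expect_lt(ssforge:::vnorm(mc[[1]]$coords$SG_b - at_b$SG), 0.1)

  expect_length(model_cystine(st, pr), 9)  # 3 x 3 chi1 seeds

  # glycine: virtual CB is constructed, operation succeeds
  h <- make_helix(8)
  h$atoms$resid[h$atoms$chain == "A" & h$atoms$resno == 4] <- "GLY"
  h$atoms <- h$atoms[!(h$atoms$resno == 4 & h$atoms$elety == "CB"), ]
  prh <- residue_pair(h, "A", 4, "A", 8)
  mch <- model_cystine(h, prh)
  expect_length(mch, 9)
  expect_true(all(is.finite(mch[[1]]$coords$CB_a)))

  # missing backbone atom is reported with residue and atom
  h2 <- make_helix(8)
  h2$atoms <- h2$atoms[!(h2$atoms$resno == 3 & h2$atoms$elety == "N"), ]
  expect_error(model_cystine(h2, residue_pair(h2, "A", 3, "A", 7)),
               "missing atom N", class = "ssf_missing_atom")
})

test_that("extract_geometry reads back generator parameters and is rigid-invariant", {
  st <- make_cystine_structure(chi3 = 97, sg_sg = 2.05)
  pr <- residue_pair(st, "A", 2, "A", 10)
  g <- extract_geometry(st, pr, use_modeled = FALSE)
  expect_equal(g$sg_sg, 2.05, tolerance = 0.01)
  expect_equal(g$chi[["chi3"]], 97, tolerance = 0.5)
  # duplicate scalars are consistent with the distance table
  expect_identical(g$ca_ca, g$cross_distances[["d_CA_CA"]])
  expect_identical(g$sg_sg, g$cross_distances[["d_SG_SG"]])
  expect_true(all(g$cross_distances > 0))

  set.seed(61)
  R <- ssforge:::random_rotation()
  st2 <- transform_structure(st, R, c(4, -2, 9))
  g2 <- extract_geometry(st2, pr, use_modeled = FALSE)
  expect_equal(g2$features, g$features, tolerance = 1e-6)
})

test_that("modeled sg_sg respects the rotamer-reach bound", {
  # triangle inequality: sg_sg >= cb_cb - 2 * (Cb-Sg bond)
  h <- make_helix(14)
  set.seed(71)
  for (rep in 1:10) {
    ij <- sort(sample(1:14, 2))
    pr <- residue_pair(h, "A", ij[1], "A", ij[2])
    combos <- model_cystine(h, pr)
    g <- extract_geometry(h, pr, use_modeled = TRUE)
    bound <- g$cb_cb - 2 * 1.81
    for (cb in combos) expect_gte(cb$sg_sg, bound - 1e-9)
  }
  # a pair with CA-CA = 12 A cannot reach a bond: all rotamers leave
  # sg_sg above 5 A (brute-force over the rotamer grid)
  st <- make_two_helix_bundle()
  rt <- structure_residues(st)
  ca <- function(i) residue_atoms(st, rt$chain[i], rt$resno[i])$CA
  found <- FALSE
  for (i in 1:(nrow(rt) - 1)) for (j in (i + 1):nrow(rt)) {
    if (abs(ssforge:::vnorm(ca(j) - ca(i)) - 12) < 0.5) {
      pr <- residue_pair(st, rt$chain[i], rt$resno[i], rt$chain[j], rt$resno[j])
      sgs <- vapply(model_cystine(st, pr), function(x) x$sg_sg, numeric(1))
      expect_gt(min(sgs), 5)
      found <- TRUE
      break
    }
    if (found) break
  }
  expect_true(found)
})
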