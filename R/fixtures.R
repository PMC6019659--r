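## Synthetic structure and ensemble generators. These emulate the inputs
## the predictor consumes in production (a native-disulfide structure
## corpus, target structures, MD-like coordinate ensembles) with known
## ground truth, so every other module can be validated without external
## data. All generators are deterministic under a fixed seed.

## build one ideal residue backbone (N, CA, C, O, CB) at the origin
ideal_residue <- function(psi_for_o = -47) {
  n <- c(0, 0, 0)
  ca <- c(ss_ideal$b_n_ca, 0, 0)
  c_ <- place_atom(c(0, 1, 0), n, ca, ss_ideal$b_ca_c, ss_ideal$a_n_ca_c, -120)
  o <- place_atom(n, ca, c_, ss_ideal$b_c_o, ss_ideal$a_ca_c_o, psi_for_o + 180)
  cb <- virtual_cb(n, ca, c_)
  list(N = n, CA = ca, C = c_, O = o, CB = cb)
}

## improper torsion CB-N-CA-C of an ideal L-residue; imposing the same
## value when rebuilding a backbone outward from CB preserves chirality
l_improper <- function() {
  r <- ideal_residue()
  dihedral(r$CB, r$N, r$CA, r$C)
}

## Build an ideal cystine bridge: full N/CA/C/O/CB/SG coordinates for two
## residues with the given chi angles and S-S bond length. Residue A is
## built at the origin; residue B is grown outward across the bridge.
make_cystine_pair <- function(chi1 = -60, chi2 = -85, chi3 = 97,
                              chi2p = -85, chi1p = -60,
                              sg_sg = ss_ideal$b_sg_sg) {
  a <- ideal_residue()
  a$SG <- place_atom(a$N, a$CA, a$CB, ss_ideal$b_cb_sg, ss_ideal$a_ca_cb_sg, chi1)
  b <- list()
  sgb <- place_atom(a$CA, a$CB, a$SG, sg_sg, ss_ideal$a_cb_sg_sg, chi2)
  cbb <- place_atom(a$CB, a$SG, sgb, ss_ideal$b_cb_sg, ss_ideal$a_cb_sg_sg, chi3)
  cab <- place_atom(a$SG, sgb, cbb, ss_ideal$b_ca_cb, ss_ideal$a_ca_cb_sg, chi2p)
  nb <- place_atom(sgb, cbb, cab, ss_ideal$b_n_ca, ss_ideal$a_n_ca_cb, chi1p)
  cb_ <- place_atom(cbb, nb, cab, ss_ideal$b_ca_c, ss_ideal$a_n_ca_c, l_improper())
  ob <- place_atom(nb, cab, cb_, ss_ideal$b_c_o, ss_ideal$a_ca_c_o, -47 + 180)
  b <- list(N = nb, CA = cab, C = cb_, O = ob, CB = cbb, SG = sgb)
  list(a = a, b = b)
}

res_rows <- function(coords, chain, resno, resid, atoms = names(coords)) {
  do.call(rbind, lapply(atoms, function(nm) {
    v <- coords[[nm]]
    data.frame(chain = chain, resno = resno, insert = "", resid = resid,
               elety = nm, x = v[1], y = v[2], z = v[3], occ = 1,
               stringsAsFactors = FALSE)
  }))
}

#' Generate an ideal poly-alanine alpha-helix
#'
#' Backbone built by internal coordinates with phi = -57, psi = -47,
#' omega = 180 degrees and ideal bond lengths/angles; every residue
#' carries N, CA, C, O and a virtual CB. Optional isotropic Gaussian
#' coordinate noise.
#'
#' @param n_res Number of residues (>= 3).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param noise_sd Per-coordinate Gaussian noise SD in Angstrom.
#' @param chain Chain identifier.
#' @param resno_start First author residue number.
#' @param phi,psi,omega Backbone torsions in degrees.
#' @param id Structure id.
#' @return An `ssf_structure`.
#' @export
make_helix <- function(n_res, seed = 1, noise_sd = 0, chain = "A",
                       resno_start = 1L, phi = -57, psi = -47, omega = 180,
                       id = "ideal_helix") {
  if (n_res < 3) stop_ssf("make_helix: n_res must be >= 3", "ssf_contract_error")
  res <- vector("list", n_res)
  res[[1]] <- ideal_residue(psi_for_o = psi)[c("N", "CA", "C")]
  for (i in 2:n_res) {
    prev <- res[[i - 1]]
    n <- place_atom(prev$N, prev$CA, prev$C, ss_ideal$b_c_n,
                    ss_ideal$a_ca_c_n, psi)
    ca <- place_atom(prev$CA, prev$C, n, ss_ideal$b_n_ca,
                     ss_ideal$a_c_n_ca, omega)
    c_ <- place_atom(prev$C, n, ca, ss_ideal$b_ca_c, ss_ideal$a_n_ca_c, phi)
    res[[i]] <- list(N = n, CA = ca, C = c_)
  }
  for (i in seq_len(n_res)) {
    res[[i]]$O <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                             ss_ideal$b_c_o, ss_ideal$a_ca_c_o, psi + 180)
    res[[i]]$CB <- virtual_cb(res[[i]]$N, res[[i]]$CA, res[[i]]$C)
    res[[i]] <- res[[i]][c("N", "CA", "C", "O", "CB")]
  }
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i)
    res_rows(res[[i]], chain, resno_start + i - 1L, "ALA")))
  if (noise_sd > 0) {
    set.seed(seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      stats::rnorm(3 * nrow(atoms), 0, noise_sd)
  }
  new_structure(id, atoms)
}

#' Generate a structure containing one cystine
#'
#' Two cysteine residues joined by an ideal disulfide bridge with the
#' requested chi angles and Sgamma-Sgamma distance, emitted as a
#' two-residue structure (author numbers `resno`).
#'
#' @param chi1,chi2,chi3,chi2p,chi1p Cystine chi angles in degrees.
#' @param sg_sg S-S distance in Angstrom.
#' @param resno Author residue numbers of the two cysteines.
#' @param chain Chain id.
#' @param id Structure id.
#' @return An `ssf_structure` of two CYS residues.
#' @export
make_cystine_structure <- function(chi1 = -60, chi2 = -85, chi3 = 97,
                                   chi2p = -85, chi1p = -60,
                                   sg_sg = ss_ideal$b_sg_sg,
                                   resno = c(2L, 10L), chain = "A",
                                   id = "cystine") {
  cp <- make_cystine_pair(chi1, chi2, chi3, chi2p, chi1p, sg_sg)
  atoms <- rbind(res_rows(cp$a, chain, resno[1], "CYS"),
                 res_rows(cp$b, chain, resno[2], "CYS"))
  new_structure(id, atoms)
}

#' Generate a corpus of structures with planted native disulfides
#'
#' Each structure contains one cystine whose Sgamma-Sgamma distance is
#' drawn from Normal(2.05, `noise_sd`) and whose chi3 is drawn uniformly
#' from `chi3_modes` (plus optional angular noise). Ground-truth
#' parameters are attached as the `"ground_truth"` attribute for
#' recovery tests.
#'
#' @param n Number of structures (>= 1).
#' @param chi3_modes chi3 mode mixture in degrees; native disulfides
#'   cluster near +97 and -97.
#' @param noise_sd SD of the S-S bond length noise in Angstrom.
#' @param chi_noise_sd SD of angular noise on all five chi angles (deg).
#' @param seed RNG seed.
#' @return List of `ssf_structure`, with attribute `ground_truth`
#'   (data.frame of the sampled chi3 and sg_sg per structure).
#' @export
make_cystine_corpus <- function(n, chi3_modes = c(-97, 97), noise_sd = 0.02,
                                chi_noise_sd = 0, seed = 1) {
  if (n < 1) stop_ssf("make_cystine_corpus: n must be >= 1", "ssf_contract_error")
  set.seed(seed)
  gt <- data.frame(chi3 = numeric(n), sg_sg = numeric(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    chi3 <- chi3_modes[sample.int(length(chi3_modes), 1)]
    noise <- if (chi_noise_sd > 0) stats::rnorm(5, 0, chi_noise_sd) else numeric(5)
    chi3 <- wrap_angle(chi3 + noise[3])
    ss <- stats::rnorm(1, ss_ideal$b_sg_sg, noise_sd)
    gt$chi3[i] <- chi3; gt$sg_sg[i] <- ss
    out[[i]] <- make_cystine_structure(
      chi1 = -60 + noise[1], chi2 = -85 + noise[2], chi3 = chi3,
      chi2p = -85 + noise[4], chi1p = -60 + noise[5], sg_sg = ss,
      id = sprintf("cystine_%03d", i))
  }
  attr(out, "ground_truth") <- gt
  out
}

#' Generate a two-helix bundle with one planted ideal disulfide site
#'
#' Two ideal alpha-helices on one chain, positioned so that exactly one
#' cross-helix residue pair forms an ideal engineered disulfide when
#' virtually mutated to cysteine (chi1 = chi1' = -60, chi3 as given,
#' S-S = 2.05 A). All residues are alanine; the planted pair is recorded
#' in the `"planted"` attribute. Author numbering leaves a gap between
#' the helices, so the two helices are ordinal positions 1..n and
#' n+1..2n of the same chain.
#'
#' @param n_res Residues per helix.
#' @param planted_index Position of the planted residue within each helix.
#' @param chi3 chi3 of the planted bridge (degrees).
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @param noise_sd Per-coordinate Gaussian noise SD in Angstrom.
#' @return An `ssf_structure` with attribute `planted` (a one-row pair
#'   data.frame as from [residue_pair()]).
#' @export
make_two_helix_bundle <- function(n_res = 12, planted_index = c(6, 6),
                                  chi3 = 97, seed = 1, noise_sd = 0) {
  if (n_res < 5) stop_ssf("make_two_helix_bundle: n_res must be >= 5",
                          "ssf_contract_error")
  bridge <- make_cystine_pair(chi3 = chi3)
  helixA <- grow_helix_through(bridge$a, n_res, planted_index[1])
  helixB <- grow_helix_through(bridge$b, n_res, planted_index[2])
  atoms <- rbind(
    do.call(rbind, lapply(seq_len(n_res), function(i)
      res_rows(helixA[[i]], "A", i, "ALA"))),
    do.call(rbind, lapply(seq_len(n_res), function(i)
      res_rows(helixB[[i]], "A", 20L + i, "ALA"))))
  if (noise_sd > 0) {
    set.seed(seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      stats::rnorm(3 * nrow(atoms), 0, noise_sd)
  }
  st <- new_structure("two_helix_bundle", atoms)
  attr(st, "planted") <- residue_pair(st, "A", planted_index[1],
                                      "A", 20L + planted_index[2])
  st
}

## extend an alpha-helix through an already-placed residue backbone,
## growing forward and backward with ideal helical torsions
grow_helix_through <- function(seed_res, n_res, at_index,
                               phi = -57, psi = -47, omega = 180) {
  res <- vector("list", n_res)
  res[[at_index]] <- seed_res[c("N", "CA", "C", "O", "CB")]
  i <- at_index
  while (i < n_res) {           # forward
    prev <- res[[i]]
    n <- place_atom(prev$N, prev$CA, prev$C, ss_ideal$b_c_n,
                    ss_ideal$a_ca_c_n, psi)
    ca <- place_atom(prev$CA, prev$C, n, ss_ideal$b_n_ca,
                     ss_ideal$a_c_n_ca, omega)
    c_ <- place_atom(prev$C, n, ca, ss_ideal$b_ca_c, ss_ideal$a_n_ca_c, phi)
    res[[i + 1]] <- list(N = n, CA = ca, C = c_)
    i <- i + 1
  }
  i <- at_index
  while (i > 1) {               # backward
    nxt <- res[[i]]
    c_ <- place_atom(nxt$C, nxt$CA, nxt$N, ss_ideal$b_c_n,
                     ss_ideal$a_c_n_ca, phi)
    ca <- place_atom(nxt$CA, nxt$N, c_, ss_ideal$b_ca_c,
                     ss_ideal$a_ca_c_n, omega)
    n <- place_atom(nxt$N, c_, ca, ss_ideal$b_n_ca, ss_ideal$a_n_ca_c, psi)
    res[[i - 1]] <- list(N = n, CA = ca, C = c_)
    i <- i - 1
  }
  for (j in seq_len(n_res)) {
    if (is.null(res[[j]]$O)) {
      res[[j]]$O <- place_atom(res[[j]]$N, res[[j]]$CA, res[[j]]$C,
                               ss_ideal$b_c_o, ss_ideal$a_ca_c_o, psi + 180)
    }
    if (is.null(res[[j]]$CB)) {
      res[[j]]$CB <- virtual_cb(res[[j]]$N, res[[j]]$CA, res[[j]]$C)
    }
    res[[j]] <- res[[j]][c("N", "CA", "C", "O", "CB")]
  }
  res
}

#' Generate a Gaussian coordinate ensemble with a known mode spectrum
#'
#' Frames are drawn from a zero-mean Gaussian in the mass-weighted
#' internal-coordinate subspace of a fixed mean structure: displacement
#' components are sampled only along directions orthogonal to the six
#' rigid-body modes, with the requested variances (eigenvalues, in
#' amu A^2). The specified eigenvalues are therefore the ground-truth
#' quasi-harmonic spectrum of the ensemble, so the closed-form entropy is
#' available as an oracle for [quasiharmonic_entropy()].
#'
#' @param n_atoms Number of atoms.
#' @param n_frames Number of frames (>= 2).
#' @param eigenvalues Mode variances in amu A^2; length at most
#'   `3 * n_atoms - 6`, all positive. Recycled to that length if scalar.
#' @param seed RNG seed.
#' @param temperature Kelvin.
#' @param masses Atomic masses in amu.
#' @return An `ssf_ensemble` (see [new_ensemble()]) with attribute
#'   `eigenvalues` (the ground truth).
#' @export
make_gaussian_ensemble <- function(n_atoms, n_frames, eigenvalues,
                                   seed = 1, temperature = 300,
                                   masses = rep(1, n_atoms)) {
  if (n_frames < 2) stop_ssf("need at least 2 frames", "ssf_contract_error")
  nint <- 3L * n_atoms - 6L
  if (length(eigenvalues) == 1L) eigenvalues <- rep(eigenvalues, nint)
  if (any(eigenvalues <= 0)) stop_ssf("eigenvalues must be positive",
                                      "ssf_contract_error")
  if (length(eigenvalues) > nint) {
    stop_ssf(sprintf("at most %d internal modes for %d atoms", nint, n_atoms),
             "ssf_contract_error")
  }
  ## deterministic well-spread mean structure (helical curve)
  t <- seq_len(n_atoms)
  mean_xyz <- cbind(6 * cos(0.7 * t), 6 * sin(0.7 * t), 1.5 * t)
  mean_xyz <- sweep(mean_xyz, 2, colMeans(mean_xyz))
  ## rigid-body modes in mass-weighted coordinates
  sm <- sqrt(rep(masses, each = 3))
  rigid <- matrix(0, 3 * n_atoms, 6)
  for (k in 1:3) rigid[seq(k, 3 * n_atoms, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(apply(mean_xyz, 1, function(r) vcross(axes[, k], r)))
    rigid[, 3 + k] <- as.vector(t(rot))
  }
  rigid <- rigid * sm
  ## orthonormal basis whose first 6 columns span the rigid modes
  Q <- qr.Q(qr(cbind(rigid, diag(3 * n_atoms))))
  V <- Q[, 7:(6 + length(eigenvalues)), drop = FALSE]
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_frames * length(eigenvalues)), n_frames) %*%
    diag(sqrt(eigenvalues), length(eigenvalues))
  disp <- Z %*% t(V)             # mass-weighted displacements
  disp <- sweep(disp, 2, sm, "/")
  frames <- array(0, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    frames[f, , ] <- mean_xyz + matrix(disp[f, ], n_atoms, 3, byrow = TRUE)
  }
  e <- new_ensemble(frames, masses = masses, temperature = temperature)
  attr(e, "eigenvalues") <- eigenvalues
  e
}

#' Generate a linearly separable classifier training set
#'
#' Positive examples cluster near (0.9, 0.9, 0.8) and negatives near
#' (0.1, 0.1, 0.1) in (p_geom, p_rmsd, p_delta_s) space, with isotropic
#' Gaussian spread clipped to `[0, 1]`. The clusters are far apart
#' relative to the spread, so the set is separable by construction.
#'
#' @param n Total number of examples (half per class).
#' @param seed RNG seed.
#' @param sd Cluster spread.
#' @param pos_center,neg_center Cluster centers (length-3).
#' @return List with `features` (n x 3 matrix) and `labels` (factor with
#'   levels positive/negative).
#' @export
make_training_set <- function(n = 100, seed = 42, sd = 0.05,
                              pos_center = c(0.9, 0.9, 0.8),
                              neg_center = c(0.1, 0.1, 0.1)) {
  set.seed(seed)
  n_pos <- n %/% 2; n_neg <- n - n_pos
  pos <- matrix(stats::rnorm(3 * n_pos, rep(pos_center, each = n_pos), sd), n_pos)
  neg <- matrix(stats::rnorm(3 * n_neg, rep(neg_center, each = n_neg), sd), n_neg)
  features <- pmin(pmax(rbind(pos, neg), 0), 1)
  colnames(features) <- c("p_geom", "p_rmsd", "p_delta_s")
  list(features = features,
       labels = factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                       levels = c("positive", "negative")))
}
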