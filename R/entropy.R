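## Quasi-harmonic conformational entropy and fluctuation statistics for
## coordinate ensembles (MD-trajectory-like inputs).

## physical constants (SI)
.kB <- 1.380649e-23        # J/K
.hbar <- 1.054571817e-34   # J s
.NAv <- 6.02214076e23      # 1/mol
.amu <- 1.66053906660e-27  # kg
.cal <- 4.184              # J/cal

#' Construct a coordinate ensemble
#'
#' @param frames `n_frames x n_atoms x 3` array (Angstrom), or a list of
#'   `n_atoms x 3` matrices.
#' @param masses Atomic masses in amu (default unit masses).
#' @param atom_names Optional atom names.
#' @param temperature Kelvin.
#' @return Object of class `ssf_ensemble`.
#' @export
new_ensemble <- function(frames, masses = NULL, atom_names = NULL,
                         temperature = 300) {
  if (is.list(frames)) {
    n_atoms <- nrow(frames[[1]])
    arr <- array(0, c(length(frames), n_atoms, 3))
    for (i in seq_along(frames)) arr[i, , ] <- as.matrix(frames[[i]])
    frames <- arr
  }
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L) {
    stop_ssf("frames must be an n_frames x n_atoms x 3 array",
             "ssf_contract_error")
  }
  n_atoms <- dim(frames)[2]
  masses <- masses %||% rep(1, n_atoms)
  if (length(masses) != n_atoms || any(masses <= 0)) {
    stop_ssf("need one positive mass per atom", "ssf_contract_error")
  }
  structure(list(frames = frames, masses = masses,
                 atom_names = atom_names, temperature = temperature),
            class = "ssf_ensemble")
}

#' @export
print.ssf_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ssf_ensemble: %d frames x %d atoms, T = %g K\n",
              d[1], d[2], x$temperature))
  invisible(x)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Each MODEL becomes one frame; atomic masses are assigned from the
#' element inferred from the atom name (H/C/N/O/S/P).
#'
#' @param path Multi-model PDB file.
#' @param temperature Kelvin.
#' @return An `ssf_ensemble`.
#' @export
read_ensemble <- function(path, temperature = 300) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop_ssf(paste0("PDB parse error: ", conditionMessage(e)),
                             "ssf_parse_error"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- ncol(xyz) / 3
  frames <- array(0, c(nrow(xyz), n_atoms, 3))
  for (i in seq_len(nrow(xyz))) {
    frames[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  mass_table <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)
  elem <- substr(gsub("[0-9]", "", pdb$atom$elety), 1, 1)
  masses <- unname(mass_table[elem])
  masses[is.na(masses)] <- 12.011
  new_ensemble(frames, masses = masses, atom_names = pdb$atom$elety,
               temperature = temperature)
}

## frames as an n_frames x 3N matrix
ensemble_matrix <- function(e) {
  d <- dim(e$frames)
  t(apply(e$frames, 1, function(m) as.vector(t(m))))
}

## iteratively superpose every frame onto the mean structure (Kabsch,
## unweighted), `passes` rounds of mean refinement
superpose_frames <- function(X, passes = 2) {
  n_atoms <- ncol(X) / 3
  to_mat <- function(v) matrix(v, n_atoms, 3, byrow = TRUE)
  ref <- to_mat(colMeans(X))
  for (p in seq_len(passes)) {
    for (i in seq_len(nrow(X))) {
      sp <- superpose(to_mat(X[i, ]), ref)
      X[i, ] <- as.vector(t(sp$fitted))
    }
    ref <- to_mat(colMeans(X))
  }
  X
}

#' Quasi-harmonic conformational entropy of an ensemble
#'
#' Frames are best-fit superposed onto the iteratively refined mean
#' structure (removing rigid-body motion), the mass-weighted covariance
#' matrix of the fluctuations is diagonalized, each retained eigenvalue
#' lambda_i (amu A^2) defines a mode frequency
#' `omega_i = sqrt(kB T / lambda_i)`, and the per-mode entropy is the
#' quantum harmonic oscillator value
#' `s = kB * ( u/(e^u - 1) - ln(1 - e^-u) )` with `u = hbar omega / kB T`,
#' summed over modes and reported per mole in cal/mol/K. Modes with
#' eigenvalue below `variance_floor` (numerical null space, including the
#' residual rigid-body modes) are discarded, and at most 3N - 6 modes are
#' retained. `method = "schlitter"` instead applies Schlitter's
#' upper-bound formula to the same spectrum.
#'
#' @param e An `ssf_ensemble` with at least two frames.
#' @param temperature Kelvin; defaults to the ensemble's.
#' @param variance_floor Minimum eigenvalue retained (amu A^2).
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @param method `"quantum"` (default) or `"schlitter"`.
#' @return Object of class `ssf_entropy`: `total_entropy` (cal/mol/K),
#'   `mode_frequencies` (rad/s, in descending variance order),
#'   `per_mode_entropy` (cal/mol/K), `eigenvalues` (amu A^2) and
#'   `n_modes_used`.
#' @export
quasiharmonic_entropy <- function(e, temperature = NULL,
                                  variance_floor = 1e-8, superpose = TRUE,
                                  method = c("quantum", "schlitter")) {
  method <- match.arg(method)
  temperature <- temperature %||% e$temperature
  d <- dim(e$frames)
  if (d[1] < 2L) stop_ssf("need at least 2 frames", "ssf_contract_error")
  X <- ensemble_matrix(e)
  if (max(abs(sweep(X, 2, X[1, ]))) < 1e-12) {
    stop_ssf("zero fluctuation: all frames identical", "ssf_zero_fluctuation")
  }
  if (superpose) X <- superpose_frames(X)
  D <- sweep(X, 2, colMeans(X))
  W <- sweep(D, 2, sqrt(rep(e$masses, each = 3)), "*")
  C <- crossprod(W) / (nrow(W) - 1)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  keep <- ev[ev > variance_floor]
  nmax <- 3L * d[2] - 6L
  if (length(keep) > nmax) keep <- keep[seq_len(nmax)]
  if (length(keep) == 0L) {
    stop_ssf("zero fluctuation: no mode above the variance floor",
             "ssf_zero_fluctuation")
  }
  lam <- keep * .amu * 1e-20                     # kg m^2
  omega <- sqrt(.kB * temperature / lam)         # rad/s
  s_mode <- qh_mode_entropy(omega, temperature, method)
  structure(list(total_entropy = sum(s_mode),
                 per_mode_entropy = s_mode,
                 mode_frequencies = omega,
                 eigenvalues = keep,
                 n_modes_used = length(keep),
                 temperature = temperature,
                 method = method), class = "ssf_entropy")
}

## per-mode entropy in cal/mol/K for angular frequencies omega (rad/s)
qh_mode_entropy <- function(omega, temperature, method = "quantum") {
  u <- .hbar * omega / (.kB * temperature)
  s <- if (method == "quantum") {
    .kB * (u / expm1(u) - log1p(-exp(-u)))
  } else {
    ## Schlitter upper bound: (kB/2) ln(1 + e^2 / u^2)
    0.5 * .kB * log1p(exp(2) / u^2)
  }
  s * .NAv / .cal
}

#' Closed-form quasi-harmonic entropy for a known mode spectrum
#'
#' The entropy a Gaussian ensemble with the given mass-weighted
#' covariance eigenvalues has in the quasi-harmonic model; the analytic
#' counterpart of [quasiharmonic_entropy()] used as an oracle for
#' ensembles generated by [make_gaussian_ensemble()].
#'
#' @param eigenvalues Mode variances in amu A^2.
#' @param temperature Kelvin.
#' @param method `"quantum"` or `"schlitter"`.
#' @return Entropy in cal/mol/K.
#' @export
analytic_qh_entropy <- function(eigenvalues, temperature = 300,
                                method = "quantum") {
  lam <- eigenvalues * .amu * 1e-20
  omega <- sqrt(.kB * temperature / lam)
  sum(qh_mode_entropy(omega, temperature, method))
}

#' @export
print.ssf_entropy <- function(x, ...) {
  cat(sprintf("Quasi-harmonic entropy (%s): %.2f cal/mol/K over %d modes at %g K\n",
              x$method, x$total_entropy, x$n_modes_used, x$temperature))
  invisible(x)
}

#' Per-atom B-factors from ensemble fluctuations
#'
#' `B = (8 pi^2 / 3) <dr^2>` per atom, after rigid-body superposition.
#'
#' @param e An `ssf_ensemble` with at least two frames.
#' @param superpose Remove rigid-body motion first.
#' @return Numeric vector of B-factors in A^2.
#' @export
fluctuation_bfactors <- function(e, superpose = TRUE) {
  d <- dim(e$frames)
  if (d[1] < 2L) stop_ssf("need at least 2 frames", "ssf_contract_error")
  X <- ensemble_matrix(e)
  if (superpose && max(abs(sweep(X, 2, X[1, ]))) > 1e-12) {
    X <- superpose_frames(X)
  }
  D <- sweep(X, 2, colMeans(X))
  msf <- vapply(seq_len(d[2]), function(a) {
    cols <- (3 * (a - 1) + 1):(3 * a)
    mean(rowSums(D[, cols, drop = FALSE]^2))
  }, numeric(1))
  (8 * pi^2 / 3) * msf
}

#' Inter-atom distance series across an ensemble
#'
#' Euclidean distance between two atoms in every frame, e.g. the
#' N-/C-terminal distance used as a stability indicator.
#'
#' @param e An `ssf_ensemble`.
#' @param atom_i,atom_j Atom indices.
#' @return List with `distances` (per frame), `mean` and `sd`.
#' @export
terminal_distance_series <- function(e, atom_i, atom_j) {
  d <- dim(e$frames)
  if (atom_i < 1 || atom_i > d[2] || atom_j < 1 || atom_j > d[2]) {
    stop_ssf("atom index out of range", "ssf_contract_error")
  }
  dist <- vapply(seq_len(d[1]), function(f)
    sqrt(sum((e$frames[f, atom_i, ] - e$frames[f, atom_j, ])^2)), numeric(1))
  list(distances = dist, mean = mean(dist), sd = stats::sd(dist))
}
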