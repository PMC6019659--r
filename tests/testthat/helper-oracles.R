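# Independent oracles used across tests.

# Brute-force rigid-superposition RMSD: coarse search over Euler angles
# followed by Nelder-Mead refinement. Never uses the Kabsch solution.
euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

oracle_rmsd <- function(moving, fixed) {
  M <- sweep(as.matrix(moving), 2, colMeans(moving))
  F <- sweep(as.matrix(fixed), 2, colMeans(fixed))
  obj <- function(par) {
    R <- euler_rotation(par[1], par[2], par[3])
    sqrt(mean(rowSums((M %*% t(R) - F)^2)))
  }
  grid <- seq(0, 2 * pi, by = pi / 9)
  gridb <- seq(0, pi, by = pi / 9)
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a in grid) for (b in gridb) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < bestv) { bestv <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(bestv, opt$value)
}

# Independent closed-form quasi-harmonic entropy (quantum harmonic
# oscillator per mode), written out here rather than calling the
# package's own helper.
oracle_entropy <- function(eigenvalues, temperature) {
  kB <- 1.380649e-23; hbar <- 1.054571817e-34
  NAv <- 6.02214076e23; amu <- 1.66053906660e-27
  lam <- eigenvalues * amu * 1e-20
  omega <- sqrt(kB * temperature / lam)
  u <- hbar * omega / (kB * temperature)
  sum(kB * (u / (exp(u) - 1) - log(1 - exp(-u)))) * NAv / 4.184
}

# shared fixtures: a planted-cystine corpus, its mined library, and the
# two-helix target (built once per test run)
shared <- new.env()
shared$corpus <- ssforge::make_cystine_corpus(50, chi3_modes = c(-97, 97),
                                              noise_sd = 0.02, seed = 7)
shared$library <- ssforge::build_library(shared$corpus)
shared$bundle <- ssforge::make_two_helix_bundle(n_res = 12, chi3 = 97)
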