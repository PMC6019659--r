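## shared internal helpers

stop_ssf <- function(msg, class) {
  stop(structure(class = c(class, "ssf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## three-letter codes of the 20 standard amino acids
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

## atom set over which cross-residue distances are taken
SS_ATOMS <- c("N", "CA", "C", "O", "CB", "SG")

## names of the 44 geometric descriptor features, in canonical order:
## 36 cross-residue distances, 3 inter-plane dihedrals, 5 chi angles
ss_feature_names <- function() {
  d <- as.vector(outer(SS_ATOMS, SS_ATOMS,
                       function(a, b) paste0("d_", a, "_", b)))
  c(d, "plane_C_CA_CB", "plane_CA_CB_N", "plane_C_CA_N",
    "chi1", "chi2", "chi3", "chi2p", "chi1p")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
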