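## Virtual cystine modelling and extraction of the geometric descriptor
## vector (36 cross-residue distances, 3 inter-plane dihedrals, 5 chi
## angles) for a residue pair.

## backbone coordinates (N, CA, C, O, CB-if-present, SG-if-present) of a
## residue, erroring on missing mandatory atoms
residue_frame <- function(structure, chain, resno, insert = "",
                          need_o = TRUE) {
  at <- residue_atoms(structure, chain, resno, insert)
  need <- c("N", "CA", "C", if (need_o) "O")
  for (nm in need) {
    if (is.null(at[[nm]])) {
      stop_ssf(sprintf("missing atom %s in residue %s:%d%s", nm, chain, resno, insert),
               "ssf_missing_atom")
    }
  }
  at
}

#' Model cystine side chains onto a residue pair
#'
#' Virtually mutates both residues of a pair to cysteine: Cbeta is taken
#' from the experimental coordinates when present (glycine gets a virtual
#' Cbeta constructed from N/CA/C by ideal tetrahedral geometry) and Sgamma
#' is placed by ideal internal coordinates (Cbeta-Sgamma 1.81 A,
#' CA-Cbeta-Sgamma 114.0 deg) for every chi1 value in `rotamer_set`, on
#' both residues. All rotamer combinations are returned.
#'
#' @param structure An `ssf_structure`.
#' @param pair A pair row from [residue_pair()].
#' @param rotamer_set chi1 seed angles in degrees; default the three
#'   staggered rotamers -60, +60, 180.
#' @return List with one element per chi1 combination, each a list with
#'   `coords` (named list of atom coordinates for both residues, suffixes
#'   `_a`/`_b`), `chi` (named vector chi1, chi2, chi3, chi2p, chi1p),
#'   `sg_sg` and `chi1_seeds`.
#' @export
model_cystine <- function(structure, pair, rotamer_set = c(-60, 60, 180)) {
  if (length(rotamer_set) == 0L) {
    stop_ssf("rotamer_set must be non-empty", "ssf_contract_error")
  }
  fa <- residue_frame(structure, pair$chain_a, pair$resno_a, pair$insert_a)
  fb <- residue_frame(structure, pair$chain_b, pair$resno_b, pair$insert_b)
  cb_a <- fa$CB %||% virtual_cb(fa$N, fa$CA, fa$C)
  cb_b <- fb$CB %||% virtual_cb(fb$N, fb$CA, fb$C)
  sg_a <- lapply(rotamer_set, function(chi1)
    place_atom(fa$N, fa$CA, cb_a, ss_ideal$b_cb_sg, ss_ideal$a_ca_cb_sg, chi1))
  sg_b <- lapply(rotamer_set, function(chi1)
    place_atom(fb$N, fb$CA, cb_b, ss_ideal$b_cb_sg, ss_ideal$a_ca_cb_sg, chi1))
  combos <- list()
  for (i in seq_along(rotamer_set)) {
    for (j in seq_along(rotamer_set)) {
      sga <- sg_a[[i]]; sgb <- sg_b[[j]]
      chi <- tryCatch(
        c(chi1 = dihedral(fa$N, fa$CA, cb_a, sga),
          chi2 = dihedral(fa$CA, cb_a, sga, sgb),
          chi3 = dihedral(cb_a, sga, sgb, cb_b),
          chi2p = dihedral(fb$CA, cb_b, sgb, sga),
          chi1p = dihedral(fb$N, fb$CA, cb_b, sgb)),
        ssf_degenerate_geometry = function(e)
          c(chi1 = NA_real_, chi2 = NA_real_, chi3 = NA_real_,
            chi2p = NA_real_, chi1p = NA_real_))
      coords <- list(N_a = fa$N, CA_a = fa$CA, C_a = fa$C, O_a = fa$O,
                     CB_a = cb_a, SG_a = sga,
                     N_b = fb$N, CA_b = fb$CA, C_b = fb$C, O_b = fb$O,
                     CB_b = cb_b, SG_b = sgb)
      combos[[length(combos) + 1L]] <- list(
        coords = coords, chi = chi, sg_sg = vnorm(sgb - sga),
        chi1_seeds = c(rotamer_set[i], rotamer_set[j]))
    }
  }
  combos
}

## assemble the full descriptor vector from a coordinate set
geometry_from_coords <- function(coords, chi, pair, chi1_seeds = NULL) {
  dists <- numeric(36)
  names(dists) <- ss_feature_names()[1:36]
  k <- 0L
  for (b in SS_ATOMS) for (a in SS_ATOMS) {
    k <- k + 1L
    dists[k] <- vnorm(coords[[paste0(b, "_b")]] - coords[[paste0(a, "_a")]])
  }
  planes <- c(
    plane_C_CA_CB = plane_dihedral(coords$C_a, coords$CA_a, coords$CB_a,
                                   coords$C_b, coords$CA_b, coords$CB_b),
    plane_CA_CB_N = plane_dihedral(coords$CA_a, coords$CB_a, coords$N_a,
                                   coords$CA_b, coords$CB_b, coords$N_b),
    plane_C_CA_N = plane_dihedral(coords$C_a, coords$CA_a, coords$N_a,
                                  coords$C_b, coords$CA_b, coords$N_b))
  features <- c(dists, planes, chi)
  structure(list(
    features = features,
    cross_distances = dists,
    plane_dihedrals = planes,
    chi = chi,
    ca_ca = dists[["d_CA_CA"]],
    cb_cb = dists[["d_CB_CB"]],
    sg_sg = dists[["d_SG_SG"]],
    coords = coords,
    pair = pair,
    chi1_seeds = chi1_seeds), class = "ssf_geometry")
}

#' @export
print.ssf_geometry <- function(x, ...) {
  cat(sprintf("Disulfide geometry %s:%d%s - %s:%d%s\n",
              x$pair$chain_a, x$pair$resno_a, x$pair$insert_a,
              x$pair$chain_b, x$pair$resno_b, x$pair$insert_b))
  cat(sprintf("  sg_sg %.2f A, cb_cb %.2f A, ca_ca %.2f A, chi3 %.1f deg\n",
              x$sg_sg, x$cb_cb, x$ca_ca, x$chi[["chi3"]]))
  invisible(x)
}

#' Extract the geometric descriptor vector for a residue pair
#'
#' Computes the full descriptor set used by the geometric probability:
#' the 36 cross-residue distances over the atom set
#' \{N, CA, C, O, CB, SG\}, the three inter-plane dihedrals between
#' corresponding C/CA/CB, CA/CB/N and C/CA/N planes, and the five cystine
#' chi angles (chi1, chi2, chi3, chi2', chi1').
#'
#' With `use_modeled = TRUE` (the default, appropriate for candidate
#' pairs of arbitrary residue type) the cysteine side chains are modelled
#' by [model_cystine()] and the rotamer combination whose Sgamma-Sgamma
#' distance is closest to the ideal 2.05 A is kept. With
#' `use_modeled = FALSE` the experimental CB/SG coordinates are required
#' (native disulfide mining).
#'
#' @param structure An `ssf_structure`.
#' @param pair A pair row from [residue_pair()].
#' @param use_modeled Model side chains (`TRUE`) or use experimental
#'   coordinates (`FALSE`).
#' @param rotamer_set chi1 seeds passed to [model_cystine()].
#' @return An `ssf_geometry` object; `$features` is the named 44-vector.
#' @export
extract_geometry <- function(structure, pair, use_modeled = TRUE,
                             rotamer_set = c(-60, 60, 180)) {
  if (use_modeled) {
    combos <- model_cystine(structure, pair, rotamer_set)
    dev <- vapply(combos, function(cb) abs(cb$sg_sg - ss_ideal$b_sg_sg),
                  numeric(1))
    best <- combos[[which.min(dev)]]
    geometry_from_coords(best$coords, best$chi, pair, best$chi1_seeds)
  } else {
    fa <- residue_frame(structure, pair$chain_a, pair$resno_a, pair$insert_a)
    fb <- residue_frame(structure, pair$chain_b, pair$resno_b, pair$insert_b)
    for (nm in c("CB", "SG")) {
      if (is.null(fa[[nm]]))
        stop_ssf(sprintf("missing atom %s in residue %s:%d%s", nm,
                         pair$chain_a, pair$resno_a, pair$insert_a),
                 "ssf_missing_atom")
      if (is.null(fb[[nm]]))
        stop_ssf(sprintf("missing atom %s in residue %s:%d%s", nm,
                         pair$chain_b, pair$resno_b, pair$insert_b),
                 "ssf_missing_atom")
    }
    coords <- list(N_a = fa$N, CA_a = fa$CA, C_a = fa$C, O_a = fa$O,
                   CB_a = fa$CB, SG_a = fa$SG,
                   N_b = fb$N, CA_b = fb$CA, C_b = fb$C, O_b = fb$O,
                   CB_b = fb$CB, SG_b = fb$SG)
    chi <- c(chi1 = dihedral(fa$N, fa$CA, fa$CB, fa$SG),
             chi2 = dihedral(fa$CA, fa$CB, fa$SG, fb$SG),
             chi3 = dihedral(fa$CB, fa$SG, fb$SG, fb$CB),
             chi2p = dihedral(fb$CA, fb$CB, fb$SG, fa$SG),
             chi1p = dihedral(fb$N, fb$CA, fb$CB, fb$SG))
    geometry_from_coords(coords, chi, pair)
  }
}

#' Eight-atom coordinate frame of a disulfide geometry
#'
#' The N/CA/CB/SG frame of both residues, used for template matching and
#' the RMSD probability.
#'
#' @param geometry An `ssf_geometry`.
#' @return 8 x 3 numeric matrix, rows N_a, CA_a, CB_a, SG_a, N_b, CA_b,
#'   CB_b, SG_b.
#' @export
geometry_frame <- function(geometry) {
  cs <- geometry$coords
  m <- rbind(cs$N_a, cs$CA_a, cs$CB_a, cs$SG_a,
             cs$N_b, cs$CA_b, cs$CB_b, cs$SG_b)
  rownames(m) <- c("N_a", "CA_a", "CB_a", "SG_a", "N_b", "CA_b", "CB_b", "SG_b")
  m
}
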