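## Structure input/output: PDB parsing (via bio3d), PDB writing, native
## disulfide detection and the candidate table format.

#' Construct a structure object from an atom table
#'
#' Low-level constructor. Most users will call [parse_structure()] or one
#' of the fixture generators instead.
#'
#' @param id Structure identifier.
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   numbering), `insert` (insertion code, `""` if none), `resid`
#'   (3-letter residue name), `elety` (atom name), `x`, `y`, `z`
#'   (Angstrom) and optionally `occ`.
#' @return Object of class `ssf_structure`.
#' @export
new_structure <- function(id, atoms) {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop_ssf(paste0("atom table must have columns: ",
                    paste(need, collapse = ", ")), "ssf_contract_error")
  }
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop_ssf("non-finite atom coordinates", "ssf_contract_error")
  }
  structure(list(id = id, atoms = atoms), class = "ssf_structure")
}

#' @export
print.ssf_structure <- function(x, ...) {
  rt <- structure_residues(x)
  cat(sprintf("ssf_structure '%s': %d chain(s), %d residues, %d atoms\n",
              x$id, length(unique(rt$chain)), nrow(rt), nrow(x$atoms)))
  invisible(x)
}

#' Residue table of a structure
#'
#' One row per residue in file order, with `ord` the ordinal position of
#' the residue within its chain (used for sequence separations, so that
#' author-numbering gaps do not distort loop lengths).
#'
#' @param structure An `ssf_structure`.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`, `ord`.
#' @export
structure_residues <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  rt <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   insert = a$insert[first], resid = a$resid[first],
                   stringsAsFactors = FALSE)
  rt$ord <- stats::ave(seq_len(nrow(rt)), rt$chain, FUN = seq_along)
  rt
}

## named coordinate lookup for one residue; returns list atom -> 3-vector
residue_atoms <- function(structure, chain, resno, insert = "") {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == resno & a$insert == insert
  if (!any(sel)) {
    stop_ssf(sprintf("residue %s:%d%s not found", chain, resno, insert),
             "ssf_contract_error")
  }
  sub <- a[sel, ]
  out <- lapply(seq_len(nrow(sub)), function(i) as.numeric(sub[i, c("x", "y", "z")]))
  names(out) <- sub$elety
  out[!duplicated(names(out))]
}

residue_resid <- function(structure, chain, resno, insert = "") {
  a <- structure$atoms
  sel <- a$chain == chain & a$resno == resno & a$insert == insert
  if (!any(sel)) return(NA_character_)
  a$resid[which(sel)[1]]
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records through [bio3d::read.pdb()]. Alternate
#' locations are resolved by keeping the highest-occupancy conformer
#' (ties broken by altloc letter order); only residues with standard
#' amino-acid names are retained. For multi-model files a single model is
#' extracted (`model = 1` by default); use [read_ensemble()] to treat all
#' models as a conformational ensemble.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @param model Model number to extract from multi-model files.
#' @param id Structure id; defaults to the file name.
#' @return An `ssf_structure`.
#' @export
parse_structure <- function(source, model = 1L, id = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    path <- source
    id <- id %||% sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    id <- id %||% "structure"
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  }
  ## validate coordinate fields so parse failures name the offending line
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (any(is_atom)) {
    for (i in which(is_atom)) {
      xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                           substr(lines[i], 39, 46),
                                           substr(lines[i], 47, 54))))
      if (any(is.na(xyz))) {
        stop_ssf(sprintf("PDB parse error at line %d: unreadable coordinates", i),
                 "ssf_parse_error")
      }
    }
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop_ssf(paste0("PDB parse error: ", conditionMessage(e)),
                                 "ssf_parse_error"))
  at <- pdb$atom
  nm <- max(1L, nrow(pdb$xyz))
  if (model < 1L || model > nm) {
    stop_ssf(sprintf("model %d not present (%d models)", model, nm),
             "ssf_contract_error")
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  at$alt[is.na(at$alt)] <- ""
  at <- at[at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop_ssf("empty structure: no standard protein residues",
             "ssf_empty_structure")
  }
  ## altloc policy: highest occupancy wins, ties by altloc letter order;
  ## file atom order is preserved
  at$o[is.na(at$o)] <- 1
  at$.idx <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  o <- order(key, -at$o, at$alt)
  at <- at[o, ]
  at <- at[!duplicated(key[o]), ]
  at <- at[order(at$.idx), ]
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, occ = at$o,
                      stringsAsFactors = FALSE)
  st <- new_structure(id, atoms)
  ssbond_check(lines, st)
  st
}

## cross-check SSBOND header records against geometric detection; a
## disagreement is logged (message), never fatal.
ssbond_check <- function(lines, st) {
  ss <- lines[substr(lines, 1, 6) == "SSBOND"]
  if (length(ss) == 0L) return(invisible(NULL))
  declared <- lapply(ss, function(l) {
    c(chain_a = substr(l, 16, 16), resno_a = trimws(substr(l, 18, 21)),
      chain_b = substr(l, 30, 30), resno_b = trimws(substr(l, 32, 35)))
  })
  det <- detect_native_disulfides(st)
  det_key <- character(0)
  if (nrow(det) > 0) {
    det_key <- paste(det$chain_a, det$resno_a, det$chain_b, det$resno_b)
  }
  for (d in declared) {
    k1 <- paste(d["chain_a"], d["resno_a"], d["chain_b"], d["resno_b"])
    k2 <- paste(d["chain_b"], d["resno_b"], d["chain_a"], d["resno_a"])
    if (!(k1 %in% det_key) && !(k2 %in% det_key)) {
      message(sprintf(
        "SSBOND record %s:%s-%s:%s not confirmed geometrically",
        d["chain_a"], d["resno_a"], d["chain_b"], d["resno_b"]))
    }
  }
  invisible(NULL)
}

#' Write a structure as PDB text
#'
#' @param structure An `ssf_structure`.
#' @param file Path, or `NULL` to return the lines invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(structure, file = NULL) {
  a <- structure$atoms
  elem <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  lines <- vapply(seq_len(nrow(a)), function(i) {
    name <- a$elety[i]
    name <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name, "", a$resid[i], a$chain[i], a$resno[i], a$insert[i],
            a$x[i], a$y[i], a$z[i], a$occ[i], 0, elem[i])
  }, character(1))
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Canonical residue pair
#'
#' Builds the canonical representation of a residue pair: residues ordered
#' by chain then ordinal position, with the ordinal sequence separation
#' (number of chain positions between the two residues; `NA` for
#' inter-chain pairs).
#'
#' @param structure An `ssf_structure`.
#' @param chain_a,resno_a,chain_b,resno_b Residue identifiers.
#' @param insert_a,insert_b Insertion codes.
#' @return One-row data.frame with columns `chain_a`, `resno_a`, `insert_a`,
#'   `chain_b`, `resno_b`, `insert_b`, `same_chain`, `separation`.
#' @export
residue_pair <- function(structure, chain_a, resno_a, chain_b, resno_b,
                         insert_a = "", insert_b = "") {
  rt <- structure_residues(structure)
  ia <- which(rt$chain == chain_a & rt$resno == resno_a & rt$insert == insert_a)
  ib <- which(rt$chain == chain_b & rt$resno == resno_b & rt$insert == insert_b)
  if (length(ia) != 1L || length(ib) != 1L) {
    stop_ssf("residue_pair: residue not found in structure", "ssf_contract_error")
  }
  if (ia == ib) stop_ssf("residue_pair: identical residues", "ssf_contract_error")
  ## canonical order: lower chain id first, then lower residue number,
  ## regardless of the order residues appear in the file
  key <- function(i) paste(rt$chain[i], sprintf("%08d", rt$resno[i]), rt$insert[i])
  if (key(ia) > key(ib)) { tmp <- ia; ia <- ib; ib <- tmp }
  same <- rt$chain[ia] == rt$chain[ib]
  data.frame(chain_a = rt$chain[ia], resno_a = rt$resno[ia], insert_a = rt$insert[ia],
             chain_b = rt$chain[ib], resno_b = rt$resno[ib], insert_b = rt$insert[ib],
             same_chain = same,
             separation = if (same) abs(rt$ord[ib] - rt$ord[ia]) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Detect native disulfide bonds geometrically
#'
#' Finds CYS-CYS pairs whose Sgamma-Sgamma distance is at most
#' `sg_cutoff`. Each cysteine is assigned to at most one pair; when a
#' cysteine could partner several others the closest pair wins (greedy
#' matching by ascending distance).
#'
#' @param structure An `ssf_structure`.
#' @param sg_cutoff Sgamma-Sgamma distance cutoff in Angstrom. The default
#'   2.3 covers the covalent S-S bond (~2.05 A) plus coordinate error.
#' @return data.frame of pairs (possibly empty) with the columns of
#'   [residue_pair()] plus `sg_dist`.
#' @export
detect_native_disulfides <- function(structure, sg_cutoff = 2.3) {
  if (sg_cutoff <= 0) stop_ssf("sg_cutoff must be positive", "ssf_contract_error")
  a <- structure$atoms
  sel <- a$resid == "CYS" & a$elety == "SG"
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      insert_a = character(0), chain_b = character(0),
                      resno_b = integer(0), insert_b = character(0),
                      same_chain = logical(0), separation = integer(0),
                      sg_dist = numeric(0), stringsAsFactors = FALSE)
  if (sum(sel) < 2L) return(empty)
  sg <- a[sel, ]
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d <= sg_cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    pr <- residue_pair(structure, sg$chain[i], sg$resno[i],
                       sg$chain[j], sg$resno[j], sg$insert[i], sg$insert[j])
    pr$sg_dist <- d[i, j]
    rows[[length(rows) + 1L]] <- pr
  }
  out <- do.call(rbind, rows)
  out[order(out$chain_a, out$resno_a, out$insert_a), , drop = FALSE]
}

#' Write a candidate table
#'
#' Tab-separated table of scored candidate pairs, one row per record in
#' the given order. Scores are printed with six decimals.
#'
#' @param records Candidate data.frame as returned by [rank_candidates()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_candidates <- function(records, file) {
  out <- data.frame(
    chain_a = records$chain_a %||% character(0),
    res_a = if (nrow(records)) paste0(records$resno_a, records$insert_a) else character(0),
    chain_b = records$chain_b %||% character(0),
    res_b = if (nrow(records)) paste0(records$resno_b, records$insert_b) else character(0),
    p_geom = sprintf("%.6f", records$p_geom %||% numeric(0)),
    p_rmsd = sprintf("%.6f", records$p_rmsd %||% numeric(0)),
    delta_s = sprintf("%.6f", records$delta_s %||% numeric(0)),
    svm_label = as.character(records$svm_label %||% character(0)),
    svm_score = sprintf("%.6f", records$svm_margin %||% numeric(0)),
    stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    out <- out[0, , drop = FALSE]
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param file Path to a candidate TSV.
#' @return data.frame with numeric score columns.
#' @export
read_candidates <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    colClasses = c(chain_a = "character", res_a = "character",
                                   chain_b = "character", res_b = "character",
                                   p_geom = "numeric", p_rmsd = "numeric",
                                   delta_s = "numeric", svm_label = "character",
                                   svm_score = "numeric"),
                    stringsAsFactors = FALSE)
}
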