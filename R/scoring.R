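## The three candidate scores -- geometric probability, native-template
## RMSD probability, loop-closure entropy probability -- and the
## enumerate / filter / rank procedure over all residue pairs.

#' Geometric probability of a candidate disulfide
#'
#' Evaluates each of the 44 descriptor features against its mined native
#' density, normalizes by that feature's maximum density (so each factor
#' lies in (0, 1]), and combines the factors by geometric mean. The score
#' is exactly zero if and only if at least one feature falls outside the
#' range observed among native disulfides; within the observed range
#' Laplace smoothing keeps every factor positive, so a zero is a
#' disqualifying geometric violation, never a sampling hole.
#'
#' @param geometry An `ssf_geometry` from [extract_geometry()].
#' @param library An `ssf_library`.
#' @return Probability in `[0, 1]`.
#' @export
p_geom <- function(geometry, library) {
  if (library$n_observations < 1L) {
    stop_ssf("empty library", "ssf_contract_error")
  }
  f <- geometry$features
  factors <- vapply(names(f), function(nm) {
    h <- library$feature_histograms[[nm]]
    if (is.null(h)) stop_ssf(paste0("library lacks feature ", nm),
                             "ssf_contract_error")
    d <- histogram_density(h, f[[nm]])
    if (d <= 0) 0 else d / max(h$density)
  }, numeric(1))
  if (any(factors == 0)) return(0)
  exp(mean(log(factors)))
}

#' Template RMSD probability
#'
#' Superposes the candidate's 8-atom frame onto the geometrically closest
#' native disulfide template and maps the RMSD through a Gaussian kernel:
#' `p = exp(-rmsd^2 / (2 sigma^2))`.
#'
#' @param frame 8 x 3 coordinate matrix from [geometry_frame()].
#' @param library An `ssf_library`.
#' @param sigma Kernel width in Angstrom (default 0.5).
#' @return List with `p_rmsd`, `rmsd` and `template_id`.
#' @export
p_rmsd <- function(frame, library, sigma = 0.5) {
  if (sigma <= 0) stop_ssf("sigma must be positive", "ssf_contract_error")
  nt <- nearest_template(frame, library)
  list(p_rmsd = exp(-nt$rmsd^2 / (2 * sigma^2)), rmsd = nt$rmsd,
       template_id = nt$id)
}

#' Loop-closure conformational entropy score
#'
#' Entropy change of closing a chain segment of n residues with a
#' crosslink, using the loop-closure form
#' `dS = -2.1 - (3/2) R ln(n)` cal/mol/K with R = 1.987 cal/mol/K and
#' `n = ordinal separation + 1`. The probability is the capped magnitude
#' `min(1, |dS| / s_cap)`, set to zero (disqualifying) when the
#' separation is below `min_separation` or the pair is inter-chain
#' (no covalent path to close).
#'
#' @param pair A pair row from [residue_pair()].
#' @param structure An `ssf_structure` (unused beyond the pair's own
#'   separation, kept for interface symmetry with the other scores).
#' @param min_separation Minimum ordinal sequence separation (default 4).
#' @param s_cap Saturation value for the probability map (cal/mol/K).
#' @return List with `delta_s` (cal/mol/K) and `p_delta_s`.
#' @export
p_delta_s <- function(pair, structure = NULL, min_separation = 4, s_cap = 25) {
  if (min_separation < 2) {
    stop_ssf("min_separation must be >= 2", "ssf_contract_error")
  }
  R <- 1.987
  if (!isTRUE(pair$same_chain)) {
    return(list(delta_s = NA_real_, p_delta_s = 0))
  }
  n <- pair$separation + 1
  ds <- -2.1 - 1.5 * R * log(n)
  p <- if (pair$separation < min_separation) 0 else min(1, abs(ds) / s_cap)
  list(delta_s = ds, p_delta_s = p)
}

#' Enumerate, score, filter and rank candidate disulfide pairs
#'
#' Every residue pair of the structure is treated as a potential
#' engineered disulfide: side chains are virtually mutated to cysteine
#' ([model_cystine()]; the rotamer combination with S-S distance closest
#' to 2.05 A is scored), the three probabilities are computed, pairs with
#' `p_geom = 0` or `p_delta_s = 0` are removed, the classifier (when
#' provided) labels the survivors, and the result is sorted by `p_geom`
#' descending (ties: ascending template RMSD, then residue order).
#'
#' @param structure An `ssf_structure`.
#' @param library An `ssf_library`.
#' @param classifier Optional `ssf_classifier` from [train_classifier()].
#' @param min_separation Minimum ordinal sequence separation.
#' @param sigma RMSD kernel width (Angstrom).
#' @param rotamer_set chi1 seeds for virtual mutation.
#' @param inter_chain Also enumerate inter-chain pairs (they are always
#'   removed by the entropy gate unless scored with a custom rule, so the
#'   default is intra-chain only).
#' @param top Optionally keep only the top N records after ranking.
#' @return data.frame of class `ssf_candidates`, one row per surviving
#'   pair, with scores, chi3, sg_sg, classifier label and margin.
#'   Filtering counts are in `attr(x, "counts")`.
#' @export
rank_candidates <- function(structure, library, classifier = NULL,
                            min_separation = 4, sigma = 0.5,
                            rotamer_set = c(-60, 60, 180),
                            inter_chain = FALSE, top = NULL) {
  rt <- structure_residues(structure)
  n <- nrow(rt)
  counts <- c(total = 0L, entropy_filtered = 0L, geom_filtered = 0L,
              missing_atoms = 0L, kept = 0L)
  rows <- list()
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (!inter_chain && rt$chain[i] != rt$chain[j]) next
    counts["total"] <- counts["total"] + 1L
    pair <- residue_pair(structure, rt$chain[i], rt$resno[i],
                         rt$chain[j], rt$resno[j],
                         rt$insert[i], rt$insert[j])
    ds <- p_delta_s(pair, structure, min_separation = min_separation)
    if (ds$p_delta_s == 0) { counts["entropy_filtered"] <- counts["entropy_filtered"] + 1L; next }
    g <- tryCatch(
      extract_geometry(structure, pair, use_modeled = TRUE,
                       rotamer_set = rotamer_set),
      ssf_missing_atom = function(e) NULL)
    if (is.null(g)) { counts["missing_atoms"] <- counts["missing_atoms"] + 1L; next }
    pg <- p_geom(g, library)
    if (pg == 0) { counts["geom_filtered"] <- counts["geom_filtered"] + 1L; next }
    pr <- p_rmsd(geometry_frame(g), library, sigma = sigma)
    rec <- data.frame(pair,
                      p_geom = pg, p_rmsd = pr$p_rmsd, rmsd = pr$rmsd,
                      template_id = pr$template_id,
                      delta_s = ds$delta_s, p_delta_s = ds$p_delta_s,
                      sg_sg = g$sg_sg, chi3 = g$chi[["chi3"]],
                      svm_label = "unscored", svm_margin = NA_real_,
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rec
    counts["kept"] <- counts["kept"] + 1L
  }
  if (length(rows) == 0L) {
    out <- data.frame()
    attr(out, "counts") <- counts
    class(out) <- c("ssf_candidates", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  if (!is.null(classifier)) {
    pred <- predict_classifier(classifier,
                               as.matrix(out[, c("p_geom", "p_rmsd", "p_delta_s")]))
    out$svm_label <- pred$label
    out$svm_margin <- pred$margin
  }
  ord <- order(-out$p_geom, out$rmsd, out$chain_a, out$resno_a, out$insert_a,
               out$chain_b, out$resno_b, out$insert_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  attr(out, "counts") <- counts
  class(out) <- c("ssf_candidates", "data.frame")
  out
}

#' @export
print.ssf_candidates <- function(x, ...) {
  cn <- attr(x, "counts")
  cat(sprintf("ssf_candidates: %d record(s)", nrow(x)))
  if (!is.null(cn)) {
    cat(sprintf(" (of %d pairs: %d entropy-filtered, %d geometry-filtered)",
                cn[["total"]], cn[["entropy_filtered"]],
                cn[["geom_filtered"]] + cn[["missing_atoms"]]))
  }
  cat("\n")
  if (nrow(x) > 0) {
    print.data.frame(utils::head(
      x[, c("chain_a", "resno_a", "chain_b", "resno_b",
            "p_geom", "p_rmsd", "delta_s", "svm_label")], 10), digits = 4)
  }
  invisible(x)
}
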