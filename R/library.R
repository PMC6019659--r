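## Native-disulfide statistics library: per-feature empirical
## distributions, superposable coordinate templates and the local
## environment profile, mined from a structure corpus.

#' Library mining configuration
#'
#' @param dist_bin Distance bin width in Angstrom.
#' @param dist_range Distance binning domain in Angstrom.
#' @param angle_bin Angle bin width in degrees (domain is (-180, 180]).
#' @param sg_cutoff Native-disulfide Sgamma-Sgamma cutoff in Angstrom.
#' @return Named list of configuration values.
#' @export
library_config <- function(dist_bin = 0.25, dist_range = c(0, 15),
                           angle_bin = 10, sg_cutoff = 2.3) {
  list(dist_bin = dist_bin, dist_range = dist_range,
       angle_bin = angle_bin, sg_cutoff = sg_cutoff)
}

## histogram with Laplace-smoothed density restricted to the occupied
## support: bins between the first and last occupied bin get count + 1,
## bins outside get density zero, and the density integrates to one.
## A zero therefore means "outside the range ever observed in natives",
## not "a sampling hole".
smoothed_histogram <- function(values, lo, hi, width) {
  edges <- seq(lo, hi, by = width)
  nb <- length(edges) - 1L
  bin <- pmin(nb, pmax(1L, ceiling((values - lo) / width)))
  bin <- bin[values > lo - 1e-9 & values <= hi + 1e-9]
  counts <- tabulate(bin, nbins = nb)
  occ <- which(counts > 0)
  density <- numeric(nb)
  if (length(occ) > 0) {
    idx <- occ[1]:occ[length(occ)]
    density[idx] <- counts[idx] + 1
    density <- density / (sum(density) * width)
  }
  list(edges = edges, counts = counts, density = density,
       support = if (length(occ) > 0) c(edges[occ[1]], edges[occ[length(occ)] + 1L])
                 else c(NA_real_, NA_real_))
}

## density of a smoothed histogram at a value (0 outside support); values
## sitting exactly on a support edge (up to 1e-9) are treated as inside
histogram_density <- function(h, value) {
  if (is.na(h$support[1])) return(0)
  eps <- 1e-9
  if (value < h$support[1] - eps || value > h$support[2] + eps) return(0)
  lo <- h$edges[1]; width <- h$edges[2] - h$edges[1]
  nb <- length(h$edges) - 1L
  ## nudge edge values strictly inside so the bin index stays in support
  value <- min(max(value, h$support[1] + width * 1e-6),
               h$support[2] - width * 1e-6)
  bin <- min(nb, max(1L, ceiling((value - lo) / width)))
  h$density[bin]
}

## is a feature value inside the angle or distance domain of its histogram
feature_is_angle <- function(name) {
  !startsWith(name, "d_")
}

#' Build a native-disulfide library from a structure corpus
#'
#' Detects native disulfides in every structure, extracts the full
#' geometric descriptor vector of each (from experimental coordinates),
#' and aggregates: per-feature smoothed empirical densities, the 8-atom
#' (N/CA/CB/SG x 2) coordinate templates, and the local-environment
#' profile (secondary-structure class from phi/psi x burial class from
#' the number of neighbouring CA atoms within 10 A).
#'
#' @param corpus List of `ssf_structure`.
#' @param config Configuration from [library_config()].
#' @return Object of class `ssf_library`.
#' @export
build_library <- function(corpus, config = library_config()) {
  if (length(corpus) == 0L) stop_ssf("empty corpus", "ssf_contract_error")
  feats <- list(); templates <- list(); envs <- character(0)
  for (s in corpus) {
    pairs <- detect_native_disulfides(s, config$sg_cutoff)
    if (nrow(pairs) == 0L) next
    for (r in seq_len(nrow(pairs))) {
      pr <- pairs[r, , drop = FALSE]
      g <- tryCatch(extract_geometry(s, pr, use_modeled = FALSE),
                    ssf_missing_atom = function(e) NULL)
      if (is.null(g)) next
      feats[[length(feats) + 1L]] <- g$features
      templates[[length(templates) + 1L]] <- list(
        id = sprintf("%s|%s%d%s-%s%d%s", s$id,
                     pr$chain_a, pr$resno_a, pr$insert_a,
                     pr$chain_b, pr$resno_b, pr$insert_b),
        coords = geometry_frame(g), source = s$id)
      envs <- c(envs,
                env_class(s, pr$chain_a, pr$resno_a, pr$insert_a),
                env_class(s, pr$chain_b, pr$resno_b, pr$insert_b))
    }
  }
  if (length(feats) == 0L) {
    stop_ssf("corpus contains no native disulfides", "ssf_empty_library")
  }
  fm <- do.call(rbind, feats)
  hists <- lapply(colnames(fm), function(f) {
    v <- fm[, f]
    if (feature_is_angle(f)) {
      smoothed_histogram(v, -180, 180, config$angle_bin)
    } else {
      smoothed_histogram(v, config$dist_range[1], config$dist_range[2],
                         config$dist_bin)
    }
  })
  names(hists) <- colnames(fm)
  env_profile <- as.list(table(envs) / length(envs))
  structure(list(schema_version = 1L,
                 config = config,
                 feature_histograms = hists,
                 templates = templates,
                 env_profile = env_profile,
                 n_observations = nrow(fm)),
            class = "ssf_library")
}

#' @export
print.ssf_library <- function(x, ...) {
  cat(sprintf("ssf_library: %d native disulfides, %d templates, %d features\n",
              x$n_observations, length(x$templates),
              length(x$feature_histograms)))
  invisible(x)
}

## local environment class of one residue: phi/psi secondary-structure
## region x CA-burial (neighbour CA count within 10 A; > 10 = buried)
env_class <- function(structure, chain, resno, insert = "") {
  rt <- structure_residues(structure)
  i <- which(rt$chain == chain & rt$resno == resno & rt$insert == insert)
  ss <- "other"
  if (length(i) == 1L && i > 1L && i < nrow(rt) &&
      rt$chain[i - 1] == chain && rt$chain[i + 1] == chain) {
    prev <- residue_atoms(structure, rt$chain[i - 1], rt$resno[i - 1], rt$insert[i - 1])
    self <- residue_atoms(structure, chain, resno, insert)
    nxt <- residue_atoms(structure, rt$chain[i + 1], rt$resno[i + 1], rt$insert[i + 1])
    if (!is.null(prev$C) && !is.null(self$N) && !is.null(self$CA) &&
        !is.null(self$C) && !is.null(nxt$N)) {
      phi <- dihedral(prev$C, self$N, self$CA, self$C)
      psi <- dihedral(self$N, self$CA, self$C, nxt$N)
      if (phi > -120 && phi < -30 && psi > -80 && psi < -5) {
        ss <- "helix"
      } else if (phi > -180 && phi < -45 && (psi > 90 || psi < -150)) {
        ss <- "strand"
      }
    }
  }
  a <- structure$atoms
  ca <- a[a$elety == "CA", ]
  self_ca <- ca[ca$chain == chain & ca$resno == resno & ca$insert == insert, ]
  burial <- "exposed"
  if (nrow(self_ca) == 1L) {
    d <- sqrt((ca$x - self_ca$x)^2 + (ca$y - self_ca$y)^2 + (ca$z - self_ca$z)^2)
    if (sum(d <= 10) - 1L > 10L) burial <- "buried"
  }
  paste(ss, burial, sep = "_")
}

#' Nearest native disulfide template
#'
#' Superposes the query 8-atom frame onto every template (both residue
#' orderings, since a disulfide is symmetric) and returns the template
#' with minimal RMSD. Ties are broken by template order.
#'
#' @param frame 8 x 3 coordinate matrix (N/CA/CB/SG of both residues),
#'   e.g. from [geometry_frame()].
#' @param library An `ssf_library` with at least one template.
#' @return List with `id`, `rmsd` (Angstrom) and `index`.
#' @export
nearest_template <- function(frame, library) {
  if (length(library$templates) == 0L) {
    stop_ssf("library has no templates", "ssf_contract_error")
  }
  swap <- c(5:8, 1:4)
  best <- NULL
  for (k in seq_along(library$templates)) {
    tc <- library$templates[[k]]$coords
    r <- min(superpose(frame, tc)$rmsd, superpose(frame, tc[swap, ])$rmsd)
    if (is.null(best) || r < best$rmsd - 1e-12) {
      best <- list(id = library$templates[[k]]$id, rmsd = r, index = k)
    }
  }
  best
}

#' Save a disulfide library to JSON
#'
#' @param library An `ssf_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_library <- function(library, path) {
  obj <- unclass(library)
  obj$templates <- lapply(obj$templates, function(t)
    list(id = t$id, source = t$source, coords = unname(as.matrix(t$coords))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a disulfide library from JSON
#'
#' @param path Path written by [save_library()].
#' @return An `ssf_library`.
#' @export
load_library <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_ssf(paste0("library parse error: ", conditionMessage(e)),
                             "ssf_parse_error"))
  v <- obj$schema_version
  if (is.null(v)) stop_ssf("library parse error: no schema_version",
                           "ssf_parse_error")
  if (v > 1) stop_ssf(sprintf("library schema version %s is newer than supported (1)", v),
                      "ssf_version_error")
  hists <- lapply(obj$feature_histograms, function(h)
    list(edges = as.numeric(unlist(h$edges)),
         counts = as.numeric(unlist(h$counts)),
         density = as.numeric(unlist(h$density)),
         support = as.numeric(unlist(h$support))))
  templates <- lapply(obj$templates, function(t) {
    m <- do.call(rbind, lapply(t$coords, function(row) as.numeric(unlist(row))))
    rownames(m) <- c("N_a", "CA_a", "CB_a", "SG_a", "N_b", "CA_b", "CB_b", "SG_b")
    list(id = t$id, coords = m, source = t$source)
  })
  cfg <- lapply(obj$config, function(x) as.numeric(unlist(x)))
  structure(list(schema_version = as.integer(v), config = cfg,
                 feature_histograms = hists, templates = templates,
                 env_profile = lapply(obj$env_profile, as.numeric),
                 n_observations = as.integer(obj$n_observations)),
            class = "ssf_library")
}
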