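# a minimal geometry stub: p_geom only consumes $features
geom_stub <- function(features) {
  structure(list(features = features), class = "ssf_geometry")
}

# feature vector sitting in the modal bin of every library histogram
modal_features <- function(lib) {
  vapply(names(lib$feature_histograms), function(nm) {
    h <- lib$feature_histograms[[nm]]
    k <- which.max(h$density)
    (h$edges[k] + h$edges[k + 1]) / 2
  }, numeric(1))
}

test_that("p_geom is 1 on modal geometry and 0 out of native support", {
  lib <- shared$library
  f <- modal_features(lib)
  expect_equal(p_geom(geom_stub(f), lib), 1)

  f2 <- f; f2["d_SG_SG"] <- 14.9   # far outside anything native
  expect_equal(p_geom(geom_stub(f2), lib), 0)

  # moving a single feature to a lower-density bin cannot increase p_geom
  h <- lib$feature_histograms$chi3
  occ <- which(h$counts > 0)
  for (k in occ) {
    f3 <- f; f3["chi3"] <- (h$edges[k] + h$edges[k + 1]) / 2
    expect_lte(p_geom(geom_stub(f3), lib), 1)
    expect_gt(p_geom(geom_stub(f3), lib), 0)
  }
})

test_that("p_geom equals the hand-computed geometric mean of 44 factors", {
  lib <- shared$library
  st <- shared$bundle
  g <- extract_geometry(st, attr(st, "planted"), use_modeled = TRUE)
  got <- p_geom(g, lib)
  # independent re-evaluation: look up each smoothed density directly
  logs <- vapply(names(g$features), function(nm) {
    h <- lib$feature_histograms[[nm]]
    v <- g$features[[nm]]
    w <- h$edges[2] - h$edges[1]
    bin <- min(length(h$density), max(1, ceiling((max(v, h$support[1] + w * 1e-6) -
                                                    h$edges[1]) / w)))
    d <- if (v < h$support[1] - 1e-9 || v > h$support[2] + 1e-9) 0 else h$density[bin]
    log(d / max(h$density))
  }, numeric(1))
  expect_length(logs, 44)
  expect_equal(got, exp(mean(logs)), tolerance = 1e-12)
})

test_that("p_rmsd follows the Gaussian kernel of the template distance", {
  lib <- shared$library
  tq <- lib$templates[[3]]$coords
  res <- p_rmsd(tq, lib)
  expect_equal(res$p_rmsd, 1, tolerance = 1e-9)
  expect_equal(res$rmsd, 0, tolerance = 1e-6)

  q <- tq; q[4, ] <- q[4, ] + c(0.3, 0, 0)
  res2 <- p_rmsd(q, lib, sigma = 0.5)
  expect_equal(res2$p_rmsd, exp(-res2$rmsd^2 / (2 * 0.25)), tolerance = 1e-12)
  # rmsd = sigma gives exp(-1/2)
  res3 <- p_rmsd(q, lib, sigma = res2$rmsd)
  expect_equal(res3$p_rmsd, exp(-0.5), tolerance = 1e-9)
  expect_error(p_rmsd(tq, lib, sigma = 0), class = "ssf_contract_error")
})

test_that("loop-closure entropy follows the ln(n) law and gates short loops", {
  st <- make_helix(40)
  # n = 28: separation 27
  pr <- residue_pair(st, "A", 1, "A", 28)
  expect_equal(pr$separation + 1, 28)
  res <- p_delta_s(pr, st)
  expect_equal(res$delta_s, -2.1 - 1.5 * 1.987 * log(28), tolerance = 1e-9)
  expect_equal(round(res$delta_s, 2), -12.03)
  expect_equal(res$p_delta_s, min(1, abs(res$delta_s) / 25))

  # monotone: longer loop, more negative
  expect_lt(p_delta_s(residue_pair(st, "A", 1, "A", 40), st)$delta_s,
            res$delta_s)

  # short separation is disqualifying, not merely down-weighted
  pr2 <- residue_pair(st, "A", 5, "A", 7)
  expect_equal(p_delta_s(pr2, st, min_separation = 4)$p_delta_s, 0)
  expect_error(p_delta_s(pr, st, min_separation = 1),
               class = "ssf_contract_error")
})

test_that("rank_candidates retrieves the planted pair first (exhaustive oracle)", {
  lib <- shared$library
  st <- shared$bundle
  cand <- rank_candidates(st, lib)
  planted <- attr(st, "planted")
  expect_gt(nrow(cand), 0)
  expect_equal(cand$resno_a[1], planted$resno_a)
  expect_equal(cand$resno_b[1], planted$resno_b)

  # oracle: independent exhaustive scoring of every admissible pair
  rt <- structure_residues(st)
  best <- list(p = -1)
  n_admissible <- 0
  for (i in 1:(nrow(rt) - 1)) for (j in (i + 1):nrow(rt)) {
    pr <- residue_pair(st, rt$chain[i], rt$resno[i], rt$chain[j], rt$resno[j])
    if (p_delta_s(pr, st)$p_delta_s == 0) next
    g <- extract_geometry(st, pr, use_modeled = TRUE)
    pg <- p_geom(g, lib)
    if (pg > 0) n_admissible <- n_admissible + 1
    if (pg > best$p) best <- list(p = pg, i = rt$resno[i], j = rt$resno[j])
  }
  expect_equal(best$i, planted$resno_a)
  expect_equal(best$j, planted$resno_b)
  expect_equal(nrow(cand), n_admissible)
  expect_equal(max(cand$p_geom), best$p, tolerance = 1e-12)
})

test_that("emitted candidates always satisfy the filter and sort contracts", {
  lib <- shared$library
  for (st in list(shared$bundle,
                  make_two_helix_bundle(n_res = 10, chi3 = -97),
                  make_helix(12))) {
    cand <- rank_candidates(st, lib)
    if (nrow(cand) == 0) next
    expect_true(all(cand$p_geom > 0))
    expect_true(all(cand$p_delta_s > 0))
    if (nrow(cand) > 1) {
      expect_true(all(diff(cand$p_geom) <= 1e-12))
    }
  }
  # every pair below the separation gate: empty result
  tri <- make_helix(3)
  expect_equal(nrow(rank_candidates(tri, lib)), 0L)
})

test_that("rank_candidates is invariant under rigid-body transforms", {
  lib <- shared$library
  st <- shared$bundle
  set.seed(101)
  R <- ssforge:::random_rotation()
  st2 <- transform_structure(st, R, c(11, -3, 6))
  c1 <- rank_candidates(st, lib)
  c2 <- rank_candidates(st2, lib)
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(c2$p_geom, c1$p_geom, tolerance = 1e-6)
  expect_equal(c2$p_rmsd, c1$p_rmsd, tolerance = 1e-6)
  expect_equal(c2$resno_a, c1$resno_a)
  expect_equal(c2$resno_b, c1$resno_b)
})

test_that("the native-like site outscores nearly all pairs on p_rmsd", {
  lib <- shared$library
  st <- shared$bundle
  planted <- attr(st, "planted")
  rt <- structure_residues(st)
  pr_all <- c()
  for (i in 1:(nrow(rt) - 1)) for (j in (i + 1):nrow(rt)) {
    pr <- residue_pair(st, rt$chain[i], rt$resno[i], rt$chain[j], rt$resno[j])
    g <- extract_geometry(st, pr, use_modeled = TRUE)
    pr_all <- c(pr_all, p_rmsd(geometry_frame(g), lib)$p_rmsd)
  }
  g0 <- extract_geometry(st, planted, use_modeled = TRUE)
  p0 <- p_rmsd(geometry_frame(g0), lib)$p_rmsd
  expect_gte(mean(p0 >= pr_all), 0.95)
})
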