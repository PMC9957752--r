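test_that("marker_ratio computes the tissue/cell fraction ratio", {
  tissue <- profile_from_counts("L", c(g1 = 1, g2 = 999999))
  cell <- profile_from_counts("C", c(g1 = 100, g2 = 999900))
  expect_equal(marker_ratio("g1", tissue, cell), 1e-6 / 1e-4)

  # identical profiles give ratio 1 for every gene
  expect_equal(marker_ratio("g2", cell, cell), 1)

  expect_error(marker_ratio("absent", tissue, cell), "absent")
  zero <- profile_from_counts("Z", c(g1 = 0, g2 = 5))
  expect_error(marker_ratio("g1", tissue, zero), "invalid marker")

  # zero tissue expression is a valid ratio of 0 (cell type may be absent)
  tz <- profile_from_counts("T0", c(g1 = 0, g2 = 7))
  expect_equal(marker_ratio("g1", tz, cell), 0)
})

test_that("noise-free mixtures are recovered to machine precision", {
  for (k in c(3, 6)) {
    rs <- make_reference_set(k, 1200, 20, seed = 40 + k)
    f <- c(0.6, rep(0.4 / (k - 1), k - 1))
    prof <- to_molecule_counts(
      mix_whole_tissue(rs, f, noise = "none")$library)
    sets <- find_cell_specific_genes(rs$profiles, min_own_fraction = 0,
                                     max_other_relative = 0)
    for (i in seq_len(k)) {
      ct <- rs$cell_types[i]
      est <- estimate_cell_fraction(sets[[ct]], prof, rs$profiles[[ct]])
      expect_lt(abs(est$fraction - f[i]), 1e-10)
      expect_equal(est$n_markers, 20)
    }
  }
})

test_that("estimates are invariant to linear renormalization of inputs", {
  rs <- make_reference_set(3, 800, 20, seed = 5)
  f <- c(0.2, 0.3, 0.5)
  prof <- to_molecule_counts(mix_whole_tissue(rs, f, noise = "none")$library)
  sets <- find_cell_specific_genes(rs$profiles, min_own_fraction = 0,
                                   max_other_relative = 0)
  base <- estimate_cell_fraction(sets$type2, prof, rs$profiles$type2)
  # rescale tissue and cell profile: the library totals cancel
  alt <- estimate_cell_fraction(sets$type2,
                                renormalize(prof, "total"),
                                renormalize(rs$profiles$type2, "median"))
  expect_equal(alt$fraction, base$fraction, tolerance = 1e-12)
})

test_that("increasing a true fraction increases its estimate", {
  rs <- make_reference_set(3, 800, 20, seed = 6)
  sets <- find_cell_specific_genes(rs$profiles, min_own_fraction = 0,
                                   max_other_relative = 0)
  f2 <- c(0.05, 0.15, 0.30)
  prev <- -Inf
  for (f in f2) {
    w <- c(f, (1 - f) * 0.5, (1 - f) * 0.5)
    prof <- to_molecule_counts(
      mix_whole_tissue(rs, w, noise = "none")$library)
    est <- estimate_cell_fraction(sets$type1, prof, rs$profiles$type1)
    expect_gt(est$fraction, prev)
    prev <- est$fraction
  }
})

test_that("averaging, dispersion and clipping behave as documented", {
  # mean of known ratios
  tissue <- profile_from_counts("L", c(a = 1, b = 3, c = 2, d = 994))
  cell <- profile_from_counts("C", c(a = 100, b = 100, c = 100, d = 700))
  ms <- structure(list(cell_type = "x", genes = c("a", "b", "c"),
                       specificity = rep(Inf, 3)), class = "MarkerSet")
  est <- estimate_cell_fraction(ms, tissue, cell)
  r <- c(0.001 / 0.1, 0.003 / 0.1, 0.002 / 0.1)
  expect_equal(est$fraction, mean(r))
  expect_equal(est$dispersion, sd(r))
  med <- estimate_cell_fraction(ms, tissue, cell, average = "median")
  expect_equal(med$fraction, median(r))

  # pure mixture: fraction 1, dispersion 0
  self <- estimate_cell_fraction(ms, cell, cell)
  expect_equal(self$fraction, 1)
  expect_equal(self$dispersion, 0)

  # markers invalid in the cell profile are skipped and reported
  cell2 <- profile_from_counts("C2", c(a = 100, b = 0, c = 100, d = 800))
  est2 <- estimate_cell_fraction(ms, tissue, cell2)
  expect_equal(est2$skipped, "b")
  expect_equal(est2$n_markers, 2)

  # a ratio average above 1 is clipped with a warning, raw ratios kept
  big <- profile_from_counts("B", c(a = 900, b = 50, c = 25, d = 25))
  cellb <- profile_from_counts("CB", c(a = 100, b = 100, c = 100, d = 700))
  msa <- structure(list(cell_type = "x", genes = "a",
                        specificity = Inf), class = "MarkerSet")
  expect_warning(estb <- estimate_cell_fraction(msa, big, cellb), "clipped")
  expect_equal(estb$fraction, 1)
  expect_gt(estb$per_marker_ratios$ratio[1], 1)
})

test_that("NPC summation and hepatocyte-by-subtraction are exact", {
  mk <- function(ct, f) structure(
    list(cell_type = ct, fraction = f, n_markers = 5L, dispersion = 0,
         clipped = FALSE), class = "CellFractionEstimate")
  ests <- Map(mk, c("chol", "sin", "kupffer", "fibro", "stellate"),
              c(0.003, 0.010, 0.016, 0.001, 0.010))
  nh <- estimate_npc_and_hepatocyte(ests)
  expect_equal(nh$npc_fraction, 0.04)
  expect_equal(nh$hepatocyte_fraction, 0.96)

  # degenerate empty list: all of the transcriptome is hepatocyte
  expect_equal(estimate_npc_and_hepatocyte(list())$hepatocyte_fraction, 1)

  expect_error(estimate_npc_and_hepatocyte(c(ests, ests["chol"])),
               "duplicate")
  expect_warning(nh2 <- estimate_npc_and_hepatocyte(list(mk("a", 0.7),
                                                         mk("b", 0.5))),
                 "clipped")
  expect_equal(nh2$hepatocyte_fraction, 0)

  # ground-truth recovery with a held-out hepatocyte-like type
  rs <- make_reference_set(4, 1000, 15, seed = 8)
  f <- c(0.9, 0.04, 0.03, 0.03)           # type1 plays the hepatocyte
  prof <- to_molecule_counts(mix_whole_tissue(rs, f, noise = "none")$library)
  sets <- find_cell_specific_genes(rs$profiles, min_own_fraction = 0,
                                   max_other_relative = 0)
  npc_est <- lapply(rs$cell_types[-1], function(ct)
    estimate_cell_fraction(sets[[ct]], prof, rs$profiles[[ct]]))
  nh3 <- estimate_npc_and_hepatocyte(npc_est)
  expect_lt(abs(nh3$hepatocyte_fraction - 0.9), 1e-10)
})

test_that("apportionment conserves each gene's expression", {
  rs <- make_reference_set(3, 900, 20, seed = 12)
  f <- c(0.8, 0.15, 0.05)
  prof <- to_molecule_counts(mix_whole_tissue(rs, f, noise = "none")$library)
  sets <- find_cell_specific_genes(rs$profiles, min_own_fraction = 0,
                                   max_other_relative = 0)
  ests <- lapply(rs$cell_types, function(ct)
    estimate_cell_fraction(sets[[ct]], prof, rs$profiles[[ct]]))

  # shared genes: contributions match the closed form and sum to 1
  for (g in rs$shared_genes[1:25]) {
    row <- apportion_gene(g, ests, rs$profiles, prof)
    expected <- vapply(seq_along(f), function(i)
      f[i] * rs$profiles[[i]]$fractions[[g]] / prof$fractions[[g]],
      numeric(1))
    expect_equal(unname(row$per_type_contribution), expected,
                 tolerance = 1e-12)
    expect_equal(sum(row$per_type_contribution) + row$residual, 1,
                 tolerance = 1e-12)
    expect_true(all(row$per_type_contribution >= 0))
  }

  # exclusive genes apportion entirely to their own type
  g1 <- rs$marker_truth$type2[1]
  row <- apportion_gene(g1, ests, rs$profiles, prof)
  expect_equal(unname(row$per_type_contribution["type2"]), 1,
               tolerance = 1e-10)
  expect_equal(unname(row$per_type_contribution["type1"]), 0)

  # a type with zero estimated fraction contributes nothing
  ests0 <- ests
  ests0[[3]]$fraction <- 0
  row0 <- apportion_gene(rs$shared_genes[1], ests0, rs$profiles, prof)
  expect_equal(unname(row0$per_type_contribution["type3"]), 0)

  # residual can be credited to hepatocytes when they lack a profile
  npc_only <- ests[2:3]
  rowh <- apportion_gene(rs$shared_genes[1], npc_only, rs$profiles, prof,
                         residual_policy = "assign_hepatocyte")
  expect_equal(sum(rowh$per_type_contribution), 1, tolerance = 1e-12)
  expect_equal(rowh$residual, 0)
  expect_true("hepatocyte" %in% names(rowh$per_type_contribution))

  expect_error(apportion_gene("nope", ests, rs$profiles, prof), "absent")
})

test_that("deconvolve_tissue wraps the full estimator", {
  rs <- make_reference_set(4, 1000, 15, seed = 30)
  f <- c(0.9, 0.05, 0.03, 0.02)
  prof <- to_molecule_counts(mix_whole_tissue(rs, f, noise = "none")$library)
  sets <- find_cell_specific_genes(rs$profiles[-1], min_own_fraction = 0,
                                   max_other_relative = 0)
  res <- deconvolve_tissue(prof, rs$profiles[-1], sets,
                           apportion = rs$shared_genes[1:5])
  expect_equal(res$hepatocyte_fraction, 0.9, tolerance = 1e-10)
  got <- res$fractions$fraction[match(rs$cell_types[-1],
                                      res$fractions$cell_type)]
  expect_equal(got, f[-1], tolerance = 1e-10)
  ap <- res$apportionment
  expect_equal(unname(rowSums(ap[, -1])), rep(1, 5), tolerance = 1e-9)
})
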