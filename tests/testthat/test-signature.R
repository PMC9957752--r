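test_that("de_rank flags planted genes and is null on identical groups", {
  cm <- make_two_condition_matrix(500, 50, 25, 25, 3.0, seed = 11)
  dr <- de_rank(cm, ref_group = "reference")
  up <- dr[dr$gene %in% cm$truth$up_genes, ]
  expect_gte(mean(up$q < 0.05 & up$log2fc >= 1), 0.9)

  # identical groups: every log2fc is exactly 0
  dmat <- cbind(cm$expr[, 1:4], cm$expr[, 1:4])
  colnames(dmat) <- paste0("s", 1:8)
  dup <- cohort_matrix(dmat,
                       data.frame(sample_id = paste0("s", 1:8),
                                  group = rep(c("a", "b"), each = 4)))
  dr0 <- de_rank(dup)
  expect_true(all(dr0$log2fc == 0))
  expect_true(all(dr0$p == 1))

  expect_error(de_rank(cohort_matrix(
    cm$expr[, 1:3, drop = FALSE],
    data.frame(sample_id = colnames(cm$expr)[1:3],
               group = c("a", "a", "b")))), ">= 2 samples")
})

test_that("welch_rows agrees with t.test gene by gene", {
  set.seed(4)
  a <- matrix(rnorm(30 * 6), 30)
  b <- matrix(rnorm(30 * 8, mean = 0.5), 30)
  wt <- hepatodecon:::welch_rows(a, b)
  for (i in c(1, 7, 30)) {
    tt <- t.test(a[i, ], b[i, ])
    expect_equal(wt$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(wt$diff[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
})

test_that("signature derivation applies thresholds, ordering and top_k", {
  cm <- make_two_condition_matrix(500, 50, 25, 25, 3.0, seed = 11)
  dr <- de_rank(cm, ref_group = "reference")
  sig <- derive_signature(dr, min_abs_log2fc = 1, max_q = 0.05)
  recovered <- mean(cm$truth$up_genes %in% sig$genes)
  false_members <- mean(!sig$genes %in% cm$truth$up_genes)
  expect_gte(recovered, 0.9)
  expect_lte(false_members, 0.05)

  # top_k truncation keeps exactly the k smallest q among qualifiers
  sig10 <- derive_signature(dr, 1, 0.05, top_k = 10)
  expect_length(sig10$genes, 10)
  qualifiers <- dr[dr$log2fc >= 1 & dr$q <= 0.05, ]
  brute <- qualifiers[order(qualifiers$q, -qualifiers$log2fc,
                            qualifiers$gene), ]
  expect_identical(sig10$genes, head(brute$gene, 10))

  # nestedness of truncations
  for (k in c(3, 10, 17))
    expect_true(all(derive_signature(dr, 1, 0.05, top_k = k)$genes %in%
                      sig$genes))

  expect_error(derive_signature(dr, 1, max_q = 0), "no gene passes")
})

test_that("sample scoring is a per-gene z-score average", {
  genes <- paste0("sig", 1:20)
  cm <- make_staged_cohort(c(30, 30, 30, 30), genes, stage_effect = 0.5,
                           noise_sd = 0.1, seed = 13)
  sig <- structure(list(genes = genes, direction = "up_in_reference"),
                   class = "SignatureGeneSet")
  sc <- score_samples(cm, sig)
  means <- tapply(sc$score, sc$stage, mean)
  expect_true(all(diff(means) < 0))      # stepwise decline across stages

  # single-gene signature reduces to that gene's z-score
  one <- score_samples(cm, genes[1])
  z <- as.numeric(scale(log2(cm$expr[genes[1], ] + 1)))
  expect_equal(one$score, z, tolerance = 1e-12)

  # invariant to adding non-signature genes to the matrix
  extra <- rbind(cm$expr,
                 matrix(50, 5, ncol(cm$expr),
                        dimnames = list(paste0("x", 1:5),
                                        colnames(cm$expr))))
  cm2 <- cohort_matrix(extra, cm$samples)
  expect_equal(score_samples(cm2, sig)$score, sc$score, tolerance = 1e-12)

  # a sample at the cohort maximum for every signature gene scores highest
  top <- cm$expr
  top[genes, 1] <- apply(cm$expr[genes, ], 1, max) * 1.01
  cm3 <- cohort_matrix(top, cm$samples)
  sc3 <- score_samples(cm3, sig)
  expect_equal(which.max(sc3$score), 1L)

  expect_message(score_samples(cm, c(genes, "missing_gene")), "absent")
  expect_error(score_samples(cm, "missing_gene"), "no signature gene")
})

test_that("stage trend testing is exact on small cohorts and calibrated", {
  # perfectly decreasing scores attain the most negative rho any stage
  # assignment allows (tied stage ranks bound |rho| below 1)
  st <- data.frame(sample_id = paste0("s", 1:8),
                   stage = factor(rep(c("a", "b", "c", "d"), each = 2),
                                  ordered = TRUE),
                   score = 8:1)
  tr <- stage_trend(st)
  expect_equal(tr$rho, cor(8:1, rep(1:4, each = 2), method = "spearman"))
  expect_true(tr$exact)
  all_rhos <- vapply(hepatodecon:::multiset_permutations(rep(1:4, each = 2)),
                     function(p) cor(st$score, p, method = "spearman"),
                     numeric(1))
  expect_equal(tr$rho, min(all_rhos))

  # exhaustive enumeration on the 6-sample toy: compare against a direct
  # scan over all 20 stage-label assignments
  toy <- data.frame(sample_id = paste0("s", 1:6),
                    stage = factor(rep(c("lo", "hi"), each = 3),
                                   ordered = TRUE),
                    score = c(5, 4, 6, 2, 1, 3))
  got <- stage_trend(toy)
  idx <- rep(1:2, each = 3)
  perms <- combn(6, 3)
  rho_obs <- cor(toy$score, idx, method = "spearman")
  rhos <- apply(perms, 2, function(lo) {
    lab <- rep(2L, 6); lab[lo] <- 1L
    cor(toy$score, lab, method = "spearman")
  })
  expect_true(got$exact)
  expect_equal(got$n_perm_used, 20)
  expect_equal(got$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12))

  # constant scores: rho 0, p 1
  cst <- transform(toy, score = 1)
  expect_equal(stage_trend(cst), list(rho = 0, p = 1, n_perm_used = 0L,
                                      exact = TRUE))

  # permuted stage labels are null in nearly all replicate draws
  set.seed(17)
  hits <- 0
  for (i in 1:20) {
    sc <- data.frame(sample_id = sprintf("s%03d", 1:120),
                     stage = factor(sample(rep(c("a", "b", "c", "d"),
                                               each = 30)), ordered = TRUE),
                     score = rnorm(120))
    if (stage_trend(sc, n_perm = 500, seed = i)$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
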