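test_that("point-mass GLCM has the closed-form feature values", {
  P <- matrix(0, 4, 4)
  P[2, 2] <- 1
  f <- features_from_glcm(P)
  expect_equal(unname(f["f01_energy"]), 1)
  expect_equal(unname(f["f02_entropy"]), 0)
  expect_equal(unname(f["f04_contrast"]), 0)
  expect_equal(unname(f["f05_homogeneity"]), 1)
  expect_equal(unname(f["f08_inertia"]), 0)
  expect_equal(unname(f["f11_max_prob"]), 1)
  expect_equal(unname(f["f12_idm"]), 1)
  expect_true(isTRUE(attr(f, "degenerate")))
})

test_that("hand-evaluated 2x2 examples are reproduced", {
  diag2 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  f <- features_from_glcm(diag2)
  expect_equal(unname(f["f01_energy"]), 0.5)
  expect_equal(unname(f["f02_entropy"]), log(2))
  expect_equal(unname(f["f04_contrast"]), 0)
  expect_equal(unname(f["f11_max_prob"]), 0.5)
  expect_equal(unname(f["f07_sum_mean"]), 3)  # 2*0.5 + 4*0.5

  anti <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  g <- features_from_glcm(anti)
  expect_equal(unname(g["f04_contrast"]), 1)
  expect_equal(unname(g["f08_inertia"]), 1)
  expect_equal(unname(g["f05_homogeneity"]), 0.5)
  expect_equal(unname(g["f12_idm"]), 0.5)
  expect_equal(unname(g["f09_cluster_shade"]), 0)
})

test_that("all 12 features match the literal transcription oracle", {
  set.seed(5)
  for (k in 1:50) {
    P <- random_prob_matrix(4)
    f <- features_from_glcm(P)
    expect_lt(max(abs(unname(f) - haralick_brute(P))), 1e-10)
  }
})

test_that("formula identities and extremes hold on random GLCMs", {
  set.seed(6)
  for (k in 1:50) {
    P <- random_prob_matrix(sample(3:6, 1))
    f <- features_from_glcm(P)
    expect_equal(unname(f["f04_contrast"]), unname(f["f08_inertia"]))
    expect_equal(unname(f["f05_homogeneity"]), unname(f["f12_idm"]))
    expect_true(f["f01_energy"] >= 0 && f["f01_energy"] <= 1)
    expect_gte(unname(f["f02_entropy"]), 0)
    expect_gt(unname(f["f11_max_prob"]), 0)
  }
  ng <- 5
  unif <- matrix(1 / ng^2, ng, ng)
  fu <- features_from_glcm(unif)
  expect_equal(unname(fu["f02_entropy"]), log(ng^2))
  expect_equal(unname(fu["f01_energy"]), 1 / ng^2)  # minimal energy
  set.seed(7)
  expect_gte(features_from_glcm(random_prob_matrix(ng))["f01_energy"][[1]],
             1 / ng^2)
  expect_error(features_from_glcm(matrix(0.3, 2, 2)), "probability")
})

test_that("feature matrices have the grouped layout and are deterministic", {
  s <- small_sample("BH", seed = 4, size = 48, bands = 9)
  q <- equalize_to_levels(s$volume, s$truth_mask, Ng = 8)
  sm <- list(a = list(quant = q, mask = s$truth_mask),
             b = list(quant = q, mask = s$truth_mask))
  g3 <- assemble_group(sm, group = "G3", Ng = 8)
  expect_equal(ncol(g3), 156)
  expect_equal(attr(g3, "group"), "G3")
  g5 <- assemble_group(sm, group = "G5", Ng = 8)
  expect_equal(ncol(g5), 624)
  # structurally identical samples give identical rows
  expect_equal(unname(g5[1, ]), unname(g5[2, ]))
  # offset-major, direction, then f1..f12 column order
  expect_equal(colnames(g5)[1], "o1_d3_01_f01_energy")
  expect_equal(colnames(g5)[13], "o1_d3_02_f01_energy")
  expect_equal(colnames(g5)[157], "o2_d3_01_f01_energy")
  # permuting samples permutes rows identically
  g5r <- assemble_group(rev(sm), group = "G5", Ng = 8)
  expect_equal(g5r["a", ], g5["a", ])
})

test_that("per-class feature summary behaves on degenerate classes", {
  s <- small_sample("BH", seed = 4, size = 48, bands = 9)
  q <- equalize_to_levels(s$volume, s$truth_mask, Ng = 8)
  sm <- list(a = list(quant = q, mask = s$truth_mask),
             b = list(quant = q, mask = s$truth_mask),
             c = list(quant = q, mask = s$truth_mask))
  f <- assemble_group(sm, group = "G1", Ng = 8)
  tab <- mean_feature_table(f, c("BH", "BH", "IN"))
  expect_equal(nrow(tab), 12)
  expect_equal(tab$sd_IN, rep(NA_real_, 12))  # single-sample class: no SD
  expect_equal(tab$sd_BH, rep(0, 12))         # identical samples
  expect_equal(tab$mean_IN, tab$mean_BH)      # same underlying sample
})
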