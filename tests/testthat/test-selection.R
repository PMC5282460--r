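test_that("z-score uses the sample-SD convention and drops constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_warning(z <- zscore(x), "zero-variance")
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_false("b" %in% colnames(z))
  expect_equal(attr(z, "dropped"), "b")
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  # idempotence
  z2 <- zscore(z)
  expect_equal(as.vector(z2), as.vector(z), tolerance = 1e-10)
  expect_error(zscore(x[1, , drop = FALSE]), "2 rows")
})

test_that("anova p-values match the stats::oneway.test oracle", {
  set.seed(12)
  labels <- rep(c("BH", "IN", "Ca"), each = 9)
  x <- matrix(rnorm(27 * 20), 27, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  x[, 1] <- x[, 1] + (labels == "Ca") * 2
  sel <- anova_select(x, labels, alpha = 0.01)
  oracle <- apply(x, 2, function(col) {
    stats::oneway.test(col ~ factor(labels), var.equal = TRUE)$p.value
  })
  expect_lt(max(abs(sel$pvalues - oracle)), 1e-10)
  expect_true(all(sel$pvalues[sel$selected] < 0.01))
  expect_error(anova_select(x, rep("BH", 27)), "2 classes")
  expect_error(anova_select(x[1:10, ], c("BH", rep(c("IN", "Ca"), c(4, 5)))),
               ">= 2 samples")
})

test_that("a constant-by-class feature is never selected; a planted one is", {
  set.seed(13)
  labels <- rep(c("BH", "IN", "Ca"), each = 9)
  flat <- rnorm(27, sd = 1e-6) + 5
  planted <- c(rnorm(9, 0), rnorm(9, 3), rnorm(9, 6))
  sel <- anova_select(cbind(flat = flat, planted = planted), labels)
  expect_false("flat" %in% sel$selected)
  expect_true("planted" %in% sel$selected)
})

test_that("pca retains the smallest component set reaching the target", {
  set.seed(14)
  # rank-2 data: two components explain everything
  basis <- matrix(rnorm(20 * 2), 20, 2)
  x <- basis %*% matrix(rnorm(2 * 10), 2, 10)
  p <- pca_reduce(x, variance_target = 0.97)
  expect_equal(p$k, 2)
  expect_gt(p$cumvar[2], 0.999999)

  y <- matrix(rnorm(30 * 8), 30, 8)
  py <- pca_reduce(y, 0.97)
  expect_gte(py$cumvar[py$k], 0.97)
  if (py$k > 1) expect_lt(py$cumvar[py$k - 1], 0.97)
  # reconstruction error bounded by the discarded variance
  recon <- sweep(py$scores %*% t(py$loadings), 2, -py$center)
  tot <- sum(sweep(y, 2, colMeans(y))^2)
  expect_lte(sum((y - recon)^2) / tot, 1 - 0.97 + 1e-10)
  # sign convention: largest |loading| entry positive
  for (c in seq_len(py$k)) {
    v <- py$loadings[, c]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_reduce(y, 1.5), "variance_target")
})

test_that("pca scores are sign-stable under feature permutation", {
  set.seed(15)
  x <- matrix(rnorm(25 * 12), 25, 12, dimnames = list(NULL, letters[1:12]))
  p1 <- pca_reduce(x, 0.9)
  perm <- sample(12)
  p2 <- pca_reduce(x[, perm], 0.9)
  expect_equal(p2$k, p1$k)
  expect_equal(abs(unname(p2$scores)), abs(unname(p1$scores)),
               tolerance = 1e-8)
})

test_that("class-blocked correlations are proper correlation matrices", {
  set.seed(16)
  labels <- rep(c("BH", "IN"), each = 6)
  x <- cbind(a = rnorm(12), b = rnorm(12))
  x <- cbind(x, c = -x[, "a"], k = rep(1, 12))
  fc <- feature_correlation(x, labels)
  expect_named(fc, c("BH", "IN"))
  cc <- fc$BH
  expect_equal(unname(diag(cc)[1:3]), rep(1, 3))
  expect_equal(cc["a", "c"], -1)
  expect_equal(cc[, ], t(cc)[, ])
  expect_true(all(is.na(cc[c("a", "b", "c"), "k"])))
  expect_equal(attr(cc, "undefined"), "k")
})
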