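test_that("direction sets have the documented geometry", {
  d2 <- directions_2d()
  d3 <- directions_3d()
  expect_equal(nrow(d2), 4)
  expect_equal(nrow(d3), 13)
  v <- as.matrix(d3[, c("dx", "dy", "dz")])
  expect_true(all(v %in% -1:1))
  expect_false(any(rowSums(abs(v)) == 0))
  # no two directions are negatives of each other
  keys <- apply(v, 1, paste, collapse = ",")
  anti <- apply(-v, 1, paste, collapse = ",")
  expect_length(intersect(keys, anti), 0)
  # the four in-plane 3D directions coincide with the 2D set
  inplane <- v[v[, "dz"] == 0, c("dx", "dy")]
  d2m <- as.matrix(d2[, c("dx", "dy")])
  expect_setequal(apply(inplane, 1, paste, collapse = ","),
                  apply(d2m, 1, paste, collapse = ","))
})

test_that("2x2 worked example counts both horizontal pairs", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)   # rows (0,0) and (1,1)
  g <- compute_glcm(q, matrix(TRUE, 2, 2), c(1, 0, 0), Ng = 2)
  expect_equal(g$counts, matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(g$prob, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(g$n_pairs, 2)

  const <- matrix(2L, 4, 4)
  gc <- compute_glcm(const, matrix(TRUE, 4, 4), c(0, 1, 0), Ng = 4)
  expect_equal(sum(gc$prob > 0), 1)
  expect_equal(gc$prob[3, 3], 1)
})

test_that("reversing the displacement transposes the GLCM", {
  set.seed(3)
  dirs <- directions_3d()
  for (rep in 1:10) {
    q <- array(sample(0:3, 5 * 6 * 3, TRUE), dim = c(5, 6, 3))
    mask <- random_mask(5, 6)
    for (r in seq_len(nrow(dirs))) {
      disp <- c(dirs$dx[r], dirs$dy[r], dirs$dz[r])
      g1 <- compute_glcm(q, mask, disp, Ng = 4)
      g2 <- compute_glcm(q, mask, -disp, Ng = 4)
      expect_identical(g1$counts, t(g2$counts))
    }
  }
})

test_that("masked counting matches the brute-force oracle", {
  set.seed(17)
  dirs <- directions_3d()
  for (rep in 1:25) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:3, 1))
    q <- array(sample(0:4, prod(d), TRUE), dim = d)
    mask <- random_mask(d[1], d[2])
    for (r in seq_len(nrow(dirs))) {
      for (off in 1:2) {
        disp <- off * c(dirs$dx[r], dirs$dy[r], dirs$dz[r])
        if (any(abs(disp) >= c(d[2], d[1], d[3]))) next
        g <- compute_glcm(q, mask, disp, Ng = 5)
        expect_identical(g$counts, glcm_brute(q, mask, disp, Ng = 5))
        expect_equal(g$n_pairs, sum(g$counts))
        if (g$n_pairs > 0) expect_lt(abs(sum(g$prob) - 1), 1e-12)
      }
    }
  }
})

test_that("empty and invalid displacements are flagged", {
  q <- matrix(0L, 4, 4)
  expect_error(compute_glcm(q, matrix(TRUE, 4, 4), c(0, 0, 0)), "not all zero")
  expect_error(compute_glcm(q, matrix(TRUE, 4, 4), c(9, 0, 0)), "extent")
  g <- compute_glcm(q, matrix(FALSE, 4, 4), c(1, 0, 0), Ng = 2)
  expect_equal(g$n_pairs, 0)
  expect_null(g$prob)
  expect_error(features_from_glcm(g), "empty")
})

test_that("glcm_count reproduces the 2D/3D bookkeeping", {
  expect_equal(glcm_count(10, 2, "2d"), 80L)
  expect_equal(glcm_count(1, 2, "3d"), 26L)
  expect_equal(glcm_count(99, 2, "3d"), 26L)
  expect_equal(glcm_count(1, 4, "2d"), 16L)
  expect_error(glcm_count(0, 1), "positive")
})
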