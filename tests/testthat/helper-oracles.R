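# Independent oracles and shared fixtures, all generated in code.

# Brute-force GLCM: triple loop over every voxel pair, no shared logic with
# the package kernel.
glcm_brute <- function(q, mask, disp, Ng) {
  d <- dim(q)
  out <- matrix(0L, Ng, Ng)
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    x2 <- x + disp[1]; y2 <- y + disp[2]; z2 <- z + disp[3]
    if (x2 >= 1 && x2 <= d[2] && y2 >= 1 && y2 <= d[1] &&
        z2 >= 1 && z2 <= d[3] && mask[y, x] && mask[y2, x2]) {
      i <- q[y, x, z] + 1L
      j <- q[y2, x2, z2] + 1L
      out[i, j] <- out[i, j] + 1L
    }
  }
  out
}

# Literal, unoptimized transcription of the twelve texture statistics.
haralick_brute <- function(P) {
  ng <- nrow(P)
  px <- sapply(1:ng, function(i) sum(P[i, ]))
  py <- sapply(1:ng, function(j) sum(P[, j]))
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  f <- numeric(12)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f[1] <- f[1] + p^2
    if (p > 0) f[2] <- f[2] - p * log(p)
    f[5] <- f[5] + p / (1 + (i - j)^2)
    f[6] <- f[6] + (i - mux)^2 * p + (j - muy)^2 * p
    f[8] <- f[8] + (i - j)^2 * p
    f[9] <- f[9] + (i + j - mux - muy)^3 * p
    f[10] <- f[10] + (i + j - mux - muy)^2 * p
    f[12] <- f[12] + p / (1 + (i - j)^2)
  }
  f[3] <- if (sx == 0 || sy == 0) 0 else
    (sum(outer(1:ng, 1:ng) * P) - mux * muy) / (sx * sy)
  for (n in 0:(ng - 1)) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (abs(i - j) == n) s <- s + P[i, j]
    f[4] <- f[4] + n^2 * s
  }
  for (n in 2:(2 * ng)) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (i + j == n) s <- s + P[i, j]
    f[7] <- f[7] + n * s
  }
  f[11] <- max(P)
  f
}

random_prob_matrix <- function(ng) {
  m <- matrix(stats::rexp(ng * ng), ng, ng)
  m / sum(m)
}

random_mask <- function(ny, nx, p = 0.6) {
  matrix(stats::runif(ny * nx) < p, ny, nx)
}

# Published reference confusion matrices (rows = true BH/IN/Ca) for the
# worked-example metric checks.
reference_confusions <- function() {
  cls <- c("BH", "IN", "Ca")
  mk <- function(v) matrix(v, 3, 3, byrow = TRUE, dimnames = list(cls, cls))
  list(
    DT = mk(c(9, 0, 0,  1, 7, 1,  0, 0, 9)),
    NN = mk(c(8, 1, 0,  5, 4, 0,  0, 0, 9)),
    NB = mk(c(9, 0, 0,  1, 8, 0,  0, 0, 9))
  )
}

# A small, quick phantom for I/O and feature tests.
small_sample <- function(class_label = "IN", seed = 11, size = 64,
                         bands = 4) {
  generate_phantom(phantom_spec(class_label, image_size = size,
                                n_bands = bands, seed = seed))
}
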