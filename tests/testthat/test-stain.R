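test_that("optical density transform matches its defining formula", {
  px <- function(v) array(rep(v, each = 1), dim = c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_od(px(c(255, 255, 255)), i0 = 255)), c(0, 0, 0))
  expect_equal(as.numeric(rgb_to_od(px(rep(25.5, 3)), i0 = 255)), rep(1, 3))
  expect_equal(as.numeric(rgb_to_od(px(c(0, 0, 0)), i0 = 255, epsilon = 1)),
               rep(log10(255), 3), tolerance = 1e-12)
  expect_error(rgb_to_od(px(c(1, 1, 1)), i0 = -1), "i0")
  expect_error(rgb_to_od(px(c(1, 1, 1)), i0 = 255, epsilon = 0), "epsilon")
})

test_that("OD transform is strictly decreasing in intensity", {
  iv <- seq(1, 255, by = 1)
  img <- array(rep(iv, 3), dim = c(length(iv), 1, 3))
  od <- rgb_to_od(img, i0 = 255)
  expect_true(all(diff(od[, 1, 1]) < 0))
})

test_that("stain matrix construction normalises, inverts, and rejects rank deficiency", {
  m <- stain_matrix_default()
  expect_equal(rowSums(m$M^2), c(nuclei = 1, tunel = 1, pigment = 1), tolerance = 1e-9)
  expect_equal(m$inverse %*% m$M, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  # second row is the TUNEL vector as calibrated, up to normalisation
  raw <- c(0.776, 0.501, 0.382)
  expect_equal(as.numeric(m$M["tunel", ]), raw / sqrt(sum(raw^2)), tolerance = 1e-12)

  id <- build_stain_matrix(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(id$M, diag(3), ignore_attr = TRUE)
  expect_equal(id$inverse, diag(3), ignore_attr = TRUE)

  expect_error(build_stain_matrix(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
               "singular|ill-conditioned")
  expect_error(stain_vector(c(0, 0, 0)), "zero")
})

test_that("deconvolution is linear and recovers single-stain pixels", {
  m <- stain_matrix_default()
  od1 <- array(0.7 * m$M["tunel", ], dim = c(1, 1, 3))
  expect_equal(as.numeric(deconvolve(od1, m)), c(0, 0.7, 0), tolerance = 1e-9)
  od2 <- array(0.3 * m$M["nuclei", ] + 0.2 * m$M["pigment", ], dim = c(1, 1, 3))
  expect_equal(as.numeric(deconvolve(od2, m)), c(0.3, 0, 0.2), tolerance = 1e-9)
  expect_error(deconvolve(matrix(1, 2, 3), m), "array")
})

test_that("compose produces blank fields and one-decade attenuation", {
  id <- build_stain_matrix(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  zero <- array(0, dim = c(2, 2, 3))
  expect_true(all(compose(zero, id, i0 = 255) == 255))
  one_red <- array(0, dim = c(1, 1, 3)); one_red[1, 1, 1] <- 1
  out <- compose(one_red, id, i0 = 255)
  expect_equal(as.numeric(out), c(25.5, 255, 255), tolerance = 1e-9)
})

test_that("compose/deconvolve round-trip recovers random concentration fields", {
  m <- stain_matrix_default()
  set.seed(42)
  conc <- array(runif(100 * 3, 0, 2), dim = c(10, 10, 3))
  img <- compose(conc, m, i0 = 255)
  back <- deconvolve(rgb_to_od(img, i0 = 255, epsilon = 1e-9), m)
  expect_lt(max(abs(back - conc)), 1e-6)
})

test_that("quantised round-trip error never exceeds the propagation bound", {
  # Half-count rounding perturbs each channel OD by at most
  # log10((I + 0.5) / (I - 0.5)); unmixing amplifies channel c's
  # perturbation by at most max_j |inv[c, j]|, so the worst-case per-pixel
  # error is the dot product of the two.  The implementation must never do
  # worse than pure quantisation noise allows.
  m <- stain_matrix_default()
  set.seed(5)
  conc <- array(runif(20 * 20 * 3, 0, 1), dim = c(20, 20, 3))
  img8 <- compose(conc, m, i0 = 255, quantize = TRUE)
  back8 <- deconvolve(rgb_to_od(img8, i0 = 255, epsilon = 0.5), m)
  amp <- apply(abs(m$inverse), 1, max)          # per-channel amplification
  dod <- log10((img8 + 0.5) / pmax(img8 - 0.5, 0.5))
  bound <- matrix(dod, ncol = 3) %*% amp
  err <- apply(abs(matrix(back8 - conc, ncol = 3)), 1, max)
  expect_true(all(err <= bound + 1e-9))
})

test_that("unmixing is invariant to positive pre-scaling of a stain vector", {
  m1 <- stain_matrix_default()
  m2 <- build_stain_matrix(c(0.482, 0.719, 0.501),
                           3.7 * c(0.776, 0.501, 0.382),   # same direction
                           c(0.446, 0.616, 0.649))
  set.seed(7)
  od <- array(runif(48, 0, 1.5), dim = c(4, 4, 3))
  expect_equal(deconvolve(od, m1), deconvolve(od, m2), tolerance = 1e-12)
})

test_that("negative concentrations are retained and diagnosed, not clipped", {
  m <- stain_matrix_default()
  od <- array(c(0.9, 0.05, 0.05), dim = c(1, 1, 3))  # far outside the stain cone
  conc <- deconvolve(od, m)
  expect_true(any(conc < 0))
  expect_gt(attr(conc, "negative_fraction"), 0)
  # and composition still reproduces the OD exactly
  flat <- matrix(conc, ncol = 3) %*% m$M
  expect_equal(as.numeric(flat), as.numeric(od), tolerance = 1e-9)
})
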