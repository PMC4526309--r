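test_that("quantization is linear min-max binning", {
  img <- matrix(0:255, 16, 16)
  q <- quantize(img, bits = 5)
  expect_equal(q$levels, matrix(floor((0:255) / 8), 16, 16))
  expect_equal(q$g, 32L)

  # constant region maps to level 0
  qc <- quantize(matrix(7, 4, 4))
  expect_true(all(qc$levels == 0L))

  # invariance under positive affine rescaling
  set.seed(8)
  for (i in 1:20) {
    im <- matrix(rnorm(64), 8, 8)
    mask <- matrix(runif(64) < 0.8, 8, 8)
    if (!any(mask)) next
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    expect_identical(quantize(im, mask)$levels,
                     quantize(a * im + b, mask)$levels)
  }
})

test_that("co-occurrence matrix matches hand enumeration on tiny images", {
  # rows (0,0) and (1,1): 4 symmetrized counts horizontally (2 equal
  # pairs per row), 4 vertically and 2 per diagonal (one ordered pair
  # each), 12 in total
  q <- quantize(matrix(c(0, 1, 0, 1), 2, 2), bits = 1)
  m <- glcm(q)
  expect_equal(m$n_pairs, 12)
  expect_equal(m$p, rbind(c(2, 4), c(4, 2)) / 12)
  expect_equal(sum(m$p), 1, tolerance = 1e-12)
  expect_equal(m$p, t(m$p))

  # constant image: single cell
  mc <- glcm(quantize(matrix(5, 4, 4)))
  expect_equal(mc$p[1, 1], 1)
  expect_equal(sum(mc$p), 1)

  # a mask with no adjacent pixels has no pairs
  lone <- matrix(FALSE, 5, 5); lone[1, 1] <- TRUE; lone[5, 5] <- TRUE
  expect_error(glcm(quantize(matrix(rnorm(25), 5, 5), lone)), "no valid pixel pair")
})

test_that("GLCM and features match brute-force oracles on random images", {
  set.seed(21)
  for (i in 1:60) {
    h <- sample(6:10, 1); w <- sample(6:10, 1)
    ri <- random_masked_image(h, w)
    q <- quantize(ri$img, ri$mask, bits = sample(2:5, 1))
    m <- glcm(q)
    expect_equal(m$p, oracle_glcm(q$levels, q$g), tolerance = 1e-12)
    f <- glcm_features(m)
    expect_equal(unclass(f)[names(f)], oracle_glcm_features(m$p),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("degenerate and checkerboard co-occurrence features are exact", {
  f <- glcm_features(glcm(quantize(matrix(3, 6, 6))))
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["inv_diff_moment"]), 1)
  expect_equal(unname(f["correlation"]), 0)
  expect_true(attr(f, "degenerate"))

  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  q <- quantize(cb, bits = 1)
  m <- glcm(q)
  expect_equal(m$p, oracle_glcm(q$levels, 2), tolerance = 1e-14)
  f2 <- glcm_features(m)
  expect_equal(unclass(f2)[names(f2)], oracle_glcm_features(m$p),
               tolerance = 1e-12, ignore_attr = TRUE)
  # energy = 1 iff entropy = 0
  expect_gt(f2["entropy"], 0)
  expect_lt(f2["energy"], 1)
})

test_that("GLCM features are invariant to transposition and 180-degree rotation", {
  set.seed(5)
  for (i in 1:10) {
    img <- matrix(rnorm(81), 9, 9)
    f0 <- glcm_features(glcm(quantize(img, bits = 3)))
    ft <- glcm_features(glcm(quantize(t(img), bits = 3)))
    fr <- glcm_features(glcm(quantize(img[9:1, 9:1], bits = 3)))
    expect_equal(unclass(f0), unclass(ft), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(f0), unclass(fr), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("run-length matrix matches hand enumeration", {
  # single row 0,0,0,1,1,2 -> three runs
  q <- quantize(matrix(c(0, 0, 0, 1, 1, 2) * 1.0, 1, 6), bits = 2)
  r <- rlm(q, directions = "0")
  expect_equal(r$n_runs, 3)
  expect_equal(r$pixel_basis, 6)
  expect_equal(r$r[4, 1], 1)  # level 3 (value 2 -> top level), length 1
  f <- rlm_features(r)
  expect_equal(unname(f["sre"]), (1 / 9 + 1 / 4 + 1) / 3, tolerance = 1e-12)
  expect_equal(unname(f["lre"]), (9 + 4 + 1) / 3, tolerance = 1e-12)
  expect_equal(unname(f["rp"]), 0.5)

  # constant n x n image, single direction: n runs of length n
  n <- 5
  rc <- rlm(quantize(matrix(1, n, n)), directions = "0")
  expect_equal(rc$n_runs, n)
  fc <- rlm_features(rc)
  expect_equal(unname(fc["lre"]), n^2)
  expect_equal(unname(fc["sre"]), 1 / n^2)
  expect_equal(unname(fc["gln"]), n)
})

test_that("runs partition the in-mask pixels in every direction", {
  set.seed(31)
  for (i in 1:20) {
    ri <- random_masked_image(7, 9)
    q <- quantize(ri$img, ri$mask, bits = 2)
    for (d in c("0", "45", "90", "135")) {
      r <- rlm(q, directions = d)
      expect_equal(r$pixel_basis, sum(ri$mask))
    }
    r4 <- rlm(q)
    expect_equal(r4$pixel_basis, 4 * sum(ri$mask))
  }
})

test_that("RLM and features match brute-force oracles on random images", {
  set.seed(41)
  for (i in 1:60) {
    h <- sample(6:10, 1); w <- sample(6:10, 1)
    ri <- random_masked_image(h, w)
    q <- quantize(ri$img, ri$mask, bits = sample(2:4, 1))
    r <- rlm(q)
    ref <- oracle_rlm(q$levels, q$g)
    expect_equal(r$r[, 1:ncol(ref)], ref, tolerance = 0)
    f <- rlm_features(r)
    expect_equal(unclass(f), oracle_rlm_features(ref), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("texture maps are consistent with windowed features", {
  set.seed(6)
  img <- matrix(rnorm(15 * 15), 15, 15)
  tm <- texture_map(img, "contrast", window = 3)
  expect_true(all(is.na(tm[1, ])))           # border undefined
  # map value at an interior pixel equals the feature of the 3x3 crop,
  # up to the global 0-255 scaling
  raw <- matrix(NA_real_, 15, 15)
  for (r in 2:14) for (c in 2:14)
    raw[r, c] <- glcm_features(glcm(quantize(img[(r - 1):(r + 1),
                                                 (c - 1):(c + 1)])))["contrast"]
  rng <- range(raw, na.rm = TRUE)
  expect_equal(tm[8, 8], (raw[8, 8] - rng[1]) / (rng[2] - rng[1]) * 255,
               tolerance = 1e-10)

  flat <- texture_map(matrix(1, 6, 6), "contrast")
  expect_true(attr(flat, "flat"))
  expect_true(all(flat[2:5, 2:5] == 0))
  expect_error(texture_map(img, "contrast", window = 4), "odd")
  expect_error(texture_map(img, "sre"), "must be one of")
  expect_error(texture_map(matrix(1, 2, 2), "contrast", window = 3), "larger")
})

test_that("homogeneity maps tell smooth from textured regions", {
  set.seed(9)
  img <- matrix(80, 24, 24)
  img[, 13:24] <- 80 + rnorm(24 * 12, 0, 25)   # right half textured
  tm <- texture_map(img, "homogeneity", window = 3)
  expect_gt(mean(tm[2:23, 3:10]), mean(tm[2:23, 15:22]))
})
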