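test_that("a 2x2 patch with one horizontal displacement counts two pairs", {
  # quantized levels: [[0,0],[1,1]] row-wise
  px <- matrix(c(0, 128, 0, 128), 2L, 2L) # rows: (0,0),(128,128)
  cfg <- glcm_config(2L, gray_levels = 2L,
                     displacements = list(list(d1 = c(1, 0))))
  tens <- compute_glcm(px, cfg)
  expect_length(tens, 1L)
  counts <- tens[[1L]]$counts
  expect_equal(counts[1L, 1L], 1L) # (0,0)
  expect_equal(counts[2L, 2L], 1L) # (1,1)
  expect_equal(sum(counts), 2L)
})

test_that("a constant patch puts all mass on the main diagonal", {
  px <- matrix(200, 8L, 8L)
  for (cfg in list(glcm_config(2L), glcm_config(3L))) {
    for (tns in compute_glcm(px, cfg)) {
      nz <- which(tns$counts > 0, arr.ind = TRUE)
      expect_true(all(nz == nz[, 1L])) # g, g, (g)
    }
  }
})

test_that("the canonical displacement sets match the stated enumeration", {
  c2 <- glcm_config(2L)
  expect_length(c2$displacements, 8L)
  d2 <- t(vapply(c2$displacements, function(d) d$d1, numeric(2L)))
  expect_true(all(rowSums(abs(d2)) >= 1 & apply(abs(d2), 1, max) == 1))
  expect_equal(nrow(unique(d2)), 8L)
  c3 <- glcm_config(3L)
  expect_length(c3$displacements, 12L)
  for (d in c3$displacements) {
    expect_true(all(abs(c(d$d1, d$d2)) %in% c(0, 2)))
  }
  # 4 collinear pairs (opposite directions), 8 right-angle pairs
  collinear <- vapply(c3$displacements, function(d)
    all(d$d1 == -d$d2), logical(1L))
  expect_equal(sum(collinear), 4L)
  ortho <- vapply(c3$displacements, function(d)
    sum(d$d1 * d$d2) == 0, logical(1L))
  expect_equal(sum(ortho & !collinear), 8L)
})

test_that("order-2 tensors equal the brute-force enumeration oracle", {
  for (seed in 1:6) {
    px <- random_patch(8, seed)
    cfg <- glcm_config(2L, gray_levels = 8L)
    tens <- compute_glcm(px, cfg)
    for (i in seq_along(tens)) {
      want <- oracle_glcm(px, 8L, cfg$displacements[[i]]$d1)
      expect_identical(tens[[i]]$counts, want)
    }
  }
})

test_that("order-3 tensors equal the brute-force triple enumeration oracle", {
  for (seed in 1:4) {
    px <- random_patch(8, seed + 50)
    cfg <- glcm_config(3L, gray_levels = 4L)
    tens <- compute_glcm(px, cfg)
    for (i in seq_along(tens)) {
      want <- oracle_glcm(px, 4L, cfg$displacements[[i]]$d1,
                          cfg$displacements[[i]]$d2)
      expect_identical(tens[[i]]$counts, want)
    }
  }
})

test_that("patches smaller than the displacement reach are rejected", {
  expect_error(compute_glcm(matrix(0, 2L, 2L), glcm_config(3L)),
               "displacement reach")
})

test_that("Haralick closed form on the two-point diagonal distribution", {
  # p = {(0,0): 1/2, (1,1): 1/2}
  counts <- array(0L, c(2L, 2L)); counts[1L, 1L] <- 5L; counts[2L, 2L] <- 5L
  tens <- structure(list(counts = counts, order = 2L, gray_levels = 2L,
                         displacement = list(d1 = c(1, 0))),
                    class = "glcm_tensor")
  h <- haralick_features(list(tens))
  expect_equal(h[["energy"]], 0.5)
  expect_equal(h[["entropy"]], 1)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["homogeneity"]], 1)
  expect_equal(h[["correlation"]], 1)
})

test_that("constant patches give degenerate Haralick values", {
  h <- haralick_features(compute_glcm(matrix(37, 8L, 8L), glcm_config(2L)))
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["correlation"]], 0) # zero-variance convention
})

test_that("order-2 Haralick equals the straight-sum textbook oracle", {
  for (seed in 1:5) {
    px <- random_patch(8, seed + 80)
    cfg <- glcm_config(2L, gray_levels = 8L)
    tens <- compute_glcm(px, cfg)
    got <- haralick_features(tens)
    want <- rowMeans(vapply(tens, function(t)
      oracle_haralick2(t$counts), numeric(6L)))
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-12)
  }
})

test_that("empty tensors are rejected", {
  tens <- structure(list(counts = array(0L, c(2L, 2L)), order = 2L,
                         gray_levels = 2L, displacement = list(d1 = c(1, 0))),
                    class = "glcm_tensor")
  expect_error(haralick_features(list(tens)), "empty tensor")
})
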