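test_that("median prefilter matches the sorted-window oracle", {
  px <- random_patch(8, seed = 21)
  expect_equal(median_prefilter(px), oracle_median3(px))
  expect_equal(median_prefilter(matrix(9, 6L, 6L)), matrix(9, 6L, 6L))
  imp <- matrix(0, 7L, 7L); imp[4L, 4L] <- 255
  expect_equal(median_prefilter(imp)[4L, 4L], 0)
  expect_error(median_prefilter(px, kernel = 4L), "odd")
})

test_that("autocorrelation index behaves on constants, checkerboards, zeros", {
  expect_equal(autocorrelation_index(matrix(80, 10L, 10L)), 1)
  chk <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2L)
  expect_equal(autocorrelation_index(chk), 1) # diagonal neighbors are equal
  expect_equal(autocorrelation_index(matrix(0, 5L, 5L)), 0)
  px <- random_patch(9, seed = 22)
  a <- px[-9L, -9L]; b <- px[-1L, -1L]
  expect_equal(autocorrelation_index(px), sum(a * b) / sum(a^2))
})

test_that("Hurst estimator recovers the roughness of synthetic surfaces", {
  for (H in c(0.3, 0.5, 0.7)) {
    est <- vapply(1:10, function(s)
      hurst_index(oracle_fbm_surface(64L, H, seed = s * 7L)), numeric(1L))
    expect_lt(abs(mean(est) - H), 0.15)
  }
  # i.i.d. noise is rough: estimate near 0
  noise <- vapply(1:10, function(s) hurst_index(random_patch(32, s)),
                  numeric(1L))
  expect_true(all(noise < 0.3))
  expect_equal(hurst_index(matrix(4, 16L, 16L)), 1)
})

test_that("the Otsu threshold matches the EBImage reference", {
  skip_if_not_installed("EBImage")
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(c(rgamma(300, 2, 1), rgamma(100, 8, 1)), 20L)
    got <- sonotex:::otsu_threshold(v)
    want <- as.numeric(EBImage::otsu(EBImage::Image(v / max(v)),
                                     range = c(0, 1), levels = 256L)) * max(v)
    expect_equal(got, want, tolerance = 0.01 * max(v))
  }
})

test_that("edge statistics: constants, a vertical step, bounds", {
  expect_equal(unname(edge_statistics(matrix(7, 16L, 16L))), c(0, 0, 0))
  step <- cbind(matrix(0, 32L, 16L), matrix(255, 32L, 16L))
  es <- edge_statistics(step)
  expect_gt(es[["edge_frequency"]], 0)
  expect_lt(min(abs(es[["edge_orientation"]] - c(0, pi))), 1e-6)
  es2 <- edge_statistics(random_patch(16, seed = 23))
  expect_gte(es2[["edge_frequency"]], 0)
  expect_lte(es2[["edge_frequency"]], 1)
})

test_that("Laws kernel bank is built from the standard zero-sum vectors", {
  ks <- laws_kernels()
  expect_named(ks, c("L5", "E5", "S5", "W5", "R5"))
  expect_equal(ks$E5, outer(c(1, 4, 6, 4, 1), c(-1, -2, 0, 2, 1)))
  for (nm in c("E5", "S5", "W5", "R5")) expect_equal(sum(ks[[nm]]), 0)
  lf <- laws_features(matrix(123, 12L, 12L))
  for (nm in c("E5", "S5", "W5", "R5")) {
    expect_equal(lf[[paste0("laws_", nm, "_density")]], 0)
    expect_equal(lf[[paste0("laws_", nm, "_frequency")]], 0)
  }
})

test_that("Laws response maps equal the direct convolution oracle", {
  px <- random_patch(8, seed = 24)
  for (k in laws_kernels()) {
    got <- sonotex:::filter2_reflect(px + 0, k)
    expect_equal(got, oracle_filter2(px, k), tolerance = 1e-9)
  }
})

test_that("wavelet entropies: zeros, point mass, equal coefficients", {
  expect_true(all(wavelet_entropies(matrix(0, 8L, 8L)) == 0))
  # one nonzero pixel: the level-1 subbands each have a single nonzero
  # coefficient -> entropy 0
  px <- matrix(0, 8L, 8L); px[3L, 3L] <- 200
  w <- wavelet_entropies(px)
  expect_equal(unname(w[c("wav1_ll", "wav1_lh", "wav1_hl", "wav1_hh")]),
               rep(0, 4L))
  # four equal-magnitude coefficients -> 2 bits
  q <- matrix(0, 8L, 8L)
  q[cbind(c(1L, 1L, 5L, 5L), c(1L, 5L, 1L, 5L))] <- 64
  expect_equal(wavelet_entropies(q)[["wav1_ll"]], 2)
  expect_error(wavelet_entropies(matrix(0, 6L, 6L)), "divisible by 4")
})

test_that("the Haar step is the orthonormal 2x2 transform", {
  px <- random_patch(8, seed = 25) + 0
  hs <- sonotex:::haar_step(px)
  blk <- px[1:2, 3:4]
  expect_equal(hs$ll[1L, 2L], sum(blk) / 2)
  expect_equal(hs$lh[1L, 2L], (blk[1L, 1L] - blk[1L, 2L] +
                                 blk[2L, 1L] - blk[2L, 2L]) / 2)
  # energy preservation
  expect_equal(sum(px^2),
               sum(hs$ll^2) + sum(hs$lh^2) + sum(hs$hl^2) + sum(hs$hh^2))
})

test_that("LBP codes follow the strict sign rule with p=0 on the axis", {
  px <- matrix(0, 5L, 5L)
  px[3L, 3L] <- 5
  # neighbors p = 0..7 counterclockwise from +x: values 6,4,6,4,6,4,6,4
  px[3L, 4L] <- 6  # p=0: right
  px[2L, 3L] <- 6  # p=2: up
  px[3L, 2L] <- 6  # p=4: left
  px[4L, 3L] <- 6  # p=6: down
  px[2L, 4L] <- 4; px[2L, 2L] <- 4; px[4L, 2L] <- 4; px[4L, 4L] <- 4
  # keep diagonal bilinear samples below center: surroundings are 0/4
  cfg <- lbp_config(radius = 1, neighbors = 8L, cell_size = 5L)
  h <- lbp_histogram(px, cfg)
  codes <- which(h > 0) # bins are code+1
  expect_true((85 + 1) %in% codes)
  # all-equal neighborhood gives code 0 (strict inequality)
  flat <- matrix(66, 6L, 6L)
  h0 <- lbp_histogram(flat, lbp_config(cell_size = 6L))
  expect_equal(unname(h0[1L]), 16L) # 4x4 interior pixels, all code 0
  expect_equal(sum(h0[-1L]), 0L)
})

test_that("constant 56x56 patches give 16 cell histograms massed at code 0", {
  h <- lbp_histogram(matrix(10, 56L, 56L), lbp_config(cell_size = 14L))
  expect_length(h, 16L * 256L)
  per_cell <- matrix(h, nrow = 256L)
  expect_true(all(colSums(per_cell) == colSums(per_cell * (row(per_cell) == 1L))))
})

test_that("the 47-feature descriptor is complete, finite and deterministic", {
  px <- random_patch(56, seed = 26)
  v1 <- extract_feature_vector(px)
  v2 <- extract_feature_vector(px)
  expect_length(v1, 47L)
  expect_identical(names(v1), feature_names())
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)
  # degenerate inputs must not produce NaN/Inf anywhere
  for (bad in list(matrix(0, 56L, 56L), matrix(255, 56L, 56L),
                   {m <- matrix(0, 56L, 56L); m[28L, 28L] <- 255; m})) {
    expect_true(all(is.finite(extract_feature_vector(bad))))
  }
})

test_that("feature extraction tabulates labels and patients", {
  pats <- list(us_patch(random_patch(56, 1), "HCC", patient_id = "A"),
               us_patch(random_patch(56, 2), "PAR", patient_id = "B"))
  df <- extract_features(pats)
  expect_equal(dim(df), c(2L, 49L))
  expect_equal(df$label, c("HCC", "PAR"))
  df2 <- extract_features(pats[1L], lbp = TRUE)
  expect_equal(ncol(df2), 47L + 16L * 256L + 2L)
})
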