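square_image <- function(side = 400L, lo = 100, hi = 300) {
  annotated_image(matrix(128L, side, side),
                  list(via_polygon(c(lo, hi, hi, lo), c(lo, lo, hi, hi))),
                  patient_id = "P1")
}

test_that("axis-aligned square yields the 3x3 grid of disjoint HCC windows", {
  ps <- generate_patches(square_image())
  lb <- vapply(ps, function(p) p$label, character(1L))
  expect_equal(sum(lb == "HCC"), 9L)
})

test_that("greedy generation equals the literal raster-scan oracle", {
  img <- annotated_image(matrix(100L, 240L, 240L),
                         list(via_polygon(c(70, 170, 180, 60),
                                          c(60, 70, 170, 180))),
                         patient_id = "P1")
  got <- generate_patches(img)
  inside <- sonotex:::polygon_mask(img$annotations[[1L]]$vertices, 240L, 240L)
  outline <- sonotex:::polygon_outline(img$annotations[[1L]]$vertices, 240L, 240L)
  near <- sonotex:::dilate1(outline)
  want <- oracle_patches(inside, near)
  expect_equal(length(got), length(want))
  for (i in seq_along(got)) {
    expect_equal(unname(got[[i]]$origin), c(want[[i]]$x, want[[i]]$y))
    expect_equal(got[[i]]$label, want[[i]]$label)
  }
})

test_that("patch postconditions hold: interiors, disjointness, overlap bound", {
  img <- square_image()
  ps <- generate_patches(img)
  mask <- sonotex:::polygon_mask(img$annotations[[1L]]$vertices, 400L, 400L)
  orig <- t(vapply(ps, function(p) p$origin, integer(2L)))
  lb <- vapply(ps, function(p) p$label, character(1L))
  for (i in seq_along(ps)) {
    win <- mask[(orig[i, 2L] + 1L):(orig[i, 2L] + 56L),
                (orig[i, 1L] + 1L):(orig[i, 1L] + 56L)]
    if (lb[i] == "HCC") expect_true(all(win)) else expect_false(any(win))
  }
  hcc <- which(lb == "HCC")
  for (i in hcc) for (j in hcc) {
    if (i >= j) next
    ix <- max(0L, min(orig[i, 1L], orig[j, 1L]) + 56L -
                max(orig[i, 1L], orig[j, 1L]))
    iy <- max(0L, min(orig[i, 2L], orig[j, 2L]) + 56L -
                max(orig[i, 2L], orig[j, 2L]))
    inter <- ix * iy
    expect_lt(inter / (2 * 56^2 - inter), 0.001)
  }
})

test_that("polygons smaller than the window give zero HCC patches", {
  img <- annotated_image(matrix(50L, 200L, 200L),
                         list(via_polygon(c(80, 120, 120, 80),
                                          c(80, 80, 120, 120))),
                         patient_id = "P1")
  expect_warning(ps <- generate_patches(img), "0 HCC")
  expect_false(any(vapply(ps, function(p) p$label, character(1L)) == "HCC"))
})

test_that("images without annotations are rejected", {
  expect_error(generate_patches(annotated_image(matrix(0L, 100L, 100L))),
               "no polygon")
})

test_that("augmentation multiplies tenfold, keeps labels/sizes, reproduces", {
  p <- us_patch(random_patch(56, seed = 8), "HCC", c(0L, 0L), "P1")
  aug <- augment(p, seed = 3)
  expect_length(aug, 10L)
  expect_identical(aug[[1L]]$pixels, p$pixels)
  for (a in aug) {
    expect_equal(dim(a$pixels), c(56L, 56L))
    expect_equal(a$label, "HCC")
    expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  }
  aug2 <- augment(p, seed = 3)
  expect_identical(lapply(aug, `[[`, "pixels"), lapply(aug2, `[[`, "pixels"))
  # distinct transforms: the 9 non-identity results differ from the input
  expect_true(all(vapply(aug[-1L], function(a)
    !identical(a$pixels, p$pixels), logical(1L))))
})

test_that("the identity transform reproduces the patch exactly", {
  px <- random_patch(56, seed = 9)
  expect_equal(sonotex:::transform_patch(px, 0, 1, FALSE),
               matrix(as.integer(px), 56, 56))
})

test_that("rotating by 90 degrees twice equals a 180-degree rotation", {
  # sanity of the geometric core on an asymmetric pattern (no interpolation
  # error at multiples of 90)
  px <- random_patch(56, seed = 10)
  r180 <- sonotex:::transform_patch(px, 180, 1, FALSE)
  expect_equal(r180, px[56:1, 56:1], tolerance = 0)
})

test_that("splits partition exactly with the requested proportions", {
  pats <- lapply(1:100, function(i) {
    us_patch(matrix(0L, 8L, 8L), if (i <= 50) "HCC" else "PAR",
             patient_id = sprintf("P%02d", (i - 1L) %/% 10L))
  })
  sp <- split_spec(0.8, 0, 0.2, group_by_patient = FALSE, seed = 1)
  parts <- split_dataset(pats, sp)
  expect_length(parts$train, 80L)
  expect_length(parts$validation, 0L)
  expect_length(parts$test, 20L)
  all_ids <- sort(c(vapply(parts$train, function(p) p$patient_id, ""),
                    vapply(parts$test, function(p) p$patient_id, "")))
  expect_length(all_ids, 100L)
  # determinism
  parts2 <- split_dataset(pats, sp)
  expect_identical(vapply(parts$train, function(p) p$patient_id, ""),
                   vapply(parts2$train, function(p) p$patient_id, ""))
})

test_that("patient grouping keeps every patient in one partition", {
  pats <- lapply(1:100, function(i) {
    us_patch(matrix(0L, 8L, 8L), if (i %% 2) "HCC" else "PAR",
             patient_id = sprintf("P%02d", (i - 1L) %/% 10L))
  })
  parts <- split_dataset(pats, split_spec(0.6, 0.2, 0.2,
                                          group_by_patient = TRUE, seed = 2))
  ids <- lapply(parts, function(ps) unique(vapply(ps, function(p)
    p$patient_id, "")))
  expect_length(intersect(ids$train, ids$test), 0L)
  expect_length(intersect(ids$train, ids$validation), 0L)
  expect_length(intersect(ids$validation, ids$test), 0L)
})

test_that("invalid split fractions are rejected", {
  expect_error(split_spec(0.8, 0.1, 0.2), "sum to 1")
})
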