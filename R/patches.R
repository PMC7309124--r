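#' Image patch
#'
#' A square intensity window cut from an annotated frame, with its class
#' label (`"HCC"` inside the tumor polygon, `"PAR"` in the adjacent
#' parenchyma), the 0-based `(x, y)` of its top-left pixel in the source
#' image, and source provenance.
#'
#' @param pixels Square intensity matrix in `[0, 255]`.
#' @param label `"HCC"` or `"PAR"`.
#' @param origin `(x, y)` of the top-left pixel in the source image.
#' @param patient_id,image_id Source provenance.
#' @return An object of class `us_patch`.
#' @export
us_patch <- function(pixels, label, origin = c(NA_integer_, NA_integer_),
                     patient_id = NA_character_, image_id = NA_character_) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (!label %in% c("HCC", "PAR")) stop("label must be 'HCC' or 'PAR'")
  structure(list(pixels = pixels, label = label,
                 origin = as.integer(origin),
                 patient_id = as.character(patient_id),
                 image_id = as.character(image_id)),
            class = "us_patch")
}

# Rasterized polygon outline: every pixel crossed by an edge, sampled at
# quarter-pixel steps. Returned as a logical matrix (h x w).
polygon_outline <- function(vert, h, w) {
  out <- matrix(FALSE, h, w)
  nv <- nrow(vert)
  for (i in seq_len(nv)) {
    a <- vert[i, ]; b <- vert[if (i == nv) 1L else i + 1L, ]
    len <- max(abs(b - a))
    n <- max(2L, ceiling(len * 4) + 1L)
    t <- seq(0, 1, length.out = n)
    xs <- round(a[1L] + t * (b[1L] - a[1L]))
    ys <- round(a[2L] + t * (b[2L] - a[2L]))
    keep <- xs >= 0 & xs <= w - 1L & ys >= 0 & ys <= h - 1L
    out[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- TRUE
  }
  out
}

# Dilate a logical matrix by one pixel (8-neighborhood).
dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    if (dr == 0L && dc == 0L) next
    rs <- max(1L, 1L + dr):min(h, h + dr)
    rt <- rs - dr
    cs <- max(1L, 1L + dc):min(w, w + dc)
    ct <- cs - dc
    out[rs, cs] <- out[rs, cs] | m[rt, ct]
  }
  out
}

# Summed-area table lookup: number of TRUE cells of `mask` inside the
# window with top-left (x, y) (0-based) and side `ps`, for vectors x, y.
window_sums <- function(sat, x, y, ps) {
  # sat is (h+1) x (w+1) integral image with zero first row/col
  sat[cbind(y + ps + 1L, x + ps + 1L)] - sat[cbind(y + 1L, x + ps + 1L)] -
    sat[cbind(y + ps + 1L, x + 1L)] + sat[cbind(y + 1L, x + 1L)]
}

# Intersection area of an axis-aligned ps x ps window at (x, y) with each
# previously accepted window (vectors ax, ay).
rect_intersections <- function(x, y, ax, ay, ps) {
  ix <- pmin(x + ps, ax + ps) - pmax(x, ax)
  iy <- pmin(y + ps, ay + ps) - pmax(y, ay)
  pmax(ix, 0L) * pmax(iy, 0L)
}

#' Generate HCC and PAR patches from an annotated image
#'
#' Implements the controlled sliding-window procedure: the image is
#' traversed row-major with stride 1 by a `patch_size` window. A window
#' fully inside the tumor polygon becomes an HCC patch if its
#' intersection-over-union with every previously accepted patch is below
#' `overlap_tolerance`. A window fully outside the polygon with at least
#' one corner on the polygon boundary (rasterized outline, 1-pixel
#' tolerance) becomes a PAR patch if its intersection with every accepted
#' patch is below `overlap_tolerance` of its own area. Acceptance is greedy
#' in scan order, so the output is deterministic.
#'
#' @param image An [annotated_image()] with at least one polygon.
#' @param patch_size Window side in pixels (clinical choice: 56).
#' @param overlap_tolerance Maximum allowed overlap fraction (0.001 = 0.1%).
#' @return List of [us_patch()]; empty HCC set (with a warning) when no
#'   window fits inside the polygon.
#' @export
generate_patches <- function(image, patch_size = 56L, overlap_tolerance = 0.001) {
  stopifnot(inherits(image, "annotated_image"))
  if (length(image$annotations) == 0L) stop("image has no polygon annotations")
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  ps <- as.integer(patch_size)
  if (ps > h || ps > w) stop("patch does not fit inside the image")

  inside <- matrix(FALSE, h, w)
  outline <- matrix(FALSE, h, w)
  for (p in image$annotations) {
    inside <- inside | polygon_mask(p$vertices, h, w)
    outline <- outline | polygon_outline(p$vertices, h, w)
  }
  near_outline <- dilate1(outline)

  sat <- matrix(0L, h + 1L, w + 1L)
  sat[-1L, -1L] <- apply(apply(inside, 2L, cumsum), 1L, cumsum) |> t()

  xs0 <- seq.int(0L, w - ps) # candidate top-left coordinates
  ys0 <- seq.int(0L, h - ps)
  grid_x <- rep(xs0, times = length(ys0))
  grid_y <- rep(ys0, each = length(xs0)) # row-major: y outer, x inner
  counts <- window_sums(sat, grid_x, grid_y, ps)

  full <- ps * ps
  is_hcc_cand <- counts == full
  corners_on <- function(x, y) {
    near_outline[cbind(y + 1L, x + 1L)] |
      near_outline[cbind(y + 1L, x + ps)] |
      near_outline[cbind(y + ps, x + 1L)] |
      near_outline[cbind(y + ps, x + ps)]
  }
  is_par_cand <- counts == 0L & corners_on(grid_x, grid_y)

  keep <- which(is_hcc_cand | is_par_cand) # already in raster order
  acc_x <- integer(0L); acc_y <- integer(0L)
  acc_label <- character(0L)
  for (i in keep) {
    x <- grid_x[i]; y <- grid_y[i]
    if (length(acc_x)) {
      inter <- rect_intersections(x, y, acc_x, acc_y, ps)
      if (is_hcc_cand[i]) {
        iou <- inter / (2 * full - inter)
        if (any(iou >= overlap_tolerance)) next
      } else {
        if (any(inter / full >= overlap_tolerance)) next
      }
    }
    acc_x <- c(acc_x, x); acc_y <- c(acc_y, y)
    acc_label <- c(acc_label, if (is_hcc_cand[i]) "HCC" else "PAR")
  }
  if (!any(acc_label == "HCC")) {
    warning("polygon too small to admit any interior window: 0 HCC patches")
  }
  lapply(seq_along(acc_x), function(i) {
    x <- acc_x[i]; y <- acc_y[i]
    us_patch(image$pixels[(y + 1L):(y + ps), (x + 1L):(x + ps), drop = FALSE],
             label = acc_label[i], origin = c(x, y),
             patient_id = image$patient_id, image_id = image$device_tag)
  })
}

# Bilinear sampling of `img` at (possibly fractional) 0-based coordinates,
# reflect-padded outside the support.
bilinear_sample <- function(img, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ix0 <- reflect_index(as.integer(x0) + 1L, w)
  ix1 <- reflect_index(as.integer(x0) + 2L, w)
  iy0 <- reflect_index(as.integer(y0) + 1L, h)
  iy1 <- reflect_index(as.integer(y0) + 2L, h)
  v00 <- img[cbind(iy0, ix0)]; v01 <- img[cbind(iy0, ix1)]
  v10 <- img[cbind(iy1, ix0)]; v11 <- img[cbind(iy1, ix1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Apply (reflection, rotation, zoom) about the patch center; bilinear
# interpolation with reflected borders; output size equals input size.
transform_patch <- function(px, angle_deg, zoom, reflect) {
  n <- nrow(px)
  c0 <- (n - 1) / 2
  xs <- rep(seq_len(n) - 1L, each = n) - c0   # output coords, row-major
  ys <- rep(seq_len(n) - 1L, times = n) - c0
  th <- -angle_deg * pi / 180 # inverse rotation
  sx <- xs / zoom; sy <- ys / zoom
  rx <- cos(th) * sx - sin(th) * sy
  ry <- sin(th) * sx + cos(th) * sy
  if (reflect) rx <- -rx
  vals <- bilinear_sample(px, rx + c0, ry + c0)
  m <- matrix(0L, n, n)
  m[cbind(ys + c0 + 1L, xs + c0 + 1L)] <- as.integer(round(vals))
  m
}

# The augmentation transform pool: rotations every 5 degrees in [-45, 45],
# zoom in {0.8, 1, 1.2}, horizontal reflection in {no, yes}; the identity
# (0 degrees, zoom 1, no reflection) is excluded (the original is kept).
augment_pool <- function() {
  g <- expand.grid(angle = seq(-45, 45, by = 5), zoom = c(0.8, 1, 1.2),
                   reflect = c(FALSE, TRUE))
  g[!(g$angle == 0 & g$zoom == 1 & !g$reflect), ]
}

#' Augment a patch tenfold
#'
#' Returns the original patch plus 9 seeded draws (without replacement)
#' from the transform pool of rotations every 5 degrees in
#' `[-45, 45]` degrees, zoom factors 0.8 / 1 / 1.2 and horizontal
#' reflection. The multiplier of exactly 10 reproduces the clinical
#' training-set bookkeeping (e.g. 5324 -> 53,240 patches). Transformed
#' patches are bilinearly resampled about the center with reflected borders
#' and keep their label and size.
#'
#' @param patch An [us_patch()] (square).
#' @param seed Integer seed for the transform draw.
#' @return List of 10 [us_patch()], the first being the input.
#' @export
augment <- function(patch, seed) {
  stopifnot(inherits(patch, "us_patch"))
  if (nrow(patch$pixels) != ncol(patch$pixels)) stop("non-square patch")
  pool <- augment_pool()
  pick <- with_seed(seed, sample.int(nrow(pool), 9L))
  out <- vector("list", 10L)
  out[[1L]] <- patch
  for (k in seq_len(9L)) {
    tr <- pool[pick[k], ]
    q <- patch
    q$pixels <- transform_patch(patch$pixels, tr$angle, tr$zoom, tr$reflect)
    out[[k + 1L]] <- q
  }
  out
}

#' Dataset split specification
#'
#' @param train_fraction,validation_fraction,test_fraction Non-negative
#'   proportions summing to 1 (clinical protocol: 80% train / 20% test).
#' @param group_by_patient When `TRUE` (default) all patches of a patient
#'   land in the same partition, preventing patient-level leakage.
#' @param seed Integer seed for the shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, validation_fraction = 0,
                       test_fraction = 0.2, group_by_patient = TRUE,
                       seed = 1L) {
  fr <- c(train_fraction, validation_fraction, test_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("fractions must be non-negative and sum to 1")
  }
  structure(list(train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 test_fraction = test_fraction,
                 group_by_patient = isTRUE(group_by_patient),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Partition row indices by seeded shuffling: patient-grouped or per-class
# stratified. Returns integer index vectors for train/validation/test.
split_indices <- function(labels, patient_ids, spec) {
  fr <- c(spec$train_fraction, spec$validation_fraction, spec$test_fraction)
  assign_counts <- function(n) {
    k <- floor(fr * n)
    rem <- n - sum(k)
    if (rem > 0L) { # hand leftovers to the largest remainders first
      ord <- order(fr * n - k, decreasing = TRUE)
      k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
    }
    k
  }
  part_of <- integer(length(labels))
  if (spec$group_by_patient) {
    ids <- unique(patient_ids)
    ord <- with_seed(spec$seed, sample(ids))
    grp <- rep(1:3, times = assign_counts(length(ids)))
    for (i in seq_along(ord)) part_of[patient_ids == ord[i]] <- grp[i]
  } else {
    for (lb in unique(labels)) {
      idx <- which(labels == lb)
      ordered <- with_seed(spec$seed + match(lb, sort(unique(labels))),
                           sample(idx))
      part_of[ordered] <- rep(1:3, times = assign_counts(length(idx)))
    }
  }
  list(train = which(part_of == 1L),
       validation = which(part_of == 2L),
       test = which(part_of == 3L))
}

#' Split patches into train / validation / test partitions
#'
#' Produces disjoint, exhaustive partitions by seeded shuffling. With
#' `group_by_patient`, whole patients are assigned to partitions (fractions
#' then apply to patch counts as closely as whole patients allow);
#' otherwise patches are split individually with per-class stratification.
#'
#' @param patches List of [us_patch()].
#' @param spec A [split_spec()].
#' @return Named list `train` / `validation` / `test` of patch lists.
#' @export
split_dataset <- function(patches, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), length(patches) >= 1L)
  labels <- vapply(patches, function(p) p$label, character(1L))
  if (length(unique(labels)) < 2L) {
    stop("need at least one patch per class")
  }
  pids <- vapply(patches, function(p) p$patient_id, character(1L))
  idx <- split_indices(labels, pids, spec)
  fr <- c(spec$train_fraction, spec$validation_fraction, spec$test_fraction)
  out <- list(train = patches[idx$train],
              validation = patches[idx$validation],
              test = patches[idx$test])
  for (nm in c("train", "test")) {
    if (fr[match(nm, c("train", "validation", "test"))] > 0) {
      lb <- labels[idx[[nm]]]
      if (!spec$group_by_patient && length(unique(lb)) < 2L) {
        stop("a class is absent from the ", nm, " partition")
      }
    }
  }
  out
}

#' Tabulate a patch list
#'
#' @param patches List of [us_patch()].
#' @return Data frame with label, origin and provenance per patch.
#' @export
patch_manifest <- function(patches) {
  data.frame(
    label = vapply(patches, function(p) p$label, character(1L)),
    origin_x = vapply(patches, function(p) p$origin[1L], integer(1L)),
    origin_y = vapply(patches, function(p) p$origin[2L], integer(1L)),
    patient_id = vapply(patches, function(p) p$patient_id, character(1L)),
    stringsAsFactors = FALSE)
}
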