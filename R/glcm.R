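# Gray-level co-occurrence matrices of order 2 and 3.
#
# Order 2 uses the 8 unit displacement vectors at multiples of 45 degrees.
# Order 3 relates the current (central) pixel to two neighbors along a
# direction pair: the pixels are either collinear or form a right-angle
# triangle with the current pixel at the corner; displacement components
# have magnitude 2 (45-degree directions step 2 in both components).

# (dx, dy) displacement for a direction in degrees with component
# magnitude `step` (y axis points down; the sign convention only permutes
# matrix entries and does not affect any derived statistic).
direction_step <- function(angle_deg, step) {
  a <- angle_deg %% 360
  dx <- switch(as.character(a),
               "0" = 1, "45" = 1, "90" = 0, "135" = -1,
               "180" = -1, "225" = -1, "270" = 0, "315" = 1)
  dy <- switch(as.character(a),
               "0" = 0, "45" = -1, "90" = -1, "135" = -1,
               "180" = 0, "225" = 1, "270" = 1, "315" = 1)
  c(dx, dy) * step
}

order2_displacements <- function() {
  lapply(seq(0, 315, by = 45), function(a) list(d1 = direction_step(a, 1)))
}

order3_direction_pairs <- function() {
  collinear <- list(c(0, 180), c(90, 270), c(45, 225), c(135, 315))
  right_angle <- list(c(0, 90), c(90, 180), c(180, 270), c(0, 270),
                      c(45, 135), c(135, 225), c(225, 315), c(45, 315))
  lapply(c(collinear, right_angle), function(pr) {
    list(d1 = direction_step(pr[1], 2), d2 = direction_step(pr[2], 2))
  })
}

#' Co-occurrence configuration
#'
#' @param order 2 or 3 (pair or triple co-occurrences).
#' @param gray_levels Quantization depth (uniform binning of `[0, 255]`);
#'   defaults: 32 levels for order 2, 16 for order 3.
#' @param displacements List of displacement configurations; by default the
#'   canonical enumeration (8 unit vectors at 45-degree multiples for order
#'   2; the 4 collinear plus 8 right-angle direction pairs with magnitude-2
#'   components for order 3).
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(order = 2L, gray_levels = if (order == 2L) 32L else 16L,
                        displacements = NULL) {
  stopifnot(order %in% c(2L, 3L), gray_levels >= 2L)
  if (is.null(displacements)) {
    displacements <- if (order == 2L) order2_displacements()
                     else order3_direction_pairs()
  }
  stopifnot(length(displacements) >= 1L)
  structure(list(order = as.integer(order),
                 gray_levels = as.integer(gray_levels),
                 displacements = displacements),
            class = "glcm_config")
}

quantize_levels <- function(px, levels) {
  q <- pmin(floor(px * levels / 256), levels - 1L) # 255 falls in the top bin
  matrix(as.integer(q), nrow(px), ncol(px))
}

# Count co-occurrences for one displacement configuration. `q` is the
# quantized matrix; returns an array of dimension levels^order.
glcm_counts <- function(q, levels, disp) {
  h <- nrow(q); w <- ncol(q)
  offs <- list(c(0, 0), disp$d1, if (!is.null(disp$d2)) disp$d2)
  offs <- offs[!vapply(offs, is.null, logical(1L))]
  dx <- vapply(offs, `[`, numeric(1L), 1L)
  dy <- vapply(offs, `[`, numeric(1L), 2L)
  # valid base pixels: every tuple member stays in bounds
  x0 <- max(0, -min(dx)); x1 <- (w - 1) - max(0, max(dx))
  y0 <- max(0, -min(dy)); y1 <- (h - 1) - max(0, max(dy))
  if (x0 > x1 || y0 > y1) {
    stop("patch smaller than the largest displacement reach")
  }
  xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
  lin <- rep(0L, length(xs) * length(ys))
  for (m in seq_along(offs)) {
    sub <- q[ys + dy[m] + 1L, xs + dx[m] + 1L, drop = FALSE]
    lin <- lin + as.integer(sub) * levels^(m - 1L)
  }
  counts <- tabulate(lin + 1L, nbins = levels^length(offs))
  array(counts, dim = rep(levels, length(offs)))
}

#' Compute gray-level co-occurrence tensors
#'
#' Quantizes the patch to `config$gray_levels` and counts gray-level tuples
#' for every displacement configuration; one tensor is retained per
#' configuration so that derived statistics can be averaged over them.
#'
#' @param patch An [us_patch()] or intensity matrix in `[0, 255]`.
#' @param config A [glcm_config()].
#' @return List of `glcm_tensor` objects (count array plus config).
#' @export
compute_glcm <- function(patch, config = glcm_config()) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  stopifnot(is.matrix(px))
  q <- quantize_levels(px, config$gray_levels)
  lapply(config$displacements, function(disp) {
    structure(list(counts = glcm_counts(q, config$gray_levels, disp),
                   order = config$order,
                   gray_levels = config$gray_levels,
                   displacement = disp),
              class = "glcm_tensor")
  })
}

# Haralick statistics of one normalized co-occurrence distribution.
# Pairwise quantities (contrast, homogeneity, correlation) average over the
# tuple pairs for order 3; variance averages the per-position variances.
haralick_one <- function(tensor) {
  counts <- tensor$counts
  total <- sum(counts)
  if (total == 0) stop("empty tensor (total count 0)")
  p <- counts / total
  nd <- length(dim(p))
  L <- dim(p)[1L]
  g <- seq_len(L) - 1 # gray level of each index
  # marginals per tuple position
  marg <- lapply(seq_len(nd), function(i) apply(p, i, sum))
  mu <- vapply(seq_len(nd), function(i) sum(g * marg[[i]]), numeric(1L))
  sg2 <- vapply(seq_len(nd), function(i) sum((g - mu[i])^2 * marg[[i]]),
                numeric(1L))
  # index grids
  idx <- lapply(seq_len(nd), function(i) {
    slice.index(p, i) - 1
  })
  pairs <- if (nd == 2L) list(c(1L, 2L)) else list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  sqdiff <- Reduce(`+`, lapply(pairs, function(pr) {
    (idx[[pr[1L]]] - idx[[pr[2L]]])^2
  })) / length(pairs)
  energy <- sum(p^2)
  pos <- p[p > 0]
  entropy <- -sum(pos * log2(pos))
  contrast <- sum(p * sqdiff)
  homogeneity <- sum(p / (1 + sqdiff))
  variance <- mean(vapply(seq_len(nd), function(i) {
    sum(p * (idx[[i]] - mu[i])^2)
  }, numeric(1L)))
  corr_pair <- vapply(pairs, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    if (sg2[i] <= 0 || sg2[j] <= 0) return(0)
    sum(p * (idx[[i]] - mu[i]) * (idx[[j]] - mu[j])) / sqrt(sg2[i] * sg2[j])
  }, numeric(1L))
  c(homogeneity = homogeneity, energy = energy, entropy = entropy,
    correlation = mean(corr_pair), contrast = contrast, variance = variance)
}

#' Haralick features of a set of co-occurrence tensors
#'
#' Computes homogeneity, energy, entropy, correlation, contrast and
#' variance on each normalized tensor and returns the arithmetic mean of
#' each statistic over the tensors (one per displacement configuration).
#' For order-3 tensors the pairwise quantities use the average over the
#' three tuple pairs and correlation is the mean of the three pairwise
#' correlations. A zero-variance marginal yields correlation 0.
#'
#' @param tensors List of `glcm_tensor` objects of a common order, as
#'   returned by [compute_glcm()].
#' @return Named numeric vector of the 6 statistics.
#' @export
haralick_features <- function(tensors) {
  stopifnot(length(tensors) >= 1L)
  orders <- vapply(tensors, function(t) t$order, integer(1L))
  if (length(unique(orders)) != 1L) stop("tensors must share the same order")
  per <- vapply(tensors, haralick_one, numeric(6L))
  rowMeans(per)
}
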