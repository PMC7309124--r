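# The 47 conventional textural features: 6 Haralick statistics on the
# order-2 co-occurrence matrices, 6 on the order-3 tensors, autocorrelation
# index, Hurst fractal index, 3 edge statistics, 10 Laws energy statistics
# and 20 Haar wavelet entropies.

#' Median prefilter
#'
#' Per-pixel median within an odd square window, reflect-padded at the
#' borders; applied before feature extraction to attenuate speckle noise.
#'
#' @param patch [us_patch()] or intensity matrix.
#' @param kernel Odd window side (default 3).
#' @return Same type as the input, filtered.
#' @export
median_prefilter <- function(patch, kernel = 3L) {
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  if (inherits(patch, "us_patch")) {
    patch$pixels <- matrix(as.integer(cpp_median_filter(patch$pixels + 0.0,
                                                        as.integer(kernel))),
                           nrow(patch$pixels), ncol(patch$pixels))
    patch
  } else {
    cpp_median_filter(patch + 0.0, as.integer(kernel))
  }
}

#' Autocorrelation index
#'
#' Normalized spatial autocorrelation at diagonal unit lag:
#' `sum(I(x, y) * I(x+1, y+1)) / sum(I(x, y)^2)`, both sums over the pixels
#' with a valid diagonal neighbor. An all-zero patch yields 0.
#'
#' @param patch [us_patch()] or intensity matrix, at least 2x2.
#' @return Scalar granularity measure.
#' @export
autocorrelation_index <- function(patch) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  stopifnot(nrow(px) >= 2L, ncol(px) >= 2L)
  a <- px[-nrow(px), -ncol(px)]
  b <- px[-1L, -1L]
  den <- sum(as.numeric(a)^2)
  if (den == 0) return(0)
  sum(as.numeric(a) * as.numeric(b)) / den
}

#' Hurst fractal index
#'
#' Roughness exponent of the intensity surface, estimated as the slope of
#' `log(mean |I(p) - I(q)|)` against `log(distance)` over horizontal and
#' vertical lags 1..8 (the increment-scaling estimator for fractional
#' Brownian surfaces), clipped to `[0, 1]`. A constant patch returns 1
#' (maximal smoothness).
#'
#' @param patch [us_patch()] or intensity matrix, at least 16x16.
#' @return Scalar in `[0, 1]`.
#' @export
hurst_index <- function(patch) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  stopifnot(nrow(px) >= 16L, ncol(px) >= 16L)
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  lags <- 1:8
  m <- vapply(lags, function(d) {
    hdiff <- abs(px[, -seq_len(d), drop = FALSE] -
                   px[, seq_len(ncol(px) - d), drop = FALSE])
    vdiff <- abs(px[-seq_len(d), , drop = FALSE] -
                   px[seq_len(nrow(px) - d), , drop = FALSE])
    (sum(hdiff) + sum(vdiff)) / (length(hdiff) + length(vdiff))
  }, numeric(1L))
  if (any(m == 0)) return(1) # constant (or degenerate) surface
  slope <- stats::coef(stats::lm.fit(cbind(1, log(lags)), log(m)))[2L]
  min(max(slope, 0), 1)
}

sobel_gradients <- function(px) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L) # d/dx (columns)
  list(gx = filter2_reflect(px, kx), gy = filter2_reflect(px, t(kx)))
}

# Otsu threshold of a non-negative map: the 256-bin between-class-variance
# maximizer, evaluated directly on the histogram (kept in-package because
# the per-call overhead of wrapping each gradient map in an image object
# dominates batch feature extraction; agreement with EBImage::otsu is
# asserted in the test suite).
otsu_threshold <- function(v, levels = 256L) {
  mx <- max(v)
  if (mx <= 0) return(0)
  breaks <- seq(0, mx, length.out = levels + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w1 <- cumsum(h)
  m1 <- cumsum(h * mids)
  total <- w1[levels]; mu <- m1[levels]
  w1 <- w1[-levels]; m1 <- m1[-levels]
  w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  if (!any(valid)) return(0)
  bcv <- (mu * w1 - m1 * total)^2 / (w1 * w2)
  mids[-levels][valid][which.max(bcv[valid])]
}

#' Edge statistics
#'
#' Sobel-gradient statistics of a patch: edge pixels are those whose
#' gradient magnitude exceeds the Otsu threshold of the magnitude map.
#' Returns the edge-pixel fraction (`edge_frequency`), the mean gradient
#' magnitude over edge pixels (`edge_contrast`, 0 if none) and the circular
#' mean of gradient orientations modulo pi (`edge_orientation`, radians in
#' `[0, pi)`, 0 if none). A constant patch yields `(0, 0, 0)`.
#'
#' @param patch [us_patch()] or intensity matrix, at least 3x3.
#' @return Named numeric vector of 3 statistics.
#' @export
edge_statistics <- function(patch) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  stopifnot(nrow(px) >= 3L, ncol(px) >= 3L)
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  g <- sobel_gradients(px)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) {
    return(c(edge_frequency = 0, edge_contrast = 0, edge_orientation = 0))
  }
  th <- otsu_threshold(mag)
  edge <- mag > th
  if (!any(edge)) {
    return(c(edge_frequency = 0, edge_contrast = 0, edge_orientation = 0))
  }
  theta <- atan2(g$gy[edge], g$gx[edge]) %% pi
  z <- sum(exp(2i * theta))
  orient <- if (Mod(z) == 0) 0 else (Arg(z) / 2) %% pi
  c(edge_frequency = mean(edge),
    edge_contrast = mean(mag[edge]),
    edge_orientation = orient)
}

#' Laws texture energy kernels
#'
#' The five separable 5x5 kernels built from the standard 1-D level, edge,
#' spot, wave and ripple vectors; each is `outer(L5, v)` (level smoothing
#' across rows), the level map being `outer(L5, L5)`.
#'
#' @return Named list of 5x5 matrices `L5`, `E5`, `S5`, `W5`, `R5`.
#' @export
laws_kernels <- function() {
  v <- list(L5 = c(1, 4, 6, 4, 1),
            E5 = c(-1, -2, 0, 2, 1),
            S5 = c(-1, 0, 2, 0, -1),
            W5 = c(-1, 2, 0, -2, 1),
            R5 = c(1, -4, 6, -4, 1))
  lapply(v, function(u) outer(v$L5, u))
}

#' Laws texture energy features
#'
#' Filters the patch with the five Laws kernels (reflected borders) and
#' computes, per response map, the density (mean absolute response) and
#' frequency (fraction of pixels with absolute response strictly above the
#' map's mean absolute response) of the textural micro-structures.
#'
#' @param patch [us_patch()] or intensity matrix, at least 5x5.
#' @return Named numeric vector of 10 features.
#' @export
laws_features <- function(patch) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  stopifnot(nrow(px) >= 5L, ncol(px) >= 5L)
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  ks <- laws_kernels()
  out <- numeric(0L)
  for (nm in names(ks)) {
    resp <- abs(filter2_reflect(px, ks[[nm]]))
    dens <- mean(resp)
    freq <- if (dens == 0) 0 else mean(resp > dens)
    if (nm != "L5" && dens < .Machine$double.eps * 1e4 * max(abs(px), 1)) {
      # zero-sum kernels annihilate constants up to roundoff
      dens <- 0; freq <- 0
    }
    out <- c(out, stats::setNames(c(dens, freq),
                                  paste0("laws_", nm, c("_density", "_frequency"))))
  }
  out
}

# One Haar analysis step: 2x2 orthonormal transform producing the ll, lh,
# hl, hh subbands at half resolution (lh = horizontal detail: differences
# along x).
haar_step <- function(px) {
  er <- seq(1L, nrow(px), by = 2L); oc <- seq(1L, ncol(px), by = 2L)
  a <- px[er, oc, drop = FALSE];      b <- px[er, oc + 1L, drop = FALSE]
  c_ <- px[er + 1L, oc, drop = FALSE]; d <- px[er + 1L, oc + 1L, drop = FALSE]
  list(ll = (a + b + c_ + d) / 2,
       lh = (a - b + c_ - d) / 2,
       hl = (a + b - c_ - d) / 2,
       hh = (a - b - c_ + d) / 2)
}

#' Haar wavelet entropies
#'
#' Applies a single-level Haar decomposition (ll, lh, hl, hh), then a
#' second Haar level on each component (16 subbands), and computes the
#' Shannon entropy `-sum(q * log2(q))` of each component's L1-normalized
#' coefficient magnitudes `q = |c| / sum(|c|)` (so the quantity is a proper
#' entropy and scale invariant). With `normalize = FALSE` the sum is
#' evaluated literally on the raw magnitudes. Components that are entirely
#' zero yield entropy 0.
#'
#' @param patch [us_patch()] or intensity matrix with sides divisible by 4.
#' @param normalize L1-normalize each component first (default `TRUE`).
#' @return Named numeric vector of 4 + 16 = 20 entropies.
#' @export
wavelet_entropies <- function(patch, normalize = TRUE) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  if (nrow(px) %% 4L != 0L || ncol(px) %% 4L != 0L) {
    stop("patch sides must be divisible by 4")
  }
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  ent <- function(m) {
    a <- abs(as.numeric(m))
    if (normalize) {
      s <- sum(a)
      if (s == 0) return(0)
      a <- a / s
    }
    a <- a[a > 0]
    if (length(a) == 0L) return(0)
    -sum(a * log2(a))
  }
  lvl1 <- haar_step(px)
  out <- vapply(lvl1, ent, numeric(1L))
  names(out) <- paste0("wav1_", names(lvl1))
  for (nm in names(lvl1)) {
    lvl2 <- haar_step(lvl1[[nm]])
    e2 <- vapply(lvl2, ent, numeric(1L))
    names(e2) <- paste0("wav2_", nm, "_", names(lvl2))
    out <- c(out, e2)
  }
  out
}

#' Local binary pattern configuration
#'
#' @param radius Circle radius R in pixels (`>= 1`).
#' @param neighbors Number of circular neighbors N (`>= 4`).
#' @param cell_size Side of the non-overlapping histogram cells; must
#'   divide the patch side.
#' @return An object of class `lbp_config`.
#' @export
lbp_config <- function(radius = 1, neighbors = 8L, cell_size = 14L) {
  stopifnot(radius >= 1, neighbors >= 4L)
  structure(list(radius = radius, neighbors = as.integer(neighbors),
                 cell_size = as.integer(cell_size)),
            class = "lbp_config")
}

#' Local binary pattern histograms
#'
#' Computes the LBP code of every pixel whose full circular neighborhood
#' fits in the patch (border pixels are skipped): neighbor `p` of
#' `N` sits at angle `2*pi*p/N` on the circle of radius `R` (bilinear
#' interpolation off-grid) and contributes `2^p` when strictly brighter
#' than the center. The patch is divided into non-overlapping
#' `cell_size`-pixel cells and a `2^N`-bin histogram of codes is computed
#' per cell; histograms are concatenated in raster cell order.
#'
#' @param patch [us_patch()] or intensity matrix.
#' @param config An [lbp_config()].
#' @return Named integer vector of concatenated per-cell histograms.
#' @export
lbp_histogram <- function(patch, config = lbp_config()) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  h <- nrow(px); w <- ncol(px)
  if (h %% config$cell_size != 0L || w %% config$cell_size != 0L) {
    stop("cell_size must divide the patch sides")
  }
  px <- matrix(as.numeric(px), h, w)
  R <- config$radius; N <- config$neighbors
  b <- ceiling(R)
  rows <- (b + 1L):(h - b); cols <- (b + 1L):(w - b)
  if (length(rows) == 0L || length(cols) == 0L) stop("patch too small for radius")
  xs <- rep(cols - 1L, each = length(rows)) # 0-based centers
  ys <- rep(rows - 1L, times = length(cols))
  center <- px[cbind(ys + 1L, xs + 1L)]
  code <- rep(0L, length(center))
  for (p in seq_len(N) - 1L) {
    ang <- 2 * pi * p / N
    nx <- xs + R * cos(ang)
    ny <- ys - R * sin(ang)
    val <- bilinear_sample(px, nx, ny)
    code <- code + as.integer(val - center > 0) * 2L^p
  }
  code_mat <- matrix(NA_integer_, h, w)
  code_mat[cbind(ys + 1L, xs + 1L)] <- code
  n_codes <- 2L^N
  cells_y <- h %/% config$cell_size
  cells_x <- w %/% config$cell_size
  out <- integer(0L)
  for (cy in seq_len(cells_y)) {   # raster order: left-to-right, top-to-bottom
    for (cx in seq_len(cells_x)) {
      rr <- ((cy - 1L) * config$cell_size + 1L):(cy * config$cell_size)
      cc <- ((cx - 1L) * config$cell_size + 1L):(cx * config$cell_size)
      codes <- code_mat[rr, cc]
      codes <- codes[!is.na(codes)]
      hist <- tabulate(codes + 1L, nbins = n_codes)
      names(hist) <- sprintf("lbp_c%02d_%03d", (cy - 1L) * cells_x + cx - 1L,
                             seq_len(n_codes) - 1L)
      out <- c(out, hist)
    }
  }
  out
}

#' Canonical names of the 47 textural features
#'
#' @return Character vector of length 47, in extraction order.
#' @export
feature_names <- function() {
  har <- c("homogeneity", "energy", "entropy", "correlation", "contrast",
           "variance")
  wav <- names(wavelet_entropies(matrix(0, 8L, 8L)))
  c(paste0("glcm2_", har), paste0("glcm3_", har),
    "autocorrelation", "hurst",
    "edge_frequency", "edge_contrast", "edge_orientation",
    paste0("laws_", rep(c("L5", "E5", "S5", "W5", "R5"), each = 2L),
           c("_density", "_frequency")),
    wav)
}

#' Extract the 47-feature textural descriptor of one patch
#'
#' Applies the 3x3 median prefilter and computes, in canonical order:
#' 6 Haralick statistics on the 8 order-2 co-occurrence matrices, 6 on the
#' 12 order-3 tensors, the autocorrelation index, the Hurst index, 3 edge
#' statistics, 10 Laws energy statistics and 20 wavelet entropies.
#' Deterministic, and finite for every 8-bit input.
#'
#' @param patch [us_patch()] or square intensity matrix with side divisible
#'   by 4 (clinical size 56).
#' @param glcm2,glcm3 Co-occurrence configurations (defaults: 32 levels /
#'   order 2, 16 levels / order 3 with the canonical displacement sets).
#' @return Named numeric vector of 47 finite values.
#' @export
extract_feature_vector <- function(patch, glcm2 = glcm_config(2L),
                                   glcm3 = glcm_config(3L)) {
  px <- if (inherits(patch, "us_patch")) patch$pixels else patch
  px <- median_prefilter(px)
  har <- c("homogeneity", "energy", "entropy", "correlation", "contrast",
           "variance")
  h2 <- haralick_features(compute_glcm(px, glcm2))
  h3 <- haralick_features(compute_glcm(px, glcm3))
  out <- c(stats::setNames(h2, paste0("glcm2_", har)),
           stats::setNames(h3, paste0("glcm3_", har)),
           autocorrelation = autocorrelation_index(px),
           hurst = hurst_index(px),
           edge_statistics(px),
           laws_features(px),
           wavelet_entropies(px))
  names(out)[names(out) == "autocorrelation.autocorrelation"] <- "autocorrelation"
  stopifnot(length(out) == 47L, all(is.finite(out)))
  out
}

#' Extract features for a list of patches
#'
#' @param patches List of [us_patch()].
#' @param lbp Also append the concatenated LBP histograms (the
#'   LBP+GLCM published-method variant).
#' @param lbp_cfg LBP configuration used when `lbp = TRUE`.
#' @return Data frame: 47 feature columns (plus LBP bins if requested), a
#'   `label` column, and a `patient_id` column.
#' @export
extract_features <- function(patches, lbp = FALSE, lbp_cfg = lbp_config()) {
  stopifnot(length(patches) >= 1L)
  rows <- lapply(patches, function(p) {
    v <- extract_feature_vector(p)
    if (lbp) v <- c(v, lbp_histogram(median_prefilter(p$pixels), lbp_cfg))
    v
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$label <- vapply(patches, function(p) p$label, character(1L))
  df$patient_id <- vapply(patches, function(p) p$patient_id, character(1L))
  df
}
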