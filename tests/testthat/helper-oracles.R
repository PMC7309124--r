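# Independent brute-force oracles used to verify the fast implementations.
# These are deliberately literal (loops, direct sums) and share no code
# with the package internals.

# Literal co-occurrence counting: enumerate every base pixel and tuple.
oracle_glcm <- function(px, levels, d1, d2 = NULL) {
  q <- matrix(pmin(floor(px * levels / 256), levels - 1L),
              nrow(px), ncol(px))
  n <- if (is.null(d2)) 2L else 3L
  counts <- array(0L, dim = rep(levels, n))
  h <- nrow(px); w <- ncol(px)
  for (y in 0:(h - 1L)) {
    for (x in 0:(w - 1L)) {
      x1 <- x + d1[1L]; y1 <- y + d1[2L]
      if (x1 < 0 || x1 >= w || y1 < 0 || y1 >= h) next
      if (is.null(d2)) {
        idx <- cbind(q[y + 1L, x + 1L] + 1L, q[y1 + 1L, x1 + 1L] + 1L)
        counts[idx] <- counts[idx] + 1L
      } else {
        x2 <- x + d2[1L]; y2 <- y + d2[2L]
        if (x2 < 0 || x2 >= w || y2 < 0 || y2 >= h) next
        idx <- cbind(q[y + 1L, x + 1L] + 1L, q[y1 + 1L, x1 + 1L] + 1L,
                     q[y2 + 1L, x2 + 1L] + 1L)
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  counts
}

# Haralick statistics of an order-2 count matrix by direct summation.
oracle_haralick2 <- function(counts) {
  p <- counts / sum(counts)
  L <- nrow(p)
  g <- 0:(L - 1L)
  I <- matrix(g, L, L, byrow = FALSE)  # first index
  J <- matrix(g, L, L, byrow = TRUE)   # second index
  mu1 <- sum(I * p); mu2 <- sum(J * p)
  s1 <- sqrt(sum((I - mu1)^2 * p)); s2 <- sqrt(sum((J - mu2)^2 * p))
  pos <- p[p > 0]
  corr <- if (s1 == 0 || s2 == 0) 0 else
    sum((I - mu1) * (J - mu2) * p) / (s1 * s2)
  c(homogeneity = sum(p / (1 + (I - J)^2)),
    energy = sum(p^2),
    entropy = -sum(pos * log2(pos)),
    correlation = corr,
    contrast = sum(p * (I - J)^2),
    variance = (sum((I - mu1)^2 * p) + sum((J - mu2)^2 * p)) / 2)
}

# Direct centered cross-correlation with reflected borders.
oracle_filter2 <- function(x, k) {
  hr <- (nrow(k) - 1L) %/% 2L; hc <- (ncol(k) - 1L) %/% 2L
  refl <- function(i, n) {
    while (any(i < 1L) || any(i > n)) {
      i <- ifelse(i < 1L, 1L - i, i)
      i <- ifelse(i > n, 2L * n + 1L - i, i)
    }
    i
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) {
    for (c in seq_len(ncol(x))) {
      acc <- 0
      for (a in seq_len(nrow(k))) {
        for (b in seq_len(ncol(k))) {
          acc <- acc + k[a, b] *
            x[refl(r + a - 1L - hr, nrow(x)), refl(c + b - 1L - hc, ncol(x))]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# Median filter by explicit window sort.
oracle_median3 <- function(x) {
  refl <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
  out <- matrix(0, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) {
    for (c in seq_len(ncol(x))) {
      vals <- numeric(0L)
      for (dr in -1:1) for (dc in -1:1) {
        vals <- c(vals, x[refl(r + dr, nrow(x)), refl(c + dc, ncol(x))])
      }
      out[r, c] <- median(vals)
    }
  }
  out
}

# AUC by exhaustive positive-negative pair counting, ties worth 1/2.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "HCC" | labels == 1 | labels == TRUE]
  neg <- scores[!(labels == "HCC" | labels == 1 | labels == TRUE)]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Literal sliding-window patch rules: enumerate every window in raster
# order and apply the acceptance tests against a pixel mask.
oracle_patches <- function(inside_mask, near_outline, ps = 56L, tol = 0.001) {
  h <- nrow(inside_mask); w <- ncol(inside_mask)
  acc <- list()
  for (y in 0:(h - ps)) {
    for (x in 0:(w - ps)) {
      win <- inside_mask[(y + 1L):(y + ps), (x + 1L):(x + ps)]
      n_in <- sum(win)
      corner <- near_outline[y + 1L, x + 1L] || near_outline[y + 1L, x + ps] ||
        near_outline[y + ps, x + 1L] || near_outline[y + ps, x + ps]
      cand_hcc <- n_in == ps * ps
      cand_par <- n_in == 0L && corner
      if (!cand_hcc && !cand_par) next
      ok <- TRUE
      for (a in acc) {
        ix <- max(0L, min(x + ps, a$x + ps) - max(x, a$x))
        iy <- max(0L, min(y + ps, a$y + ps) - max(y, a$y))
        inter <- ix * iy
        frac <- if (cand_hcc) inter / (2 * ps * ps - inter) else inter / (ps * ps)
        if (frac >= tol) { ok <- FALSE; break }
      }
      if (ok) acc[[length(acc) + 1L]] <-
          list(x = x, y = y, label = if (cand_hcc) "HCC" else "PAR")
    }
  }
  acc
}

# Fractional Brownian surface via spectral synthesis (power-law spectrum
# with exponent -(H + 1), random phases), rescaled to [0, 255].
oracle_fbm_surface <- function(n, H, seed) {
  set.seed(seed)
  fx <- c(0:(n / 2), -((n / 2 - 1):1)) / n
  f2 <- outer(fx^2, fx^2, "+")
  amp <- f2^(-(H + 1) / 2)
  amp[1L, 1L] <- 0
  phase <- matrix(runif(n * n, 0, 2 * pi), n, n)
  spec <- amp * exp(1i * phase)
  surf <- Re(fft(spec, inverse = TRUE)) / n
  surf <- surf - min(surf)
  if (max(surf) > 0) surf <- surf / max(surf)
  matrix(round(surf * 255), n, n)
}

# Small annotated feature table with a planted class-linked feature and
# pure-noise columns (for selection tests).
make_planted_table <- function(n = 200L, n_noise = 8L, seed = 1L) {
  set.seed(seed)
  label <- rep(c("HCC", "PAR"), length.out = n)
  planted <- ifelse(label == "HCC", 1, 0) + rnorm(n, 0, 0.05)
  X <- matrix(rnorm(n * n_noise), n)
  colnames(X) <- paste0("noise", seq_len(n_noise))
  df <- data.frame(planted = planted, X, check.names = FALSE)
  df$label <- label
  df
}

random_patch <- function(n, seed) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}
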