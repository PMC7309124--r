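# Internal helpers shared across modules.

# Reflect an integer index into 1..n (symmetric padding with edge repeat:
# ... 2 1 | 1 2 ... n-1 n | n n-1 ...). Works for any distance outside.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period # 0 .. 2n-1
  ifelse(j < n, j + 1L, period - j)
}

# Pad a matrix by reflection on all sides.
pad_reflect <- function(x, top, bottom = top, left = top, right = top) {
  ri <- reflect_index(seq.int(1L - top, nrow(x) + bottom), nrow(x))
  ci <- reflect_index(seq.int(1L - left, ncol(x) + right), ncol(x))
  x[ri, ci, drop = FALSE]
}

# Centered cross-correlation ("filtering") with an odd-sized kernel and
# reflected borders; output has the same size as the input.
filter2_reflect <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  xp <- pad_reflect(x, top = hr, bottom = hr, left = hc, right = hc)
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kernel[a, b]
      if (w == 0) next
      out <- out + w * xp[a:(a + nrow(x) - 1L), b:(b + ncol(x) - 1L)]
    }
  }
  out
}

# Separable Gaussian blur with reflected borders (phantom synthesis).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- matrix(g, ncol = 1L)
  filter2_reflect(filter2_reflect(x, k), t(k))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls do not perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw `n` independent sub-seeds from a master seed (splittable streams for
# cohort members, augmentation draws, ...). Values stay below 2^31.
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# `px`, `py` are point coordinates; `vert` is an n x 2 matrix of vertices of
# a closed ring (last edge joins row n to row 1). Points exactly on an edge
# may fall on either side; patch generation resolves boundary questions
# against the rasterized outline instead.
points_in_polygon <- function(px, py, vert) {
  nv <- nrow(vert)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vert[i, 1L]; yi <- vert[i, 2L]
    xj <- vert[j, 1L]; yj <- vert[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Proper intersection test for two closed segments, excluding touching at
# shared polygon vertices (used by the simple-ring validity check).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(vert) {
  nv <- nrow(vert)
  if (nv < 3L) return(FALSE)
  edges <- cbind(seq_len(nv), c(seq_len(nv)[-1L], 1L))
  for (i in seq_len(nv - 1L)) {
    for (j in seq.int(i + 1L, nv)) {
      # skip adjacent edges (they share a vertex)
      if (abs(i - j) <= 1L || (i == 1L && j == nv)) next
      if (segments_cross(vert[edges[i, 1L], ], vert[edges[i, 2L], ],
                         vert[edges[j, 1L], ], vert[edges[j, 2L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
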