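# Relevant-feature selection: CFS and consistency subset evaluators driven
# by a genetic search, information-gain and gain-ratio rankers, and the
# union of the four methods' relevant sets.

feature_matrix <- function(data) {
  fn <- setdiff(names(data), c("label", "patient_id"))
  X <- as.matrix(data[, fn, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = data$label, names = fn)
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Correlation-based feature selection merit
#'
#' Merit of a feature subset: `k * rcf / sqrt(k + k*(k-1) * rff)` where
#' `rcf` is the mean absolute feature-class correlation (point-biserial
#' against the binary label) and `rff` the mean absolute pairwise
#' feature-feature Pearson correlation. Zero-variance features contribute
#' zero correlations.
#'
#' @param subset Character vector of feature names (non-empty).
#' @param data Feature data frame with a `label` column.
#' @return Scalar merit.
#' @export
cfs_merit <- function(subset, data) {
  stopifnot(length(subset) >= 1L)
  fm <- feature_matrix(data)
  stopifnot(all(subset %in% fm$names))
  X <- fm$X[, subset, drop = FALSE]
  ybin <- as.numeric(factor(fm$y)) - 1
  k <- ncol(X)
  rcf <- mean(abs(vapply(seq_len(k), function(j) safe_cor(X[, j], ybin),
                         numeric(1L))))
  rff <- if (k == 1L) 0 else {
    prs <- utils::combn(k, 2L)
    mean(abs(vapply(seq_len(ncol(prs)), function(i) {
      safe_cor(X[, prs[1L, i]], X[, prs[2L, i]])
    }, numeric(1L))))
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

discretize_eqfreq <- function(x, bins = 10L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Consistency score of a feature subset
#'
#' After equal-frequency 10-bin discretization, the score is
#' `1 - sum(pattern_count - majority_class_count) / n` over the distinct
#' value patterns of the subset: 1 means the subset determines the class
#' everywhere.
#'
#' @param subset Character vector of feature names (non-empty).
#' @param data Feature data frame with a `label` column.
#' @param bins Discretization bins (default 10).
#' @return Scalar in `[0, 1]`.
#' @export
consistency_score <- function(subset, data, bins = 10L) {
  stopifnot(length(subset) >= 1L)
  fm <- feature_matrix(data)
  stopifnot(all(subset %in% fm$names))
  disc <- vapply(subset, function(nm) discretize_eqfreq(fm$X[, nm], bins),
                 integer(nrow(fm$X)))
  pattern <- apply(matrix(disc, nrow = nrow(fm$X)), 1L, paste, collapse = "|")
  inconsist <- sum(vapply(split(fm$y, pattern), function(cls) {
    length(cls) - max(table(cls))
  }, numeric(1L)))
  1 - inconsist / nrow(fm$X)
}

#' Genetic search over feature subsets
#'
#' Standard generational GA over bit-mask chromosomes: population 20,
#' single-point crossover probability 0.6, per-bit mutation probability
#' 0.033, elitism 1. Empty masks are penalized so the best subset is always
#' non-empty. Deterministic given `seed`.
#'
#' @param evaluator Function mapping a character vector of feature names to
#'   a scalar merit.
#' @param feature_names Character vector of all candidate features.
#' @param generations Number of generations (default 20).
#' @param pop_size,crossover_p,mutation_p,elitism GA hyperparameters.
#' @param seed Integer seed.
#' @return Character vector: the best subset found.
#' @export
genetic_search <- function(evaluator, feature_names, generations = 20L,
                           pop_size = 20L, crossover_p = 0.6,
                           mutation_p = 0.033, elitism = 1L, seed = 1L) {
  nf <- length(feature_names)
  if (nf == 0L) stop("zero features")
  score_mask <- function(mask) {
    if (!any(mask)) return(-Inf)
    evaluator(feature_names[mask])
  }
  with_seed(seed, {
    pop <- lapply(seq_len(pop_size), function(i) runif(nf) < 0.5)
    fit <- vapply(pop, score_mask, numeric(1L))
    best_mask <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    gen <- 0L
    while (gen < generations) {
      gen <- gen + 1L
      # fitness-proportional selection on rank (robust to -Inf)
      rk <- rank(fit, ties.method = "first")
      prob <- rk / sum(rk)
      new_pop <- vector("list", pop_size)
      ord <- order(fit, decreasing = TRUE)
      for (e in seq_len(elitism)) new_pop[[e]] <- pop[[ord[e]]]
      i <- elitism
      while (i < pop_size) {
        pa <- pop[[sample.int(pop_size, 1L, prob = prob)]]
        pb <- pop[[sample.int(pop_size, 1L, prob = prob)]]
        if (runif(1L) < crossover_p && nf > 1L) {
          cut <- sample.int(nf - 1L, 1L)
          ch1 <- c(pa[seq_len(cut)], pb[-seq_len(cut)])
          ch2 <- c(pb[seq_len(cut)], pa[-seq_len(cut)])
        } else {
          ch1 <- pa; ch2 <- pb
        }
        for (ch in list(ch1, ch2)) {
          if (i >= pop_size) break
          flip <- runif(nf) < mutation_p
          ch <- xor(ch, flip)
          i <- i + 1L
          new_pop[[i]] <- ch
        }
      }
      pop <- new_pop
      fit <- vapply(pop, score_mask, numeric(1L))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_mask <- pop[[which.max(fit)]]
      }
    }
    feature_names[best_mask]
  })
}

# --- Fayyad-Irani MDL discretization -------------------------------------

entropy_of <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Recursive MDL cut-point search; returns sorted cut values (possibly none).
# Split entropies are evaluated from cumulative class counts so every
# candidate boundary is scored in one vectorized pass.
mdl_cuts <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(unique(y)) < 2L) return(numeric(0L))
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  lev <- sort(unique(y))
  k <- length(lev)
  ent_s <- entropy_of(y)
  cand <- which(diff(x) > 0) # boundary after position i
  if (length(cand) == 0L) return(numeric(0L))
  cum <- vapply(lev, function(lv) cumsum(y == lv), numeric(n)) # n x k
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  left_counts <- cum[cand, , drop = FALSE]
  right_counts <- matrix(cum[n, ], nrow = length(cand), ncol = k,
                         byrow = TRUE) - left_counts
  n1 <- cand; n2 <- n - cand
  e1 <- -rowSums(plogp(left_counts / n1))
  e2 <- -rowSums(plogp(right_counts / n2))
  gain <- ent_s - (n1 / n) * e1 - (n2 / n) * e2
  bi <- which.max(gain)
  best_gain <- gain[bi]
  k1 <- rowSums(left_counts[bi, , drop = FALSE] > 0)
  k2 <- rowSums(right_counts[bi, , drop = FALSE] > 0)
  delta <- log2(3^k - 2) - (k * ent_s - k1 * e1[bi] - k2 * e2[bi])
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) return(numeric(0L))
  i <- cand[bi]
  cut_val <- (x[i] + x[i + 1L]) / 2
  left <- seq_len(i)
  sort(c(mdl_cuts(x[left], y[left]), cut_val,
         mdl_cuts(x[-left], y[-left])))
}

discretize_mdl <- function(x, y) {
  cuts <- mdl_cuts(x, y)
  if (length(cuts) == 0L) return(rep(1L, length(x)))
  findInterval(x, cuts) + 1L
}

#' Information-gain and gain-ratio feature scores
#'
#' Continuous features are discretized with the Fayyad-Irani MDL method
#' against the class, then `IG(f) = H(class) - H(class | f)` and
#' `GR(f) = IG(f) / H(f)` (0 when `H(f) = 0`). Scores are in bits and
#' returned sorted descending.
#'
#' @param data Feature data frame with a `label` column.
#' @param criterion `"information_gain"` or `"gain_ratio"`.
#' @return Named numeric vector of per-feature scores, sorted descending.
#' @export
ranker_scores <- function(data, criterion = c("information_gain", "gain_ratio")) {
  criterion <- match.arg(criterion)
  fm <- feature_matrix(data)
  y <- fm$y
  if (length(unique(y)) < 2L) {
    return(sort(stats::setNames(rep(0, length(fm$names)), fm$names),
                decreasing = TRUE))
  }
  hy <- entropy_of(y)
  scores <- vapply(fm$names, function(nm) {
    d <- discretize_mdl(fm$X[, nm], y)
    tab <- table(d)
    cond <- sum(vapply(split(y, d), function(cls) {
      length(cls) / length(y) * entropy_of(cls)
    }, numeric(1L)))
    ig <- hy - cond
    if (criterion == "information_gain") return(ig)
    hf <- entropy_of(d)
    if (hf == 0) 0 else ig / hf
  }, numeric(1L))
  sort(scores, decreasing = TRUE)
}

#' Select relevant textural features
#'
#' Union of the four selectors: the best CFS subset found by genetic
#' search, the best consistency subset found by genetic search, and the
#' features whose information-gain or gain-ratio score exceeds
#' `threshold` (0.3 bits). An empty union degenerates to all features with
#' a warning.
#'
#' @param data Feature data frame with a `label` column (2 classes).
#' @param threshold Ranker relevance threshold (default 0.3).
#' @param generations GA generations (default 20).
#' @param seed Integer seed for the two genetic searches.
#' @return Object of class `selection_result`: list with `selected` (the
#'   union, in canonical column order) and the four per-method results.
#' @export
select_relevant <- function(data, threshold = 0.3, generations = 20L,
                            seed = 1L) {
  fm <- feature_matrix(data)
  if (length(unique(fm$y)) < 2L) stop("need at least 2 classes")
  seeds <- split_seeds(seed, 2L)
  fnames <- sort(fm$names) # canonical order: search independent of columns
  cfs_set <- genetic_search(function(s) cfs_merit(s, data), fnames,
                            generations = generations, seed = seeds[1L])
  cons_set <- genetic_search(function(s) consistency_score(s, data), fnames,
                             generations = generations, seed = seeds[2L])
  ig <- ranker_scores(data, "information_gain")
  gr <- ranker_scores(data, "gain_ratio")
  union_set <- unique(c(cfs_set, cons_set,
                        names(ig)[ig > threshold], names(gr)[gr > threshold]))
  if (length(union_set) == 0L) {
    warning("no relevant features found; falling back to all features")
    union_set <- fm$names
  }
  structure(list(selected = fm$names[fm$names %in% union_set],
                 cfs = cfs_set, consistency = cons_set,
                 information_gain = ig, gain_ratio = gr,
                 threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected\n", length(x$selected)))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
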