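# Confusion-matrix metrics, ROC/AUC and sliding-window confidence maps.
# HCC is the positive class throughout; PAR is the negative class.

#' Confusion-matrix metrics
#'
#' Counts true/false positives/negatives (HCC positive) and derives
#' accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`. A zero denominator yields `NA` for the affected metric
#' (flagged, not an error).
#'
#' @param labels,predictions Vectors of `"HCC"`/`"PAR"` (or logical/0-1,
#'   `TRUE`/1 meaning HCC), equal length.
#' @return Object of class `eval_report` with counts and metrics.
#' @export
confusion_metrics <- function(labels, predictions) {
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(predictions))
  to_pos <- function(v) {
    if (is.character(v) || is.factor(v)) as.character(v) == POSITIVE_CLASS
    else as.logical(v)
  }
  lp <- to_pos(labels); pp <- to_pos(predictions)
  tp <- sum(lp & pp); fn <- sum(lp & !pp)
  tn <- sum(!lp & !pp); fp <- sum(!lp & pp)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = div(tp + tn, tp + tn + fp + fn),
                 sensitivity = div(tp, tp + fn),
                 specificity = div(tn, tn + fp),
                 roc = NULL, auc = NA_real_),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> acc %.3f | sens %.3f | spec %.3f | auc %s\n",
              x$accuracy, x$sensitivity, x$specificity,
              ifelse(is.na(x$auc), "-", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive (HCC) outranks a random
#' negative, with ties counted 1/2 — equivalently the trapezoidal area
#' under the ROC curve. ROC points are one per distinct threshold
#' (descending score), from `(0, 0)` to `(1, 1)`.
#'
#' @param labels Vector of `"HCC"`/`"PAR"` (or logical/0-1), both classes
#'   present.
#' @param scores Real-valued scores, higher meaning more HCC-like.
#' @return List with `roc` (data frame of `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  pos <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == POSITIVE_CLASS else as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(diff(s) != 0, TRUE) # last index of each tied block
  roc <- data.frame(fpr = c(0, fp[last] / n0),
                    tpr = c(0, tp[last] / n1),
                    threshold = c(Inf, s[last]))
  list(roc = roc, auc = auc)
}

# Full evaluation of probabilistic scores at the 0.5 operating point.
evaluate_scores <- function(labels, hcc_scores, threshold = 0.5) {
  rep_ <- confusion_metrics(labels,
                            ifelse(hcc_scores > threshold,
                                   POSITIVE_CLASS, "PAR"))
  ra <- roc_auc(labels, hcc_scores)
  rep_$roc <- ra$roc
  rep_$auc <- ra$auc
  rep_
}

#' Sliding-window confidence map
#'
#' Slides a window of `window` pixels at the given stride over the image,
#' scores each window with `scorer` (a function patch-matrix -> HCC
#' probability) and accumulates the per-pixel mean probability over all
#' covering windows. Pixels covered by no window are flagged in the
#' coverage mask and set to `NA`.
#'
#' @param scorer Function mapping a `window x window` intensity matrix to a
#'   probability in `[0, 1]`.
#' @param image [annotated_image()] or intensity matrix, at least
#'   `window` pixels in each dimension.
#' @param stride Window stride in pixels (default 14, a quarter window).
#' @param window Window side (default 56).
#' @return Object of class `confidence_map`: `probability` matrix,
#'   `covered` logical matrix, and the stride used.
#' @export
confidence_map <- function(scorer, image, stride = 14L, window = 56L) {
  px <- if (inherits(image, "annotated_image")) image$pixels else image
  h <- nrow(px); w <- ncol(px)
  if (h < window || w < window) stop("image smaller than the window")
  stopifnot(stride >= 1L)
  xs <- unique(c(seq.int(0L, w - window, by = stride), w - window))
  ys <- unique(c(seq.int(0L, h - window, by = stride), h - window))
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (y in ys) {
    for (x in xs) {
      rows <- (y + 1L):(y + window); cols <- (x + 1L):(x + window)
      p <- scorer(px[rows, cols, drop = FALSE])
      acc[rows, cols] <- acc[rows, cols] + p
      cnt[rows, cols] <- cnt[rows, cols] + 1L
    }
  }
  prob <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  structure(list(probability = prob, covered = cnt > 0L,
                 stride = as.integer(stride), window = as.integer(window)),
            class = "confidence_map")
}

#' Render a confidence map as a red/green overlay
#'
#' High HCC probability is rendered red, high PAR probability green
#' (uncovered pixels keep the grayscale background), alpha-blended over
#' the source image.
#'
#' @param map A [confidence_map()].
#' @param image The source image ([annotated_image()] or matrix).
#' @param alpha Overlay opacity in `[0, 1]`.
#' @return `height x width x 3` RGB array in `[0, 1]`, writable with
#'   `png::writePNG`.
#' @export
render_confidence_overlay <- function(map, image, alpha = 0.4) {
  px <- if (inherits(image, "annotated_image")) image$pixels else image
  g <- px / 255
  p <- map$probability
  p[!map$covered] <- NA
  r_chan <- ifelse(is.na(p), g, (1 - alpha) * g + alpha * p)
  g_chan <- ifelse(is.na(p), g, (1 - alpha) * g + alpha * (1 - p))
  b_chan <- ifelse(is.na(p), g, (1 - alpha) * g)
  out <- array(0, c(nrow(px), ncol(px), 3L))
  out[, , 1L] <- r_chan; out[, , 2L] <- g_chan; out[, , 3L] <- b_chan
  out
}
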