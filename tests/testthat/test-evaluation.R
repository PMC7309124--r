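test_that("confusion metrics count by hand on the worked example", {
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  preds <- c(1, 1, 1, 0, 0, 0, 1, 0)
  r <- confusion_metrics(labels, preds)
  expect_equal(r$tp, 3L); expect_equal(r$fn, 1L)
  expect_equal(r$tn, 3L); expect_equal(r$fp, 1L)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, 0.75)
  expect_equal(r$accuracy, 0.75)
})

test_that("perfect and degenerate predictions hit the closed forms", {
  r <- confusion_metrics(c("HCC", "PAR"), c("HCC", "PAR"))
  expect_equal(c(r$accuracy, r$sensitivity, r$specificity), c(1, 1, 1))
  r2 <- confusion_metrics(rep(c("HCC", "PAR"), 5L), rep("HCC", 10L))
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0)
  expect_equal(r2$accuracy, 0.5)
  # undefined metric flagged as NA, not an error
  r3 <- confusion_metrics(rep("HCC", 4L), rep("HCC", 4L))
  expect_true(is.na(r3$specificity))
  expect_error(confusion_metrics(character(0L), character(0L)), "empty")
})

test_that("AUC equals pairwise ordering probability on the worked example", {
  ra <- roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3))
  expect_equal(ra$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4L))$auc, 0.5)
  expect_error(roc_auc(rep(1, 4L), runif(4L)), "both classes")
})

test_that("AUC equals brute-force pair counting and the pROC oracle", {
  skip_if_not_installed("pROC")
  for (seed in 1:8) {
    set.seed(seed)
    n <- 60L
    labels <- sample(rep(c("HCC", "PAR"), n / 2L))
    scores <- round(runif(n), 2L) # ties likely
    got <- roc_auc(labels, scores)$auc
    expect_equal(got, oracle_auc(labels, scores), tolerance = 1e-12)
    want <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("PAR", "HCC"),
      direction = "<", quiet = TRUE)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("ROC points run from (0,0) to (1,1) monotonically", {
  set.seed(9)
  labels <- sample(rep(c("HCC", "PAR"), 25L))
  roc <- roc_auc(labels, runif(50L))$roc
  expect_equal(unlist(roc[1L, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(roc[nrow(roc), c("fpr", "tpr")], use.names = FALSE),
               c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("confidence maps aggregate window scores by pixel mean", {
  img <- matrix(0L, 70L, 70L)
  cm <- confidence_map(function(w) 1, img, stride = 7L)
  expect_true(all(cm$probability[cm$covered] == 1))
  expect_true(all(cm$covered))
  # stride pushing windows to corners only
  cm2 <- confidence_map(function(w) 0.5, img, stride = 70L - 55L)
  expect_true(cm2$covered[1L, 1L])
  expect_true(cm2$covered[70L, 70L])
  expect_error(confidence_map(function(w) 1, matrix(0L, 40L, 40L)),
               "smaller than the window")
})

test_that("confidence maps are invariant to window processing order", {
  # scorer depends only on content, so any visit order gives the same map;
  # check against a direct per-pixel average computed independently
  set.seed(10)
  img <- matrix(sample(0:255, 84 * 84, TRUE), 84L, 84L)
  scorer <- function(w) mean(w) / 255
  cm <- confidence_map(scorer, img, stride = 28L)
  xs <- unique(c(seq.int(0L, 84L - 56L, by = 28L), 84L - 56L))
  acc <- matrix(0, 84L, 84L); cnt <- matrix(0L, 84L, 84L)
  for (x in xs) for (y in xs) {
    rows <- (y + 1L):(y + 56L); cols <- (x + 1L):(x + 56L)
    acc[rows, cols] <- acc[rows, cols] + scorer(img[rows, cols])
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  expect_equal(cm$probability, acc / cnt, tolerance = 1e-12)
})

test_that("the overlay renderer emits a valid RGB array", {
  img <- matrix(128L, 60L, 60L)
  cm <- confidence_map(function(w) 0.9, img, stride = 4L)
  rgb <- render_confidence_overlay(cm, img)
  expect_equal(dim(rgb), c(60L, 60L, 3L))
  expect_true(all(rgb >= 0 & rgb <= 1))
  # HCC-leaning map is redder than green
  expect_gt(mean(rgb[, , 1L]), mean(rgb[, , 2L]))
})
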