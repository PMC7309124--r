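test_that("CFS merit collapses to |r_cf| for single features", {
  df <- make_planted_table(n = 100L, seed = 31)
  ybin <- as.numeric(factor(df$label)) - 1
  expect_equal(cfs_merit("planted", df),
               abs(cor(df$planted, ybin)), tolerance = 1e-12)
})

test_that("CFS merit follows the subset formula on constructed data", {
  # two identical copies of a feature with known class correlation:
  # rcf for each copy equal, rff = 1 -> merit = 2*rcf / sqrt(2 + 2) = rcf
  set.seed(32)
  n <- 400L
  label <- rep(c("HCC", "PAR"), n / 2L)
  f <- ifelse(label == "HCC", 1, 0) + rnorm(n, 0, 1)
  df <- data.frame(f1 = f, f2 = f, label = label)
  r <- abs(cor(f, as.numeric(factor(label)) - 1))
  expect_equal(cfs_merit(c("f1", "f2"), df), 2 * r / sqrt(2 + 2 * 1),
               tolerance = 1e-10)
  # a redundant feature carrying only f1's noise (correlated with f1,
  # uncorrelated with the class) strictly lowers the merit
  noise <- f - ifelse(label == "HCC", 1, 0)
  df2 <- data.frame(f1 = f, f2 = noise, label = label)
  expect_lt(cfs_merit(c("f1", "f2"), df2), cfs_merit("f1", df2))
})

test_that("zero-variance features contribute zero correlations", {
  df <- data.frame(flat = rep(1, 50L),
                   label = rep(c("HCC", "PAR"), 25L))
  expect_equal(cfs_merit("flat", df), 0)
})

test_that("consistency score: identifying subsets, constants, monotonicity", {
  # a subset whose discretized patterns determine the class scores 1
  df <- make_planted_table(n = 60L, seed = 33)
  expect_equal(consistency_score("planted", df), 1)
  flat <- data.frame(c1 = rep(1, 40L), label = rep(c("HCC", "PAR"), 20L))
  expect_equal(consistency_score("c1", flat), 0.5)
  # adding features never decreases the score
  for (seed in 1:5) {
    d2 <- make_planted_table(n = 80L, seed = seed)
    s1 <- consistency_score("noise1", d2)
    s2 <- consistency_score(c("noise1", "noise2"), d2)
    expect_gte(s2, s1)
  }
})

test_that("genetic search finds the exhaustive-best subset on small problems", {
  df <- make_planted_table(n = 150L, n_noise = 5L, seed = 34)
  fn <- setdiff(names(df), "label")
  evaluator <- function(s) cfs_merit(s, df)
  # exhaustive search over the 2^6 - 1 subsets
  best_val <- -Inf; best_set <- NULL
  for (m in seq_len(2^length(fn) - 1L)) {
    s <- fn[bitwAnd(m, 2^(seq_along(fn) - 1L)) > 0]
    v <- evaluator(s)
    if (v > best_val) { best_val <- v; best_set <- s }
  }
  hits <- 0L
  for (seed in 1:5) {
    got <- genetic_search(evaluator, fn, generations = 20L, seed = seed)
    if (setequal(got, best_set)) hits <- hits + 1L
  }
  expect_gte(hits, 4L) # stochastic search; allow one miss
  # determinism and the zero-generation boundary
  expect_identical(genetic_search(evaluator, fn, seed = 7),
                   genetic_search(evaluator, fn, seed = 7))
  g0 <- genetic_search(evaluator, fn, generations = 0L, seed = 7)
  expect_true(length(g0) >= 1L)
  expect_error(genetic_search(evaluator, character(0L)), "zero features")
})

test_that("information gain and gain ratio behave on canonical cases", {
  n <- 200L
  label <- rep(c("HCC", "PAR"), n / 2L)
  df <- data.frame(copy = as.numeric(label == "HCC"),
                   flat = rep(3, n),
                   label = label)
  ig <- ranker_scores(df, "information_gain")
  expect_equal(ig[["copy"]], 1)
  expect_equal(ig[["flat"]], 0)
  gr <- ranker_scores(df, "gain_ratio")
  expect_equal(gr[["copy"]], 1) # H(f) = 1 bit as well
  expect_equal(gr[["flat"]], 0)
  expect_true(all(diff(unname(ig)) <= 0)) # sorted descending
})

test_that("permuted features carry (almost) no information gain", {
  for (seed in 1:10) {
    set.seed(seed * 13L)
    n <- 500L
    df <- data.frame(perm = rnorm(n),
                     label = sample(rep(c("HCC", "PAR"), n / 2L)))
    ig <- ranker_scores(df, "information_gain")
    expect_lt(ig[["perm"]], 0.05)
  }
})

test_that("select_relevant unions the four methods and keeps planted signal", {
  for (seed in 1:10) {
    df <- make_planted_table(n = 200L, n_noise = 6L, seed = seed)
    res <- select_relevant(df, seed = seed)
    expect_true("planted" %in% res$selected)
    expect_true(all(res$selected %in% setdiff(names(df), "label")))
    expect_true(all(res$cfs %in% res$selected))
    expect_true(all(res$consistency %in% res$selected))
    expect_true(all(names(res$information_gain)[res$information_gain > 0.3]
                    %in% res$selected))
  }
})

test_that("the selected set is invariant to feature column order", {
  df <- make_planted_table(n = 150L, n_noise = 4L, seed = 35)
  perm <- df[, c("noise2", "planted", "noise4", "noise1", "noise3", "label")]
  a <- select_relevant(df, seed = 3)
  b <- select_relevant(perm, seed = 3)
  expect_setequal(a$selected, b$selected)
})
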