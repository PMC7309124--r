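# Separable two-feature table: class means far apart relative to noise.
make_separable_table <- function(n = 120L, gap = 4, seed = 41L) {
  set.seed(seed)
  label <- rep(c("HCC", "PAR"), n / 2L)
  mu <- ifelse(label == "HCC", gap, 0)
  data.frame(f1 = mu + rnorm(n), f2 = -mu + rnorm(n), label = label,
             patient_id = sprintf("P%03d", seq_len(n)))
}

test_that("classifier specs carry the clinical defaults", {
  expect_equal(make_spec("random_forest")$hyperparameters$n_trees, 100L)
  expect_equal(make_spec("adaboost_trees")$hyperparameters$n_rounds, 100L)
  mlp <- make_spec("mlp")$hyperparameters
  expect_equal(mlp$learning_rate, 0.2)
  expect_equal(mlp$momentum, 0.8)
  expect_equal(mlp$epochs, 500L)
  expect_equal(mlp_base_width(46L, 2L), 24L)
  expect_error(make_spec("svm_linear", overrides = list(bogus = 1)),
               "unknown hyperparameters")
})

test_that("all four classifiers separate an easy problem", {
  tab <- make_separable_table()
  for (kind in c("svm_linear", "random_forest", "adaboost_trees", "mlp")) {
    spec <- make_spec(kind,
                      overrides = if (kind == "mlp")
                        list(epochs = 100L, layer_grid = 1L) else list(),
                      seed = 5L)
    mdl <- fit(spec, tab)
    sc <- predict_scores(mdl, tab)
    expect_true(all(abs(rowSums(sc) - 1) < 1e-8))
    expect_true(all(sc >= 0 & sc <= 1))
    acc <- mean(ifelse(sc[, "HCC"] > 0.5, "HCC", "PAR") == tab$label)
    expect_gte(acc, 0.95)
  }
})

test_that("the linear SVM attains perfect training accuracy when separable", {
  tab <- make_separable_table(gap = 8)
  mdl <- fit(make_spec("svm_linear"), tab)
  sc <- predict_scores(mdl, tab)
  expect_equal(mean(ifelse(sc[, "HCC"] > 0.5, "HCC", "PAR") == tab$label), 1)
})

test_that("fits are deterministic given the seed", {
  tab <- make_separable_table(seed = 42L)
  for (kind in c("svm_linear", "random_forest", "adaboost_trees")) {
    m1 <- fit(make_spec(kind, seed = 9L), tab)
    m2 <- fit(make_spec(kind, seed = 9L), tab)
    expect_equal(predict_scores(m1, tab), predict_scores(m2, tab))
  }
})

test_that("degenerate inputs are rejected", {
  tab <- make_separable_table()
  one <- tab[tab$label == "HCC", ]
  expect_error(fit(make_spec("svm_linear"), one), "single-class")
  bad <- tab; bad$f1[1L] <- NA
  expect_error(fit(make_spec("random_forest"), bad), "non-finite")
})

test_that("prediction requires matching feature order", {
  tab <- make_separable_table()
  mdl <- fit(make_spec("random_forest"), tab)
  swapped <- tab[, c("f2", "f1", "label", "patient_id")]
  expect_error(predict_scores(mdl, swapped), "feature columns")
})

test_that("row permutation permutes scores identically", {
  tab <- make_separable_table(seed = 43L)
  mdl <- fit(make_spec("svm_linear"), tab)
  perm <- sample(nrow(tab))
  sc <- predict_scores(mdl, tab)
  sc_perm <- predict_scores(mdl, tab[perm, ])
  expect_equal(unname(sc_perm), unname(sc[perm, ]), tolerance = 1e-10)
})

test_that("run_comparison reports one row per spec and selection variant", {
  tab <- make_separable_table(n = 100L)
  specs <- list(make_spec("svm_linear", seed = 1L),
                make_spec("random_forest", seed = 1L))
  rep_ <- run_comparison(tab, selection = "f1", specs = specs,
                         split = split_spec(0.8, 0, 0.2,
                                            group_by_patient = FALSE,
                                            seed = 2L))
  expect_equal(nrow(rep_), 4L)
  expect_setequal(unique(rep_$selection), c("before", "after"))
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1))
  expect_true(all(rep_$auc >= 0.9)) # easy problem
  expect_equal(rep_$n_features[rep_$selection == "after"], c(1L, 1L))
})

test_that("pure-noise features do not lift the linear SVM on easy data", {
  base <- make_separable_table(n = 160L, seed = 44L)
  aucs <- matrix(NA_real_, 5L, 2L)
  for (s in 1:5) {
    set.seed(100L + s)
    noisy <- base
    for (j in 1:5) noisy[[paste0("junk", j)]] <- rnorm(nrow(base))
    noisy <- noisy[, c(setdiff(names(noisy), c("label", "patient_id")),
                       "label", "patient_id")]
    spl <- split_spec(0.8, 0, 0.2, group_by_patient = FALSE, seed = s)
    r1 <- run_comparison(base, specs = list(make_spec("svm_linear", seed = s)),
                         split = spl)
    r2 <- run_comparison(noisy, specs = list(make_spec("svm_linear", seed = s)),
                         split = spl)
    aucs[s, ] <- c(r1$auc, r2$auc)
  }
  expect_true(all(aucs[, 2L] - aucs[, 1L] <= 0.05))
})
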