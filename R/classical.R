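# The four conventional classifiers: linear-kernel SVM (normalized inputs),
# multi-layer perceptron with the clinical topology grid, random forest
# (100 trees) and AdaBoost.M1 over information-gain decision trees.

POSITIVE_CLASS <- "HCC"

#' Classifier specification
#'
#' Defaults follow the clinical protocol: `svm_linear` is a degree-1
#' polynomial (linear) kernel SVM with C = 1 on min-max normalized
#' features; `random_forest` uses 100 trees; `adaboost_trees` uses 100
#' boosting rounds over entropy-split decision trees; `mlp` searches hidden
#' topologies \{1, 2, 3 layers\} x \{a, a/2, a/3\} nodes with
#' `a = floor((n_features + n_classes) / 2)`, learning rate 0.2, momentum
#' 0.8 and 500 epochs, keeping the best topology by an internal 90/10
#' validation split.
#'
#' @param kind One of `"svm_linear"`, `"mlp"`, `"random_forest"`,
#'   `"adaboost_trees"`.
#' @param overrides Named list of hyperparameter overrides.
#' @param seed Integer seed.
#' @return An object of class `classifier_spec`.
#' @export
make_spec <- function(kind = c("svm_linear", "mlp", "random_forest",
                               "adaboost_trees"),
                      overrides = list(), seed = 1L) {
  kind <- match.arg(kind)
  hp <- switch(kind,
    svm_linear = list(cost = 1),
    random_forest = list(n_trees = 100L),
    adaboost_trees = list(n_rounds = 100L),
    mlp = list(learning_rate = 0.2, momentum = 0.8, epochs = 500L,
               batch_size = 32L, layer_grid = 1:3,
               width_divisors = c(1, 2, 3)))
  unknown <- setdiff(names(overrides), names(hp))
  if (length(unknown)) stop("unknown hyperparameters: ",
                            paste(unknown, collapse = ", "))
  hp[names(overrides)] <- overrides
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Hidden-layer width of the clinical MLP grid
#'
#' @param n_features,n_classes Input and output dimensions.
#' @return `a = floor((n_features + n_classes) / 2)`.
#' @export
mlp_base_width <- function(n_features, n_classes = 2L) {
  as.integer((n_features + n_classes) %/% 2L)
}

minmax_fit <- function(X) {
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}

minmax_apply <- function(X, s) {
  sweep(sweep(X, 2L, s$lo, "-"), 2L, s$rng, "/")
}

# --- hand-rolled MLP ------------------------------------------------------

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fan_in <- sizes[i]; fan_out <- sizes[i + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_out * fan_in, -lim, lim), fan_out, fan_in),
         b = numeric(fan_out))
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(layers, X) { # X: n x d
  A <- t(X)
  acts <- list(A)
  L <- length(layers)
  for (i in seq_len(L)) {
    Z <- layers[[i]]$W %*% A + layers[[i]]$b
    A <- if (i < L) sigmoid(Z) else {
      E <- exp(sweep(Z, 2L, apply(Z, 2L, max), "-"))
      sweep(E, 2L, colSums(E), "/")
    }
    acts[[i + 1L]] <- A
  }
  list(probs = t(A), acts = acts)
}

mlp_train <- function(X, y01, sizes, lr, momentum, epochs, batch_size) {
  layers <- mlp_init(sizes)
  vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  n <- nrow(X)
  L <- length(layers)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (at in seq(1L, n, by = batch_size)) {
      ids <- ord[at:min(n, at + batch_size - 1L)]
      fw <- mlp_forward(layers, X[ids, , drop = FALSE])
      m <- length(ids)
      delta <- t(fw$probs)
      delta[cbind(y01[ids] + 1L, seq_len(m))] <-
        delta[cbind(y01[ids] + 1L, seq_len(m))] - 1
      delta <- delta / m
      for (i in seq.int(L, 1L)) {
        A_prev <- fw$acts[[i]]
        gW <- delta %*% t(A_prev)
        gb <- rowSums(delta)
        if (i > 1L) {
          A <- fw$acts[[i]]
          delta <- (t(layers[[i]]$W) %*% delta) * A * (1 - A)
        }
        vel[[i]]$W <- momentum * vel[[i]]$W - lr * gW
        vel[[i]]$b <- momentum * vel[[i]]$b - lr * gb
        layers[[i]]$W <- layers[[i]]$W + vel[[i]]$W
        layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
      }
    }
  }
  layers
}

fit_mlp <- function(X, y, hp, seed) {
  classes <- levels(y)
  y01 <- as.integer(y) - 1L
  a <- mlp_base_width(ncol(X), length(classes))
  topologies <- list()
  for (nl in hp$layer_grid) {
    for (dv in hp$width_divisors) {
      wdt <- max(1L, a %/% dv)
      topologies[[length(topologies) + 1L]] <- rep(wdt, nl)
    }
  }
  with_seed(seed, {
    n <- nrow(X)
    val_n <- max(1L, round(0.1 * n))
    ord <- sample.int(n)
    val_ids <- ord[seq_len(val_n)]
    tr_ids <- ord[-seq_len(val_n)]
    best <- NULL; best_acc <- -1
    for (topo in topologies) {
      sizes <- c(ncol(X), topo, length(classes))
      layers <- mlp_train(X[tr_ids, , drop = FALSE], y01[tr_ids], sizes,
                          hp$learning_rate, hp$momentum, hp$epochs,
                          hp$batch_size)
      pv <- mlp_forward(layers, X[val_ids, , drop = FALSE])$probs
      acc <- mean((pv[, 2L] > 0.5) == (y01[val_ids] == 1L))
      if (acc > best_acc) { best_acc <- acc; best <- layers }
    }
    best
  })
}

# --- hand-rolled AdaBoost.M1 over entropy trees ---------------------------

fit_adaboost <- function(X, y, n_rounds, seed) {
  df <- data.frame(X, check.names = FALSE)
  df$.y <- y
  n <- nrow(df)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0L)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fitm <- rpart::rpart(.y ~ ., data = df, weights = w,
                           method = "class",
                           parms = list(split = "information"),
                           control = rpart::rpart.control(cp = 0.01,
                                                          xval = 0L))
      pred <- predict(fitm, df, type = "class")
      err <- sum(w[pred != y]) / sum(w)
      if (err >= 0.5) break
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err)
      learners[[length(learners) + 1L]] <- fitm
      alphas <- c(alphas, alpha)
      if (err == 1e-10) break # perfect learner: reweighting degenerates
      w <- w * exp(alpha * (pred != y))
      w <- w / sum(w)
    }
  })
  list(learners = learners, alphas = alphas, classes = levels(y))
}

predict_adaboost <- function(model, X) {
  df <- data.frame(X, check.names = FALSE)
  votes <- matrix(0, nrow(df), length(model$classes))
  colnames(votes) <- model$classes
  for (i in seq_along(model$learners)) {
    pred <- predict(model$learners[[i]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + model$alphas[i]
  }
  sweep(votes, 1L, pmax(rowSums(votes), .Machine$double.eps), "/")
}

# --- unified fit / predict ------------------------------------------------

#' Fit a conventional classifier
#'
#' @param spec A [make_spec()] specification.
#' @param train_table Feature data frame with a `label` column (two
#'   classes, finite features; a `patient_id` column is ignored).
#' @return An object of class `trained_model` that remembers the feature
#'   order used at fit time.
#' @export
fit <- function(spec, train_table) {
  stopifnot(inherits(spec, "classifier_spec"))
  fm <- feature_matrix(train_table)
  if (!all(is.finite(fm$X))) stop("non-finite feature values")
  y <- factor(fm$y, levels = sort(unique(fm$y)))
  if (nlevels(y) < 2L) stop("single-class training data")
  hp <- spec$hyperparameters
  state <- switch(spec$kind,
    svm_linear = {
      sc <- minmax_fit(fm$X)
      Xn <- minmax_apply(fm$X, sc)
      mdl <- with_seed(spec$seed,
        e1071::svm(Xn, y, kernel = "linear", cost = hp$cost, scale = FALSE,
                   probability = TRUE))
      list(model = mdl, scaler = sc)
    },
    random_forest = {
      mdl <- with_seed(spec$seed,
        randomForest::randomForest(fm$X, y, ntree = hp$n_trees))
      list(model = mdl)
    },
    adaboost_trees = list(model = fit_adaboost(fm$X, y, hp$n_rounds,
                                               spec$seed)),
    mlp = {
      sc <- minmax_fit(fm$X)
      Xn <- minmax_apply(fm$X, sc)
      list(model = fit_mlp(Xn, y, hp, spec$seed), scaler = sc)
    })
  structure(list(spec = spec, state = state, feature_order = fm$names,
                 classes = levels(y)),
            class = "trained_model")
}

#' Class scores of a trained model
#'
#' @param model A [fit()] result.
#' @param table Feature data frame with the same feature columns (order is
#'   checked against the fit-time order).
#' @return Matrix of per-row class probabilities in `[0, 1]`, one column
#'   per class, rows summing to 1.
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "trained_model"))
  fm <- feature_matrix(table)
  if (!identical(fm$names, model$feature_order)) {
    stop("feature columns do not match the model's fit-time order")
  }
  X <- fm$X
  kind <- model$spec$kind
  probs <- switch(kind,
    svm_linear = {
      Xn <- minmax_apply(X, model$state$scaler)
      pr <- predict(model$state$model, Xn, probability = TRUE)
      attr(pr, "probabilities")[, model$classes, drop = FALSE]
    },
    random_forest = predict(model$state$model, X, type = "prob")[,
                            model$classes, drop = FALSE],
    adaboost_trees = predict_adaboost(model$state$model, X)[,
                            model$classes, drop = FALSE],
    mlp = {
      Xn <- minmax_apply(X, model$state$scaler)
      pr <- mlp_forward(model$state$model, Xn)$probs
      colnames(pr) <- model$classes
      pr
    })
  probs <- pmin(pmax(probs, 0), 1)
  sweep(probs, 1L, pmax(rowSums(probs), .Machine$double.eps), "/")
}

#' Compare conventional classifiers before/after feature selection
#'
#' For each specification: stratified seeded 80/20 split, fit on the
#' training portion (with all features and, when `selection` is given,
#' restricted to the selected features) and evaluation on the held-out
#' portion with HCC as the positive class.
#'
#' @param features_table Feature data frame with a `label` column.
#' @param selection Optional character vector of selected feature names.
#' @param specs List of [make_spec()] specifications.
#' @param split A [split_spec()]; defaults to a stratified (non-grouped)
#'   80/20 split.
#' @return Data frame with one row per spec x \{before, after\} selection:
#'   accuracy, sensitivity, specificity, AUC.
#' @export
run_comparison <- function(features_table, selection = NULL,
                           specs = lapply(c("svm_linear", "mlp",
                                            "random_forest",
                                            "adaboost_trees"), make_spec),
                           split = split_spec(group_by_patient = FALSE)) {
  if (!"label" %in% names(features_table)) stop("table has no labels")
  idx <- split_table_indices(features_table, split)
  variants <- if (is.null(selection)) list(before = NULL)
              else list(before = NULL, after = selection)
  rows <- list()
  for (v in names(variants)) {
    tab <- features_table
    if (!is.null(variants[[v]])) {
      keep <- c(variants[[v]], intersect(c("label", "patient_id"), names(tab)))
      tab <- tab[, keep, drop = FALSE]
    }
    for (spec in specs) {
      mdl <- fit(spec, tab[idx$train, , drop = FALSE])
      sc <- predict_scores(mdl, tab[idx$test, , drop = FALSE])
      rep_ <- evaluate_scores(tab$label[idx$test], sc[, POSITIVE_CLASS])
      rows[[length(rows) + 1L]] <- data.frame(
        method = spec$kind, selection = v,
        n_features = length(setdiff(names(tab), c("label", "patient_id"))),
        accuracy = rep_$accuracy, sensitivity = rep_$sensitivity,
        specificity = rep_$specificity, auc = rep_$auc)
    }
  }
  do.call(rbind, rows)
}

# Stratified (or patient-grouped) train/validation/test row indices of a
# feature table.
split_table_indices <- function(table, split) {
  pids <- if ("patient_id" %in% names(table)) table$patient_id
          else as.character(seq_len(nrow(table)))
  split_indices(table$label, pids, split)
}
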