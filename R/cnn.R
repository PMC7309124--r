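# R-side interface of the multi-resolution ASPP network. The compute
# engine (im2col convolutions, batch normalization, max-pooling, SGD with
# momentum) lives in src/cnn.cpp.

#' Network configuration
#'
#' The architecture: two parallel multi-resolution convolution blocks
#' (kernels `2p+1` for `p = 1, 2, 3`, i.e. 3/5/7, each with NF filters,
#' half-kernel padding, each convolution followed by ReLU and batch
#' normalization), shortcut concatenations of each block's input, 2x2/2
#' max-pooling after each block, then an ASPP module with 5 branches (1x1
#' convolution; 3x3 dilated convolutions at atrous rates 2, 3, 4 with
#' padding equal to the rate; adaptive average pooling with a 1x1
#' convolution broadcast back) fused by a 1x1 convolution with batch
#' normalization and dropout, and a single fully connected layer to 2
#' softmax classes.
#'
#' @param nf1,nf2,nf3 Filter counts of block 1, block 2 and the ASPP.
#' @param atrous_rates Dilation rates of the three dilated branches.
#' @param dropout Dropout probability after the ASPP fusion (default 0.5).
#' @param input_size Input patch side (default 56; must be divisible by 4).
#' @param n_classes Number of output classes (2: HCC vs PAR).
#' @param relu_before_bn Use the published conv -> ReLU -> BN ordering
#'   (default `TRUE`); `FALSE` gives the conventional conv -> BN -> ReLU.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(nf1 = 128L, nf2 = nf1, nf3 = nf2,
                       atrous_rates = c(2L, 3L, 4L), dropout = 0.5,
                       input_size = 56L, n_classes = 2L,
                       relu_before_bn = TRUE) {
  stopifnot(nf1 >= 1L, nf2 >= 1L, nf3 >= 1L, all(atrous_rates >= 1L),
            dropout >= 0, dropout < 1, input_size %% 4L == 0L,
            n_classes == 2L)
  if (input_size / 4L < 2L * max(atrous_rates) + 1L) {
    stop("input too small for the largest dilation")
  }
  structure(list(nf1 = as.integer(nf1), nf2 = as.integer(nf2),
                 nf3 = as.integer(nf3), kernel_set = c(3L, 5L, 7L),
                 atrous_rates = as.integer(atrous_rates),
                 dropout = dropout, input_size = as.integer(input_size),
                 n_classes = 2L, relu_before_bn = isTRUE(relu_before_bn)),
            class = "cnn_config")
}

#' Filter-count setups of the architecture study
#'
#' Setup 1 shrinks the feature space with depth (`NF2 = NF1/2`,
#' `NF3 = NF1/4`), setup 2 grows it (`NF2 = 2 NF1`, `NF3 = 4 NF2`), setup
#' 3 keeps it constant (`NF1 = NF2 = NF3`, the best-performing
#' configuration).
#'
#' @param setup 1, 2 or 3.
#' @param nf1 First-block filter count.
#' @param ... Passed to [cnn_config()].
#' @return A [cnn_config()].
#' @export
cnn_setup <- function(setup, nf1 = 128L, ...) {
  stopifnot(setup %in% 1:3)
  nf1 <- as.integer(nf1)
  switch(setup,
         cnn_config(nf1 = nf1, nf2 = max(1L, nf1 %/% 2L),
                    nf3 = max(1L, nf1 %/% 4L), ...),
         cnn_config(nf1 = nf1, nf2 = 2L * nf1, nf3 = 8L * nf1, ...),
         cnn_config(nf1 = nf1, nf2 = nf1, nf3 = nf1, ...))
}

glorot_mat <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Build the multi-resolution ASPP model
#'
#' Initializes all convolution and fully-connected weights with
#' Glorot-uniform draws, batch-normalization scale/shift at 1/0, and
#' running statistics at 0/1. Deterministic given `seed`.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for the initialization.
#' @return Object of class `multires_cnn` holding the parameter list, the
#'   configuration and the (empty) training history.
#' @export
build_model <- function(config = cnn_config(), seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  nf1 <- config$nf1; nf2 <- config$nf2; nf3 <- config$nf3
  s4 <- (config$input_size %/% 4L)^2
  c1 <- 3L * nf1 + 1L           # block-1 concat channels
  c2 <- 3L * nf2 + c1           # block-2 concat channels
  defs <- list(
    b1k3 = c(nf1, 1L, 3L), b1k5 = c(nf1, 1L, 5L), b1k7 = c(nf1, 1L, 7L),
    b2k3 = c(nf2, c1, 3L), b2k5 = c(nf2, c1, 5L), b2k7 = c(nf2, c1, 7L),
    a1 = c(nf3, c2, 1L), a2 = c(nf3, c2, 3L), a3 = c(nf3, c2, 3L),
    a4 = c(nf3, c2, 3L), a5 = c(nf3, c2, 1L), fus = c(nf3, 5L * nf3, 1L))
  params <- with_seed(seed, {
    p <- list()
    for (nm in names(defs)) {
      d <- defs[[nm]]
      p[[paste0(nm, ".W")]] <- glorot_mat(d[1L], d[2L] * d[3L]^2)
      p[[paste0(nm, ".b")]] <- numeric(d[1L])
      p[[paste0(nm, ".gamma")]] <- rep(1, d[1L])
      p[[paste0(nm, ".beta")]] <- numeric(d[1L])
      p[[paste0(nm, ".rmean")]] <- numeric(d[1L])
      p[[paste0(nm, ".rvar")]] <- rep(1, d[1L])
    }
    p[["fc.W"]] <- glorot_mat(2L, nf3 * s4)
    p[["fc.b"]] <- numeric(2L)
    p
  })
  structure(list(params = params, config = config, history = NULL,
                 seed = as.integer(seed)),
            class = "multires_cnn")
}

#' @export
print.multires_cnn <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1L)))
  cat(sprintf(
    "<multires_cnn> NF1=%d NF2=%d NF3=%d, input %dx%d, %d parameters%s\n",
    cfg$nf1, cfg$nf2, cfg$nf3, cfg$input_size, cfg$input_size, n_par,
    if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

cfg_for_cpp <- function(config) {
  list(nf1 = config$nf1, nf2 = config$nf2, nf3 = config$nf3,
       input_size = config$input_size, dropout = config$dropout,
       relu_before_bn = config$relu_before_bn,
       atrous_rates = as.integer(config$atrous_rates))
}

# Stack patches (list of us_patch or matrices) into the C++ input cube,
# scaled to [0, 1].
patches_to_array <- function(patches, input_size) {
  n <- length(patches)
  arr <- array(0, c(1L, input_size * input_size, n))
  for (i in seq_len(n)) {
    px <- if (inherits(patches[[i]], "us_patch")) patches[[i]]$pixels
          else patches[[i]]
    if (nrow(px) != input_size || ncol(px) != input_size) {
      stop("patch size does not match the network input size")
    }
    arr[1L, , i] <- as.numeric(px) / 255
  }
  arr
}

patch_labels01 <- function(patches) {
  lab <- vapply(patches, function(p) p$label, character(1L))
  as.integer(lab == POSITIVE_CLASS) # HCC = 1, PAR = 0
}

#' Stage-by-stage volume shapes
#'
#' Probes the built network with a random input and reports the actual
#' channel/height/width of every stage volume (the shapes are measured on
#' the computed volumes, not re-derived from the architecture formulas).
#'
#' @param config A [cnn_config()] (or a `multires_cnn` model).
#' @param input_size Probe input side (default: the config's).
#' @return Named list of `c(channels, height, width)` per stage plus the
#'   ASPP branch count.
#' @export
shape_report <- function(config, input_size = NULL) {
  model <- if (inherits(config, "multires_cnn")) config
           else build_model(config, seed = 1L)
  cfg <- model$config
  input_size <- input_size %||% cfg$input_size
  x <- array(with_seed(7L, runif(input_size^2)),
             c(1L, input_size * input_size, 1L))
  cpp_cnn_shapes(model$params, cfg_for_cpp(cfg), x)
}

#' Training configuration
#'
#' Clinical protocol defaults: 100 epochs, mini-batch 64, stochastic
#' gradient descent with learning rate 1e-4 and momentum 0.1.
#'
#' @param epochs,batch_size,learning_rate,momentum,seed Training
#'   hyperparameters.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         learning_rate = 1e-4, momentum = 0.1, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, momentum >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the network
#'
#' SGD with the configured hyperparameters; per-epoch mean training loss
#' and validation accuracy (evaluation mode) are recorded and the returned
#' model carries the parameters of the epoch with the best validation
#' accuracy. Seeded end to end (shuffling, dropout).
#'
#' @param model A [build_model()] result.
#' @param train_patches,val_patches Lists of [us_patch()] with binary
#'   HCC/PAR labels (validation may be empty, in which case the final
#'   epoch is kept).
#' @param tc A [train_config()].
#' @return The trained `multires_cnn`; `$history` holds `train_loss`,
#'   `val_acc`, `best_epoch` and the first-step update norms.
#' @export
train_cnn <- function(model, train_patches, val_patches = list(),
                      tc = train_config()) {
  stopifnot(inherits(model, "multires_cnn"), inherits(tc, "train_config"))
  if (length(train_patches) == 0L) stop("empty training data")
  cfg <- model$config
  X <- patches_to_array(train_patches, cfg$input_size)
  y <- patch_labels01(train_patches)
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  Xv <- if (length(val_patches)) patches_to_array(val_patches, cfg$input_size)
        else array(0, c(1L, cfg$input_size^2, 0L))
  yv <- if (length(val_patches)) patch_labels01(val_patches) else integer(0L)
  res <- cpp_cnn_train(model$params, cfg_for_cpp(cfg), X, y, Xv, yv,
                       tc$epochs, tc$batch_size, tc$learning_rate,
                       tc$momentum, tc$seed)
  model$params <- res$best_params
  model$final_params <- res$final_params
  model$history <- list(train_loss = as.numeric(res$train_loss),
                        val_acc = as.numeric(res$val_acc),
                        best_epoch = res$best_epoch,
                        first_step_update_norms =
                          res$first_step_update_norms)
  model
}

#' Class probabilities of the network
#'
#' Evaluation mode: running batch-norm statistics, no dropout; rows sum
#' to 1.
#'
#' @param model A `multires_cnn`.
#' @param patches List of [us_patch()] or intensity matrices of the input
#'   size.
#' @return Matrix with columns `PAR` and `HCC`, one row per patch.
#' @export
predict_proba <- function(model, patches) {
  stopifnot(inherits(model, "multires_cnn"))
  X <- patches_to_array(patches, model$config$input_size)
  pr <- cpp_cnn_predict(model$params, cfg_for_cpp(model$config), X)
  colnames(pr) <- c("PAR", POSITIVE_CLASS)
  pr
}

#' A confidence-map scorer backed by a trained network
#'
#' @param model A trained `multires_cnn`.
#' @return Function mapping a window matrix to its HCC probability, for
#'   [confidence_map()].
#' @export
cnn_scorer <- function(model) {
  function(window) predict_proba(model, list(window))[1L, POSITIVE_CLASS]
}
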