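#' Rectified linear unit
#'
#' `f(x) = max(0, x)`: returns 0 for any negative input and the input itself
#' for any positive input. Vectorized.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' Softmax activation
#'
#' `sigma(z)_j = exp(z_j) / sum_k exp(z_k)`, converting a score vector into a
#' probability vector. Computed with max-subtraction so that arbitrarily
#' large scores do not overflow. For a matrix, rows are treated as
#' independent score vectors.
#'
#' @param z Numeric vector, or matrix with one score vector per row.
#' @return Probabilities of the same shape; each (row) vector sums to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    zm <- z - apply(z, 1, max)
    e <- exp(zm)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Configuration of the feed-forward network
#'
#' Defaults follow the classification setup used throughout the package: two
#' hidden layers of 128 ReLU neurons, softmax output over the treatment
#' classes, categorical cross-entropy minimized with Adam
#' (beta1 = 0.9, beta2 = 0.999), and vector-normalized 1800-900 cm^-1
#' spectra as input. Training is full-batch by default: with a few dozen
#' training spectra, minibatch gradient noise measurably destabilizes the
#' decision boundary (held-out predictions vary wildly with the shuffling
#' seed), while full-batch Adam converges to a reproducible, well-
#' generalizing solution. Epochs and learning rate are chosen for stable
#' convergence at that scale; all are tunable here.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths (all >= 1).
#' @param epochs Training epochs, >= 1.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size; `NULL` (default) trains full-batch.
#'   Values larger than the training-set size are truncated to it.
#' @param seed Integer seed; fold seeds in LOOCV derive from it.
#' @param input_region `c(lo, hi)` cm^-1 region fed to the network.
#' @return An `ann_config` list.
#' @export
ann_config <- function(hidden_sizes = c(128, 128), epochs = 500,
                       learning_rate = 3e-3, batch_size = NULL, seed = 1,
                       input_region = c(900, 1800)) {
  if (any(hidden_sizes < 1) || length(hidden_sizes) < 1) {
    vs_abort("hidden_sizes must all be >= 1", "valvespectra_value_error")
  }
  if (epochs < 1) vs_abort("epochs must be >= 1", "valvespectra_value_error")
  if (!(learning_rate > 0)) {
    vs_abort("learning_rate must be positive", "valvespectra_value_error")
  }
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = if (is.null(batch_size)) NULL else
                   as.integer(batch_size),
                 seed = as.integer(seed),
                 input_region = as.numeric(input_region)),
            class = "ann_config")
}

# feature matrix for the classifier: per-specimen vector-normalized region
spectra_to_features <- function(set, region) {
  region_matrix(set, sort(region), normalize = TRUE)
}

ann_forward <- function(W, b, X) {
  L <- length(W)
  Z <- vector("list", L)
  A <- X
  acts <- vector("list", L)  # post-activation per layer (last = logits)
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A %*% W[[l]], 2, b[[l]], `+`)
    A <- if (l < L) relu(Z[[l]]) else Z[[l]]
    acts[[l]] <- A
  }
  list(Z = Z, A = acts, probs = softmax(acts[[L]]))
}

ann_loss_acc <- function(probs, yidx) {
  p <- pmax(probs[cbind(seq_len(nrow(probs)), yidx)], 1e-12)
  list(loss = -mean(log(p)),
       accuracy = mean(max.col(probs, ties.method = "first") == yidx))
}

#' Train the feed-forward classifier
#'
#' Dense ReLU network with a softmax output layer, trained by minibatch Adam
#' on the categorical cross-entropy. Labels are one-hot encoded in treatment
#' enum order (this order defines confusion-matrix axes everywhere).
#' Training is deterministic: the specimen order is canonicalized before
#' seeding, weights are initialized from `config$seed` (He-scaled normal),
#' and identical data + config + seed reproduce identical weights bitwise.
#'
#' @param x A [spectrum_set()] (features taken from `config$input_region`,
#'   vector-normalized) or a ready feature matrix (specimens x features).
#' @param labels Class label per specimen; defaults to the set's treatments.
#' @param config An [ann_config()].
#' @param record_history Evaluate loss/accuracy on the full training data
#'   after every epoch. Costs one extra forward pass per epoch; cross-
#'   validation folds switch it off.
#' @return An `ann_model`: weights `W`/`b` per layer, `class_order`,
#'   `feature_grid`, `config`, and `training_history` (tibble: epoch, loss,
#'   accuracy on the training data; empty when `record_history = FALSE`).
#' @export
train_ann <- function(x, labels = NULL, config = ann_config(),
                      record_history = TRUE) {
  if (inherits(x, "spectrum_set")) {
    if (is.null(labels)) labels <- set_metadata(x)$treatment
    X <- spectra_to_features(x, config$input_region)
  } else {
    X <- as.matrix(x)
  }
  if (is.null(labels)) {
    vs_abort("labels are required when x is a matrix", "valvespectra_class_error")
  }
  labels <- as.character(labels)
  lev <- if (all(unique(labels) %in% treatment_levels())) {
    intersect(treatment_levels(), unique(labels))
  } else unique(labels)
  if (length(lev) < 2L) {
    vs_abort("training set contains a single class", "valvespectra_class_error")
  }
  yidx <- match(labels, lev)
  # canonicalize sample order so input ordering cannot influence the RNG stream
  key <- vapply(seq_len(nrow(X)), function(i) {
    paste(format(X[i, ], digits = 17), collapse = ",")
  }, character(1))
  ord <- order(yidx, key)
  X <- X[ord, , drop = FALSE]
  yidx <- yidx[ord]

  n <- nrow(X)
  K <- length(lev)
  sizes <- c(ncol(X), config$hidden_sizes, K)
  L <- length(sizes) - 1L

  set.seed(config$seed)
  W <- vector("list", L); b <- vector("list", L)
  mW <- vector("list", L); vW <- vector("list", L)
  mb <- vector("list", L); vb <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
    mW[[l]] <- matrix(0, sizes[l], sizes[l + 1]); vW[[l]] <- mW[[l]]
    mb[[l]] <- numeric(sizes[l + 1]); vb[[l]] <- mb[[l]]
  }
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yidx)] <- 1

  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L
  hist_loss <- if (record_history) numeric(config$epochs) else numeric(0)
  hist_acc <- hist_loss

  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  for (ep in seq_len(config$epochs)) {
    perm <- if (bs < n) sample.int(n) else seq_len(n)
    starts <- seq(1L, n, by = bs)
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fw <- ann_forward(W, b, Xb)
      # backprop: softmax + cross-entropy gives dlogits = (P - Y)/m
      dZ <- (fw$probs - Yb) / length(idx)
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step
      corr2 <- 1 - beta2^t_step
      for (l in rev(seq_len(L))) {
        Ain <- if (l == 1L) Xb else relu(fw$Z[[l - 1L]])
        gW <- crossprod(Ain, dZ)
        gb <- colSums(dZ)
        if (l > 1L) {
          dZ <- (dZ %*% t(W[[l]])) * (fw$Z[[l - 1L]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + adam_eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + adam_eps)
      }
    }
    if (record_history) {
      fw <- ann_forward(W, b, X)
      la <- ann_loss_acc(fw$probs, yidx)
      hist_loss[ep] <- la$loss
      hist_acc[ep] <- la$accuracy
    }
  }

  structure(list(W = W, b = b, class_order = lev,
                 feature_grid = as.numeric(colnames(X)),
                 config = config,
                 training_history = tibble::tibble(
                   epoch = seq_along(hist_loss),
                   loss = hist_loss, accuracy = hist_acc)),
            class = "ann_model")
}

#' @param object An `ann_model`.
#' @param newdata A [spectrum_set()] or feature matrix.
#' @param ... Unused.
#' @return List with `class` (character vector) and `probabilities`
#'   (specimens x classes; rows sum to 1).
#' @rdname train_ann
#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectrum_set")) {
    spectra_to_features(newdata, object$config$input_region)
  } else as.matrix(newdata)
  probs <- ann_forward(object$W, object$b, X)$probs
  colnames(probs) <- object$class_order
  idx <- max.col(probs, ties.method = "first")
  list(class = object$class_order[idx], probabilities = probs)
}

#' Leave-one-out cross-validation of the network
#'
#' For each of the n specimens a fresh network is trained on the remaining
#' n - 1 (weights re-initialized from a fold seed derived as
#' `config$seed + fold index`; no warm starts) and predicts the held-out
#' spectrum. The n held-out predictions form the aggregated confusion
#' matrix. A fold whose training set lost a whole class proceeds with a
#' warning.
#'
#' @param set A [spectrum_set()] with metadata (or feature matrix via
#'   `labels` + `x` in [train_ann()] semantics).
#' @param labels Class label per specimen; defaults to the treatments.
#' @param config An [ann_config()].
#' @return A `loocv_result`: `$predictions` (tibble: truth, predicted,
#'   correct, fold_seed), `$probabilities`, `$confusion`
#'   (a [confusion_matrix()]), `$accuracy` (fraction), `$class_order`.
#' @export
run_loocv <- function(set, labels = NULL, config = ann_config()) {
  if (inherits(set, "spectrum_set")) {
    if (is.null(labels)) labels <- set_metadata(set)$treatment
    X <- spectra_to_features(set, config$input_region)
  } else if (is.matrix(set) || is.data.frame(set)) {
    X <- as.matrix(set)
  } else {
    vs_abort("set must be a spectrum_set or a feature matrix",
             "valvespectra_value_error")
  }
  labels <- as.character(labels)
  n <- nrow(X)
  lev <- if (all(unique(labels) %in% treatment_levels())) {
    intersect(treatment_levels(), unique(labels))
  } else unique(labels)
  if (n < length(lev) + 1L) {
    vs_abort("LOOCV needs at least n_classes + 1 specimens",
             "valvespectra_size_error")
  }
  pred <- character(n)
  probs <- matrix(NA_real_, n, length(lev), dimnames = list(NULL, lev))
  fold_seeds <- config$seed + seq_len(n)
  for (i in seq_len(n)) {
    if (!all(lev %in% labels[-i])) {
      vs_warn(sprintf("fold %d: a class is absent from the training split", i),
              "valvespectra_missing_class_warning")
    }
    cfg_i <- config
    cfg_i$seed <- fold_seeds[i]
    mod <- train_ann(X[-i, , drop = FALSE], labels[-i], cfg_i,
                     record_history = FALSE)
    pr <- predict(mod, X[i, , drop = FALSE])
    pred[i] <- pr$class
    probs[i, colnames(pr$probabilities)] <- pr$probabilities[1, ]
  }
  loocv_result(truth = labels, predicted = pred, class_order = lev,
               probabilities = probs, fold_seeds = fold_seeds,
               classifier = "ann")
}

# shared container for LOOCV outcomes (ANN and PCA+LDA routes)
loocv_result <- function(truth, predicted, class_order, probabilities = NULL,
                         fold_seeds = NULL, classifier = "ann") {
  cm <- confusion_matrix(truth, predicted, class_order)
  structure(list(
    predictions = tibble::tibble(truth = truth, predicted = predicted,
                                 correct = truth == predicted),
    probabilities = probabilities,
    fold_seeds = fold_seeds,
    class_order = class_order,
    confusion = cm,
    accuracy = mean(truth == predicted),
    classifier = classifier
  ), class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s, %d folds, accuracy %.1f%%\n",
              x$classifier, nrow(x$predictions), 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Export a trained network as portable JSON
#'
#' Architecture, class order and weights as nested arrays; no
#' framework-specific binary format.
#'
#' @param model An `ann_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_ann_json <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(
    class_order = model$class_order,
    hidden_sizes = model$config$hidden_sizes,
    input_region = model$config$input_region,
    layers = lapply(seq_along(model$W), function(l) {
      list(weights = model$W[[l]], bias = model$b[[l]])
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
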