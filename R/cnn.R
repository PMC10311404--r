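# The convolutional window classifier.
#
# Architecture: a stack of "combined" layers (3x3 same-padding convolution +
# ReLU + max-pooling of size 2 along the SNP axis), followed by one or two
# ReLU dense layers and a softmax output. Convolutions are evaluated as
# im2col patch matrices multiplied on BLAS, so training and inference run at
# dgemm speed without any external deep-learning dependency. Optimizer:
# Adam (1e-3, beta1 0.9, beta2 0.999), cross-entropy loss, batch size 64.

#' Specify a CNN architecture
#'
#' The published search space covers 2-5 combined convolution+pooling layers,
#' filter counts 8/16/32/64 in constant, increasing, or decreasing form, and
#' 1-2 dense layers of size 16/32/64. The default (3 combined layers of 32
#' filters and one dense layer of 32 units) is the architecture used for
#' sweep detection.
#'
#' @param n_conv number of combined convolution+pooling layers.
#' @param filters filter count per layer; a scalar is expanded according to
#'   `form` (constant repeats it, increasing doubles it per layer,
#'   decreasing halves it).
#' @param form filter-count progression when `filters` is scalar.
#' @param dense sizes of the dense layer(s) (1 or 2 values).
#' @param n_classes number of output classes (>= 2).
#' @return an object of class `cnn_arch`.
#' @export
cnn_arch <- function(n_conv = 3, filters = 32,
                     form = c("constant", "increasing", "decreasing"),
                     dense = 32, n_classes = 2) {
  form <- match.arg(form)
  if (n_conv < 1) stop("at least one combined layer is required")
  if (!n_conv %in% 2:5)
    warning("n_conv outside the published search space {2,3,4,5}")
  if (length(filters) == 1) {
    filters <- switch(form,
                      constant = rep(filters, n_conv),
                      increasing = filters * 2^(seq_len(n_conv) - 1),
                      decreasing = filters * 2^-(seq_len(n_conv) - 1))
    filters <- as.integer(pmax(1, filters))
  }
  if (length(filters) != n_conv)
    stop("filters must have one entry per combined layer")
  if (any(filters < 1)) stop("filter counts must be positive")
  if (!length(dense) %in% 1:2)
    stop("1 or 2 dense layers are supported")
  if (any(dense < 1)) stop("dense sizes must be positive")
  if (n_classes < 2) stop("need at least 2 classes")
  structure(list(n_conv = as.integer(n_conv), filters = as.integer(filters),
                 form = form, dense = as.integer(dense),
                 n_classes = as.integer(n_classes)),
            class = "cnn_arch")
}

#' @export
print.cnn_arch <- function(x, ...) {
  cat(sprintf(
    "CNN: %d combined layer(s) [filters %s], dense %s, %d classes\n",
    x$n_conv, paste(x$filters, collapse = "/"),
    paste(x$dense, collapse = "/"), x$n_classes))
  invisible(x)
}

# ---- layer primitives ------------------------------------------------------

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# ---- parameter initialisation and the full forward/backward pass ----------

init_params <- function(arch, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]
  params <- list(conv = list(), dense = list())
  C <- 1
  for (i in seq_len(arch$n_conv)) {
    Fl <- arch$filters[i]
    params$conv[[i]] <- list(
      K = array(rnorm(9 * C * Fl, sd = sqrt(2 / (9 * C))), c(3, 3, C, Fl)),
      b = numeric(Fl))
    C <- Fl
    if (W < 2)
      stop(sprintf(
        "pooling layer %d: input width %d cannot be pooled below 1", i, W))
    W <- W %/% 2
  }
  feat <- H * W * C
  sizes <- c(feat, arch$dense, arch$n_classes)
  for (i in seq_len(length(sizes) - 1)) {
    fan <- sizes[i]
    params$dense[[i]] <- list(
      W = matrix(rnorm(sizes[i + 1] * fan, sd = sqrt(2 / fan)),
                 sizes[i + 1], fan),
      b = numeric(sizes[i + 1]))
  }
  params
}

# forward pass through the fused conv+ReLU+pool blocks (compiled) and the
# dense head; keep = TRUE retains intermediates for backprop
cnn_forward <- function(params, X, keep = FALSE) {
  cache <- list(conv = list())
  A <- X
  for (i in seq_along(params$conv)) {
    if (dim(A)[2] < 2)
      stop(sprintf(
        "pooling layer %d: input width %d cannot be pooled below 1",
        i, dim(A)[2]))
    cv <- .conv_block_forward_cpp(A, params$conv[[i]]$K,
                                  params$conv[[i]]$b, keep)
    if (keep)
      cache$conv[[i]] <- list(xdim = dim(A), patches = cv$patches,
                              code = cv$code)
    A <- cv$out
  }
  B <- dim(A)[4]
  ft <- matrix(A, ncol = B)
  cache$flat_dim <- dim(A)
  acts <- list(ft)
  nd <- length(params$dense)
  for (i in seq_len(nd)) {
    Z <- params$dense[[i]]$W %*% ft + params$dense[[i]]$b
    ft <- if (i < nd) Z * (Z > 0) else Z
    acts[[i + 1]] <- ft
  }
  if (keep) cache$dense_acts <- acts
  list(probs = softmax_cols(ft), cache = cache)
}

cnn_backward <- function(params, fw, Y) {
  cache <- fw$cache
  B <- ncol(Y)
  grads <- list(conv = vector("list", length(params$conv)),
                dense = vector("list", length(params$dense)))
  delta <- (fw$probs - Y) / B
  nd <- length(params$dense)
  for (i in rev(seq_len(nd))) {
    A <- cache$dense_acts[[i]]
    grads$dense[[i]] <- list(dW = delta %*% t(A), db = rowSums(delta))
    if (i > 1) {
      delta <- t(params$dense[[i]]$W) %*% delta
      delta <- delta * (A > 0)
    } else {
      delta <- t(params$dense[[i]]$W) %*% delta
    }
  }
  dA <- array(delta, cache$flat_dim)
  for (i in rev(seq_along(params$conv))) {
    cc <- cache$conv[[i]]
    bk <- .conv_block_backward_cpp(dA, cc$code, cc$patches,
                                   params$conv[[i]]$K, as.integer(cc$xdim))
    grads$conv[[i]] <- list(dK = bk$dK, db = bk$db)
    dA <- bk$dX
  }
  grads
}

adam_state <- function(params) {
  zero <- function(p) list(m = p * 0, v = p * 0)
  list(conv = lapply(params$conv,
                     function(l) list(K = zero(l$K), b = zero(l$b))),
       dense = lapply(params$dense,
                      function(l) list(W = zero(l$W), b = zero(l$b))))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (i in seq_along(params$conv)) {
    r <- upd(params$conv[[i]]$K, grads$conv[[i]]$dK, state$conv[[i]]$K)
    params$conv[[i]]$K <- r$p; state$conv[[i]]$K <- r$s
    r <- upd(params$conv[[i]]$b, grads$conv[[i]]$db, state$conv[[i]]$b)
    params$conv[[i]]$b <- r$p; state$conv[[i]]$b <- r$s
  }
  for (i in seq_along(params$dense)) {
    r <- upd(params$dense[[i]]$W, grads$dense[[i]]$dW, state$dense[[i]]$W)
    params$dense[[i]]$W <- r$p; state$dense[[i]]$W <- r$s
    r <- upd(params$dense[[i]]$b, grads$dense[[i]]$db, state$dense[[i]]$b)
    params$dense[[i]]$b <- r$p; state$dense[[i]]$b <- r$s
  }
  list(params = params, state = state)
}

# checkpoint rule: the epoch with the highest validation accuracy wins,
# ties go to the earliest epoch
select_checkpoint <- function(val_acc) which.max(val_acc)

# ---- the fitting function --------------------------------------------------

#' Fit the window classifier
#'
#' Trains a convolutional neural network to classify grayscale SNP-window
#' images (e.g. "neutral" vs "selection"). After every epoch the accuracy on
#' a held-out stratified validation split is recorded, and the returned model
#' carries the weights of the epoch with the highest validation accuracy
#' (ties resolved to the earliest epoch) - the checkpoint rule.
#'
#' @param x a `window_images` array from [encode_windows()] (or any
#'   `N x W x L` array of gray levels in `{0, 127, 254}`).
#' @param labels class label per window (factor or character, >= 2 classes).
#' @param arch a [cnn_arch()].
#' @param epochs number of training epochs (>= 1, default 6).
#' @param batch_size minibatch size (default 64).
#' @param val_fraction fraction held out for validation, in (0, 1).
#' @param lr Adam learning rate.
#' @param seed optional integer seed; fixes the split, the weight
#'   initialisation and the shuffling, making the run reproducible.
#' @param verbose print per-epoch progress.
#' @return an object of class `sweep_cnn` with elements `params` (best
#'   weights), `arch`, `classes`, `input_shape`, `history` (per-epoch loss
#'   and validation accuracy) and `best_epoch`.
#' @seealso [predict.sweep_cnn()], [classify_windows()], [save_sweep_cnn()]
#' @export
fit_sweep_cnn <- function(x, labels, arch = cnn_arch(), epochs = 6,
                          batch_size = 64, val_fraction = 0.1, lr = 1e-3,
                          seed = NULL, verbose = FALSE) {
  stopifnot(inherits(arch, "cnn_arch"))
  if (epochs < 1) stop("epochs must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  x <- unclass(x)
  d <- dim(x)
  if (length(d) != 3) stop("x must be an N x W x L image array")
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("training data must contain at least 2 classes")
  if (nlevels(labels) != arch$n_classes)
    stop(sprintf("arch expects %d classes but labels have %d",
                 arch$n_classes, nlevels(labels)))
  if (length(labels) != d[3]) stop("one label per window is required")
  if (!is.null(seed)) set.seed(seed)

  # stratified validation split
  val_idx <- unlist(lapply(levels(labels), function(cl) {
    i <- which(labels == cl)
    sample(i, max(1, round(val_fraction * length(i))))
  }))
  tr_idx <- setdiff(seq_len(d[3]), val_idx)
  if (!length(tr_idx)) stop("no training samples left after the split")

  X <- array(x / 254, d)  # gray levels -> [0, 1]
  nc <- nlevels(labels)
  onehot <- diag(nc)[, as.integer(labels), drop = FALSE]

  params <- init_params(arch, d[1:2])
  state <- adam_state(params)
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_acc = NA_real_)
  best <- NULL
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, length(ord))]
      Xb <- X[, , bi, drop = FALSE]
      dim(Xb) <- c(d[1], d[2], 1, length(bi))
      Yb <- onehot[, bi, drop = FALSE]
      fw <- cnn_forward(params, Xb, keep = TRUE)
      losses <- c(losses, -mean(log(pmax(colSums(fw$probs * Yb), 1e-12))))
      grads <- cnn_backward(params, fw, Yb)
      step <- step + 1
      st <- adam_step(params, grads, state, lr, step)
      params <- st$params; state <- st$state
    }
    pv <- predict_probs(params, X[, , val_idx, drop = FALSE], batch_size)
    acc <- mean(apply(pv, 2, which.max) == as.integer(labels[val_idx]))
    history$train_loss[ep] <- mean(losses)
    history$val_acc[ep] <- acc
    if (is.null(best) || acc > best$acc)
      best <- list(params = params, acc = acc, epoch = ep)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val acc %.4f", ep,
                      mean(losses), acc))
  }

  structure(list(params = best$params, arch = arch,
                 classes = levels(labels), input_shape = d[1:2],
                 history = history,
                 best_epoch = select_checkpoint(history$val_acc),
                 seed = seed),
            class = "sweep_cnn")
}

# batched forward over an (H, W, L) array of [0,1] inputs
predict_probs <- function(params, X, batch_size = 256) {
  d <- dim(X)
  out <- matrix(0, nrow = nrow(params$dense[[length(params$dense)]]$W),
                ncol = d[3])
  for (start in seq(1, d[3], by = batch_size)) {
    bi <- start:min(start + batch_size - 1, d[3])
    Xb <- X[, , bi, drop = FALSE]
    dim(Xb) <- c(d[1], d[2], 1, length(bi))
    out[, bi] <- cnn_forward(params, Xb)$probs
  }
  out
}

#' Grid search over the architecture space
#'
#' Trains one model per architecture and reports the best validation
#' accuracy of each, covering the published search dimensions (number of
#' combined layers, filter size and form, dense depth and width).
#'
#' @param x,labels training images and labels as in [fit_sweep_cnn()].
#' @param grid a data frame with columns `n_conv`, `filters`, `form`,
#'   `dense` (one row per candidate); defaults to a small grid spanning the
#'   published space.
#' @param ... passed to [fit_sweep_cnn()] (e.g. `epochs`, `seed`).
#' @return the grid with a `val_acc` column, best first.
#' @export
search_sweep_cnn <- function(x, labels, grid = NULL, ...) {
  if (is.null(grid))
    grid <- expand.grid(n_conv = c(2, 3), filters = c(16, 32),
                        form = "constant", dense = c(16, 32),
                        stringsAsFactors = FALSE)
  grid$val_acc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    arch <- cnn_arch(n_conv = grid$n_conv[i], filters = grid$filters[i],
                     form = grid$form[i], dense = grid$dense[i])
    fit <- tryCatch(fit_sweep_cnn(x, labels, arch = arch, ...),
                    error = function(e) NULL)
    if (!is.null(fit))
      grid$val_acc[i] <- fit$history$val_acc[fit$best_epoch]
  }
  grid[order(-grid$val_acc), ]
}

#' Posterior class probabilities for window images
#'
#' @param object a fitted `sweep_cnn`.
#' @param newdata a `window_images` array (same sample size and window width
#'   as the training images).
#' @param type `"prob"` for the `c x L` posterior matrix, `"class"` for hard
#'   labels.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return for `type = "prob"`, a `prob_matrix`: classes in rows (summing to
#'   1 per column), windows in columns, with any window table of `newdata`
#'   kept in attribute `windows`.
#' @export
predict.sweep_cnn <- function(object, newdata, type = c("prob", "class"),
                              batch_size = 256, ...) {
  type <- match.arg(type)
  x <- unclass(newdata)
  d <- dim(x)
  if (length(d) != 3 || any(d[1:2] != object$input_shape))
    stop(sprintf("image shape mismatch: expected %d x %d, got %s",
                 object$input_shape[1], object$input_shape[2],
                 paste(d[1:2], collapse = " x ")))
  probs <- predict_probs(object$params, array(x / 254, d), batch_size)
  rownames(probs) <- object$classes
  if (type == "class")
    return(factor(object$classes[apply(probs, 2, which.max)],
                  levels = object$classes))
  structure(probs, windows = attr(newdata, "windows"),
            class = c("prob_matrix", class(probs)))
}

#' Classify the windows of a SNP matrix
#'
#' Convenience wrapper: encode all windows of `m` at the model's width and
#' the requested step, then return the posterior class-probability matrix.
#'
#' @param model a fitted `sweep_cnn`.
#' @param m a [snp_matrix()].
#' @param step window step in SNPs.
#' @return a `prob_matrix` (classes x windows) with the window table
#'   attached, or NULL if the matrix has fewer SNPs than the window width.
#' @export
classify_windows <- function(model, m, step = 1) {
  w <- make_windows(m, width = model$input_shape[2], step = step)
  if (!nrow(w)) return(NULL)
  predict(model, encode_windows(m, w))
}

#' @export
print.sweep_cnn <- function(x, ...) {
  cat("Window-classifying CNN\n")
  print(x$arch)
  cat(sprintf("  input %d x %d, classes: %s\n", x$input_shape[1],
              x$input_shape[2], paste(x$classes, collapse = ", ")))
  cat(sprintf("  best epoch %d (validation accuracy %.3f)\n",
              x$best_epoch, x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.sweep_cnn <- function(object, ...) {
  print(object)
  cat("training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
plot.sweep_cnn <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$val_acc, type = "b",
                 xlab = "epoch", ylab = "validation accuracy", ylim = c(0, 1),
                 main = "training history", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Save / load a fitted model bundle
#'
#' Writes the weights (`weights.rds`) together with a JSON description of the
#' architecture, classes, input shape and training history; loading restores
#' a model whose predictions are bit-identical to the saved one on the same
#' machine.
#'
#' @param model a `sweep_cnn`.
#' @param dir bundle directory (created if needed).
#' @return `save_sweep_cnn` the directory, `load_sweep_cnn` the model.
#' @export
save_sweep_cnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  meta <- list(arch = unclass(model$arch), classes = model$classes,
               input_shape = model$input_shape, history = model$history,
               best_epoch = model$best_epoch, seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_sweep_cnn
#' @export
load_sweep_cnn <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  arch <- structure(meta$arch, class = "cnn_arch")
  arch$n_conv <- as.integer(arch$n_conv)
  arch$filters <- as.integer(arch$filters)
  arch$dense <- as.integer(arch$dense)
  arch$n_classes <- as.integer(arch$n_classes)
  structure(list(params = readRDS(file.path(dir, "weights.rds")),
                 arch = arch, classes = meta$classes,
                 input_shape = meta$input_shape,
                 history = as.data.frame(meta$history),
                 best_epoch = meta$best_epoch, seed = meta$seed),
            class = "sweep_cnn")
}
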