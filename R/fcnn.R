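# Fully connected feed-forward neural network for recurrence
# classification, written directly in R: Glorot-uniform initialization,
# relu/tanh hidden activations, a two-neuron softmax output trained with
# backpropagation and Adam on the softmax cross-entropy (the two-class
# form of binary cross-entropy), and per-predictor center/scale applied
# inside the model.

#' FCNN architecture and training specification
#'
#' The default architecture follows the published recipe: an input layer of
#' `n_inputs` predictors, seven hidden layers with relu (or tanh)
#' activations and 20-150 neurons each, and a two-neuron softmax output;
#' Adam with learning rate 0.003. Epochs and batch size are not part of the
#' published recipe and have declared defaults.
#'
#' @param n_inputs number of predictors.
#' @param hidden_sizes integer vector of hidden-layer widths (default the
#'   seven-layer stack 150, 120, 90, 60, 40, 30, 20). A stack other than 7
#'   layers, or widths outside 20-150, triggers a warning, not an error.
#' @param activation `"relu"` or `"tanh"`, recycled per hidden layer.
#' @param learning_rate Adam learning rate (default 0.003).
#' @param epochs training epochs (default 200).
#' @param batch_size mini-batch size (default 8).
#' @param seed RNG seed controlling initialization and shuffling.
#' @return object of class `fcnn_spec`.
#' @export
fcnn_spec <- function(n_inputs,
                      hidden_sizes = c(150, 120, 90, 60, 40, 30, 20),
                      activation = "relu",
                      learning_rate = 0.003,
                      epochs = 200, batch_size = 8, seed = 1L) {
  stopifnot(n_inputs >= 1, learning_rate > 0, epochs >= 1, batch_size >= 1)
  activation <- rep_len(match.arg(activation, c("relu", "tanh"),
                                  several.ok = FALSE), length(hidden_sizes))
  if (length(hidden_sizes) != 7) {
    warning("hidden stack has ", length(hidden_sizes),
            " layers (the reference architecture uses 7)")
  }
  if (any(hidden_sizes < 20 | hidden_sizes > 150)) {
    warning("hidden size(s) outside the reference range [20, 150]")
  }
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden_sizes = as.integer(hidden_sizes),
                 activation = activation,
                 n_outputs = 2L,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "fcnn_spec")
}

#' Initialize an FCNN model
#'
#' Glorot-uniform weights (limit sqrt(6 / (fan_in + fan_out))) and zero
#' biases; deterministic under the spec seed.
#'
#' @param spec an [fcnn_spec()].
#' @return object of class `fcnn_model` with untrained weights, an empty
#'   scaler and empty training history.
#' @export
init_model <- function(spec) {
  stopifnot(inherits(spec, "fcnn_spec"))
  set.seed(spec$seed)
  sizes <- c(spec$n_inputs, spec$hidden_sizes, spec$n_outputs)
  weights <- vector("list", length(sizes) - 1)
  biases <- vector("list", length(sizes) - 1)
  for (l in seq_along(weights)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    weights[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                           fan_in, fan_out)
    biases[[l]] <- rep(0, fan_out)
  }
  structure(list(spec = spec, weights = weights, biases = biases,
                 scaler = NULL, history = numeric(0), adam = NULL),
            class = "fcnn_model")
}

#' Number of trainable parameters
#'
#' @param model an `fcnn_model`.
#' @return total count of weights and biases.
#' @export
n_params <- function(model) {
  sum(vapply(model$weights, length, numeric(1))) +
    sum(vapply(model$biases, length, numeric(1)))
}

#' @export
print.fcnn_model <- function(x, ...) {
  cat("FCNN:", x$spec$n_inputs, "inputs ->",
      paste(x$spec$hidden_sizes, collapse = "-"), "->",
      x$spec$n_outputs, "softmax outputs;", n_params(x), "parameters;",
      if (length(x$history)) paste(length(x$history), "epochs trained")
      else "untrained", "\n")
  invisible(x)
}

act_fun <- function(z, kind) if (kind == "relu") pmax(z, 0) else tanh(z)
act_grad <- function(z, a, kind) if (kind == "relu") (z > 0) * 1 else 1 - a^2

# Forward pass on already-scaled inputs; returns pre-activations (z),
# activations (a) and softmax probabilities.
fcnn_forward <- function(model, x) {
  n_hidden <- length(model$spec$hidden_sizes)
  z <- vector("list", n_hidden + 1)
  a <- vector("list", n_hidden + 1)
  cur <- x
  for (l in seq_len(n_hidden)) {
    z[[l]] <- sweep(cur %*% model$weights[[l]], 2, model$biases[[l]], "+")
    a[[l]] <- act_fun(z[[l]], model$spec$activation[l])
    cur <- a[[l]]
  }
  l <- n_hidden + 1
  z[[l]] <- sweep(cur %*% model$weights[[l]], 2, model$biases[[l]], "+")
  # log-sum-exp stabilized softmax
  zs <- z[[l]] - apply(z[[l]], 1, max)
  ez <- exp(zs)
  probs <- ez / rowSums(ez)
  list(z = z, a = a, probs = probs)
}

# Total (summed over the batch) cross-entropy of one-hot targets.
fcnn_loss <- function(probs, y_onehot) {
  -sum(y_onehot * log(pmax(probs, 1e-300)))
}

# Backpropagation of the summed cross-entropy; returns gradients shaped
# like the weights/biases.
fcnn_gradients <- function(model, x, y_onehot) {
  fw <- fcnn_forward(model, x)
  n_hidden <- length(model$spec$hidden_sizes)
  gw <- vector("list", n_hidden + 1)
  gb <- vector("list", n_hidden + 1)
  delta <- fw$probs - y_onehot  # softmax + cross-entropy shortcut
  for (l in (n_hidden + 1):1) {
    a_prev <- if (l == 1) x else fw$a[[l - 1]]
    gw[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(model$weights[[l]])) *
        act_grad(fw$z[[l - 1]], fw$a[[l - 1]], model$spec$activation[l - 1])
    }
  }
  list(gw = gw, gb = gb, loss = fcnn_loss(fw$probs, y_onehot))
}

# One Adam update in place on a model given gradients.
adam_step <- function(model, grads, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(model$adam)) {
    model$adam <- list(
      mw = lapply(model$weights, function(w) w * 0),
      vw = lapply(model$weights, function(w) w * 0),
      mb = lapply(model$biases, function(b) b * 0),
      vb = lapply(model$biases, function(b) b * 0),
      t = 0L)
  }
  st <- model$adam
  st$t <- st$t + 1L
  lr <- model$spec$learning_rate
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  for (l in seq_along(model$weights)) {
    st$mw[[l]] <- beta1 * st$mw[[l]] + (1 - beta1) * grads$gw[[l]]
    st$vw[[l]] <- beta2 * st$vw[[l]] + (1 - beta2) * grads$gw[[l]]^2
    model$weights[[l]] <- model$weights[[l]] -
      lr * (st$mw[[l]] / corr1) / (sqrt(st$vw[[l]] / corr2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    model$biases[[l]] <- model$biases[[l]] -
      lr * (st$mb[[l]] / corr1) / (sqrt(st$vb[[l]] / corr2) + eps)
  }
  model$adam <- st
  model
}

onehot <- function(y) cbind(`0` = 1 - y, `1` = y)

# Coerce labels to 0/1 (BCR = 1, BRF = 0).
coerce_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (!all(y %in% c("BCR", "BRF"))) stop("labels must be BCR/BRF or 0/1")
    y <- as.numeric(y == "BCR")
  }
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  y
}

#' Train an FCNN with mini-batch Adam
#'
#' Fits the per-predictor center/scale on the training rows only (a
#' zero-variance predictor gets SD 1 with a warning), one-hot encodes the
#' labels, and minimizes the softmax cross-entropy with backpropagation and
#' Adam (beta1 0.9, beta2 0.999, eps 1e-8). The shuffle stream is seeded
#' from the spec seed, so training is deterministic. The per-epoch mean
#' training loss is recorded in `history`.
#'
#' @param model an initialized `fcnn_model`.
#' @param x numeric predictor matrix (samples x predictors).
#' @param y binary labels: 0/1 or BCR/BRF (BCR = 1).
#' @param epochs,batch_size optional overrides of the spec values.
#' @return the trained `fcnn_model`.
#' @export
train_model <- function(model, x, y, epochs = NULL, batch_size = NULL) {
  stopifnot(inherits(model, "fcnn_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$spec$n_inputs) stop("x has the wrong number of predictors")
  y <- coerce_labels(y)
  if (length(unique(y)) < 2) stop("training labels must contain both classes")
  epochs <- if (is.null(epochs)) model$spec$epochs else epochs
  batch_size <- if (is.null(batch_size)) model$spec$batch_size else batch_size
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    warning("zero-variance predictor(s); scaler SD set to 1 for: ",
            paste(colnames(x)[scl == 0], collapse = ", "))
    scl[scl == 0] <- 1
  }
  model$scaler <- list(center = ctr, scale = scl)
  xs <- scale(x, center = ctr, scale = scl)
  yh <- onehot(y)
  n <- nrow(xs)
  set.seed(derive_seed(model$spec$seed, "fcnn-shuffle"))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      grads <- fcnn_gradients(model, xs[idx, , drop = FALSE],
                              yh[idx, , drop = FALSE])
      model <- adam_step(model, grads)
      ep_loss <- ep_loss + grads$loss
    }
    model$history <- c(model$history, ep_loss / n)
  }
  model
}

#' Class probabilities from an FCNN
#'
#' The model's own scaler is applied before the forward pass; rows of the
#' result sum to 1. The `p_BCR` column is the recurrence score used for
#' ROC analysis.
#'
#' @param model a trained `fcnn_model` (an untrained model predicts with
#'   its initialization and no scaling).
#' @param x predictor matrix with `n_inputs` columns.
#' @return matrix with columns `p_BRF`, `p_BCR`.
#' @export
predict_proba <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$spec$n_inputs) {
    stop("x has ", ncol(x), " columns; model expects ", model$spec$n_inputs)
  }
  if (!is.null(model$scaler)) {
    x <- scale(x, center = model$scaler$center, scale = model$scaler$scale)
  }
  probs <- fcnn_forward(model, x)$probs
  colnames(probs) <- c("p_BRF", "p_BCR")
  probs
}

#' Hard class labels from an FCNN
#'
#' BCR when the recurrence probability exceeds `threshold`; an exact tie at
#' the threshold is broken toward BRF.
#'
#' @param model a trained `fcnn_model`.
#' @param x predictor matrix.
#' @param threshold decision threshold on `p_BCR` (default 0.5).
#' @return character vector of "BCR"/"BRF".
#' @export
predict_class <- function(model, x, threshold = 0.5) {
  p <- predict_proba(model, x)[, "p_BCR"]
  ifelse(p > threshold, "BCR", "BRF")
}

#' Finite-difference gradient check
#'
#' Compares analytic backpropagation gradients with central finite
#' differences (step `h`) of the batch loss over a random subset of
#' parameters, and returns the maximum relative error. Intended for small
#' batches.
#'
#' @param model an `fcnn_model`.
#' @param x small predictor batch (scaled inputs are used as-is; the
#'   model scaler is not applied here).
#' @param y binary labels for the batch.
#' @param n_checked number of randomly chosen parameters to probe.
#' @param h finite-difference step (default 1e-5).
#' @param seed RNG seed for the parameter subset.
#' @return maximum relative error across probed parameters.
#' @export
gradient_check <- function(model, x, y, n_checked = 50, h = 1e-5, seed = 1L) {
  x <- as.matrix(x)
  yh <- onehot(coerce_labels(y))
  grads <- fcnn_gradients(model, x, yh)
  set.seed(seed)
  layer_sizes <- vapply(model$weights, length, numeric(1))
  bias_sizes <- vapply(model$biases, length, numeric(1))
  total <- sum(layer_sizes) + sum(bias_sizes)
  picks <- sample.int(total, min(n_checked, total))
  loss_at <- function() fcnn_loss(fcnn_forward(model, x)$probs, yh)
  max_err <- 0
  for (p in picks) {
    if (p <= sum(layer_sizes)) {
      l <- findInterval(p - 1, cumsum(c(0, layer_sizes)), rightmost.closed = TRUE)
      i <- p - c(0, cumsum(layer_sizes))[l]
      orig <- model$weights[[l]][i]
      ga <- grads$gw[[l]][i]
      model$weights[[l]][i] <- orig + h; up <- loss_at()
      model$weights[[l]][i] <- orig - h; dn <- loss_at()
      model$weights[[l]][i] <- orig
    } else {
      q <- p - sum(layer_sizes)
      l <- findInterval(q - 1, cumsum(c(0, bias_sizes)), rightmost.closed = TRUE)
      i <- q - c(0, cumsum(bias_sizes))[l]
      orig <- model$biases[[l]][i]
      ga <- grads$gb[[l]][i]
      model$biases[[l]][i] <- orig + h; up <- loss_at()
      model$biases[[l]][i] <- orig - h; dn <- loss_at()
      model$biases[[l]][i] <- orig
    }
    gn <- (up - dn) / (2 * h)
    err <- abs(ga - gn) / max(abs(ga), abs(gn), 1e-8)
    max_err <- max(max_err, err)
  }
  max_err
}

#' Serialize an FCNN model to JSON
#'
#' Weights, biases, scaler, spec and training history, written at full
#' numeric precision so models round-trip exactly.
#'
#' @param model an `fcnn_model`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_fcnn <- function(model, path) {
  doc <- list(spec = unclass(model$spec),
              weights = model$weights, biases = model$biases,
              scaler = model$scaler, history = model$history)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read an FCNN model written by [write_fcnn()]
#'
#' @param path JSON path.
#' @return an `fcnn_model`.
#' @export
read_fcnn <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  spec <- doc$spec
  # architecture warnings were already issued when the spec was first built
  spec <- suppressWarnings(fcnn_spec(n_inputs = spec$n_inputs,
                    hidden_sizes = unlist(spec$hidden_sizes),
                    activation = unlist(spec$activation)[1],
                    learning_rate = unlist(spec$learning_rate),
                    epochs = unlist(spec$epochs),
                    batch_size = unlist(spec$batch_size),
                    seed = unlist(spec$seed)))
  model <- init_model(spec)
  model$weights <- lapply(doc$weights, function(w) {
    if (is.matrix(w)) w else matrix(unlist(w), nrow = length(w), byrow = TRUE)
  })
  model$biases <- lapply(doc$biases, unlist)
  if (!is.null(doc$scaler)) {
    model$scaler <- list(center = unlist(doc$scaler$center),
                         scale = unlist(doc$scaler$scale))
  }
  model$history <- unlist(doc$history)
  model
}
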