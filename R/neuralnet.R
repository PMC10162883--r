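#' Tan-sigmoid activation
#'
#' The hyperbolic tangent, `tanh(x) = 2 / (1 + exp(-2x)) - 1`: odd,
#' symmetric around zero, range (-1, 1). Used by every hidden neuron of the
#' BMD network; the output neuron is linear (regression).
#'
#' @param x numeric vector.
#' @return `tanh(x)`.
#' @export
tanh_activation <- function(x) tanh(x)

#' Training configuration for the BMD network
#'
#' Defaults mirror the reference training setup: batch gradient descent at
#' learning rate 0.19, a 70/15/15 train/validation/test split, and early
#' stopping after 6 consecutive epochs without validation improvement
#' (best-validation weights restored).
#'
#' @param learning_rate gradient-descent step size, > 0.
#' @param max_epochs epoch cap.
#' @param val_patience consecutive validation failures tolerated before
#'   stopping; `Inf` disables early stopping.
#' @param split_fractions train/validation/test fractions, summing to 1.
#' @param seed integer seed controlling the split and weight initialization.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.19, max_epochs = 1000L,
                            val_patience = 6L,
                            split_fractions = c(0.70, 0.15, 0.15),
                            seed = 1L) {
  if (learning_rate <= 0)
    ct2bmd_stop("ct2bmd_parameter_error", "learning_rate must be > 0")
  if (abs(sum(split_fractions) - 1) > 1e-9 || length(split_fractions) != 3L)
    ct2bmd_stop("ct2bmd_parameter_error", "split_fractions must be 3 values summing to 1")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 val_patience = val_patience,
                 split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "training_config")
}

# --- min-max scaling to [-1, 1], fitted on the training split only ---------

fit_minmax <- function(x) {
  x <- as.matrix(x)
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

apply_minmax <- function(x, sc) {
  x <- as.matrix(x)
  rng <- sc$max - sc$min
  out <- x
  for (k in seq_len(ncol(x))) {
    out[, k] <- if (rng[k] == 0) 0 else
      2 * (x[, k] - sc$min[k]) / rng[k] - 1
  }
  out
}

invert_minmax <- function(z, sc) {
  z <- as.matrix(z)
  rng <- sc$max - sc$min
  out <- z
  for (k in seq_len(ncol(z))) {
    out[, k] <- if (rng[k] == 0) sc$min[k] else
      (z[, k] + 1) / 2 * rng[k] + sc$min[k]
  }
  out
}

#' Initialize a BMD network
#'
#' Weights drawn uniformly from `[-1/sqrt(fan_in), +1/sqrt(fan_in)]`,
#' biases zero. Architecture is fixed at `n_in` inputs, one hidden layer of
#' `n_hidden` tan-sigmoid neurons, and one linear output neuron.
#'
#' @param seed integer RNG seed.
#' @param n_in input count (default 5 texture features).
#' @param n_hidden hidden-neuron count (default 40).
#' @return Object of class `bmd_network` with weights `W1` (n_hidden x
#'   n_in), `b1`, `W2` (1 x n_hidden), `b2`, identity scalings, and the
#'   seed. Scalings are replaced when the network is trained.
#' @export
init_network <- function(seed = 1L, n_in = 5L, n_hidden = 40L) {
  set.seed(seed)
  lim1 <- 1 / sqrt(n_in); lim2 <- 1 / sqrt(n_hidden)
  structure(list(
    W1 = matrix(runif(n_hidden * n_in, -lim1, lim1), n_hidden, n_in),
    b1 = rep(0, n_hidden),
    W2 = matrix(runif(n_hidden, -lim2, lim2), 1L, n_hidden),
    b2 = 0,
    input_scaling = list(min = rep(-1, n_in), max = rep(1, n_in)),
    target_scaling = list(min = -1, max = 1),
    feature_names = if (n_in == 5L) FEATURE_NAMES else paste0("x", seq_len(n_in)),
    rng_seed = as.integer(seed)
  ), class = "bmd_network")
}

#' @export
print.bmd_network <- function(x, ...) {
  cat(sprintf("<bmd_network> %d-%d-1, tanh hidden / linear output, seed %d\n",
              ncol(x$W1), nrow(x$W1), x$rng_seed))
  invisible(x)
}

# Forward pass in scaled space. S: n_in x n matrix (columns are samples).
nn_forward_scaled <- function(net, S) {
  H <- tanh(net$W1 %*% S + net$b1)
  list(H = H, Y = drop(net$W2 %*% H) + net$b2)
}

#' Analytic backpropagation gradients
#'
#' Gradients of the scaled-space mean squared error
#' `E = mean((y_s - t_s)^2)` with respect to every weight and bias,
#' computed by the chain rule through the tanh hidden layer. Exposed so the
#' finite-difference correctness gate can address it directly.
#'
#' @param net a `bmd_network`.
#' @param S scaled inputs, `n_in x n` matrix (columns are samples).
#' @param t_scaled scaled targets, length n.
#' @return List `W1`, `b1`, `W2`, `b2` of gradients (same shapes as the
#'   parameters) plus the current `mse`.
#' @export
nn_gradient <- function(net, S, t_scaled) {
  n <- ncol(S)
  fwd <- nn_forward_scaled(net, S)
  err <- fwd$Y - t_scaled
  delta2 <- matrix(2 * err / n, 1L, n)            # dE/dy per sample
  gW2 <- delta2 %*% t(fwd$H)
  gb2 <- sum(delta2)
  delta1 <- (t(net$W2) %*% delta2) * (1 - fwd$H^2) # through tanh'
  gW1 <- delta1 %*% t(S)
  gb1 <- rowSums(delta1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, mse = mean(err^2))
}

#' Deterministic train/validation/test split
#'
#' Random disjoint exhaustive partition with sizes
#' `round(f1 * n)`, `round(f2 * n)`, and the remainder, reproducible under
#' a fixed seed.
#'
#' @param n row count (>= 3).
#' @param fractions train/validation/test fractions.
#' @param seed integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
#' @examples
#' lengths(split_dataset(20, seed = 1))
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n < 3L)
    ct2bmd_stop("ct2bmd_size_error", "need >= 3 rows to form 3 partitions (got %d)", n)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  n_test <- n - n_train - n_val
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

as_feature_matrix <- function(features, feature_names) {
  if (is.data.frame(features)) {
    missing <- setdiff(feature_names, names(features))
    if (length(missing))
      ct2bmd_stop("ct2bmd_schema_error", "missing feature columns: %s",
                  paste(missing, collapse = ", "))
    features <- as.matrix(features[feature_names])
  } else {
    features <- as.matrix(features)
  }
  if (!all(is.finite(features)))
    ct2bmd_stop("ct2bmd_input_error", "non-finite feature values")
  features
}

#' Train the BMD regression network
#'
#' Full-batch gradient descent on the mean squared error in scaled space.
#' Inputs and targets are min-max scaled to [-1, 1] using ranges fitted on
#' the training split only. Each epoch updates all weights once with the
#' configured learning rate; training stops at `max_epochs` or when the
#' validation MSE has failed to improve for `val_patience` consecutive
#' epochs, whichever comes first. The weights from the best validation
#' epoch are restored.
#'
#' @param features data frame or matrix of texture features (columns
#'   `contrast, correlation, energy, homogeneity, entropy` for the default
#'   5-input architecture), one row per sample.
#' @param targets numeric BMD targets, one per row.
#' @param config a [training_config()].
#' @param n_hidden hidden layer width (default 40).
#' @return List with `network` (trained `bmd_network`, scalings attached),
#'   `record` (a `training_record`: per-epoch train/val/test MSE in scaled
#'   space, `best_epoch`, `stop_reason`), and `split` (the index partition).
#' @export
train_bmd_network <- function(features, targets, config = training_config(),
                              n_hidden = 40L) {
  X <- if (is.data.frame(features)) as_feature_matrix(features, FEATURE_NAMES)
       else as_feature_matrix(features, NULL)
  targets <- as.numeric(targets)
  n <- nrow(X)
  if (length(targets) != n)
    ct2bmd_stop("ct2bmd_size_error", "features (%d rows) and targets (%d) differ", n, length(targets))
  if (!all(is.finite(targets)))
    ct2bmd_stop("ct2bmd_input_error", "non-finite target values")

  split <- split_dataset(n, config$split_fractions, config$seed)
  in_sc <- fit_minmax(X[split$train, , drop = FALSE])
  tg_sc <- fit_minmax(matrix(targets[split$train]))
  if (tg_sc$max == tg_sc$min)
    ct2bmd_stop("ct2bmd_degenerate_error", "training targets are constant")

  S <- t(apply_minmax(X, in_sc))          # n_in x n
  Tm <- drop(apply_minmax(matrix(targets), tg_sc))

  net <- init_network(config$seed, n_in = ncol(X), n_hidden = n_hidden)
  net$input_scaling <- in_sc
  net$target_scaling <- tg_sc
  if (is.data.frame(features)) net$feature_names <- FEATURE_NAMES

  idx_tr <- split$train; idx_va <- split$val; idx_te <- split$test
  S_tr <- S[, idx_tr, drop = FALSE]; T_tr <- Tm[idx_tr]
  lr <- config$learning_rate
  has_val <- length(idx_va) > 0L

  n_ep <- config$max_epochs
  tr_mse <- va_mse <- te_mse <- rep(NA_real_, n_ep)
  best_val <- Inf; best_epoch <- 0L; best_net <- net
  fails <- 0L; stop_reason <- "max_epochs"; epochs_run <- 0L

  split_mse <- function(idx) {
    if (!length(idx)) return(NA_real_)
    y <- nn_forward_scaled(net, S[, idx, drop = FALSE])$Y
    mean((y - Tm[idx])^2)
  }

  for (ep in seq_len(n_ep)) {
    g <- nn_gradient(net, S_tr, T_tr)
    if (!is.finite(g$mse))
      ct2bmd_stop("ct2bmd_training_diverged_error",
                  "training diverged (non-finite loss) at epoch %d", ep)
    net$W1 <- net$W1 - lr * g$W1
    net$b1 <- net$b1 - lr * g$b1
    net$W2 <- net$W2 - lr * g$W2
    net$b2 <- net$b2 - lr * g$b2
    epochs_run <- ep
    tr_mse[ep] <- split_mse(idx_tr)
    va_mse[ep] <- split_mse(idx_va)
    te_mse[ep] <- split_mse(idx_te)
    if (!is.finite(tr_mse[ep]))
      ct2bmd_stop("ct2bmd_training_diverged_error",
                  "training diverged (non-finite loss) at epoch %d", ep)
    if (has_val) {
      if (va_mse[ep] < best_val) {
        best_val <- va_mse[ep]; best_epoch <- ep; best_net <- net; fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config$val_patience) {
          stop_reason <- "early_stopping"
          break
        }
      }
    } else {
      best_epoch <- ep; best_net <- net
    }
  }
  if (has_val) net <- best_net

  record <- structure(list(
    epochs = data.frame(epoch = seq_len(epochs_run),
                        train_mse = tr_mse[seq_len(epochs_run)],
                        val_mse = va_mse[seq_len(epochs_run)],
                        test_mse = te_mse[seq_len(epochs_run)]),
    best_epoch = best_epoch,
    stop_reason = stop_reason
  ), class = "training_record")

  list(network = net, record = record, split = split)
}

#' @export
print.training_record <- function(x, ...) {
  last <- x$epochs[nrow(x$epochs), ]
  cat(sprintf("<training_record> %d epochs (%s), best epoch %d; final MSE train %.3g / val %.3g / test %.3g\n",
              nrow(x$epochs), x$stop_reason, x$best_epoch,
              last$train_mse, last$val_mse, last$test_mse))
  invisible(x)
}

#' Predict BMD from texture features
#'
#' Vectorized forward pass: scale inputs, tanh hidden layer, linear output,
#' inverse target scaling.
#'
#' @param object a trained `bmd_network`.
#' @param newdata data frame (with the feature columns) or matrix in the
#'   network's feature order.
#' @param ... unused.
#' @return Numeric vector of predicted BMD values (target units).
#' @export
predict.bmd_network <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$feature_names)
  S <- t(apply_minmax(X, object$input_scaling))
  ys <- nn_forward_scaled(object, S)$Y
  drop(invert_minmax(matrix(ys), object$target_scaling))
}

#' @rdname predict.bmd_network
#' @param net a trained `bmd_network`.
#' @param features feature rows as in `predict.bmd_network`.
#' @export
predict_bmd <- function(net, features) predict.bmd_network(net, features)

#' Regression metrics
#'
#' `mse()` is the mean squared error; `correlation_coefficient()` is the
#' Pearson product-moment correlation R between predictions and targets.
#'
#' @param pred,target numeric vectors of equal length.
#' @return A single number.
#' @export
mse <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) == 0L)
    ct2bmd_stop("ct2bmd_size_error", "pred and target must have equal non-zero length")
  mean((pred - target)^2)
}

#' @rdname mse
#' @export
correlation_coefficient <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 2L)
    ct2bmd_stop("ct2bmd_size_error", "need equal lengths >= 2")
  if (stats::sd(pred) == 0 || stats::sd(target) == 0)
    ct2bmd_stop("ct2bmd_degenerate_error", "correlation undefined for a constant vector")
  stats::cor(pred, target)
}

#' Read/write BMD network model files
#'
#' JSON round-trip of all weights, biases, scaling parameters and the seed;
#' numbers are written at full precision so a written-then-read network
#' predicts identically.
#'
#' @param net a `bmd_network`.
#' @param path JSON file path.
#' @return `write_bmd_network()` returns `path` invisibly;
#'   `read_bmd_network()` returns the `bmd_network`.
#' @export
write_bmd_network <- function(net, path) {
  x <- list(W1 = net$W1, b1 = net$b1, W2 = as.numeric(net$W2), b2 = net$b2,
            input_scaling = net$input_scaling,
            target_scaling = net$target_scaling,
            feature_names = net$feature_names, seed = net$rng_seed)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_bmd_network
#' @export
read_bmd_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    W1 = x$W1,
    b1 = as.numeric(x$b1),
    W2 = matrix(as.numeric(x$W2), 1L),
    b2 = as.numeric(x$b2),
    input_scaling = list(min = as.numeric(x$input_scaling$min),
                         max = as.numeric(x$input_scaling$max)),
    target_scaling = list(min = as.numeric(x$target_scaling$min),
                          max = as.numeric(x$target_scaling$max)),
    feature_names = x$feature_names,
    rng_seed = as.integer(x$seed)
  ), class = "bmd_network")
}
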