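#' Population variance of a peptide's RFU time course
#'
#' Collapses a peptide's uptake values across exposure times into a single
#' feature, the population variance `(1/n) * sum (x_i - mean(x))^2`.  Because
#' it is a symmetric function of the values alone, the feature is usable
#' irrespective of the number or spacing of time points.
#'
#' @param x Numeric vector of RFU values (>= 2).
#' @return A single number.
#' @examples
#' rfu_variance(c(0, 1))  # 0.25
#' @export
rfu_variance <- function(x) {
  if (length(x) < 2) {
    abort("need at least 2 RFU values to compute the variance feature",
          class = "hdx_insufficient_data_error")
  }
  mean((x - mean(x))^2)
}

#' Rectified linear unit
#'
#' `max(0, x)`: negative values become zero, positive values pass through.
#' The hidden-layer activation of the control-prediction network.
#'
#' @param x Numeric (vectorized).
#' @return `pmax(x, 0)` (dimensions preserved).
#' @export
relu <- function(x) pmax(x, 0)

#' Mean squared error
#'
#' Mean of squared element-wise differences between predicted and true
#' values; the training loss of the control-prediction network.
#'
#' @param predicted,true Numeric vectors/matrices of equal size.
#' @return A single nonnegative number.
#' @export
mse <- function(predicted, true) {
  if (length(predicted) != length(true)) {
    abort("predicted and true values have different lengths",
          class = "hdx_shape_error")
  }
  mean((predicted - true)^2)
}

#' Network specification for the control-prediction MLP
#'
#' A feedforward network mapping the single variance feature to the two
#' control targets (RFU_back, RFU_fwd): ReLU on the hidden layers, linear
#' output, trained by full-batch gradient descent on the MSE loss via
#' backpropagation.
#'
#' @param hidden Hidden-layer widths; default nine layers tapering
#'   64-64-48-48-32-32-16-16-8.
#' @param epochs Training epochs (default 1000).
#' @param learning_rate Gradient-descent step size.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `"mlp_spec"`.
#' @export
mlp_spec <- function(hidden = c(64, 64, 48, 48, 32, 32, 16, 16, 8),
                     epochs = 1000, learning_rate = 0.02, seed = 1) {
  stopifnot(all(hidden >= 1), epochs >= 0, learning_rate > 0)
  structure(list(hidden = as.integer(hidden), input_dim = 1L, output_dim = 2L,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "mlp_spec")
}

# He-initialized parameter list: weights[[l]] is (n_out x n_in), biases zero.
mlp_init <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden, spec$output_dim)
  with_seed_opt(spec$seed, {
    purrr::map(seq_len(length(dims) - 1), function(l) {
      n_in <- dims[l]
      n_out <- dims[l + 1]
      list(W = matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
           b = numeric(n_out))
    })
  })
}

# Forward pass. x: (n_samples x n_in). Returns list(activations, preacts,
# output); hidden layers ReLU, output linear.
mlp_forward <- function(params, x) {
  L <- length(params)
  a <- list(x)
  z <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- a[[l]] %*% t(params[[l]]$W) +
      matrix(params[[l]]$b, nrow(x), length(params[[l]]$b), byrow = TRUE)
    a[[l + 1]] <- if (l < L) relu(z[[l]]) else z[[l]]
  }
  list(a = a, z = z, output = a[[L + 1]])
}

# Backpropagation of the MSE loss. Returns gradients shaped like params.
mlp_gradients <- function(params, x, y) {
  L <- length(params)
  fwd <- mlp_forward(params, x)
  n <- nrow(x)
  delta <- 2 * (fwd$output - y) / (n * ncol(y))
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = t(delta) %*% fwd$a[[l]], b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% params[[l]]$W) * (fwd$z[[l - 1]] > 0)
    }
  }
  grads
}

#' Build a control-prediction training set
#'
#' Pairs each peptide's variance feature (from its uncorrected RFU time
#' course) with its back/forward control targets.
#'
#' @param uptake Long uptake tibble (uncorrected data).
#' @param controls Control tibble covering the same peptides.
#' @return A tibble `protein`, `peptide`, `start`, `end`, `variance`,
#'   `rfu_back`, `rfu_fwd` (one row per peptide).
#' @export
control_training_set <- function(uptake, controls) {
  validate_controls(controls)
  key <- c("protein", "peptide", "start", "end")
  feats <- uptake %>%
    group_by(across(all_of(key))) %>%
    summarise(variance = rfu_variance(.data$rfu), .groups = "drop")
  out <- dplyr::inner_join(feats, controls[c(key, "rfu_back", "rfu_fwd")],
                           by = key)
  if (nrow(out) != nrow(feats)) {
    abort("controls do not cover every peptide of the uptake table",
          class = "hdx_alignment_error")
  }
  out
}

#' Train the control-prediction MLP
#'
#' Full-batch gradient descent on the joint MSE over both targets, gradients
#' by backpropagation.  The variance feature is z-scored with training-set
#' statistics (stored with the model); training and validation losses are
#' recorded per epoch.  Training and validation sets must not share a protein
#' so the validation loss reflects generalization to unseen proteins.
#'
#' @param train,validation Training-set tibbles from
#'   [control_training_set()] (columns `variance`, `rfu_back`, `rfu_fwd`,
#'   `protein`).
#' @param spec An [mlp_spec()].
#' @return An object of class `"hdx_mlp"`: parameters, spec, standardization
#'   constants, and per-epoch `train_loss` / `val_loss` histories.  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
train_mlp <- function(train, validation, spec = mlp_spec()) {
  stopifnot(nrow(train) > 0, nrow(validation) > 0)
  if (length(intersect(unique(train$protein), unique(validation$protein))) > 0) {
    abort("training and validation sets must be disjoint by protein",
          class = "hdx_structural_error")
  }
  mu <- mean(train$variance)
  sigma <- sd(train$variance)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  xs <- function(d) matrix((d$variance - mu) / sigma, ncol = 1)
  ys <- function(d) cbind(d$rfu_back, d$rfu_fwd)
  x_tr <- xs(train); y_tr <- ys(train)
  x_va <- xs(validation); y_va <- ys(validation)

  params <- mlp_init(spec)
  train_loss <- val_loss <- numeric(spec$epochs)
  for (e in seq_len(spec$epochs)) {
    grads <- mlp_gradients(params, x_tr, y_tr)
    for (l in seq_along(params)) {
      params[[l]]$W <- params[[l]]$W - spec$learning_rate * grads[[l]]$W
      params[[l]]$b <- params[[l]]$b - spec$learning_rate * grads[[l]]$b
    }
    train_loss[e] <- mse(mlp_forward(params, x_tr)$output, y_tr)
    val_loss[e] <- mse(mlp_forward(params, x_va)$output, y_va)
    if (!is.finite(train_loss[e])) {
      abort(paste0("training diverged at epoch ", e,
                   " (learning_rate = ", spec$learning_rate, ")"),
            class = "hdx_training_error")
    }
  }
  structure(list(params = params, spec = spec,
                 standardization = c(mean = mu, sd = sigma),
                 train_loss = train_loss, val_loss = val_loss),
            class = "hdx_mlp")
}

#' @export
print.hdx_mlp <- function(x, ...) {
  cat("<hdx_mlp>", length(x$spec$hidden), "hidden layers (",
      paste(x$spec$hidden, collapse = "-"), "),",
      x$spec$epochs, "epochs; final train MSE =",
      signif(tail(x$train_loss, 1), 3), "\n")
  invisible(x)
}

#' @rdname train_mlp
#' @param x An `hdx_mlp` object.
#' @param ... Unused.
#' @export
tidy.hdx_mlp <- function(x, ...) {
  tibble(epoch = seq_along(x$train_loss),
         train_loss = x$train_loss, val_loss = x$val_loss)
}

#' @rdname train_mlp
#' @export
glance.hdx_mlp <- function(x, ...) {
  tibble(epochs = x$spec$epochs,
         final_train_loss = tail(x$train_loss, 1),
         final_val_loss = tail(x$val_loss, 1),
         n_layers = length(x$spec$hidden),
         learning_rate = x$spec$learning_rate)
}

#' @rdname train_mlp
#' @param object An `hdx_mlp` object (for `autoplot`).
#' @export
autoplot.hdx_mlp <- function(object, ...) {
  tidy(object) %>%
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "phase",
                        values_to = "loss") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$loss,
                                 colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MSE loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Predict per-peptide controls with a trained model
#'
#' Computes each peptide's variance feature, standardizes it with the model's
#' training statistics, and runs the forward pass.  Outputs are clamped to
#' \[0,1\]; pairs predicted with `back <= fwd` are nudged apart symmetrically
#' by a minimum gap and counted in attribute `"n_nudged"`.
#'
#' @param model An `"hdx_mlp"`.
#' @param uptake Long uptake tibble (>= 2 exposure times per peptide).
#' @param min_gap Minimum enforced `back - fwd` gap.
#' @return A control tibble with `provenance = "predicted_ai"`.
#' @export
predict_controls <- function(model, uptake, min_gap = 0.01) {
  stopifnot(inherits(model, "hdx_mlp"))
  key <- c("protein", "peptide", "start", "end")
  feats <- uptake %>%
    group_by(across(all_of(key))) %>%
    summarise(variance = rfu_variance(.data$rfu), .groups = "drop")
  x <- matrix((feats$variance - model$standardization[["mean"]]) /
                model$standardization[["sd"]], ncol = 1)
  pred <- clamp(mlp_forward(model$params, x)$output)
  back <- pred[, 1]
  fwd <- pred[, 2]
  bad <- which(back <= fwd)
  for (i in bad) {
    mid <- (back[i] + fwd[i]) / 2
    back[i] <- clamp(mid + min_gap / 2)
    fwd[i] <- clamp(mid - min_gap / 2)
    if (back[i] <= fwd[i]) back[i] <- clamp(fwd[i] + min_gap)
  }
  out <- feats %>%
    select(all_of(key)) %>%
    mutate(rfu_back = back, rfu_fwd = fwd, provenance = "predicted_ai")
  if (length(bad) > 0) {
    warn(paste0(length(bad), " predicted control pair(s) had back <= fwd and ",
                "were nudged apart"))
  }
  attr(out, "n_nudged") <- length(bad)
  out
}

#' Correct an uptake table with a trained model
#'
#' Convenience composition: [predict_controls()] followed by
#' [apply_controls()] in correction mode.
#'
#' @param uptake Long uptake tibble (uncorrected).
#' @param model An `"hdx_mlp"`.
#' @param clip Clamp corrected RFU to \[0,1\].
#' @return The corrected uptake tibble.
#' @export
correct_with_model <- function(uptake, model, clip = FALSE) {
  ctl <- predict_controls(model, uptake)
  apply_controls(uptake, ctl, mode = "correct", clip = clip)
}
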