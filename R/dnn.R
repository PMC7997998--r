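# The LogP regression network: a small fully connected feedforward net
# mapping the 319-feature fingerprint to a single partition-coefficient
# value, trained by stochastic gradient descent with Nesterov momentum on a
# mean-squared-error loss (RMSE is the monitored quantity).
#
# Layer stack (default): dense 319 units + sigmoid (the input layer carries
# its own activation and is trainable), dense 256 + sigmoid, dense 164 +
# tanh, dense 10 + sigmoid, dense 1 linear.

FL_ACTIVATIONS <- c("sigmoid", "tanh", "linear")

fl_activate <- function(x, act) {
  switch(act,
         sigmoid = stats::plogis(x),
         tanh = tanh(x),
         linear = x,
         stop("unknown activation: ", act, call. = FALSE))
}

fl_activate_grad <- function(a, act) {
  # derivative expressed through the activation value a
  switch(act,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         linear = array(1, dim = dim(a)),
         stop("unknown activation: ", act, call. = FALSE))
}

#' Network architecture specification
#'
#' @param input_width Number of input features (and units of the trainable
#'   sigmoid input layer). Default 319, the registry size.
#' @param hidden_widths Widths of the hidden layers.
#' @param hidden_activations Activation per hidden layer.
#' @param input_activation Activation of the input layer.
#' @param output_width Output units; the LogP regressor has 1.
#' @param output_activation Output nonlinearity; `"linear"` (none) for
#'   regression on raw LogP values.
#' @return An object of class `fl_model_spec`.
#' @export
model_spec <- function(input_width = 319L,
                       hidden_widths = c(256L, 164L, 10L),
                       hidden_activations = c("sigmoid", "tanh", "sigmoid"),
                       input_activation = "sigmoid",
                       output_width = 1L,
                       output_activation = "linear") {
  if (length(hidden_widths) != length(hidden_activations)) {
    stop("hidden_widths and hidden_activations must have equal length",
         call. = FALSE)
  }
  widths <- c(input_width, hidden_widths, output_width)
  if (any(widths <= 0)) {
    stop("all layer widths must be positive", call. = FALSE)
  }
  acts <- c(input_activation, hidden_activations, output_activation)
  stopifnot(all(acts %in% FL_ACTIVATIONS))
  structure(
    list(input_width = as.integer(input_width),
         hidden_widths = as.integer(hidden_widths),
         hidden_activations = hidden_activations,
         input_activation = input_activation,
         output_width = as.integer(output_width),
         output_activation = output_activation,
         # per trainable layer: input size, output size, activation
         layer_in = c(input_width, input_width, hidden_widths),
         layer_out = c(input_width, hidden_widths, output_width),
         layer_act = acts),
    class = "fl_model_spec"
  )
}

#' Training hyperparameters
#'
#' Defaults are the reference configuration: plain SGD with Nesterov
#' momentum 0.9 at learning rate 0.01, batch size 32, 78 epochs, one random
#' shuffle of the training data before the first epoch, RMSE monitored per
#' epoch.
#'
#' @param learning_rate SGD learning rate.
#' @param nesterov_momentum Momentum coefficient (Nesterov form).
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set (no early stopping).
#' @param shuffle Shuffle the training data once before training.
#' @param reshuffle_each_epoch Also reshuffle between epochs (off by
#'   default: the reference protocol shuffles only once, before training).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An object of class `fl_training_config`.
#' @export
training_config <- function(learning_rate = 0.01, nesterov_momentum = 0.9,
                            batch_size = 32L, epochs = 78L, shuffle = TRUE,
                            reshuffle_each_epoch = FALSE, seed = 1L) {
  stopifnot(learning_rate > 0, nesterov_momentum >= 0, batch_size >= 1,
            epochs >= 1)
  structure(
    list(learning_rate = learning_rate,
         nesterov_momentum = nesterov_momentum,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         shuffle = isTRUE(shuffle),
         reshuffle_each_epoch = isTRUE(reshuffle_each_epoch),
         seed = as.integer(seed)),
    class = "fl_training_config"
  )
}

fl_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build an (untrained) model
#'
#' Initializes all layer weights with uniform Glorot draws
#' (`limit = sqrt(6 / (fan_in + fan_out))`) from a seeded generator; biases
#' start at zero. The same seed always gives identical weights.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initializer.
#' @return An object of class `fl_model`: list with `spec`, `weights`
#'   (list of `W`/`b` per layer), `history` (empty until trained),
#'   `registry_version`.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "fl_model_spec"))
  n_layer <- length(spec$layer_in)
  weights <- fl_with_seed(seed, lapply(seq_len(n_layer), function(l) {
    fan_in <- spec$layer_in[l]
    fan_out <- spec$layer_out[l]
    limit <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * fan_out, -limit, limit),
                    nrow = fan_in, ncol = fan_out),
         b = numeric(fan_out))
  }))
  structure(
    list(spec = spec, weights = weights,
         history = data.frame(epoch = integer(), train_rmse = numeric(),
                              valid_rmse = numeric()),
         registry_version = NA_character_, init_seed = as.integer(seed)),
    class = "fl_model"
  )
}

#' Number of trainable parameters
#'
#' @param model An `fl_model`.
#' @param include_input_layer Count the trainable input layer too; with
#'   `FALSE` only the hidden/output stack is counted (125,729 for the
#'   default shape).
#' @return Integer parameter count.
#' @export
n_parameters <- function(model, include_input_layer = TRUE) {
  idx <- seq_along(model$weights)
  if (!include_input_layer) {
    idx <- idx[-1]
  }
  sum(vapply(model$weights[idx],
             function(w) length(w$W) + length(w$b), numeric(1)))
}

fl_forward <- function(model, X, keep_cache = FALSE) {
  acts <- model$spec$layer_act
  a <- X
  cache <- if (keep_cache) vector("list", length(model$weights) + 1L)
  if (keep_cache) cache[[1]] <- a
  for (l in seq_along(model$weights)) {
    z <- sweep(a %*% model$weights[[l]]$W, 2, model$weights[[l]]$b, "+")
    a <- fl_activate(z, acts[l])
    if (keep_cache) cache[[l + 1L]] <- a
  }
  if (keep_cache) list(output = a, cache = cache) else a
}

# Gradient of the batch MSE loss wrt every weight and bias.
fl_gradients <- function(model, X, y) {
  fw <- fl_forward(model, X, keep_cache = TRUE)
  acts <- model$spec$layer_act
  n <- nrow(X)
  n_layer <- length(model$weights)
  grads <- vector("list", n_layer)
  delta <- (fw$output - matrix(y, ncol = 1L)) * (2 / n)  # d MSE / d output
  for (l in rev(seq_len(n_layer))) {
    a_out <- fw$cache[[l + 1L]]
    delta <- delta * fl_activate_grad(a_out, acts[l])
    grads[[l]] <- list(W = crossprod(fw$cache[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(model$weights[[l]]$W)
    }
  }
  list(grads = grads, loss = mean((fw$output - y)^2))
}

fl_rmse <- function(model, X, y) {
  sqrt(mean((fl_forward(model, X) - y)^2))
}

#' Train the LogP regression network
#'
#' Minimizes mean squared error by minibatch SGD with Nesterov momentum.
#' The training data are shuffled once before the first epoch (seeded);
#' training always runs the configured number of epochs and returns the
#' final-epoch model together with the per-epoch train/validation RMSE
#' history.
#'
#' @param model An `fl_model` from [build_model()].
#' @param x_train,y_train Training feature matrix and numeric targets
#'   (experimental LogP, or LogD for ionizable compounds).
#' @param x_valid,y_valid Optional validation set monitored each epoch.
#' @param config A [training_config()].
#' @param verbose Print RMSE per epoch.
#' @return The trained `fl_model` with filled `history`.
#' @export
train_model <- function(model, x_train, y_train,
                        x_valid = NULL, y_valid = NULL,
                        config = training_config(), verbose = FALSE) {
  stopifnot(inherits(model, "fl_model"),
            inherits(config, "fl_training_config"))
  x_train <- as.matrix(x_train)
  if (ncol(x_train) != model$spec$input_width) {
    stop("feature width ", ncol(x_train), " does not match model input width ",
         model$spec$input_width, call. = FALSE)
  }
  if (nrow(x_train) != length(y_train)) {
    stop("x_train and y_train sizes disagree", call. = FALSE)
  }
  has_valid <- !is.null(x_valid)
  if (has_valid) {
    x_valid <- as.matrix(x_valid)
    stopifnot(ncol(x_valid) == model$spec$input_width,
              nrow(x_valid) == length(y_valid))
  }
  n <- nrow(x_train)
  mu <- config$nesterov_momentum
  lr <- config$learning_rate
  velocity <- lapply(model$weights, function(w) {
    list(W = array(0, dim = dim(w$W)), b = numeric(length(w$b)))
  })
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_rmse = NA_real_, valid_rmse = NA_real_)
  order_idx <- seq_len(n)
  fl_with_seed(config$seed, {
    if (config$shuffle) {
      order_idx <- sample.int(n)
    }
    for (epoch in seq_len(config$epochs)) {
      if (config$reshuffle_each_epoch && epoch > 1L) {
        order_idx <- sample.int(n)
      }
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        idx <- order_idx[s:min(s + config$batch_size - 1L, n)]
        g <- fl_gradients(model, x_train[idx, , drop = FALSE], y_train[idx])
        if (!is.finite(g$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; consider a smaller learning rate", call. = FALSE)
        }
        for (l in seq_along(model$weights)) {
          # Nesterov update: look-ahead step re-expressed on the weights
          vW <- mu * velocity[[l]]$W - lr * g$grads[[l]]$W
          vb <- mu * velocity[[l]]$b - lr * g$grads[[l]]$b
          model$weights[[l]]$W <- model$weights[[l]]$W +
            mu * vW - lr * g$grads[[l]]$W
          model$weights[[l]]$b <- model$weights[[l]]$b +
            mu * vb - lr * g$grads[[l]]$b
          velocity[[l]]$W <- vW
          velocity[[l]]$b <- vb
        }
      }
      history$train_rmse[epoch] <- fl_rmse(model, x_train, y_train)
      if (has_valid) {
        history$valid_rmse[epoch] <- fl_rmse(model, x_valid, y_valid)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train RMSE %.4f  valid RMSE %s",
                        epoch, history$train_rmse[epoch],
                        if (has_valid)
                          sprintf("%.4f", history$valid_rmse[epoch])
                        else "-"))
      }
    }
  })
  model$history <- history
  model
}

#' Predict LogP for a feature matrix
#'
#' @param model A trained (or loaded) `fl_model`.
#' @param features Numeric matrix, one molecule per row, feature width
#'   matching the model input.
#' @return Numeric vector of predicted LogP values, one per row.
#' @export
predict_logp <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$spec$input_width) {
    stop("feature width ", ncol(features),
         " does not match model input width ", model$spec$input_width,
         call. = FALSE)
  }
  as.numeric(fl_forward(model, features))
}

#' Save / load a trained model as two files
#'
#' The model is persisted in two separate files: a JSON architecture file
#' (layer shapes, activations, registry version, training history) and a
#' weights file holding the numeric tensors at full precision. Loading
#' reconstructs a model whose predictions are bit-identical to the saved
#' one.
#'
#' @param model A trained `fl_model`.
#' @param arch_path Path for the JSON architecture file.
#' @param weights_path Path for the weights file.
#' @return `save_model()`: invisibly, the two paths. `load_model()`: the
#'   reconstructed `fl_model`.
#' @export
save_model <- function(model, arch_path, weights_path) {
  stopifnot(inherits(model, "fl_model"))
  arch <- list(
    format = "fraglogp-model-1",
    input_width = model$spec$input_width,
    hidden_widths = model$spec$hidden_widths,
    hidden_activations = model$spec$hidden_activations,
    input_activation = model$spec$input_activation,
    output_width = model$spec$output_width,
    output_activation = model$spec$output_activation,
    input_layer_note = paste(
      "the input layer is a trainable dense layer of input_width units",
      "with its own activation; parameter counts include it"),
    registry_version = model$registry_version,
    init_seed = model$init_seed,
    n_parameters = n_parameters(model),
    history = model$history
  )
  jsonlite::write_json(arch, arch_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  saveRDS(model$weights, weights_path)
  invisible(c(arch_path, weights_path))
}

#' @rdname save_model
#' @export
load_model <- function(arch_path, weights_path) {
  if (!file.exists(arch_path)) {
    stop("architecture file not found: ", arch_path, call. = FALSE)
  }
  if (!file.exists(weights_path)) {
    stop("weights file not found: ", weights_path, call. = FALSE)
  }
  arch <- jsonlite::read_json(arch_path, simplifyVector = TRUE)
  if (!identical(arch$format, "fraglogp-model-1")) {
    stop("unrecognized architecture file format", call. = FALSE)
  }
  spec <- model_spec(
    input_width = arch$input_width,
    hidden_widths = arch$hidden_widths,
    hidden_activations = arch$hidden_activations,
    input_activation = arch$input_activation,
    output_width = arch$output_width,
    output_activation = arch$output_activation
  )
  weights <- readRDS(weights_path)
  expect_shapes <- Map(c, spec$layer_in, spec$layer_out)
  got_shapes <- lapply(weights, function(w) dim(w$W))
  for (l in seq_along(expect_shapes)) {
    if (!identical(as.integer(got_shapes[[l]]),
                   as.integer(expect_shapes[[l]]))) {
      stop("weights file does not match architecture: layer ", l,
           " expects ", paste(expect_shapes[[l]], collapse = "x"),
           ", found ", paste(got_shapes[[l]], collapse = "x"),
           call. = FALSE)
    }
  }
  history <- as.data.frame(arch$history)
  structure(
    list(spec = spec, weights = weights, history = history,
         registry_version = arch$registry_version,
         init_seed = arch$init_seed),
    class = "fl_model"
  )
}
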