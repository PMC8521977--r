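#' Regressor configuration
#'
#' Training recipe for the funnel MLP: five hidden layers of 256, 128, 64,
#' 16 and 4 units (fully connected, then batch normalization, then ReLU),
#' a linear output head, RMSE loss, and Adam with initial learning rate
#' 3e-4 and the standard moment decays 0.9/0.999. An inner holdout (10% of
#' the training rows, seeded) drives early stopping.
#'
#' @param hidden_widths Hidden layer widths, narrowing down the funnel.
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without holdout improvement tolerated
#'   before stopping.
#' @param holdout_fraction Fraction of training rows held out for early
#'   stopping.
#' @param input_standardize Z-score inputs using training-fold statistics.
#' @param seed Integer seed for initialisation, holdout choice and batch
#'   shuffles.
#' @return A `regressor_config` list.
#' @export
regressor_config <- function(hidden_widths = c(256L, 128L, 64L, 16L, 4L),
                             learning_rate = 3e-4, batch_size = 256L,
                             max_epochs = 200L, early_stop_patience = 10L,
                             holdout_fraction = 0.1,
                             input_standardize = TRUE, seed = 1L) {
  hidden_widths <- vapply(hidden_widths, check_count, integer(1),
                          name = "hidden_widths")
  check_number(learning_rate, "learning_rate", min = 0, strict_min = TRUE)
  structure(list(
    hidden_widths = hidden_widths,
    learning_rate = learning_rate,
    batch_size = check_count(batch_size, "batch_size"),
    max_epochs = check_count(max_epochs, "max_epochs"),
    early_stop_patience = check_count(early_stop_patience,
                                      "early_stop_patience"),
    holdout_fraction = check_number(holdout_fraction, "holdout_fraction",
                                    min = 0, max = 0.5),
    input_standardize = isTRUE(input_standardize),
    seed = check_seed(seed)
  ), class = "regressor_config")
}

#' Trainable parameter count of the funnel MLP
#'
#' Affine parameters (weights + biases) down the funnel and into the
#' 1-unit output head, plus two learnable batch-norm parameters (scale and
#' shift) per hidden unit. Running batch-norm statistics are not trainable
#' and are not counted.
#'
#' @param input_dim Input feature dimension.
#' @param hidden_widths Hidden layer widths.
#' @return Integer parameter count.
#' @export
mlp_param_count <- function(input_dim, hidden_widths = c(256L, 128L, 64L, 16L, 4L)) {
  input_dim <- check_count(input_dim, "input_dim")
  dims <- c(input_dim, hidden_widths, 1L)
  affine <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  bn <- 2L * sum(hidden_widths)
  as.integer(affine + bn)
}

#' Build an untrained funnel MLP
#'
#' Initialises weights with He-scaled normals (appropriate for ReLU
#' activations), zero biases, unit batch-norm scales and zero shifts, as a
#' pure function of `(input_dim, config)` including the seed.
#'
#' @param input_dim Input feature dimension.
#' @param config A [regressor_config()].
#' @return An untrained model of class `mlp_model`.
#' @export
build_mlp <- function(input_dim, config = regressor_config()) {
  input_dim <- check_count(input_dim, "input_dim")
  widths <- config$hidden_widths
  params <- with_seed(derive_seed(config$seed, "init"), {
    dims <- c(input_dim, widths)
    hidden <- lapply(seq_along(widths), function(i) {
      list(W = matrix(rnorm(dims[i] * dims[i + 1], sd = sqrt(2 / dims[i])),
                      dims[i], dims[i + 1]),
           b = numeric(widths[i]),
           gamma = rep(1, widths[i]),
           beta = numeric(widths[i]),
           rm = numeric(widths[i]),
           rv = rep(1, widths[i]))
    })
    # near-zero output head: predictions start at the output intercept and
    # the head grows as the funnel learns useful features
    out <- list(W = rnorm(widths[length(widths)], sd = 0.01), b = 0)
    list(hidden = hidden, out = out)
  })
  structure(list(kind = "mlp", params = params, input_dim = input_dim,
                 config = config, trained = FALSE, scaler = NULL,
                 feature_layout = NULL, training_log = NULL),
            class = c("mlp_model", "incembed_model"))
}

features_xy <- function(features) {
  if (inherits(features, "feature_matrix")) {
    list(x = features$x, y = features$y, layout = features$layout)
  } else if (is.list(features) && all(c("x", "y") %in% names(features))) {
    list(x = as.matrix(features$x), y = as.numeric(features$y),
         layout = features$layout)
  } else {
    abort("features must be a feature_matrix or a list(x, y)",
          "incembed_invalid_argument")
  }
}

#' Train the funnel MLP
#'
#' Minimises root-mean-squared error between predictions and the log10
#' targets with Adam (moment decays 0.9/0.999). A seeded inner holdout of
#' `holdout_fraction` of the training rows is monitored each epoch; the
#' parameters with the best holdout RMSE are kept, and training stops after
#' `early_stop_patience` epochs without improvement. Input standardization
#' (if enabled) is fitted on the supplied rows only, so no validation-fold
#' information can leak in.
#'
#' @param model An untrained model from [build_mlp()] (or `NULL` to build
#'   one matching the features).
#' @param features A `feature_matrix` (or `list(x, y)`).
#' @param config A [regressor_config()]; defaults to the model's.
#' @return A trained `mlp_model` with a per-epoch `training_log`.
#' @export
train_regressor <- function(model, features, config = model$config) {
  fx <- features_xy(features)
  if (nrow(fx$x) == 0) {
    abort("no training rows", "incembed_invalid_argument")
  }
  if (!all(is.finite(fx$y))) {
    abort("all targets must be finite (filter zero incidence first)",
          "incembed_invalid_argument")
  }
  if (is.null(model)) model <- build_mlp(ncol(fx$x), config)
  stopifnot(inherits(model, "mlp_model"))
  if (ncol(fx$x) != model$input_dim) {
    abort(sprintf("model expects input_dim %d, features have %d",
                  model$input_dim, ncol(fx$x)),
          "incembed_invalid_argument")
  }
  scaler <- NULL
  x <- fx$x
  if (config$input_standardize) {
    scaler <- fit_scaler(x)
    x <- apply_scaler(scaler, x)
  }
  # output intercept starts at the training-target mean so the optimizer
  # spends its steps on structure, not on the global level
  if (!model$trained && identical(model$params$out$b, 0)) {
    model$params$out$b <- mean(fx$y)
  }
  n <- nrow(x)
  n_hold <- floor(config$holdout_fraction * n)
  hold_idx <- if (n_hold >= 2) {
    with_seed(derive_seed(config$seed, "holdout"), sample.int(n, n_hold))
  } else {
    integer(0)
  }
  train_idx <- setdiff(seq_len(n), hold_idx)
  fit <- .mlp_train_cpp(model$params,
                        x[train_idx, , drop = FALSE], fx$y[train_idx],
                        x[hold_idx, , drop = FALSE], fx$y[hold_idx],
                        config$batch_size, config$max_epochs,
                        config$learning_rate, config$early_stop_patience,
                        0.9, 0.999, derive_seed(config$seed, "shuffle"))
  log <- data.frame(epoch = seq_along(fit$train_rmse),
                    train_rmse = fit$train_rmse)
  log$holdout_rmse <- if (length(fit$val_rmse)) fit$val_rmse else NA_real_
  model$params <- fit$params
  model$trained <- TRUE
  model$scaler <- scaler
  model$feature_layout <- fx$layout
  model$training_log <- log
  model$best_epoch <- fit$best_epoch
  model$config <- config
  model
}

check_layout <- function(model_layout, layout) {
  if (is.null(model_layout) || is.null(layout)) return(invisible())
  a <- model_layout$segments
  b <- layout$segments
  for (i in seq_len(nrow(a))) {
    if (i > nrow(b) || a$length[i] != b$length[i] ||
        a$provider[i] != b$provider[i]) {
      abort(sprintf(
        "feature layout mismatch in segment %s: model has %s (length %d)",
        dQuote(a$name[i]), a$provider[i], a$length[i]),
        "incembed_layout_error")
    }
  }
  invisible()
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  if (!object$trained) abort("model is untrained", "incembed_invalid_argument")
  if (inherits(newdata, "feature_matrix")) {
    check_layout(object$feature_layout, newdata$layout)
    x <- newdata$x
  } else {
    x <- as.matrix(newdata)
  }
  if (ncol(x) != object$input_dim) {
    abort(sprintf("model expects %d features, got %d",
                  object$input_dim, ncol(x)),
          "incembed_layout_error")
  }
  if (!is.null(object$scaler)) x <- apply_scaler(object$scaler, x)
  as.numeric(.mlp_predict_cpp(object$params, x))
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> funnel %s -> 1, input_dim=%d, %s (%d parameters)\n",
              paste(x$config$hidden_widths, collapse = "-"), x$input_dim,
              if (x$trained) sprintf("trained (%d epochs)",
                                     nrow(x$training_log)) else "untrained",
              mlp_param_count(x$input_dim, x$config$hidden_widths)))
  invisible(x)
}
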