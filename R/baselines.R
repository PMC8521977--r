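#' Global-average baseline
#'
#' The naive baseline every model should outperform: the mean log10
#' incidence of the disease of interest over the training rows (optionally
#' per disease-age cell). For an entity absent from training the prediction
#' is undefined and reported as not-applicable (`NA`), mirroring the "N/A"
#' entries such baselines produce for the unseen-disease application.
#'
#' @param train An [incidence_table()] of training rows with strictly
#'   positive incidence.
#' @param grouping `"disease"` (default) or `"disease-age"`.
#' @return A `global_model`.
#' @export
fit_global_baseline <- function(train, grouping = c("disease", "disease-age")) {
  stopifnot(inherits(train, "incidence_table"))
  grouping <- match.arg(grouping)
  if (nrow(train) == 0) {
    abort("empty training table", "incembed_invalid_argument")
  }
  y <- log_transform(train$incidence)
  key <- if (grouping == "disease") train$disease else
    paste(train$disease, train$age_group, sep = "\r")
  means <- tapply(y, key, mean)
  structure(list(kind = "global", grouping = grouping,
                 means = structure(as.numeric(means), names = names(means))),
            class = c("global_model", "incembed_model"))
}

#' @export
predict.global_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "data.frame"))
  key <- if (object$grouping == "disease") normalize_name(newdata$disease) else
    paste(normalize_name(newdata$disease), newdata$age_group, sep = "\r")
  unname(object$means[key])  # NA = not applicable for unseen entities
}

#' Ridge regression baseline on embedding features
#'
#' Linear model with an L2 penalty on the coefficients (intercept
#' unpenalised, handled by centring). The penalty weight is chosen from
#' `alpha_grid` by seeded inner 5-fold cross-validation on the training
#' rows; the solve is closed-form via a single SVD per fold, exact to
#' machine precision, so `alpha -> 0` recovers the least-squares solution
#' and `alpha -> Inf` shrinks predictions to the training mean.
#'
#' @param features A `feature_matrix` (or `list(x, y)`) of training rows.
#' @param alpha_grid Positive penalty weights to search.
#' @param seed Integer seed for the inner CV fold assignment.
#' @param inner_k Inner CV folds (default 5; reduced automatically for tiny
#'   inputs).
#' @return A `ridge_model` with the chosen `alpha`.
#' @export
fit_ridge <- function(features, alpha_grid = 10^seq(-3, 3, length.out = 7),
                      seed = 1L, inner_k = 5L) {
  fx <- features_xy(features)
  if (nrow(fx$x) == 0) abort("no training rows", "incembed_invalid_argument")
  if (any(!is.finite(alpha_grid)) || any(alpha_grid <= 0)) {
    abort("alpha_grid must be strictly positive", "incembed_invalid_argument")
  }
  seed <- check_seed(seed)
  x <- fx$x
  y <- fx$y
  n <- nrow(x)

  ridge_path <- function(xtr, ytr, alphas) {
    xc <- colMeans(xtr)
    yc <- mean(ytr)
    sv <- svd(sweep(xtr, 2, xc, "-"))
    uty <- crossprod(sv$u, ytr - yc)
    lapply(alphas, function(a) {
      beta <- sv$v %*% (uty * sv$d / (sv$d^2 + a))
      list(beta = as.numeric(beta),
           intercept = yc - sum(xc * beta))
    })
  }

  alpha <- alpha_grid[1]
  if (length(alpha_grid) > 1) {
    k <- max(2L, min(check_count(inner_k, "inner_k", min = 2L), n))
    fold_id <- with_seed(derive_seed(seed, "ridge-cv"),
                         sample(rep(seq_len(k), length.out = n)))
    cv_sse <- numeric(length(alpha_grid))
    for (f in seq_len(k)) {
      va <- fold_id == f
      fits <- ridge_path(x[!va, , drop = FALSE], y[!va], alpha_grid)
      for (j in seq_along(alpha_grid)) {
        pred <- x[va, , drop = FALSE] %*% fits[[j]]$beta + fits[[j]]$intercept
        cv_sse[j] <- cv_sse[j] + sum((pred - y[va])^2)
      }
    }
    alpha <- alpha_grid[which.min(cv_sse)]
  }
  fit <- ridge_path(x, y, alpha)[[1]]
  structure(list(kind = "ridge", beta = fit$beta, intercept = fit$intercept,
                 alpha = alpha, alpha_grid = alpha_grid, seed = seed,
                 feature_layout = fx$layout, input_dim = ncol(x)),
            class = c("ridge_model", "incembed_model"))
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) {
    check_layout(object$feature_layout, newdata$layout)
    x <- newdata$x
  } else {
    x <- as.matrix(newdata)
  }
  if (ncol(x) != object$input_dim) {
    abort(sprintf("model expects %d features, got %d",
                  object$input_dim, ncol(x)), "incembed_layout_error")
  }
  as.numeric(x %*% object$beta + object$intercept)
}

#' One-hot features for the OneHot baselines
#'
#' Disease and/or country indicator blocks (vocabulary fixed on the
#' training fold) concatenated with the age one-hot. Indicators carry no
#' cross-entity context, so rows whose disease or country lies outside the
#' training vocabulary cannot be encoded; such rows are flagged
#' `applicable = FALSE` and must be reported as not-applicable downstream.
#'
#' @param table An [incidence_table()] with strictly positive incidence.
#' @param variant `"d"` (disease only), `"c"` (country only) or `"dc"`.
#' @param vocab Vocabulary list `list(diseases =, countries =)` from the
#'   training fold; built from `table` when `NULL`.
#' @param n_age Number of age bands.
#' @return A `feature_matrix` with additional fields `applicable` (logical
#'   per row) and `vocab`. Non-applicable rows are all-zero in the entity
#'   blocks.
#' @export
build_onehot_features <- function(table, variant = c("dc", "d", "c"),
                                  vocab = NULL,
                                  n_age = attr(table, "n_age")) {
  stopifnot(inherits(table, "incidence_table"))
  variant <- match.arg(variant)
  if (is.null(n_age)) n_age <- 20L
  n_age <- check_count(n_age, "n_age")
  if (is.null(vocab)) {
    vocab <- list(diseases = sort(unique(table$disease)),
                  countries = sort(unique(table$country)))
  }
  n <- nrow(table)
  applicable <- rep(TRUE, n)
  blocks <- list()
  seg_names <- character()
  seg_providers <- character()
  seg_lengths <- integer()
  if (variant %in% c("d", "dc")) {
    idx <- match(table$disease, vocab$diseases)
    applicable <- applicable & !is.na(idx)
    block <- matrix(0, n, length(vocab$diseases))
    ok <- !is.na(idx)
    block[cbind(which(ok), idx[ok])] <- 1
    blocks <- c(blocks, list(block))
    seg_names <- c(seg_names, "disease")
    seg_providers <- c(seg_providers, "onehot-disease")
    seg_lengths <- c(seg_lengths, length(vocab$diseases))
  }
  if (variant %in% c("c", "dc")) {
    idx <- match(table$country, vocab$countries)
    applicable <- applicable & !is.na(idx)
    block <- matrix(0, n, length(vocab$countries))
    ok <- !is.na(idx)
    block[cbind(which(ok), idx[ok])] <- 1
    blocks <- c(blocks, list(block))
    seg_names <- c(seg_names, "country")
    seg_providers <- c(seg_providers, "onehot-country")
    seg_lengths <- c(seg_lengths, length(vocab$countries))
  }
  amat <- matrix(0, n, n_age)
  amat[cbind(seq_len(n), table$age_group + 1L)] <- 1
  x <- do.call(cbind, c(blocks, list(amat)))
  layout <- list(
    segments = data.frame(
      name = c(seg_names, "age"),
      provider = c(seg_providers, "onehot-age"),
      offset = cumsum(c(0L, utils::head(c(seg_lengths, n_age), -1))),
      length = c(seg_lengths, n_age),
      stringsAsFactors = FALSE
    ),
    n_age = n_age
  )
  structure(list(x = x, y = log_transform(table$incidence),
                 keys = table[, c("disease", "country", "age_group")],
                 layout = layout, applicable = applicable, vocab = vocab,
                 variant = variant),
            class = c("onehot_features", "feature_matrix"))
}
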