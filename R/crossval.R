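#' Cross-validated training and evaluation
#'
#' Runs one model kind over a split plan: per fold, features are assembled
#' from the fold's training rows only (input standardization, one-hot
#' vocabularies and the early-stopping holdout are all fitted inside the
#' fold), the model is trained and applied to the fold's validation rows,
#' and the validation predictions are pooled over folds — so every record
#' is predicted exactly once — before being handed to
#' [evaluate_predictions()].
#'
#' Model kinds: `"mlp"` (funnel MLP on embedding features), `"ridge"`
#' (closed-form ridge on the same features), `"global"` (per-disease mean),
#' and `"onehot-d"` / `"onehot-c"` / `"onehot-dc"` (funnel MLP on one-hot
#' entity indicators). Baselines that cannot encode an unseen entity
#' produce not-applicable (`NA`) predictions for those rows.
#'
#' @param table A zero-filtered [incidence_table()].
#' @param disease_provider,country_provider [embedding_provider]s (ignored
#'   by the `global` and `onehot-*` kinds).
#' @param plan A `split_plan` over `table`.
#' @param model One of the kinds above.
#' @param config A [regressor_config()] (used by the MLP-based kinds; its
#'   seed also seeds the ridge inner CV).
#' @param group_of Concordance grouping column of `table` (default
#'   `"country"`: disease rankings are compared within each country).
#' @param strata Optional stratification column name (e.g. `"age_group"`).
#' @param global_grouping Grouping for the global baseline.
#' @return A list of class `cv_result`: `report` (an `evaluation_report`),
#'   `predictions` (one row per record: keys, truth, pred, fold), `model`,
#'   `scheme`.
#' @export
cross_validate <- function(table, disease_provider = NULL,
                           country_provider = NULL, plan,
                           model = c("mlp", "ridge", "global",
                                     "onehot-d", "onehot-c", "onehot-dc"),
                           config = regressor_config(),
                           group_of = "country", strata = NULL,
                           global_grouping = "disease") {
  stopifnot(inherits(table, "incidence_table"), inherits(plan, "split_plan"))
  model <- match.arg(model)
  if (any(table$incidence == 0)) {
    abort("table contains zero incidence; apply filter_zero_incidence() first",
          "incembed_invalid_argument")
  }
  check <- validate_split(plan, table)
  if (!check$pass) {
    abort(paste("invalid split plan:", check$failures[1]),
          "incembed_invalid_argument")
  }
  needs_embeddings <- model %in% c("mlp", "ridge")
  if (needs_embeddings &&
      (!inherits(disease_provider, "embedding_provider") ||
       !inherits(country_provider, "embedding_provider"))) {
    abort(sprintf("model %s needs disease and country embedding providers",
                  dQuote(model)), "incembed_invalid_argument")
  }

  truth <- log_transform(table$incidence)
  pred <- rep(NA_real_, nrow(table))
  fold_of <- rep(NA_integer_, nrow(table))

  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    train_tab <- table[fold$train, , drop = FALSE]
    val_tab <- table[fold$validation, , drop = FALSE]
    class(train_tab) <- class(val_tab) <- class(table)
    attr(train_tab, "n_age") <- attr(val_tab, "n_age") <- attr(table, "n_age")
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, sprintf("fold-%d", i))
    fold_pred <- tryCatch(
      fit_predict_fold(model, train_tab, val_tab, disease_provider,
                       country_provider, fold_config, global_grouping),
      incembed_error = function(e) {
        abort(sprintf("fold %d (%s scheme) failed: %s", i, plan$scheme,
                      conditionMessage(e)), "incembed_fold_error")
      })
    pred[fold$validation] <- fold_pred
    fold_of[fold$validation] <- i
  }

  evaluated <- !is.na(fold_of)
  report <- evaluate_predictions(
    pred[evaluated], truth[evaluated],
    group_of = if (!is.null(group_of)) table[[group_of]][evaluated],
    strata = if (!is.null(strata)) table[[strata]][evaluated])
  predictions <- data.frame(table[, c("disease", "country", "age_group")],
                            truth = truth, pred = pred, fold = fold_of,
                            stringsAsFactors = FALSE)
  structure(list(report = report, predictions = predictions,
                 model = model, scheme = plan$scheme, k = plan$k,
                 seed = config$seed),
            class = "cv_result")
}

fit_predict_fold <- function(model, train_tab, val_tab, disease_provider,
                             country_provider, config, global_grouping) {
  if (model %in% c("mlp", "ridge")) {
    fx_train <- assemble_features(train_tab, disease_provider,
                                  country_provider)
    fx_val <- assemble_features(val_tab, disease_provider, country_provider)
    if (model == "mlp") {
      fitted <- train_regressor(NULL, fx_train, config)
    } else {
      fitted <- fit_ridge(fx_train, seed = config$seed)
    }
    return(predict(fitted, fx_val))
  }
  if (model == "global") {
    fitted <- fit_global_baseline(train_tab, global_grouping)
    return(predict(fitted, val_tab))
  }
  variant <- sub("^onehot-", "", model)
  fx_train <- build_onehot_features(train_tab, variant)
  fx_val <- build_onehot_features(val_tab, variant, vocab = fx_train$vocab)
  out <- rep(NA_real_, nrow(val_tab))
  if (all(!fx_val$applicable)) return(out)
  fitted <- train_regressor(NULL, fx_train, config)
  out[fx_val$applicable] <- predict(
    fitted, fx_val$x[fx_val$applicable, , drop = FALSE])
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> model=%s, scheme=%s, k=%d\n",
              x$model, x$scheme, x$k))
  print(x$report)
  invisible(x)
}
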