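#' Construct a group labeling
#'
#' Maps each entity name to exactly one categorical label (a disease group
#' or a country cluster). Used as the target of the embedding-context
#' classification experiments.
#'
#' @param entity_labels Named character vector: names are entity names
#'   (normalized on construction), values are labels.
#' @param kind `"disease-group"` or `"country-cluster"`.
#' @return An object of class `group_labeling`.
#' @export
group_labeling <- function(entity_labels,
                           kind = c("disease-group", "country-cluster")) {
  kind <- match.arg(kind)
  if (length(entity_labels) == 0 || is.null(names(entity_labels))) {
    abort("entity_labels must be a named vector", "incembed_invalid_argument")
  }
  nm <- normalize_name(names(entity_labels))
  if (anyDuplicated(nm)) {
    dup <- nm[duplicated(nm)]
    conflicting <- vapply(unique(dup), function(d) {
      length(unique(entity_labels[nm == d])) > 1
    }, logical(1))
    if (any(conflicting)) {
      abort(sprintf("conflicting labels for entity %s",
                    dQuote(unique(dup)[conflicting][1])),
            "incembed_validation_error")
    }
    keep <- !duplicated(nm)
    entity_labels <- entity_labels[keep]
    nm <- nm[keep]
  }
  labels <- structure(as.character(entity_labels), names = nm)
  label_set <- sort(unique(labels))
  if (length(label_set) < 2) {
    abort("a labeling needs at least 2 distinct labels",
          "incembed_invalid_argument")
  }
  structure(list(entity_labels = labels, label_set = label_set, kind = kind),
            class = "group_labeling")
}

#' @export
print.group_labeling <- function(x, ...) {
  cat(sprintf("<group_labeling> %s: %d entities over %d labels\n",
              x$kind, length(x$entity_labels), length(x$label_set)))
  invisible(x)
}

#' Read / write group labelings as two-column delimited files
#'
#' The file holds a header and one `entity,label` row per entity. Entities
#' are normalized on read; duplicate entities with conflicting labels are
#' an error.
#'
#' @param path File path.
#' @param kind Labeling kind tag.
#' @return `read_group_labels()`: a [group_labeling()];
#'   `write_group_labels()`: invisibly, `path`.
#' @export
read_group_labels <- function(path, kind = "disease-group") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "incembed_invalid_argument")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    abort(sprintf("expected two columns (entity, label) in %s", path),
          "incembed_format_error")
  }
  group_labeling(structure(as.character(df[[2]]), names = df[[1]]),
                 kind = kind)
}

#' @rdname read_group_labels
#' @param labeling A [group_labeling()] to write.
#' @export
write_group_labels <- function(labeling, path) {
  stopifnot(inherits(labeling, "group_labeling"))
  write.csv(data.frame(entity = names(labeling$entity_labels),
                       label = unname(labeling$entity_labels),
                       stringsAsFactors = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stratified fold assignment: within each class, shuffled members are dealt
# round-robin so every fold sees every class where possible.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

svm_accuracy <- function(x, y, train, test, cost) {
  scaler <- fit_scaler(x[train, , drop = FALSE])
  fit <- e1071::svm(apply_scaler(scaler, x[train, , drop = FALSE]),
                    y[train], kernel = "linear", cost = cost, scale = FALSE)
  pred <- predict(fit, apply_scaler(scaler, x[test, , drop = FALSE]))
  mean(pred == y[test])
}

#' Embedding-context classification experiment
#'
#' Measures how much group structure an embedding carries: linear support
#' vector machines predict each entity's group label from its embedding
#' vector under repeated stratified k-fold cross-validation. Per outer
#' fold, the SVM cost is selected from `c_grid` by nested stratified CV on
#' the training portion only; embeddings are standardized per feature using
#' training-fold statistics. The experiment is repeated `repeats` times
#' with reshuffled folds (seeds derived from `seed`) and the mean and
#' standard deviation of the per-repeat accuracies are reported.
#'
#' @param embeddings An entity-level [embedding_table()] covering every
#'   labeled entity.
#' @param labels A [group_labeling()].
#' @param folds Outer (and nested) fold count, default 3.
#' @param repeats Number of repetitions, default 10.
#' @param c_grid Candidate SVM cost values.
#' @param seed Integer seed.
#' @return A list of class `context_eval_result` with `mean`, `sd`,
#'   `per_repeat` accuracies, `chance` (1 / number of classes), `folds`,
#'   `repeats`, `n_entities` and `standardized = TRUE`.
#' @export
run_classification <- function(embeddings, labels, folds = 3L, repeats = 10L,
                               c_grid = c(0.01, 0.1, 1, 10, 100),
                               seed = 1L) {
  stopifnot(inherits(embeddings, "embedding_table"),
            inherits(labels, "group_labeling"))
  folds <- check_count(folds, "folds", min = 2L)
  repeats <- check_count(repeats, "repeats")
  seed <- check_seed(seed)
  entities <- names(labels$entity_labels)
  missing_emb <- setdiff(entities, rownames(embeddings$vectors))
  if (length(missing_emb)) {
    abort(sprintf("no embedding for labeled entity %s",
                  dQuote(missing_emb[1])), "incembed_missing_entity")
  }
  x <- embeddings$vectors[entities, , drop = FALSE]
  y <- factor(unname(labels$entity_labels))
  class_sizes <- table(y)
  if (any(class_sizes < folds)) {
    abort(sprintf("class %s has %d member(s), fewer than folds = %d",
                  dQuote(names(class_sizes)[which.min(class_sizes)]),
                  min(class_sizes), folds),
          "incembed_invalid_argument")
  }

  per_repeat <- vapply(seq_len(repeats), function(r) {
    with_seed(derive_seed(seed, sprintf("repeat-%d", r)), {
      fold_id <- stratified_folds(as.character(y), folds)
      fold_acc <- vapply(seq_len(folds), function(f) {
        train <- which(fold_id != f)
        test <- which(fold_id == f)
        best_cost <- c_grid[1]
        if (length(c_grid) > 1) {
          inner_id <- stratified_folds(as.character(y[train]),
                                       min(folds, 3L))
          inner_acc <- vapply(c_grid, function(cost) {
            mean(vapply(seq_len(max(inner_id)), function(g) {
              svm_accuracy(x[train, , drop = FALSE], y[train],
                           which(inner_id != g), which(inner_id == g), cost)
            }, numeric(1)))
          }, numeric(1))
          best_cost <- c_grid[which.max(inner_acc)]
        }
        svm_accuracy(x, y, train, test, best_cost)
      }, numeric(1))
      mean(fold_acc)
    })
  }, numeric(1))

  structure(list(mean = mean(per_repeat), sd = sd(per_repeat),
                 per_repeat = per_repeat,
                 chance = 1 / nlevels(y), folds = folds, repeats = repeats,
                 n_entities = length(entities), kind = labels$kind,
                 standardized = TRUE, seed = seed),
            class = "context_eval_result")
}

#' @export
print.context_eval_result <- function(x, ...) {
  cat(sprintf(
    "<context_eval_result> %s: accuracy %.2f (%.2f) over %dx %d-fold CV (chance %.2f)\n",
    x$kind, x$mean, x$sd, x$repeats, x$folds, x$chance))
  invisible(x)
}
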