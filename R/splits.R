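#' Cross-validation split plans for the three applications
#'
#' Three leave-out schemes mirror the three estimation applications:
#'
#' * `split_pairs()` — held-out disease-country pairs: the distinct
#'   (disease, country) pairs are randomly partitioned into `k` near-equal
#'   folds, all age-band records of a pair travelling together. A
#'   validation pair never appears in its fold's training set, though its
#'   disease and its country may.
#' * `split_by_country()` — previously unseen countries: countries are
#'   partitioned into `k` folds; every record of a validation country is
#'   excluded from that fold's training set.
#' * `split_by_disease()` — previously unseen diseases: identical with
#'   diseases as the held-out entity.
#'
#' Fold sizes differ by at most one entity; the partition is a pure
#' function of `(table, k, seed)`.
#'
#' @param table An [incidence_table()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the entity shuffle.
#' @return A `split_plan`: list with `scheme`, `k`, `seed`, `entity_folds`
#'   (held-out entities per fold) and `folds`, a list of
#'   `list(train, validation)` row-index vectors into `table`.
#' @name split_plan
NULL

split_entities <- function(table, k, seed, scheme, entity_of) {
  stopifnot(inherits(table, "incidence_table"))
  k <- check_count(k, "k", min = 2L)
  seed <- check_seed(seed)
  entities <- unique(entity_of(table))
  if (length(entities) < k) {
    abort(sprintf("%s scheme needs at least k = %d distinct entities (have %d)",
                  scheme, k, length(entities)),
          "incembed_invalid_argument")
  }
  shuffled <- with_seed(seed, sample(entities))
  fold_id <- rep(seq_len(k), length.out = length(shuffled))
  entity_folds <- split(shuffled, fold_id)
  names(entity_folds) <- NULL
  row_entity <- entity_of(table)
  folds <- lapply(entity_folds, function(held) {
    validation <- which(row_entity %in% held)
    list(train = setdiff(seq_len(nrow(table)), validation),
         validation = validation)
  })
  structure(list(scheme = scheme, k = k, seed = seed,
                 entity_folds = entity_folds, folds = folds,
                 n_rows = nrow(table)),
            class = "split_plan")
}

pair_key <- function(table) paste(table$disease, table$country, sep = " || ")

#' @rdname split_plan
#' @export
split_pairs <- function(table, k = 10L, seed = 1L) {
  split_entities(table, k, seed, "pair", pair_key)
}

#' @rdname split_plan
#' @export
split_by_country <- function(table, k = 10L, seed = 1L) {
  split_entities(table, k, seed, "country", function(t) t$country)
}

#' @rdname split_plan
#' @export
split_by_disease <- function(table, k = 10L, seed = 1L) {
  split_entities(table, k, seed, "disease", function(t) t$disease)
}

#' Single-fold plan for independent test-set evaluation
#'
#' Models develop on a full table and are then applied once to an
#' independent test table; this is represented as a one-fold plan whose
#' training set is the whole development table and whose validation set is
#' the appended test rows.
#'
#' @param dev_rows,test_rows Row counts of the development and test parts
#'   of the combined table (development rows first).
#' @return A `split_plan` with scheme `"holdout"` and one fold.
#' @export
holdout_plan <- function(dev_rows, test_rows) {
  dev_rows <- check_count(dev_rows, "dev_rows")
  test_rows <- check_count(test_rows, "test_rows")
  structure(list(scheme = "holdout", k = 1L, seed = NA_integer_,
                 entity_folds = list(character()),
                 folds = list(list(train = seq_len(dev_rows),
                                   validation = dev_rows + seq_len(test_rows))),
                 n_rows = dev_rows + test_rows),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$validation), integer(1))
  cat(sprintf("<split_plan> scheme=%s, k=%d, seed=%s; validation rows per fold: %s\n",
              x$scheme, x$k, format(x$seed),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

scheme_entity_fn <- function(scheme) {
  switch(scheme,
         pair = pair_key,
         country = function(t) t$country,
         disease = function(t) t$disease,
         holdout = NULL)
}

#' Validate a split plan against a table
#'
#' Checks the structural guarantees every plan must satisfy — validation
#' sets are non-empty, pairwise disjoint and jointly cover all rows; per
#' fold, train and validation partition the rows — plus the scheme-specific
#' exclusivity (no held-out pair/country/disease leaks into its fold's
#' training rows). Failures are reported with counter-examples, not thrown.
#'
#' @param plan A `split_plan`.
#' @param table The [incidence_table()] the plan indexes.
#' @return A list with `pass` (logical) and `failures` (character vector of
#'   human-readable counter-examples; empty when `pass`).
#' @export
validate_split <- function(plan, table) {
  stopifnot(inherits(plan, "split_plan"), inherits(table, "incidence_table"))
  failures <- character()
  n <- nrow(table)
  if (!identical(plan$n_rows, n)) {
    failures <- c(failures, sprintf("plan built for %d rows, table has %d",
                                    plan$n_rows, n))
  }
  all_val <- unlist(lapply(plan$folds, `[[`, "validation"))
  if (anyDuplicated(all_val)) {
    failures <- c(failures, sprintf(
      "validation sets overlap (e.g. row %d in two folds)",
      all_val[duplicated(all_val)][1]))
  }
  if (plan$scheme != "holdout" && !setequal(all_val, seq_len(n))) {
    miss <- setdiff(seq_len(n), all_val)
    failures <- c(failures, sprintf(
      "validation sets do not cover all rows (e.g. row %s missing)",
      ifelse(length(miss), miss[1], "?")))
  }
  entity_of <- scheme_entity_fn(plan$scheme)
  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    if (length(fold$validation) == 0) {
      failures <- c(failures, sprintf("fold %d has an empty validation set", i))
      next
    }
    if (length(fold$train) == 0) {
      failures <- c(failures, sprintf("fold %d has an empty training set", i))
    }
    if (length(intersect(fold$train, fold$validation))) {
      failures <- c(failures, sprintf(
        "fold %d: train and validation share row %d", i,
        intersect(fold$train, fold$validation)[1]))
    }
    if (plan$scheme != "holdout" &&
        !setequal(union(fold$train, fold$validation), seq_len(n))) {
      failures <- c(failures, sprintf(
        "fold %d: train + validation do not cover the table", i))
    }
    if (!is.null(entity_of)) {
      leak <- intersect(entity_of(table[fold$train, , drop = FALSE]),
                        entity_of(table[fold$validation, , drop = FALSE]))
      if (length(leak)) {
        failures <- c(failures, sprintf(
          "fold %d: held-out %s %s appears in training rows", i,
          plan$scheme, dQuote(leak[1])))
      }
    }
  }
  list(pass = length(failures) == 0, failures = failures)
}

#' Serialize / restore split plans as JSON
#'
#' Plans are written with scheme, k, seed and per-fold held-out entity
#' lists plus row indices, so a fold assignment can be re-used exactly.
#'
#' @param plan A `split_plan`.
#' @param path JSON file path.
#' @return `write_split_plan()`: invisibly, `path`; `read_split_plan()`:
#'   the restored `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(
    list(scheme = plan$scheme, k = plan$k, seed = plan$seed,
         n_rows = plan$n_rows, entity_folds = plan$entity_folds,
         folds = lapply(plan$folds, function(f)
           list(train = f$train, validation = f$validation))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    scheme = raw$scheme, k = as.integer(raw$k), seed = as.integer(raw$seed),
    entity_folds = lapply(raw$entity_folds, function(e)
      vapply(e, as.character, character(1))),
    folds = lapply(raw$folds, function(f)
      list(train = vapply(f$train, as.integer, integer(1)),
           validation = vapply(f$validation, as.integer, integer(1)))),
    n_rows = as.integer(raw$n_rows)),
    class = "split_plan")
}
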