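#' Experiment configuration
#'
#' A declarative description of one end-to-end experiment: where the data
#' comes from (a synthetic world or files on disk), which embedding
#' provider serves each entity type, the split scheme, the model kind and
#' its training recipe, and a single top-level seed from which every stage
#' seed is derived (`derive_seed(seed, stage_name)`), so one integer
#' reproduces the whole run.
#'
#' @param data For synthetic data, `list(source = "synthetic", ...)` with
#'   any [make_world()] / [sample_incidence()] / [derive_embeddings()]
#'   arguments; for files, `list(source = "files", incidence = path,
#'   column_map = ...)`.
#' @param providers Per-entity provider specs, e.g.
#'   `list(disease = list(type = "synthetic"), country = list(type =
#'   "hash", dim = 16))`; types: `"synthetic"`, `"entity_tsv"` (needs
#'   `path`), `"word2vec"` (needs `path`; bag-of-words aggregated, honours
#'   `oov_policy`), `"hash"` (needs `dim`).
#' @param scheme `"pair"`, `"country"` or `"disease"`.
#' @param k Fold count.
#' @param model Model kind (see [cross_validate()]).
#' @param regressor Named list of [regressor_config()] overrides.
#' @param group_of Concordance grouping column (default `"country"`).
#' @param seed Top-level integer seed.
#' @return A validated `experiment_config`.
#' @export
experiment_config <- function(data = list(source = "synthetic"),
                              providers = list(
                                disease = list(type = "synthetic"),
                                country = list(type = "synthetic")),
                              scheme = c("pair", "country", "disease"),
                              k = 10L, model = "mlp",
                              regressor = list(), group_of = "country",
                              seed = 1L) {
  scheme <- match.arg(scheme)
  if (!identical(data$source, "synthetic") &&
      !identical(data$source, "files")) {
    abort("data$source must be \"synthetic\" or \"files\"",
          "incembed_invalid_argument")
  }
  cfg <- structure(list(data = data, providers = providers, scheme = scheme,
                        k = check_count(k, "k", min = 2L), model = model,
                        regressor = regressor, group_of = group_of,
                        seed = check_seed(seed)),
                   class = "experiment_config")
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(config) {
  if (identical(config$data$source, "files")) {
    if (is.null(config$data$incidence) ||
        !file.exists(config$data$incidence)) {
      abort(sprintf("incidence file not found: %s",
                    config$data$incidence %||% "<missing>"),
            "incembed_invalid_argument")
    }
  }
  for (entity in c("disease", "country")) {
    spec <- config$providers[[entity]]
    if (is.null(spec$type)) {
      abort(sprintf("providers$%s$type is required", entity),
            "incembed_invalid_argument")
    }
    if (spec$type %in% c("entity_tsv", "word2vec") &&
        (is.null(spec$path) || !file.exists(spec$path))) {
      abort(sprintf("providers$%s: path not found: %s", entity,
                    spec$path %||% "<missing>"),
            "incembed_invalid_argument")
    }
    if (identical(spec$type, "synthetic") &&
        !identical(config$data$source, "synthetic")) {
      abort(sprintf(
        "providers$%s: synthetic provider requires synthetic data", entity),
        "incembed_invalid_argument")
    }
  }
  invisible(config)
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          "incembed_invalid_argument")
  }
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

build_provider <- function(spec, entity, world, config) {
  switch(spec$type,
    synthetic = entity_provider(derive_embeddings(
      world, entity,
      dim = spec$dim %||% config$data$embedding_dim %||% 16L,
      informativeness = spec$informativeness %||%
        config$data$informativeness %||% 1,
      seed = derive_seed(config$seed, paste0("embed-", entity)))),
    entity_tsv = entity_provider(read_entity_vectors(spec$path)),
    word2vec = bow_provider(read_word_vectors(spec$path),
                            oov_policy = spec$oov_policy %||% "error"),
    hash = hash_provider(spec$dim %||% 16L,
                         seed = derive_seed(config$seed,
                                            paste0("hash-", entity))),
    abort(sprintf("unknown provider type %s", dQuote(spec$type)),
          "incembed_invalid_argument"))
}

#' Run an experiment end to end
#'
#' Executes generate/load, zero filtering, split construction, per-fold
#' training and pooled evaluation as declared by an [experiment_config()],
#' writing the evaluation report (JSON), the split plan (JSON), the pooled
#' predictions (CSV) and a structured JSON-lines log — including the
#' zero-removal count — to `out_dir`.
#'
#' @param config An `experiment_config` (or a YAML path).
#' @param out_dir Output directory; created if missing. `NULL` skips all
#'   file output.
#' @return The [cross_validate()] result, invisibly carrying `out_dir`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  validate_experiment_config(config)
  log_lines <- list()
  log_stage <- function(stage, ...) {
    log_lines[[length(log_lines) + 1]] <<- c(list(stage = stage), list(...))
  }

  world <- NULL
  if (identical(config$data$source, "synthetic")) {
    d <- config$data
    world <- make_world(
      n_diseases = d$n_diseases %||% 50L,
      n_countries = d$n_countries %||% 30L,
      n_age = d$n_age %||% 20L,
      q = d$q %||% 3L,
      n_disease_groups = d$n_disease_groups %||% 5L,
      n_country_clusters = d$n_country_clusters %||% 4L,
      seed = derive_seed(config$seed, "world"))
    table <- sample_incidence(world,
                              noise_sd = d$noise_sd %||% 0.1,
                              zero_rate = d$zero_rate %||% 0.21,
                              seed = derive_seed(config$seed, "incidence"))
    log_stage("generate", rows = nrow(table))
  } else {
    table <- read_incidence_csv(
      config$data$incidence,
      column_map = unlist(config$data$column_map) %||%
        c(disease = "disease", country = "country",
          age_group = "age_group", incidence = "incidence"),
      n_age = config$data$n_age %||% 20L)
    log_stage("load", rows = nrow(table), path = config$data$incidence)
  }

  filtered <- filter_zero_incidence(table)
  log_stage("filter_zeros", removed = filtered$removed,
            rows = nrow(filtered$table),
            removed_fraction = filtered$removed / nrow(table))
  table <- filtered$table

  disease_provider <- build_provider(config$providers$disease, "disease",
                                     world, config)
  country_provider <- build_provider(config$providers$country, "country",
                                     world, config)
  log_stage("providers", disease = disease_provider$id,
            country = country_provider$id)

  split_fn <- switch(config$scheme, pair = split_pairs,
                     country = split_by_country, disease = split_by_disease)
  plan <- split_fn(table, k = config$k,
                   seed = derive_seed(config$seed, "split"))
  log_stage("split", scheme = config$scheme, k = config$k)

  reg <- do.call(regressor_config,
                 c(config$regressor,
                   list(seed = derive_seed(config$seed, "train"))))
  result <- cross_validate(table, disease_provider, country_provider, plan,
                           model = config$model, config = reg,
                           group_of = config$group_of)
  log_stage("evaluate", mae = result$report$mae,
            concordance = result$report$concordance,
            n_scored = result$report$n_scored,
            n_not_applicable = result$report$n_not_applicable)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(result$report, file.path(out_dir, "report.json"))
    write_split_plan(plan, file.path(out_dir, "split_plan.json"))
    write.csv(result$predictions, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    writeLines(vapply(log_lines, function(l)
      jsonlite::toJSON(l, auto_unbox = TRUE, digits = 10), character(1)),
      file.path(out_dir, "log.jsonl"))
    result$out_dir <- out_dir
  }
  invisible(result)
}
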