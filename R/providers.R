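#' Embedding providers
#'
#' A provider wraps "how do I turn an entity name into a feature vector"
#' behind a uniform interface: a fixed output dimension, a provenance id,
#' and an `embed(name)` function. Providers are what the feature-assembly
#' and cross-validation layers consume, so word-aggregated, entity-native,
#' hash and fused representations are interchangeable.
#'
#' * `entity_provider()` — exact-name lookup in an entity-level table.
#' * `bow_provider()` — bag-of-words min/max/mean aggregation over a
#'   word-level table (output dimension `3 * dim`).
#' * `hash_provider()` — deterministic uninformative control vectors.
#' * `fusion_provider()` — concatenation of two or more providers, in the
#'   given order.
#'
#' @param table An [embedding_table()] of the appropriate level.
#' @param oov_policy Passed to [embed_bag_of_words()].
#' @param dim,seed For `hash_provider()`, the output dimension and seed.
#' @param providers For `fusion_provider()`, a list of providers.
#' @param id Optional provenance id override.
#' @return An object of class `embedding_provider` with fields `id`, `dim`,
#'   `level` and function `embed`.
#' @name embedding_provider
NULL

new_provider <- function(id, dim, level, embed_fn) {
  structure(list(id = id, dim = as.integer(dim), level = level,
                 embed = embed_fn),
            class = "embedding_provider")
}

#' @rdname embedding_provider
#' @export
entity_provider <- function(table, id = NULL) {
  stopifnot(inherits(table, "embedding_table"), table$level == "entity")
  if (is.null(id)) id <- table$provider_id
  new_provider(id, table$dim, "entity",
               function(name) as.numeric(embed_entity(table, name)))
}

#' @rdname embedding_provider
#' @export
bow_provider <- function(table, oov_policy = "error", id = NULL) {
  stopifnot(inherits(table, "embedding_table"), table$level == "word")
  if (is.null(id)) id <- paste0(table$provider_id, "+bow")
  new_provider(id, 3L * table$dim, "word",
               function(name) {
                 as.numeric(embed_bag_of_words(table, name, oov_policy))
               })
}

#' @rdname embedding_provider
#' @export
hash_provider <- function(dim, seed = 1L, id = "hash") {
  new_provider(id, dim, "hash",
               function(name) as.numeric(hash_embed(name, dim, seed)))
}

#' @rdname embedding_provider
#' @export
fusion_provider <- function(providers, id = NULL) {
  if (!is.list(providers) || length(providers) < 2 ||
      !all(vapply(providers, inherits, logical(1), "embedding_provider"))) {
    abort("fusion_provider needs a list of >= 2 embedding_providers",
          "incembed_invalid_argument")
  }
  ids <- vapply(providers, `[[`, character(1), "id")
  if (is.null(id)) id <- paste0("fusion(", paste(ids, collapse = "+"), ")")
  dim <- sum(vapply(providers, `[[`, integer(1), "dim"))
  new_provider(id, dim, "fused", function(name) {
    unlist(lapply(providers, function(p) p$embed(name)))
  })
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider> %s (dim %d, level %s)\n",
              x$id, x$dim, x$level))
  invisible(x)
}

# Embed each unique name once and return the n_names x dim matrix, with a
# classed error naming the offending entity on provider failure.
provider_matrix <- function(provider, names) {
  uniq <- unique(names)
  mat <- matrix(NA_real_, length(uniq), provider$dim,
                dimnames = list(uniq, NULL))
  for (nm in uniq) {
    vec <- tryCatch(provider$embed(nm), incembed_error = function(e) {
      abort(sprintf("provider %s failed for entity %s: %s",
                    provider$id, dQuote(nm), conditionMessage(e)),
            "incembed_provider_error")
    })
    if (length(vec) != provider$dim) {
      abort(sprintf("provider %s returned length %d for %s (expected %d)",
                    provider$id, length(vec), dQuote(nm), provider$dim),
            "incembed_provider_error")
    }
    mat[nm, ] <- vec
  }
  mat
}
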