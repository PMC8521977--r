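#' Construct an embedding table
#'
#' A table of fixed-dimension real vectors keyed by normalized token or
#' entity name. `level = "word"` tables are queried token-wise (and fed to
#' [embed_bag_of_words()]); `level = "entity"` tables are queried by full
#' name via [embed_entity()].
#'
#' @param vectors Numeric matrix, one row per key; rownames are the keys
#'   (normalized with [normalize_name()] on construction).
#' @param level `"word"` or `"entity"`.
#' @param provider_id Free-text provenance tag (e.g. `"glove"`, `"biobert"`,
#'   `"use"`, `"hash"`, `"synthetic"`).
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, level = c("word", "entity"),
                            provider_id = "unknown") {
  level <- match.arg(level)
  if (!is.matrix(vectors) || !is.numeric(vectors) || nrow(vectors) == 0) {
    abort("`vectors` must be a non-empty numeric matrix",
          "incembed_invalid_argument")
  }
  if (is.null(rownames(vectors))) {
    abort("`vectors` must have rownames (the keys)",
          "incembed_invalid_argument")
  }
  keys <- normalize_name(rownames(vectors))
  if (anyDuplicated(keys)) {
    warning("duplicate keys after normalization; last occurrence wins")
    keep <- !duplicated(keys, fromLast = TRUE)
    vectors <- vectors[keep, , drop = FALSE]
    keys <- keys[keep]
  }
  dimnames(vectors) <- list(keys, NULL)
  structure(list(vectors = vectors, dim = ncol(vectors), level = level,
                 provider_id = provider_id),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d %s vectors of dim %d (provider: %s)\n",
              nrow(x$vectors), x$level, x$dim, x$provider_id))
  invisible(x)
}

#' Read word vectors in word2vec text format
#'
#' Accepts the plain-text dialect used by word2vec/GloVe exports: an
#' optional first line `"<count> <dim>"`, then one line per token holding
#' the token followed by `dim` floats. Tokens are normalized to lowercase;
#' on duplicates the last occurrence wins (with a warning).
#'
#' @param path File path.
#' @param provider_id Provenance tag stored on the table (default from the
#'   file name).
#' @return An [embedding_table()] with `level = "word"`.
#' @export
read_word_vectors <- function(path, provider_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "incembed_invalid_argument")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("empty embedding file: %s", path), "incembed_format_error")
  }
  first <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  offset <- 0L
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    offset <- 1L  # count/dim header
    lines <- lines[-1L]
    if (length(lines) == 0) {
      abort(sprintf("embedding file has a header but no vectors: %s", path),
            "incembed_format_error")
    }
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  dim <- length(parts[[1]]) - 1L
  if (dim < 1) {
    abort(sprintf("%s:%d: no vector components on line", path, 1L + offset),
          "incembed_format_error")
  }
  tokens <- character(length(parts))
  vecs <- matrix(NA_real_, length(parts), dim)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != dim + 1L) {
      abort(sprintf("%s:%d: expected %d vector components, found %d",
                    path, i + offset, dim, length(p) - 1L),
            "incembed_format_error")
    }
    vals <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(vals)) {
      abort(sprintf("%s:%d: non-numeric vector component", path, i + offset),
            "incembed_format_error")
    }
    tokens[i] <- p[[1L]]
    vecs[i, ] <- vals
  }
  rownames(vecs) <- tokens
  if (is.null(provider_id)) provider_id <- basename(path)
  embedding_table(vecs, level = "word", provider_id = provider_id)
}

#' Write an embedding table in word2vec text format
#'
#' Writes the `"<count> <dim>"` header then one token per line. Spaces in
#' keys are replaced by underscores so multi-word entity names survive the
#' whitespace-delimited format; [read_word_vectors()] followed by
#' [tokenize()]-free entity lookup will not round-trip those, but
#' [read_entity_vectors()]/[write_entity_vectors()] (TSV) will.
#'
#' @param table An [embedding_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_word_vectors <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  keys <- gsub(" ", "_", rownames(table$vectors), fixed = TRUE)
  body <- vapply(seq_along(keys), function(i) {
    paste(keys[i], paste(format(table$vectors[i, ], digits = 17,
                                scientific = TRUE, trim = TRUE),
                         collapse = " "))
  }, character(1))
  writeLines(c(paste(length(keys), table$dim), body), path)
  invisible(path)
}

#' Read/write entity-level vectors as name-to-vector TSV
#'
#' The TSV dialect keeps full (possibly multi-word) entity names: a header
#' `name<TAB>v1...<TAB>v<dim>`, then one entity per line.
#'
#' @param path File path.
#' @param provider_id Provenance tag (default from the file name).
#' @return An [embedding_table()] with `level = "entity"`.
#' @export
read_entity_vectors <- function(path, provider_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "incembed_invalid_argument")
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || nrow(df) == 0) {
    abort(sprintf("malformed entity-vector TSV: %s", path),
          "incembed_format_error")
  }
  vecs <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vecs)) {
    abort(sprintf("non-numeric vector columns in %s", path),
          "incembed_format_error")
  }
  rownames(vecs) <- as.character(df[[1L]])
  if (is.null(provider_id)) provider_id <- basename(path)
  embedding_table(vecs, level = "entity", provider_id = provider_id)
}

#' @rdname read_entity_vectors
#' @param table An [embedding_table()] to write.
#' @export
write_entity_vectors <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  df <- data.frame(name = rownames(table$vectors),
                   table$vectors, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("name", paste0("v", seq_len(table$dim)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tokenize an entity name
#'
#' Disease and country names are treated as little sentences: lowercase,
#' split on whitespace, hyphens and slashes, strip remaining punctuation,
#' drop empty tokens, preserve order.
#'
#' @param name A single character string.
#' @return Character vector of tokens.
#' @examples
#' tokenize("HIV/AIDS")       # "hiv"  "aids"
#' tokenize("Guinea-Bissau")  # "guinea" "bissau"
#' @export
tokenize <- function(name) {
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    abort("`name` must be a non-empty string", "incembed_invalid_argument")
  }
  s <- tolower(name)
  s <- gsub("[-/_]", " ", s)
  s <- gsub("[^a-z0-9 ]", "", s)
  tokens <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    abort(sprintf("name %s normalizes to zero tokens", dQuote(name)),
          "incembed_invalid_argument")
  }
  tokens
}

new_sentence_embedding <- function(vector, source_level, parts = NULL) {
  structure(as.numeric(vector), source_level = source_level, parts = parts,
            class = "sentence_embedding")
}

#' Bag-of-words sentence embedding (element-wise min / max / mean)
#'
#' Word-level embedding models yield one vector per token; a multi-word
#' name is summarised by the element-wise minimum, maximum and mean of its
#' in-vocabulary token vectors, concatenated in that fixed order, giving a
#' `3 * dim` sentence vector. The aggregation is permutation-invariant and
#' idempotent for single-token names.
#'
#' @param table An [embedding_table()] with `level = "word"`.
#' @param name Entity name (tokenized with [tokenize()]).
#' @param oov_policy What to do with out-of-vocabulary tokens: `"error"`
#'   (default) aborts, `"skip"` drops them, `"zero"` substitutes a zero
#'   vector. If every token is out of vocabulary, an error is raised
#'   regardless of policy.
#' @return A `sentence_embedding` of length `3 * dim` with
#'   `source_level = "word-aggregated"` and the segment order recorded in
#'   its `parts` attribute.
#' @export
embed_bag_of_words <- function(table, name,
                               oov_policy = c("error", "skip", "zero")) {
  stopifnot(inherits(table, "embedding_table"))
  oov_policy <- match.arg(oov_policy)
  if (table$level != "word") {
    abort("bag-of-words aggregation needs a word-level table",
          "incembed_invalid_argument")
  }
  tokens <- tokenize(name)
  present <- tokens %in% rownames(table$vectors)
  if (!all(present) && oov_policy == "error") {
    abort(sprintf("out-of-vocabulary token(s) for %s: %s", dQuote(name),
                  paste(tokens[!present], collapse = ", ")),
          "incembed_missing_entity")
  }
  if (!any(present)) {
    abort(sprintf("every token of %s is out of vocabulary", dQuote(name)),
          "incembed_missing_entity")
  }
  use <- if (oov_policy == "zero") {
    rbind(table$vectors[tokens[present], , drop = FALSE],
          matrix(0, sum(!present), table$dim))
  } else {
    table$vectors[tokens[present], , drop = FALSE]
  }
  agg <- c(apply(use, 2, min), apply(use, 2, max), colMeans(use))
  new_sentence_embedding(agg, "word-aggregated",
                         parts = c("min", "max", "mean"))
}

#' Entity-level sentence embedding lookup
#'
#' Exact-match lookup of a normalized entity name in an entity-level table
#' (the path used for sentence-capable providers whose vectors are
#' precomputed per entity).
#'
#' @param table An [embedding_table()] with `level = "entity"`.
#' @param name Entity name.
#' @return A `sentence_embedding` with `source_level = "entity-native"`.
#' @export
embed_entity <- function(table, name) {
  stopifnot(inherits(table, "embedding_table"))
  if (table$level != "entity") {
    abort("embed_entity needs an entity-level table",
          "incembed_invalid_argument")
  }
  key <- normalize_name(name)
  keys <- rownames(table$vectors)
  if (!key %in% keys) {
    near <- keys[order(utils::adist(key, keys))]
    abort(sprintf("no embedding for entity %s; nearest keys: %s",
                  dQuote(key),
                  paste(utils::head(near, 3), collapse = ", ")),
          "incembed_missing_entity")
  }
  new_sentence_embedding(table$vectors[key, ], "entity-native")
}

#' Fuse sentence embeddings by concatenation
#'
#' Feature fusion combines the representations from several providers into
#' one vector by concatenation, in the supplied (and recorded) order.
#'
#' @param parts List of at least two `sentence_embedding`s (or numeric
#'   vectors).
#' @param order_tags Optional character vector naming the parts; recorded
#'   in the result's `parts` attribute.
#' @return A `sentence_embedding` whose length is the sum of part lengths.
#' @export
fuse <- function(parts, order_tags = NULL) {
  if (!is.list(parts) || length(parts) < 2) {
    abort("fusion needs at least 2 parts", "incembed_invalid_argument")
  }
  if (is.null(order_tags)) order_tags <- paste0("part", seq_along(parts))
  new_sentence_embedding(unlist(lapply(parts, as.numeric)),
                         "fused", parts = order_tags)
}

# 32-bit polynomial string hash (deterministic across platforms/sessions).
string_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

#' Deterministic pseudo-random embedding keyed by name
#'
#' An intentionally uninformative control provider: every normalized name
#' maps to a reproducible standard-normal vector keyed by `(name, seed)`,
#' so distinct names get (in expectation) uncorrelated vectors. Used to
#' measure how much of a model's performance is attributable to embedding
#' content rather than capacity.
#'
#' @param name Entity name.
#' @param dim Embedding dimension.
#' @param seed Integer seed shared by the provider.
#' @return A `sentence_embedding` of length `dim`.
#' @export
hash_embed <- function(name, dim, seed = 1L) {
  dim <- check_count(dim, "dim")
  seed <- check_seed(seed)
  key <- normalize_name(name)
  h <- (string_hash(key) + 7919 * as.numeric(seed)) %% 2147483647
  vec <- with_seed(as.integer(h), rnorm(dim))
  new_sentence_embedding(vec, "hash")
}
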