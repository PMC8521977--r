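#' Age band labels
#'
#' The canonical twenty 5-year age bands `"0-4", "5-9", ..., "90-94",
#' "95+"`; index 0 is `"0-4"`, index `n_age - 1` the open-ended last band.
#'
#' @param n_age Number of bands (default 20).
#' @return Character vector of band labels.
#' @export
age_band_labels <- function(n_age = 20L) {
  n_age <- check_count(n_age, "n_age")
  lo <- seq(0L, by = 5L, length.out = n_age)
  c(paste(lo[-n_age], lo[-n_age] + 4L, sep = "-"), paste0(lo[n_age], "+"))
}

# Accepts 0-based integer indices, band labels ("30-34", en/em dashes
# tolerated), or "95+"-style open bands; returns 0-based indices.
parse_age_group <- function(x, n_age) {
  labels <- age_band_labels(n_age)
  raw <- trimws(as.character(x))
  canon <- gsub("–|—", "-", raw)          # en/em dash -> hyphen
  canon <- gsub("[[:space:]]*-[[:space:]]*", "-", canon)
  canon <- sub("[[:space:]]+years?$", "", canon)
  idx <- match(canon, labels) - 1L
  numeric_like <- grepl("^[0-9]+$", canon)
  idx[is.na(idx) & numeric_like] <-
    as.integer(canon[is.na(idx) & numeric_like])
  bad <- is.na(idx) | idx < 0L | idx >= n_age
  if (any(bad)) {
    abort(sprintf("unknown age group label(s): %s",
                  paste(unique(raw[bad]), collapse = ", ")),
          "incembed_parse_error")
  }
  as.integer(idx)
}

#' Construct / validate an incidence table
#'
#' An incidence table is a data frame with columns `disease`, `country`,
#' `age_group` (0-based integer index into the 5-year bands) and
#' `incidence` (non-negative, cases per 100,000 population). Names are
#' normalized, ranges validated, and `(disease, country, age_group)`
#' uniqueness enforced.
#'
#' @param df A data frame with the four columns.
#' @param n_age Number of age bands used to validate `age_group`.
#' @return The validated data frame with class `incidence_table`.
#' @export
incidence_table <- function(df, n_age = max(df$age_group) + 1L) {
  required <- c("disease", "country", "age_group", "incidence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "incembed_invalid_argument")
  }
  df <- as.data.frame(df)[required]
  df$disease <- normalize_name(df$disease)
  df$country <- normalize_name(df$country)
  df$age_group <- as.integer(df$age_group)
  df$incidence <- as.numeric(df$incidence)
  if (anyNA(df$age_group) || any(df$age_group < 0L)) {
    abort("age_group must be non-negative integers",
          "incembed_validation_error")
  }
  if (anyNA(df$incidence) || any(df$incidence < 0)) {
    abort("incidence must be non-negative and non-missing",
          "incembed_validation_error")
  }
  key <- paste(df$disease, df$country, df$age_group, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(sprintf("duplicate (disease, country, age_group) key(s): %s",
                  paste(utils::head(gsub("\r", " / ", dups), 5),
                        collapse = "; ")),
          "incembed_validation_error")
  }
  rownames(df) <- NULL
  class(df) <- c("incidence_table", "data.frame")
  attr(df, "n_age") <- as.integer(n_age)
  df
}

#' Read an incidence table from delimited text
#'
#' Reads a CSV with a header row and maps its columns onto the canonical
#' `disease` / `country` / `age_group` / `incidence` schema via
#' `column_map`, so GBD-style export headers can be consumed without
#' editing the file. Age values may be 0-based indices or band labels
#' (`"30-34"`, `"95+"`, en-dashes tolerated).
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names.
#' @param n_age Number of age bands (default 20).
#' @param denominator Population denominator of the incidence column;
#'   values are rescaled to per-100,000.
#' @return An [incidence_table()].
#' @examples
#' \dontrun{
#' read_incidence_csv("gbd.csv",
#'   column_map = c(disease = "cause_name", country = "location_name",
#'                  age_group = "age_name", incidence = "val"))
#' }
#' @export
read_incidence_csv <- function(path,
                               column_map = c(disease = "disease",
                                              country = "country",
                                              age_group = "age_group",
                                              incidence = "incidence"),
                               n_age = 20L, denominator = 1e5) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "incembed_invalid_argument")
  }
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("disease", "country", "age_group", "incidence")
  if (!all(needed %in% names(column_map))) {
    abort("column_map must name disease, country, age_group and incidence",
          "incembed_invalid_argument")
  }
  absent <- setdiff(unname(column_map[needed]), names(raw))
  if (length(absent)) {
    abort(sprintf("column(s) not in file: %s", paste(absent, collapse = ", ")),
          "incembed_parse_error")
  }
  df <- data.frame(
    disease = raw[[column_map[["disease"]]]],
    country = raw[[column_map[["country"]]]],
    age_group = parse_age_group(raw[[column_map[["age_group"]]]], n_age),
    incidence = as.numeric(raw[[column_map[["incidence"]]]]) *
      (1e5 / denominator),
    stringsAsFactors = FALSE
  )
  incidence_table(df, n_age = n_age)
}

#' @rdname read_incidence_csv
#' @param table An [incidence_table()] to write (header
#'   `disease,country,age_group,incidence`).
#' @export
write_incidence_csv <- function(table, path) {
  stopifnot(inherits(table, "incidence_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove zero-incidence records
#'
#' Zero cells in GBD-like exports conflate "no data" with "truly zero", and
#' zeros have no log10 image, so they are removed before the log transform
#' rather than imputed. Original row order is preserved.
#'
#' @param table An [incidence_table()].
#' @return A list with `table` (the filtered [incidence_table()]) and
#'   `removed` (the number of rows dropped).
#' @export
filter_zero_incidence <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  keep <- table$incidence != 0
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "n_age") <- attr(table, "n_age")
  list(table = out, removed = sum(!keep))
}

#' Log10 transform of incidence and its inverse
#'
#' Incidence distributions are highly skewed, so models fit log10 rates.
#' `log_transform()` maps a positive per-100,000 rate to its log10;
#' `inverse_transform()` maps a model output `x` back to the rate
#' `10^x` per 100,000 and the corresponding proportion `10^x / 100000`.
#'
#' @param incidence Positive incidence rate(s) per 100,000.
#' @param x Log10-scale value(s).
#' @return `log_transform()`: numeric vector. `inverse_transform()`: a list
#'   with `per_100k` and `proportion`.
#' @export
log_transform <- function(incidence) {
  if (length(incidence) == 0 || anyNA(incidence) || any(incidence <= 0)) {
    abort("incidence must be > 0 for the log transform (filter zeros first)",
          "incembed_domain_error")
  }
  log10(incidence)
}

#' @rdname log_transform
#' @export
inverse_transform <- function(x) {
  per_100k <- 10^x
  list(per_100k = per_100k, proportion = per_100k / 1e5)
}

#' One-hot encode an age-band index
#'
#' @param age_group 0-based band index.
#' @param n_age Number of bands.
#' @return Binary vector of length `n_age` with a single 1.
#' @export
encode_age <- function(age_group, n_age = 20L) {
  n_age <- check_count(n_age, "n_age")
  if (length(age_group) != 1L || is.na(age_group) ||
      age_group != round(age_group) || age_group < 0 || age_group >= n_age) {
    abort(sprintf("age_group must be an integer in [0, %d]", n_age - 1L),
          "incembed_invalid_argument")
  }
  vec <- numeric(n_age)
  vec[age_group + 1L] <- 1
  vec
}

#' Assemble the model feature matrix
#'
#' Builds one row per incidence record: the disease embedding, the country
#' embedding and the one-hot age band concatenated in that order, with
#' `y = log10(incidence)` as the target. The segment layout (offsets and
#' provider ids) is recorded so models can verify inputs at predict time.
#' The table must already be zero-filtered.
#'
#' @param table An [incidence_table()] with strictly positive incidence.
#' @param disease_provider,country_provider [embedding_provider]s.
#' @param n_age Number of age bands.
#' @return A `feature_matrix`: list with `x` (numeric matrix), `y`
#'   (log10 incidence), `keys` (the record keys) and `layout`.
#' @export
assemble_features <- function(table, disease_provider, country_provider,
                              n_age = attr(table, "n_age")) {
  stopifnot(inherits(table, "incidence_table"),
            inherits(disease_provider, "embedding_provider"),
            inherits(country_provider, "embedding_provider"))
  if (is.null(n_age)) n_age <- 20L
  n_age <- check_count(n_age, "n_age")
  if (any(table$age_group >= n_age)) {
    abort("age_group exceeds n_age", "incembed_invalid_argument")
  }
  y <- log_transform(table$incidence)
  dmat <- provider_matrix(disease_provider, table$disease)
  cmat <- provider_matrix(country_provider, table$country)
  amat <- matrix(0, nrow(table), n_age)
  amat[cbind(seq_len(nrow(table)), table$age_group + 1L)] <- 1
  x <- cbind(dmat[table$disease, , drop = FALSE],
             cmat[table$country, , drop = FALSE],
             amat)
  dimnames(x) <- NULL
  layout <- list(
    segments = data.frame(
      name = c("disease", "country", "age"),
      provider = c(disease_provider$id, country_provider$id, "onehot-age"),
      offset = c(0L, disease_provider$dim,
                 disease_provider$dim + country_provider$dim),
      length = c(disease_provider$dim, country_provider$dim, n_age),
      stringsAsFactors = FALSE
    ),
    n_age = n_age
  )
  structure(list(x = x, y = y,
                 keys = table[, c("disease", "country", "age_group")],
                 layout = layout),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d rows x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s:%d", x$layout$segments$name,
                            x$layout$segments$length), collapse = " + ")))
  invisible(x)
}

# Per-feature z-scoring fit on training rows only; constant columns (e.g.
# one-hot indicators that never fire in a fold) keep sd 1 so they pass
# through unchanged.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  list(mean = mu, sd = sdev)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}
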