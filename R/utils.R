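#' @useDynLib incembed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd predict
#' @importFrom utils head read.csv write.csv
NULL

# Stop with a classed condition so callers can distinguish argument misuse,
# format problems and missing entities programmatically.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "incembed_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s)",
                  name, min, paste(format(x), collapse = ", ")),
          "incembed_invalid_argument")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.finite(x) || x > max ||
      (if (strict_min) x <= min else x < min)) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s] (got %s)",
                  name, format(min), format(max), paste(format(x), collapse = ", ")),
          "incembed_invalid_argument")
  }
  as.numeric(x)
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    abort("`seed` must be a single integer", "incembed_invalid_argument")
  }
  as.integer(seed)
}

# Derive a stage seed from a top-level seed and a character tag, so that a
# single experiment seed reproducibly determines every stage. The rule is a
# small polynomial hash of the tag folded into the seed modulo 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(check_seed(seed), code)
}

#' Normalize an entity or token name
#'
#' Lower-cases and trims outer whitespace; collapses internal runs of
#' whitespace to single spaces. Used for every embedding-table key and
#' incidence-table entity so lookups are case- and spacing-insensitive.
#'
#' @param name Character vector of names.
#' @return Character vector of normalized names.
#' @export
normalize_name <- function(name) {
  name <- tolower(trimws(as.character(name)))
  gsub("[[:space:]]+", " ", name)
}
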