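GREEK <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
           "theta", "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron",
           "pi", "rho", "sigma", "tau", "upsilon", "phi", "chi", "psi",
           "omega")

# Multi-word synthetic entity names ("disease alpha beta", ...) so that the
# bag-of-words embedding path is always exercised. Supports up to 24^2 = 576
# entities per prefix.
synthetic_names <- function(prefix, n) {
  if (n > length(GREEK)^2) {
    abort(sprintf("at most %d synthetic %s names are supported",
                  length(GREEK)^2, prefix), "incembed_invalid_argument")
  }
  i <- (seq_len(n) - 1L) %/% length(GREEK) + 1L
  j <- (seq_len(n) - 1L) %% length(GREEK) + 1L
  paste(prefix, GREEK[i], GREEK[j])
}

#' Generate a synthetic epidemiological world
#'
#' Builds the latent structure from which GBD-like incidence tables and
#' matched entity embeddings are derived: per-disease and per-country latent
#' factor vectors organised around group/cluster centroids, scalar main
#' effects, per-disease age profiles, and a global intercept, all in log10
#' incidence-per-100,000 units. Group structure is generated first (one
#' centroid per disease group and country cluster); each entity's factor
#' vector is then drawn around its centroid with within-group spread
#' `between_sd / within_ratio`, so the labels are linearly recoverable from
#' the factors.
#'
#' @param n_diseases,n_countries,n_age Number of diseases, countries and
#'   5-year age bands (defaults emulate a desk-scale GBD-like table).
#' @param q Latent factor dimension shared by diseases and countries.
#' @param n_disease_groups,n_country_clusters Number of disease groups /
#'   country clusters (must not exceed the entity counts).
#' @param seed Integer seed; the world is a pure function of its arguments.
#' @param between_sd Standard deviation of group centroids per coordinate.
#' @param within_ratio Ratio of between-group to within-group spread.
#' @return An object of class `synthetic_world`.
#' @examples
#' w <- make_world(6, 4, n_age = 20, q = 2, n_disease_groups = 3,
#'                 n_country_clusters = 2, seed = 1)
#' @export
make_world <- function(n_diseases = 50L, n_countries = 30L, n_age = 20L,
                       q = 3L, n_disease_groups = 5L, n_country_clusters = 4L,
                       seed = 1L, between_sd = 1, within_ratio = 4) {
  n_diseases <- check_count(n_diseases, "n_diseases")
  n_countries <- check_count(n_countries, "n_countries")
  n_age <- check_count(n_age, "n_age")
  q <- check_count(q, "q")
  n_disease_groups <- check_count(n_disease_groups, "n_disease_groups")
  n_country_clusters <- check_count(n_country_clusters, "n_country_clusters")
  check_number(between_sd, "between_sd", min = 0, strict_min = TRUE)
  check_number(within_ratio, "within_ratio", min = 0, strict_min = TRUE)
  if (n_disease_groups > n_diseases) {
    abort("n_disease_groups must not exceed n_diseases",
          "incembed_invalid_argument")
  }
  if (n_country_clusters > n_countries) {
    abort("n_country_clusters must not exceed n_countries",
          "incembed_invalid_argument")
  }
  seed <- check_seed(seed)
  within_sd <- between_sd / within_ratio

  diseases <- synthetic_names("disease", n_diseases)
  countries <- synthetic_names("country", n_countries)

  world <- with_seed(seed, {
    clustered_factors <- function(n, n_groups) {
      labels <- sample(rep(seq_len(n_groups), length.out = n))
      centroids <- matrix(rnorm(n_groups * q, sd = between_sd), n_groups, q)
      factors <- centroids[labels, , drop = FALSE] +
        matrix(rnorm(n * q, sd = within_sd), n, q)
      list(labels = labels, factors = factors)
    }
    dis <- clustered_factors(n_diseases, n_disease_groups)
    cty <- clustered_factors(n_countries, n_country_clusters)

    # Smooth unimodal age profiles, one bump per disease, centred to mean 0
    # so the scalar main effects carry the overall level.
    ages <- seq_len(n_age) - 1L
    peak <- runif(n_diseases, 0, n_age - 1)
    width <- runif(n_diseases, n_age / 8, n_age / 2)
    amp <- rnorm(n_diseases, sd = 0.5)
    age_profiles <- t(vapply(seq_len(n_diseases), function(i) {
      prof <- amp[i] * exp(-(ages - peak[i])^2 / (2 * width[i]^2))
      prof - mean(prof)
    }, numeric(n_age)))

    list(
      disease_factors = structure(dis$factors, dimnames = list(diseases, NULL)),
      country_factors = structure(cty$factors, dimnames = list(countries, NULL)),
      disease_main = structure(rnorm(n_diseases, sd = 1), names = diseases),
      country_main = structure(rnorm(n_countries, sd = 0.4), names = countries),
      age_profiles = structure(age_profiles, dimnames = list(diseases, NULL)),
      disease_group = structure(dis$labels, names = diseases),
      country_cluster = structure(cty$labels, names = countries)
    )
  })

  world$mu <- 1.0
  world$interaction_scale <- 0.15
  world$q <- q
  world$n_age <- n_age
  world$seed <- seed
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d diseases (%d groups) x %d countries (%d clusters) x %d ages, q=%d, seed=%d\n",
    nrow(x$disease_factors), length(unique(x$disease_group)),
    nrow(x$country_factors), length(unique(x$country_cluster)),
    x$n_age, x$q, x$seed))
  invisible(x)
}

# Noise-free log10 incidence surface for one world: diseases x countries x
# ages laid out as the row-major grid used by sample_incidence.
world_expected_log10 <- function(world) {
  interact <- world$interaction_scale *
    (world$disease_factors %*% t(world$country_factors))
  grid <- expand.grid(
    age_group = seq_len(world$n_age) - 1L,
    country = rownames(world$country_factors),
    disease = rownames(world$disease_factors),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("disease", "country", "age_group")]
  di <- match(grid$disease, rownames(world$disease_factors))
  ci <- match(grid$country, rownames(world$country_factors))
  grid$log10_incidence <- world$mu +
    world$disease_main[di] +
    world$country_main[ci] +
    interact[cbind(di, ci)] +
    world$age_profiles[cbind(di, grid$age_group + 1L)]
  rownames(grid) <- NULL
  grid
}

#' Sample an incidence table from a synthetic world
#'
#' For every (disease, country, age band) cell the log10 incidence is the
#' world's additive surface — intercept + disease and country main effects +
#' a bilinear disease-by-country interaction + the disease's age profile —
#' plus Gaussian noise; the table stores `10^` that value as cases per
#' 100,000. A fraction `zero_rate` of cells, chosen uniformly at random, is
#' then overwritten with exact zeros, emulating the zero-incidence entries
#' of GBD exports.
#'
#' @param world A `synthetic_world`.
#' @param noise_sd Observation noise standard deviation in log10 units.
#' @param zero_rate Proportion of cells replaced by exact zeros (in `[0,1)`).
#' @param seed Integer seed.
#' @return An `incidence_table` with `n_diseases * n_countries * n_age` rows.
#' @export
sample_incidence <- function(world, noise_sd = 0.1, zero_rate = 0.21,
                             seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  check_number(noise_sd, "noise_sd", min = 0)
  if (length(zero_rate) != 1L || !is.finite(zero_rate) ||
      zero_rate < 0 || zero_rate >= 1) {
    abort("`zero_rate` must be in [0, 1)", "incembed_invalid_argument")
  }
  seed <- check_seed(seed)

  grid <- world_expected_log10(world)
  n <- nrow(grid)
  with_seed(seed, {
    log10_inc <- grid$log10_incidence + rnorm(n, sd = noise_sd)
    incidence <- 10^log10_inc
    n_zero <- round(zero_rate * n)
    if (n_zero > 0) incidence[sample.int(n, n_zero)] <- 0
    incidence_table(data.frame(
      disease = grid$disease, country = grid$country,
      age_group = grid$age_group, incidence = incidence,
      stringsAsFactors = FALSE
    ))
  })
}

#' Derive entity embeddings of controllable informativeness
#'
#' Builds an entity-level embedding table whose vectors are a convex blend
#' of (a) a fixed random linear map of the entity's latent signal — its
#' factor vector concatenated with its scalar main effect — and (b)
#' independent Gaussian noise:
#' `informativeness * L([factors; main]) + (1 - informativeness) * noise`.
#' At `informativeness = 1` the latent structure is exactly linearly
#' decodable from the embedding; at 0 the embedding is pure noise. This is
#' the synthetic stand-in for pretrained language-model vectors, with the
#' information content as an explicit dial.
#'
#' @param world A `synthetic_world`.
#' @param entity `"disease"` or `"country"`.
#' @param dim Embedding dimension; must be at least `q + 1`.
#' @param informativeness Blend weight in `[0, 1]`.
#' @param seed Integer seed for the linear map and the noise.
#' @return An [embedding_table()] with `level = "entity"`,
#'   `provider_id = "synthetic"`.
#' @export
derive_embeddings <- function(world, entity = c("disease", "country"),
                              dim = 16L, informativeness = 1, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  entity <- match.arg(entity)
  dim <- check_count(dim, "dim")
  check_number(informativeness, "informativeness", min = 0, max = 1)
  seed <- check_seed(seed)
  latent <- if (entity == "disease") {
    cbind(world$disease_factors, world$disease_main)
  } else {
    cbind(world$country_factors, world$country_main)
  }
  p <- ncol(latent)
  if (dim < p) {
    abort(sprintf("`dim` must be >= q + 1 = %d", p),
          "incembed_invalid_argument")
  }
  vectors <- with_seed(seed, {
    L <- matrix(rnorm(p * dim, sd = 1 / sqrt(p)), p, dim)
    noise <- matrix(rnorm(nrow(latent) * dim), nrow(latent), dim)
    informativeness * (latent %*% L) + (1 - informativeness) * noise
  })
  rownames(vectors) <- normalize_name(rownames(latent))
  embedding_table(vectors, level = "entity", provider_id = "synthetic")
}

#' Extract the ground-truth group labelings of a synthetic world
#'
#' @param world A `synthetic_world`.
#' @return A list with components `disease` and `country`, each a
#'   [group_labeling()] mapping entity names to their disease-group /
#'   country-cluster label.
#' @export
group_labels <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  list(
    disease = group_labeling(
      structure(paste0("g", world$disease_group),
                names = normalize_name(names(world$disease_group))),
      kind = "disease-group"),
    country = group_labeling(
      structure(paste0("c", world$country_cluster),
                names = normalize_name(names(world$country_cluster))),
      kind = "country-cluster")
  )
}

#' Write a synthetic dataset to disk
#'
#' Materialises one world as the plain-text artifacts the rest of the
#' pipeline consumes: the incidence table as CSV, disease and country
#' embeddings both in word2vec text format (names with underscores) and as
#' name-to-vector TSV, and the group labelings as two-column CSVs.
#'
#' @param world A `synthetic_world`.
#' @param table An `incidence_table` sampled from it.
#' @param disease_emb,country_emb Entity-level [embedding_table()]s.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named character vector of files written.
#' @export
write_synthetic_dataset <- function(world, table, disease_emb, country_emb,
                                    out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    incidence = file.path(out_dir, "incidence.csv"),
    disease_w2v = file.path(out_dir, "disease_embeddings.w2v.txt"),
    country_w2v = file.path(out_dir, "country_embeddings.w2v.txt"),
    disease_tsv = file.path(out_dir, "disease_embeddings.tsv"),
    country_tsv = file.path(out_dir, "country_embeddings.tsv"),
    disease_labels = file.path(out_dir, "disease_groups.csv"),
    country_labels = file.path(out_dir, "country_clusters.csv")
  )
  write_incidence_csv(table, paths[["incidence"]])
  write_word_vectors(disease_emb, paths[["disease_w2v"]])
  write_word_vectors(country_emb, paths[["country_w2v"]])
  write_entity_vectors(disease_emb, paths[["disease_tsv"]])
  write_entity_vectors(country_emb, paths[["country_tsv"]])
  labels <- group_labels(world)
  write_group_labels(labels$disease, paths[["disease_labels"]])
  write_group_labels(labels$country, paths[["country_labels"]])
  invisible(paths)
}
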