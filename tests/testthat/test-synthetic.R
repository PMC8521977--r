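test_that("world dimensions, labels and determinism follow the arguments", {
  w <- make_world(6, 4, 20, q = 2, n_disease_groups = 3,
                  n_country_clusters = 2, seed = 1)
  expect_equal(dim(w$disease_factors), c(6, 2))
  expect_equal(dim(w$country_factors), c(4, 2))
  expect_equal(dim(w$age_profiles), c(6, 20))
  expect_length(w$disease_main, 6)
  expect_length(w$country_main, 4)
  expect_equal(sort(unique(unname(w$disease_group))), 1:3)
  expect_equal(sort(unique(unname(w$country_cluster))), 1:2)
  # every entity has exactly one label; names are multi-word
  expect_setequal(names(w$disease_group), rownames(w$disease_factors))
  expect_true(all(lengths(strsplit(rownames(w$disease_factors), " ")) >= 2))

  w2 <- make_world(6, 4, 20, q = 2, n_disease_groups = 3,
                   n_country_clusters = 2, seed = 1)
  expect_identical(w, w2)
  w3 <- make_world(6, 4, 20, q = 2, n_disease_groups = 3,
                   n_country_clusters = 2, seed = 2)
  expect_false(identical(w$disease_factors, w3$disease_factors))
})

test_that("invalid world arguments are rejected", {
  expect_error(make_world(0, 4, 20, 2, 1, 1, seed = 1),
               class = "incembed_invalid_argument")
  expect_error(make_world(6, 4, 20, 2, n_disease_groups = 7,
                          n_country_clusters = 2, seed = 1),
               class = "incembed_invalid_argument")
  expect_error(make_world(6, 4, 20, 2, n_disease_groups = 3,
                          n_country_clusters = 5, seed = 1),
               class = "incembed_invalid_argument")
})

test_that("sampled incidence has exact counts and generative structure", {
  w <- tiny_world()
  tab <- sample_incidence(w, noise_sd = 0, zero_rate = 0, seed = 2)
  expect_s3_class(tab, "incidence_table")
  expect_equal(nrow(tab), 6 * 4 * 20)
  expect_true(all(tab$incidence > 0))

  tab25 <- sample_incidence(w, noise_sd = 0, zero_rate = 0.25, seed = 2)
  expect_equal(sum(tab25$incidence == 0), round(0.25 * 480))

  # noiseless reconstruction: log10 incidence equals the additive surface
  recompute <- function(row) {
    di <- match(row$disease, rownames(w$disease_factors))
    ci <- match(row$country, rownames(w$country_factors))
    w$mu + w$disease_main[[di]] + w$country_main[[ci]] +
      w$interaction_scale *
        sum(w$disease_factors[di, ] * w$country_factors[ci, ]) +
      w$age_profiles[di, row$age_group + 1]
  }
  for (i in c(1, 57, 480)) {
    expect_equal(log10(tab$incidence[i]), unname(recompute(tab[i, ])),
                 tolerance = 1e-12)
  }

  expect_identical(sample_incidence(w, 0.1, 0.2, seed = 9),
                   sample_incidence(w, 0.1, 0.2, seed = 9))
  expect_error(sample_incidence(w, zero_rate = 1),
               class = "incembed_invalid_argument")
})

test_that("derived embeddings encode the latent factors per informativeness", {
  w <- make_world(60, 30, 10, q = 2, n_disease_groups = 4,
                  n_country_clusters = 3, seed = 5)
  # informativeness = 1: latent factors are exactly linearly decodable
  emb1 <- derive_embeddings(w, "disease", dim = 8, informativeness = 1,
                            seed = 11)
  fit <- lm.fit(cbind(1, emb1$vectors), w$disease_factors)
  expect_lt(max(abs(fit$residuals)), 1e-8)

  # informativeness = 0: embeddings are pure noise, uncorrelated with factors
  for (seed in 1:5) {
    w0 <- make_world(200, 10, 5, q = 2, n_disease_groups = 4,
                     n_country_clusters = 2, seed = seed)
    emb0 <- derive_embeddings(w0, "disease", dim = 6, informativeness = 0,
                              seed = seed + 50)
    cors <- abs(cor(emb0$vectors, w0$disease_factors))
    expect_lt(max(cors), 0.2)
  }

  expect_identical(derive_embeddings(w, "country", 8, 0.5, seed = 3),
                   derive_embeddings(w, "country", 8, 0.5, seed = 3))
  expect_error(derive_embeddings(w, "disease", dim = 2, seed = 1),
               class = "incembed_invalid_argument")
})

test_that("factor decoding error is non-increasing in informativeness", {
  decode_err <- function(informativeness, seed) {
    w <- make_world(80, 10, 5, q = 2, n_disease_groups = 4,
                    n_country_clusters = 2, seed = seed)
    emb <- derive_embeddings(w, "disease", dim = 8,
                             informativeness = informativeness,
                             seed = seed + 30)
    fit <- lm.fit(cbind(1, emb$vectors), w$disease_factors)
    sqrt(mean(fit$residuals^2))
  }
  for (seed in 1:5) {
    errs <- vapply(c(0, 0.5, 1), decode_err, numeric(1), seed = seed)
    expect_true(all(diff(errs) <= 1e-8))
  }
})

test_that("group_labels returns the world's labelings verbatim and stably", {
  w <- tiny_world()
  lab <- group_labels(w)
  expect_s3_class(lab$disease, "group_labeling")
  expect_length(lab$disease$entity_labels, 6)
  expect_length(unique(lab$disease$entity_labels), 3)
  expect_length(lab$country$entity_labels, 4)
  expect_length(unique(lab$country$entity_labels), 2)
  # total: every entity appears exactly once
  expect_setequal(names(lab$disease$entity_labels),
                  normalize_name(rownames(w$disease_factors)))
  expect_identical(lab, group_labels(w))
})

test_that("group labels are recoverable from factors by a linear classifier", {
  # the between:within centroid spread (4:1) must leave groups separable
  accs <- vapply(1:3, function(seed) {
    w <- make_world(100, 10, 5, q = 3, n_disease_groups = 5,
                    n_country_clusters = 2, seed = seed)
    emb <- embedding_table(
      structure(w$disease_factors,
                dimnames = list(rownames(w$disease_factors), NULL)),
      level = "entity", provider_id = "factors")
    run_classification(emb, group_labels(w)$disease, folds = 3, repeats = 2,
                       seed = seed)$mean
  }, numeric(1))
  expect_gt(mean(accs), 0.9)
})

test_that("synthetic datasets round-trip through their on-disk formats", {
  w <- tiny_world()
  tab <- filter_zero_incidence(tiny_table(zero_rate = 0.2))$table
  de <- derive_embeddings(w, "disease", 4, 1, seed = 1)
  ce <- derive_embeddings(w, "country", 4, 1, seed = 2)
  out <- withr::local_tempdir()
  paths <- write_synthetic_dataset(w, tab, de, ce, out)
  expect_true(all(file.exists(paths)))

  tab2 <- read_incidence_csv(paths[["incidence"]])
  expect_equal(tab2$incidence, tab$incidence, tolerance = 1e-12)
  de2 <- read_entity_vectors(paths[["disease_tsv"]])
  expect_equal(de2$vectors[rownames(de$vectors), ], de$vectors,
               tolerance = 1e-12)
  lab2 <- read_group_labels(paths[["disease_labels"]])
  expect_identical(lab2$entity_labels, group_labels(w)$disease$entity_labels)
})
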