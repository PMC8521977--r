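# Small fixtures shared across test files; everything is generated in code.

tiny_world <- function(seed = 1L) {
  make_world(6, 4, n_age = 20, q = 2, n_disease_groups = 3,
             n_country_clusters = 2, seed = seed)
}

tiny_table <- function(seed = 1L, noise_sd = 0, zero_rate = 0) {
  sample_incidence(tiny_world(seed), noise_sd = noise_sd,
                   zero_rate = zero_rate, seed = seed + 100L)
}

# word-level table with two tokens of dim 2 used in the worked bag-of-words
# examples
toy_word_table <- function() {
  embedding_table(matrix(c(1, 2,
                           3, 0),
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("a", "b"), NULL)),
                  level = "word", provider_id = "toy")
}

toy_entity_table <- function() {
  embedding_table(matrix(1:12 / 10, nrow = 3,
                         dimnames = list(c("hiv", "malaria", "tb"), NULL)),
                  level = "entity", provider_id = "toy")
}

# a small zero-filtered table with providers, ready for model fitting
tiny_features <- function(seed = 1L, informativeness = 1) {
  w <- tiny_world(seed)
  tab <- filter_zero_incidence(
    sample_incidence(w, noise_sd = 0.05, zero_rate = 0.1,
                     seed = seed + 7L))$table
  dp <- entity_provider(derive_embeddings(w, "disease", 8, informativeness,
                                          seed = seed + 1L))
  cp <- entity_provider(derive_embeddings(w, "country", 8, informativeness,
                                          seed = seed + 2L))
  list(world = w, table = tab, disease_provider = dp, country_provider = cp,
       features = assemble_features(tab, dp, cp))
}

# brute-force concordance oracle: explicit loop over all pairs per group
concordance_oracle <- function(pred, truth, group_of = NULL) {
  if (is.null(group_of)) group_of <- rep(1, length(pred))
  vals <- c()
  for (g in unique(group_of)) {
    idx <- which(group_of == g)
    if (length(idx) < 2) next
    total <- 0
    npairs <- 0
    for (i in idx) for (j in idx) {
      if (i >= j) next
      npairs <- npairs + 1
      dp <- pred[i] - pred[j]
      dt <- truth[i] - truth[j]
      total <- total + if (dp == 0 || dt == 0) 0.5
                       else if (sign(dp) == sign(dt)) 1 else 0
    }
    vals <- c(vals, total / npairs)
  }
  mean(vals)
}
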