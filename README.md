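# incembed

Estimating disease incidence from language-embedding features.

`incembed` is an R implementation of a transfer-learning pipeline for
imputing disease incidence tables (new cases per 100,000 population, by
disease, country and 5-year age band). Instead of hand-built
epidemiological covariates, the feature vector for a record $(d, c, a)$
is assembled from *pretrained language-model embeddings of the names*:

$$x = s_d \,\|\, e_c \,\|\, \mathrm{onehot}(a), \qquad
  y = \log_{10}(\text{incidence per }100{,}000),$$

where $s_d$ is the disease sentence embedding (entity-level, or a
bag-of-words min/max/mean aggregation of word vectors), $e_c$ the country
embedding, and the age band a 20-dim indicator. A funnel multilayer
perceptron (hidden layers 256–128–64–16–4, each fully connected + batch
normalization + ReLU; linear output head) is trained on RMSE loss with
Adam at learning rate 3×10⁻⁴. Because embeddings place similar entities
near each other, the model can impute missing disease–country pairs and
whole unseen countries; unseen diseases remain much harder.

The package is aimed at quantitative epidemiologists and ML researchers
who want to study this class of models end to end: it ships the embedding
providers (word2vec-text and name→vector TSV loaders, fusion, a hash
control), the preprocessing contract (zero-row removal before the log10
transform; per-100,000 scaling), three leave-out cross-validation schemes
(held-out pairs / countries / diseases) with validated exclusivity
guarantees, the Global / Ridge / OneHot baselines with explicit
not-applicable semantics for unseen entities, log-space MAE with its
multiplicative error factor ($10^{\mathrm{MAE}}$; 0.2 → 1.58×), an
inter-group concordance statistic in [0, 1], residual-by-magnitude
analysis, repeated linear-SVM experiments that score how much group
structure an embedding carries, and a seeded synthetic-world generator so
every stage is testable without licensed data.

## A worked example

Simulate a small world, derive fully informative embeddings, and evaluate
the regressor on the unseen-country scheme:

```r
library(incembed)

world    <- make_world(n_diseases = 20, n_countries = 10, seed = 1)
table    <- sample_incidence(world, seed = 2)
filtered <- filter_zero_incidence(table)   # removed 840 zero rows of 4000

disease_emb <- derive_embeddings(world, "disease", dim = 16,
                                 informativeness = 1, seed = 3)
country_emb <- derive_embeddings(world, "country", dim = 16,
                                 informativeness = 1, seed = 4)

plan   <- split_by_country(filtered$table, k = 5, seed = 5)
result <- cross_validate(filtered$table,
                         entity_provider(disease_emb),
                         entity_provider(country_emb),
                         plan, model = "mlp",
                         config = regressor_config(seed = 6))
result$report
#> <evaluation_report>
#>   scored: 3160   not applicable: 0
#>   MAE (log10): 0.2293   error factor: 1.70x
#>   concordance: 0.9140 (supplied grouping)
```

Read: pooled over the 5 folds, predictions for *countries the model never
saw* are typically a factor 1.70 from the truth, and within a country the
predicted ranking of disease–age cells agrees with the true ranking on
91% of pairs (ties half-credited). `inverse_transform(2.0)` converts a
log10 prediction back to 100 cases per 100,000 (proportion 0.001).

Experiments can also be driven by YAML configs (`run_experiment()`,
`read_experiment_config()`) or from a shell via the thin wrapper
`inst/cli/incembed.R` with subcommands `generate`, `run` and
`context-eval`; one top-level seed reproduces a run byte-for-byte.

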