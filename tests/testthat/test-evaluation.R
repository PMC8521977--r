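test_that("log-space MAE matches hand values and rejects bad input", {
  expect_equal(mae_log(c(1, 2), c(1, 2)), 0)
  expect_equal(mae_log(c(1.2, 1.8), c(1, 2)), 0.2)
  expect_equal(mae_log(2.0, 1.7), 0.3)
  expect_error(mae_log(numeric(0), numeric(0)),
               class = "incembed_invalid_argument")
  expect_error(mae_log(1, c(1, 2)), class = "incembed_invalid_argument")
  expect_error(mae_log(NA_real_, 1), class = "incembed_invalid_argument")
  # translation invariance
  p <- rnorm(20); t <- rnorm(20)
  expect_equal(mae_log(p + 0.7, t + 0.7), mae_log(p, t))
})

test_that("the error factor is the inverse-transformed MAE", {
  expect_equal(round(error_factor(0.2), 2), 1.58)
  expect_equal(error_factor(0), 1)
  expect_equal(error_factor(1), 10)
  expect_error(error_factor(-0.1), class = "incembed_invalid_argument")
  # >= 1 always, = 1 iff perfect
  for (m in runif(10, 0, 3)) expect_gte(error_factor(m), 1)
})

test_that("concordance matches hand-worked and boundary cases", {
  expect_equal(concordance(1:4, 1:4), 1)
  expect_equal(concordance(1:4, -(1:4)), 0)
  # worked 4-item example: one discordant pair out of six
  expect_equal(concordance(c(1, 2, 3, 4), c(1, 3, 2, 4)), 5 / 6)
  # ties give half credit
  expect_equal(concordance(c(1, 1), c(1, 2)), 0.5)
  # groups are averaged unweighted: group a is perfect (1), group b has
  # pairs C, D, D (1/3)
  expect_equal(concordance(c(1, 2, 1, 2, 3), c(1, 2, 2, 3, 1),
                           group_of = c("a", "a", "b", "b", "b")),
               mean(c(1, 1 / 3)))
  expect_warning(res <- concordance(c(1, 2, 5), c(1, 2, 9),
                                    group_of = c("a", "a", "b")),
                 "size 1")
  expect_equal(res, 1)
  expect_error(suppressWarnings(concordance(1, 1, group_of = "a")),
               class = "incembed_invalid_argument")
})

test_that("concordance equals the brute-force pair-counting oracle", {
  set.seed(202)
  for (rep in 1:300) {
    n_groups <- sample(1:3, 1)
    sizes <- sample(2:8, n_groups, replace = TRUE)
    group_of <- rep(seq_len(n_groups), sizes)
    n <- length(group_of)
    # draws with ties to exercise the half-credit branch
    pred <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.01) *
      rbinom(n, 1, 0.5)
    truth <- sample(1:5, n, replace = TRUE)
    expect_equal(concordance(pred, truth, group_of),
                 concordance_oracle(pred, truth, group_of))
  }
})

test_that("concordance is invariant under strictly increasing transforms", {
  set.seed(7)
  pred <- rnorm(40)
  truth <- rnorm(40)
  g <- sample(letters[1:4], 40, replace = TRUE)
  base <- concordance(pred, truth, g)
  expect_equal(concordance(exp(pred), truth, g), base)
  expect_equal(concordance(pred, truth^3 + 2 * truth, g), base)
  expect_equal(concordance(10^pred, exp(truth), g), base)
})

test_that("residual bins reproduce a direct per-bin computation", {
  pred <- c(2.1, 2.7, 2.4, 3.3, 3.8, 0.5)
  truth <- c(2.0, 2.9, 2.2, 3.6, 3.5, 0.9)
  bins <- residual_bins(pred, truth)
  expect_equal(bins$bin_center, c(0.5, 2.5, 3.5))
  r2 <- (pred - truth)[pred >= 2 & pred < 3]
  i2 <- which(bins$bin_center == 2.5)
  expect_equal(bins$n[i2], 3)
  expect_equal(bins$mean_residual[i2], mean(r2))
  expect_equal(bins$mae[i2], mean(abs(r2)))
  expect_equal(bins$sd[i2], sd(r2))

  # all predictions in one bin: bin MAE equals the global MAE
  one <- residual_bins(pred[1:3], truth[1:3])
  expect_equal(nrow(one), 1)
  expect_equal(one$mae, mae_log(pred[1:3], truth[1:3]))

  # symmetric residuals have near-zero signed mean
  p <- rep(2.5, 10); t <- 2.5 + c(rep(0.3, 5), rep(-0.3, 5))
  expect_equal(residual_bins(p, t)$mean_residual, 0)
})

test_that("stratified metrics recombine to the global values", {
  set.seed(11)
  pred <- rnorm(30, 2)
  truth <- rnorm(30, 2)
  strata <- rep(c("young", "old"), each = 15)
  rep_tab <- stratified_report(pred, truth, strata)
  expect_setequal(rep_tab$stratum, c("young", "old"))
  # weighted mean of per-stratum MAE = global MAE
  expect_equal(sum(rep_tab$mae * rep_tab$n) / sum(rep_tab$n),
               mae_log(pred, truth))
  # single stratum equals global
  single <- stratified_report(pred, truth, rep("all", 30))
  expect_equal(single$mae, mae_log(pred, truth))
  expect_equal(single$concordance, concordance(pred, truth))
  # tiny strata flagged
  flag <- stratified_report(pred[1:3], truth[1:3], c("a", "a", "b"))
  expect_true(flag$flagged[flag$stratum == "b"])
  expect_true(is.na(flag$concordance[flag$stratum == "b"]))
})

test_that("evaluate_predictions excludes not-applicable rows and counts them", {
  pred <- c(1, 2, NA, 4, NA)
  truth <- c(1.1, 1.9, 3, 4.2, 5)
  rep <- evaluate_predictions(pred, truth)
  expect_equal(rep$n_scored, 3)
  expect_equal(rep$n_not_applicable, 2)
  expect_equal(rep$mae, mae_log(pred[c(1, 2, 4)], truth[c(1, 2, 4)]))
  expect_equal(rep$error_factor, 10^rep$mae)

  all_na <- evaluate_predictions(c(NA_real_, NA_real_), c(1, 2))
  expect_equal(all_na$n_scored, 0)
  expect_true(is.na(all_na$mae))
})
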