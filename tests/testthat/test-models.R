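test_that("MLP parameter count equals an independent layer-by-layer count", {
  # hand count for input_dim = 30, funnel 256-128-64-16-4:
  # affine: (30*256+256)+(256*128+128)+(128*64+64)+(64*16+16)+(16*4+4)+(4*1+1)
  # batch norm: 2*(256+128+64+16+4)
  hand_affine <- (30 * 256 + 256) + (256 * 128 + 128) + (128 * 64 + 64) +
    (64 * 16 + 16) + (16 * 4 + 4) + (4 * 1 + 1)
  hand_bn <- 2 * (256 + 128 + 64 + 16 + 4)
  expect_equal(mlp_param_count(30), hand_affine + hand_bn)

  # the built network has exactly those parameter shapes
  m <- build_mlp(30, regressor_config(seed = 1))
  built <- sum(vapply(m$params$hidden, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta),
    numeric(1))) + length(m$params$out$W) + 1
  expect_equal(built, mlp_param_count(30))
  expect_equal(nrow(m$params$hidden[[1]]$W), 30)
})

test_that("MLP building and training are deterministic in the seed", {
  cfg <- regressor_config(hidden_widths = c(16, 8), max_epochs = 15,
                          batch_size = 32, seed = 42)
  expect_identical(build_mlp(10, cfg)$params, build_mlp(10, cfg)$params)
  expect_false(identical(
    build_mlp(10, cfg)$params,
    build_mlp(10, regressor_config(hidden_widths = c(16, 8),
                                   seed = 43))$params))

  set.seed(5)
  x <- matrix(rnorm(400 * 10), 400, 10)
  y <- rnorm(400)
  f1 <- train_regressor(build_mlp(10, cfg), list(x = x, y = y), cfg)
  f2 <- train_regressor(build_mlp(10, cfg), list(x = x, y = y), cfg)
  expect_identical(f1$training_log, f2$training_log)
  expect_identical(predict(f1, x), predict(f2, x))
})

test_that("C++ gradients match numerical differentiation of an R oracle", {
  cfg <- regressor_config(hidden_widths = c(5, 3), seed = 3)
  m <- build_mlp(4, cfg)
  set.seed(7)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rnorm(12)
  # independent train-mode forward pass in R (batch statistics, eps = 1e-5)
  loss_fn <- function(params) {
    A <- X
    for (l in params$hidden) {
      Z <- sweep(A %*% l$W, 2, l$b, "+")
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2, mu)^2)
      Xh <- sweep(sweep(Z, 2, mu), 2, sqrt(v + 1e-5), "/")
      A <- pmax(sweep(sweep(Xh, 2, l$gamma, "*"), 2, l$beta, "+"), 0)
    }
    mean((as.numeric(A %*% params$out$W + params$out$b) - y)^2)
  }
  g <- incembed:::.mlp_grad_cpp(m$params, X, y)
  expect_equal(g$loss, loss_fn(m$params), tolerance = 1e-10)
  num_grad <- function(get, set) {
    p0 <- get(m$params)
    gn <- p0
    for (i in seq_along(p0)) {
      up <- p0; up[i] <- up[i] + 1e-6
      dn <- p0; dn[i] <- dn[i] - 1e-6
      gn[i] <- (loss_fn(set(m$params, up)) - loss_fn(set(m$params, dn))) /
        2e-6
    }
    gn
  }
  for (li in 1:2) {
    for (field in c("W", "gamma", "beta")) {
      gn <- num_grad(function(p) p$hidden[[li]][[field]],
                     function(p, v) { p$hidden[[li]][[field]][] <- v; p })
      expect_equal(as.numeric(g$hidden[[li]][[field]]), as.numeric(gn),
                   tolerance = 1e-5)
    }
  }
  gn <- num_grad(function(p) p$out$W, function(p, v) { p$out$W[] <- v; p })
  expect_equal(as.numeric(g$out$W), as.numeric(gn), tolerance = 1e-5)
})

test_that("the regressor fits a noiseless linear target to low error", {
  set.seed(31)
  x <- matrix(rnorm(2000 * 8), 2000, 8)
  beta <- runif(8, -1, 1)
  y <- as.numeric(x %*% beta) + 0.5
  # no inner holdout so the optimizer gets enough steps to drive the
  # training error itself to zero
  cfg <- regressor_config(max_epochs = 300, batch_size = 128,
                          holdout_fraction = 0, seed = 2)
  fit <- train_regressor(build_mlp(8, cfg), list(x = x, y = y), cfg)
  final_rmse <- sqrt(mean((predict(fit, x) - y)^2))
  expect_lt(final_rmse, 0.05)
})

test_that("a constant target trains to near-zero error", {
  set.seed(8)
  x <- matrix(rnorm(500 * 6), 500, 6)
  y <- rep(2.5, 500)
  cfg <- regressor_config(hidden_widths = c(16, 4), max_epochs = 100,
                          batch_size = 64, holdout_fraction = 0, seed = 4)
  fit <- train_regressor(build_mlp(6, cfg), list(x = x, y = y), cfg)
  expect_lt(sqrt(mean((predict(fit, x) - 2.5)^2)), 0.05)
})

test_that("prediction is pure: batch equals single rows, repeats identical", {
  fix <- tiny_features()
  cfg <- regressor_config(max_epochs = 10, batch_size = 64, seed = 1)
  fit <- train_regressor(build_mlp(36, cfg), fix$features, cfg)
  p_batch <- predict(fit, fix$features)
  p_single <- vapply(1:5, function(i)
    predict(fit, fix$features$x[i, , drop = FALSE]), numeric(1))
  expect_equal(p_batch[1:5], p_single, tolerance = 1e-6)
  expect_identical(p_batch, predict(fit, fix$features))
  # layout mismatch is caught and names the segment
  other <- fix$features
  other$layout$segments$provider[2] <- "different"
  err <- tryCatch(predict(fit, other), error = identity)
  expect_s3_class(err, "incembed_layout_error")
  expect_match(conditionMessage(err), "country")
})

test_that("ridge recovers OLS as alpha -> 0 and the mean as alpha -> Inf", {
  set.seed(13)
  x <- matrix(rnorm(300 * 5), 300, 5)
  beta <- c(2, -1, 0.5, 0, 1.5)
  y <- as.numeric(x %*% beta) + 3
  fit0 <- fit_ridge(list(x = x, y = y), alpha_grid = 1e-8, seed = 1)
  ols <- qr.solve(cbind(1, x), y)  # independent least-squares solve
  expect_equal(fit0$beta, unname(ols[-1]), tolerance = 1e-4)
  expect_equal(fit0$intercept, unname(ols[1]), tolerance = 1e-4)

  fit_inf <- fit_ridge(list(x = x, y = y), alpha_grid = 1e12, seed = 1)
  expect_equal(max(abs(fit_inf$beta)), 0, tolerance = 1e-6)
  expect_equal(unique(round(predict(fit_inf, x), 6)), round(mean(y), 6))

  # deterministic, and inner CV picks a sensible alpha on noisy data
  yn <- y + rnorm(300, sd = 2)
  f1 <- fit_ridge(list(x = x, y = yn), seed = 9)
  f2 <- fit_ridge(list(x = x, y = yn), seed = 9)
  expect_identical(f1$beta, f2$beta)
  expect_true(f1$alpha %in% f1$alpha_grid)
  expect_error(fit_ridge(list(x = x, y = y), alpha_grid = c(1, -1)),
               class = "incembed_invalid_argument")
})

test_that("the global baseline stores group means and signals unseen keys", {
  df <- data.frame(disease = c("a", "a", "b"), country = c("x", "y", "x"),
                   age_group = c(0L, 0L, 1L), incidence = c(10, 1000, 50))
  tab <- incidence_table(df, n_age = 2)
  fit <- fit_global_baseline(tab)
  # disease a: mean(log10(10), log10(1000)) = mean(1, 3) = 2
  newdata <- data.frame(disease = c("a", "b", "zz"), country = "x",
                        age_group = 0L)
  expect_equal(predict(fit, newdata), c(2, log10(50), NA))

  # disease-age grouping distinguishes age cells
  fit_da <- fit_global_baseline(tab, "disease-age")
  nd <- data.frame(disease = c("b", "b"), country = "x", age_group = c(1L, 0L))
  expect_equal(predict(fit_da, nd), c(log10(50), NA))
})

test_that("one-hot features encode training vocab and flag unseen entities", {
  fix <- tiny_features()
  tab <- fix$table
  fx_d <- build_onehot_features(tab, "d")
  expect_equal(ncol(fx_d$x), 6 + 20)
  fx_dc <- build_onehot_features(tab, "dc")
  expect_equal(ncol(fx_dc$x), 6 + 4 + 20)
  expect_true(all(fx_dc$applicable))
  expect_true(all(rowSums(fx_dc$x) == 3))  # disease + country + age hot

  # vocabulary fixed on a training subset: other entities not applicable
  train_tab <- tab[tab$country != tab$country[1], ]
  class(train_tab) <- class(tab)
  attr(train_tab, "n_age") <- attr(tab, "n_age")
  vocab <- build_onehot_features(train_tab, "c")$vocab
  fx_val <- build_onehot_features(tab, "c", vocab = vocab)
  unseen <- tab$country == tab$country[1]
  expect_equal(fx_val$applicable, !unseen)
})
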