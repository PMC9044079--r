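# cheap valid trait table with a controllable weight signal: geometric traits
# of scaled copies of one measured grain
scaled_trait_table <- function(n = 150, seed = 1) {
  base <- grain_traits(quick_grain(seed = 40)$cloud)
  withr::with_seed(seed, {
    scale <- runif(n, 0.85, 1.25)
    dplyr::bind_rows(lapply(scale, function(s) {
      r <- base
      lin <- c("l", "w", "h", "D", "C_yz", "C_xz", "C_xy", "C_c")
      sq <- c("S", "S_yz", "S_xz", "S_xy", "S_c", "S_s", "S/l", "S/w", "S/h",
              "V/l", "V/w", "V/h")
      for (nm in lin) r[[nm]] <- r[[nm]] * s
      for (nm in sq) r[[nm]] <- r[[nm]] * s^2
      for (nm in c("V", "V_obb")) r[[nm]] <- r[[nm]] * s^3
      r$`S/V` <- r$S / r$V
      r$`D/h` <- r$D / r$h
      r
    }))
  })
}

test_that("the CV harness recovers a planted linear weight signal", {
  tab <- scaled_trait_table(n = 150, seed = 2)
  tab$weight <- withr::with_seed(3, 1.2 * tab$V + rnorm(150, sd = 0.5))
  rep <- suppressWarnings(
    train_weight_models(tab, models = c("LR", "BR"), folds = 5, seed = 0)
  )
  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  expect_gte(td$r2[td$model == "LR"], 0.95)
  expect_gte(td$r2[td$model == "BR"], 0.95)
  expect_lte(td$mape[td$model == "LR"], 5)

  gl <- glance(rep)
  expect_equal(gl$folds, 5)
  expect_true(gl$best_model %in% c("LR", "BR"))
})

test_that("pure-noise weights yield no predictive skill", {
  tab <- scaled_trait_table(n = 150, seed = 4)
  tab$weight <- withr::with_seed(5, runif(150, 25, 50))
  rep <- suppressWarnings(
    train_weight_models(tab, models = "LR", folds = 5, seed = 0)
  )
  expect_lte(tidy(rep)$r2, 0.1)
})

test_that("tree and neighbour models run their nested grids deterministically", {
  tab <- scaled_trait_table(n = 90, seed = 6)
  tab$weight <- withr::with_seed(7, 1.2 * tab$V + rnorm(90, sd = 1))
  r1 <- suppressWarnings(
    train_weight_models(tab, models = c("KNN", "RF", "GBR"), folds = 3,
                        seed = 11, inner_folds = 3)
  )
  r2 <- suppressWarnings(
    train_weight_models(tab, models = c("KNN", "RF", "GBR"), folds = 3,
                        seed = 11, inner_folds = 3)
  )
  expect_equal(tidy(r1)[, c("model", "r2", "mape", "rmse")],
               tidy(r2)[, c("model", "r2", "mape", "rmse")])
  expect_true(all(is.finite(unlist(tidy(r1)[, c("r2", "mape", "rmse")]))))
  # strong monotone signal: even KNN/trees capture most variance
  expect_true(all(tidy(r1)$r2 > 0.5))
  # chosen hyperparameters come from the declared grids
  kh <- tidy(r1)$hyperparameters[[which(tidy(r1)$model == "KNN")]]
  expect_true(kh$k %in% c(3, 5, 7, 9, 11))
})

test_that("Bayesian ridge matches least squares on a strong clean signal", {
  withr::with_seed(8, {
    X <- matrix(rnorm(200 * 5), 200, 5)
    beta <- c(3, -2, 1, 0.5, 4)
    y <- drop(X %*% beta) + rnorm(200, sd = 0.01)
  })
  br <- grain3d:::bayes_ridge(X, y)
  expect_equal(br$coef, beta, tolerance = 0.01)
  expect_equal(br$intercept, mean(y))
})

test_that("prediction respects schema and near-interpolates clean data", {
  tab <- scaled_trait_table(n = 80, seed = 9)
  tab$weight <- 1.2 * tab$V + 1
  rep <- suppressWarnings(
    train_weight_models(tab, models = "LR", folds = 5, seed = 0)
  )
  pred <- predict_weight(rep, tab[1:10, ], model = "LR")
  expect_equal(pred$weight, tab$weight[1:10], tolerance = 0.05)

  expect_error(predict_weight(rep, tab[, -5]), "schema")
  const <- tab
  const$weight <- 30
  expect_error(suppressWarnings(train_weight_models(const, models = "LR")),
               "constant")
  expect_error(train_weight_models(tab[1:5, ], models = "LR", folds = 10),
               "rows|folds|n = ")
})
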