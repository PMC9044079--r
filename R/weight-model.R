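#' Cross-validated grain-weight regression harness
#'
#' Trains any subset of five regressors mapping the 32 traits to single
#' grain weight (mg) -- multivariable linear regression (`LR`), Bayesian
#' ridge (`BR`), k-nearest-neighbour regression (`KNN`), random forest
#' (`RF`) and gradient boosting (`GBR`) -- and evaluates each by k-fold
#' cross-validation. Features are standardised on each training fold only;
#' hyperparameters are selected by grid search nested inside each training
#' fold (no information from the test fold leaks into model selection). The
#' reported metric per model is the mean of the per-fold test metrics
#' ([metrics()]: MAPE %, RMSE mg, R2).
#'
#' Grids: KNN k in \{3, 5, 7, 9, 11\}; RF trees in \{100, 300, 500\} x depth
#' in \{unlimited, 5, 10\}; GBR learning rate in \{0.05, 0.1\} x trees in
#' \{100, 300\} x depth in \{2, 3\}; LR and BR have no tuned
#' hyperparameters.
#'
#' @param traits A trait tibble with a positive `weight` column (mg).
#' @param models Subset of `c("LR", "BR", "KNN", "RF", "GBR")`.
#' @param folds Number of CV folds (default 10); must not exceed the row
#'   count.
#' @param seed RNG seed; fold shuffling and the tree learners are
#'   deterministic given it (default 0).
#' @param inner_folds Folds of the nested grid-search CV (default 5).
#' @return A `weight_model_report`: per-model metrics (see [tidy()]),
#'   chosen hyperparameters, and final models refit on the full table for
#'   [predict_weight()].
#' @export
train_weight_models <- function(traits, models = c("LR", "BR", "KNN", "RF", "GBR"),
                                folds = 10, seed = 0, inner_folds = 5) {
  validate_trait_table(traits, require_weight = TRUE)
  models <- match.arg(models, c("LR", "BR", "KNN", "RF", "GBR"),
                      several.ok = TRUE)
  X <- as.matrix(traits[, trait_names()])
  y <- traits$weight
  n <- nrow(X)
  if (n < folds) abort(sprintf("n = %d rows < folds = %d", n, folds))
  if (any(y <= 0)) abort("weights must be positive (mg)")
  if (sd(y) == 0) abort("constant weight column: nothing to model")
  if (median(y) < 25 || median(y) > 50) {
    warn(sprintf(
      "median weight %.1f mg is outside the typical 25-50 mg single-grain range",
      median(y)
    ))
  }

  res <- withr::with_seed(seed, {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    lapply(models, function(mod) {
      per_fold <- vector("list", folds)
      chosen <- vector("list", folds)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        hyper <- select_hyper(mod, X[tr, , drop = FALSE], y[tr], inner_folds)
        fit <- fit_regressor(mod, X[tr, , drop = FALSE], y[tr], hyper)
        pred <- predict_regressor(fit, X[!tr, , drop = FALSE])
        per_fold[[f]] <- metrics(y[!tr], pred)
        chosen[[f]] <- hyper
      }
      mm <- dplyr::bind_rows(per_fold)
      final_hyper <- select_hyper(mod, X, y, inner_folds)
      final_fit <- fit_regressor(mod, X, y, final_hyper)
      list(
        row = tibble(
          model = mod, r2 = mean(mm$r2), mape = mean(mm$mape),
          rmse = mean(mm$rmse), hyperparameters = list(final_hyper)
        ),
        fit = final_fit
      )
    })
  })

  structure(
    list(
      results = dplyr::bind_rows(lapply(res, `[[`, "row")),
      fits = stats::setNames(lapply(res, `[[`, "fit"), models),
      folds = folds, seed = seed, n = n,
      feature_names = trait_names()
    ),
    class = "weight_model_report"
  )
}

# hyperparameter grids (NULL entries mean library defaults)
model_grid <- function(model) {
  switch(model,
    LR = list(list()),
    BR = list(list()),
    KNN = lapply(c(3, 5, 7, 9, 11), function(k) list(k = k)),
    RF = {
      g <- expand.grid(ntree = c(100, 300, 500), depth = c(NA, 5, 10))
      lapply(seq_len(nrow(g)), function(i) {
        list(ntree = g$ntree[i], depth = if (is.na(g$depth[i])) NULL else g$depth[i])
      })
    },
    GBR = {
      g <- expand.grid(eta = c(0.05, 0.1), nrounds = c(100, 300), max_depth = c(2, 3))
      lapply(seq_len(nrow(g)), function(i) {
        list(eta = g$eta[i], nrounds = g$nrounds[i], max_depth = g$max_depth[i])
      })
    }
  )
}

select_hyper <- function(model, X, y, inner_folds) {
  grid <- model_grid(model)
  if (length(grid) == 1) return(grid[[1]])
  n <- nrow(X)
  k <- min(inner_folds, n)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  rmse <- vapply(grid, function(h) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold_id != f
      fit <- fit_regressor(model, X[tr, , drop = FALSE], y[tr], h)
      pred <- predict_regressor(fit, X[!tr, , drop = FALSE])
      sqrt(mean((y[!tr] - pred)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  grid[[which.min(rmse)]]
}

fit_regressor <- function(model, X, y, hyper) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  fit <- switch(model,
    LR = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(Xs)))
      df$.y <- y
      stats::lm(.y ~ ., data = df)
    },
    BR = bayes_ridge(Xs, y),
    KNN = list(X = Xs, y = y, k = hyper$k),
    RF = {
      maxnodes <- if (is.null(hyper$depth)) NULL else 2L^hyper$depth
      randomForest::randomForest(
        Xs, y, ntree = hyper$ntree, maxnodes = maxnodes
      )
    },
    GBR = xgboost::xgboost(
      data = Xs, label = y, nrounds = hyper$nrounds,
      params = list(
        eta = hyper$eta, max_depth = hyper$max_depth,
        objective = "reg:squarederror", nthread = 1
      ),
      verbose = 0
    )
  )
  list(model = model, fit = fit, center = ctr, scale = scl, hyper = hyper)
}

predict_regressor <- function(fitted, X) {
  Xs <- sweep(sweep(X, 2, fitted$center), 2, fitted$scale, "/")
  switch(fitted$model,
    LR = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(Xs)))
      unname(stats::predict(fitted$fit, newdata = df))
    },
    BR = as.numeric(Xs %*% fitted$fit$coef + fitted$fit$intercept),
    KNN = as.numeric(
      FNN::knn.reg(train = fitted$fit$X, test = Xs, y = fitted$fit$y,
                   k = fitted$fit$k)$pred
    ),
    RF = unname(stats::predict(fitted$fit, Xs)),
    GBR = as.numeric(stats::predict(fitted$fit, Xs))
  )
}

# Bayesian ridge regression by evidence (type-II maximum likelihood)
# approximation: gaussian prior w ~ N(0, 1/lambda), noise precision alpha;
# both updated by MacKay's fixed-point rules on the centred problem.
bayes_ridge <- function(X, y, max_iter = 300, tol = 1e-8) {
  n <- nrow(X)
  p <- ncol(X)
  ybar <- mean(y)
  yc <- y - ybar
  XtX <- crossprod(X)
  Xty <- crossprod(X, yc)
  eig <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  alpha <- 1 / max(var(yc), 1e-12)
  lambda <- 1
  coef <- rep(0, p)
  for (it in seq_len(max_iter)) {
    A <- XtX * alpha
    diag(A) <- diag(A) + lambda
    coef_new <- solve(A, alpha * Xty)
    gamma <- sum(alpha * eig / (lambda + alpha * eig))
    rss <- sum((yc - X %*% coef_new)^2)
    lambda_new <- gamma / max(sum(coef_new^2), 1e-12)
    alpha_new <- max(n - gamma, 1e-6) / max(rss, 1e-12)
    done <- max(abs(coef_new - coef)) < tol
    coef <- coef_new
    lambda <- lambda_new
    alpha <- alpha_new
    if (done) break
  }
  list(coef = as.numeric(coef), intercept = ybar, alpha = alpha,
       lambda = lambda)
}

#' Predict single-grain weight from traits
#'
#' Applies one of the final models of a [train_weight_models()] report to
#' new trait rows. The trait table must carry all 32 trait columns the
#' models were fitted on.
#'
#' @param report A `weight_model_report`.
#' @param traits A trait tibble (32 trait columns).
#' @param model Model name; default: the model with the highest
#'   cross-validated R2.
#' @return A tibble with `model` and predicted `weight` (mg) per row.
#' @export
predict_weight <- function(report, traits, model = NULL) {
  stopifnot(inherits(report, "weight_model_report"))
  missing <- setdiff(report$feature_names, names(traits))
  if (length(missing)) {
    abort(sprintf("trait schema mismatch: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  model <- model %||% report$results$model[which.max(report$results$r2)]
  if (!model %in% names(report$fits)) abort(sprintf("no fitted model '%s'", model))
  X <- as.matrix(traits[, report$feature_names])
  if (anyNA(X) || any(!is.finite(X))) abort("non-finite trait values")
  tibble(model = model, weight = predict_regressor(report$fits[[model]], X))
}

#' @export
print.weight_model_report <- function(x, ...) {
  cat(sprintf("<weight_model_report> %d-fold CV on %d grains (seed %d)\n",
              x$folds, x$n, x$seed))
  df <- x$results
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-4s R2 = %.4f  MAPE = %.2f%%  RMSE = %.3f mg\n",
                df$model[i], df$r2[i], df$mape[i], df$rmse[i]))
  }
  invisible(x)
}

#' @method tidy weight_model_report
#' @export
tidy.weight_model_report <- function(x, ...) {
  x$results
}

#' @method glance weight_model_report
#' @export
glance.weight_model_report <- function(x, ...) {
  best <- which.max(x$results$r2)
  tibble(
    n = x$n, folds = x$folds, seed = x$seed,
    best_model = x$results$model[best],
    best_r2 = x$results$r2[best],
    best_mape = x$results$mape[best],
    best_rmse = x$results$rmse[best]
  )
}

#' Plot a weight-model report
#'
#' Dot plot of the cross-validated R2, MAPE and RMSE per regressor.
#'
#' @param object A `weight_model_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot weight_model_report
#' @export
autoplot.weight_model_report <- function(object, ...) {
  df <- object$results |>
    dplyr::select("model", "r2", "mape", "rmse") |>
    tidyr::pivot_longer(-"model", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d-fold cross-validated weight models", object$folds))
}
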