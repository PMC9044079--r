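fake_outline <- function(area, perimeter, axis = "x") {
  structure(list(area = area, perimeter = perimeter, axis = axis),
            class = "grain_outline")
}

test_that("assemble_traits builds a consistent 32-column record", {
  outs <- list(yz = fake_outline(6, 10), xz = fake_outline(14, 16),
               xy = fake_outline(15, 17))
  rec <- assemble_traits(
    l = 6, w = 3, h = 2.8, V = 33, S = 55, D = 0.5, outlines = outs,
    C_c = 9.5, S_c = 6.4, S_s = 0.3, id = 7L
  )
  expect_equal(ncol(rec), 33)  # id + 32 traits
  expect_equal(names(rec)[-1], trait_names())
  expect_equal(rec$V_obb, 6 * 3 * 2.8)
  expect_equal(rec$V_obb, 50.4)
  expect_gte(rec$V_obb, rec$V)
  expect_equal(rec$`l/w` * rec$`w/h`, rec$`l/h`, tolerance = 1e-9)
  expect_equal(rec$c_yz, roundness(outs$yz))
  expect_equal(rec$E, sphericity(33, 55))
  expect_error(
    assemble_traits(6, 3, 0, 33, 55, 0.5, outs, 9.5, 6.4, 0.3),
    "division by zero.*h"
  )
})

test_that("agreement metrics match hand-computed values", {
  m0 <- metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m0), c(mape = 0, rmse = 0, r2 = 1))

  m1 <- metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(m1$mape, 100 * (0.1 / 1 + 0.1 / 2 + 0.2 / 3) / 3, tolerance = 1e-12)
  expect_equal(m1$mape, 7.2222, tolerance = 1e-3)
  expect_equal(m1$rmse, sqrt(0.06 / 3), tolerance = 1e-12)
  expect_equal(m1$rmse, 0.1414, tolerance = 1e-3)

  x <- c(4, 7, 9, 12)
  m2 <- metrics(x, x + 2.5)
  expect_equal(m2$rmse, 2.5)
  # hand-computed R2 under both baselines: num = 4 * 2.5^2 = 25;
  # system baseline ybar = 10.5 -> 1 - 25/59; reference xbar = 8 -> 1 - 25/34
  expect_equal(m2$r2, 1 - 25 / 59, tolerance = 1e-12)
  expect_equal(metrics(x, x + 2.5, r2_baseline = "reference")$r2,
               1 - 25 / 34, tolerance = 1e-12)

  expect_error(metrics(c(0, 1), c(1, 1)), "MAPE undefined")
  expect_error(metrics(1, 1), "at least 2")
})

test_that("correlation matrix is symmetric with planted structure", {
  g <- quick_grain(seed = 21)
  base <- grain_traits(g$cloud)
  withr::with_seed(22, {
    tab <- dplyr::bind_rows(lapply(1:12, function(i) base * runif(1, 0.8, 1.2)))
  })
  tab$weight <- 2 * tab$V + rnorm(12, sd = 1e-6)
  cm <- correlation_matrix(tab)
  expect_equal(dim(cm), c(33, 33))
  expect_equal(diag(cm), stats::setNames(rep(1, 33), colnames(cm)))
  expect_equal(cm, t(cm))
  expect_equal(cm["weight", "V"], 1, tolerance = 1e-6)
  tab2 <- tab
  tab2$weight <- -tab2$V
  expect_equal(correlation_matrix(tab2)["weight", "V"], -1, tolerance = 1e-12)

  tab3 <- tab
  tab3$D <- 0.5
  expect_warning(cm3 <- correlation_matrix(tab3), "zero-variance")
  expect_true(is.na(cm3["D", "l"]))
})

test_that("L9 range analysis reproduces the printed scan-condition table", {
  l9 <- system.file("extdata", "l9_scan_conditions.csv", package = "grain3d")
  res <- run_doe(l9)
  K <- res$K
  expect_equal(unname(K["stage_color", ]), c(0.0409, 0.0920, 0.1224),
               tolerance = 1e-3)
  expect_equal(unname(res$R[["stage_color"]]), 0.0815, tolerance = 1e-3)
  expect_equal(unname(K["scanning_angle", ]), c(0.0710, 0.1142, 0.0701),
               tolerance = 1e-3)
  expect_equal(unname(res$R[["scanning_angle"]]), 0.0441, tolerance = 1e-3)
  expect_equal(unname(K["rotation_angle", 1:2]), c(0.1045, 0.0765),
               tolerance = 1e-3)
  # the printed level-3 rotation mean is a typographical slip; the mean of
  # its three tests is 0.0743
  expect_equal(unname(K["rotation_angle", 3]), 0.07433, tolerance = 1e-3)
  expect_equal(res$best_labels[["stage_color"]], "black")
  expect_equal(res$best_labels[["rotation_angle"]], "30")
  expect_equal(res$best_labels[["scanning_angle"]], "37")
})

test_that("range analysis is permutation-invariant and rejects imbalance", {
  l9 <- system.file("extdata", "l9_scan_conditions.csv", package = "grain3d")
  tab <- read_design_table(l9)
  perm <- withr::with_seed(1, tab[sample(9), ])
  attr(perm, "levels") <- attr(tab, "levels")
  r1 <- orthogonal_analysis(tab)
  r2 <- orthogonal_analysis(perm)
  expect_equal(r1$K, r2$K)
  expect_equal(r1$R, r2$R)

  const <- tab
  const$response <- 0.05
  rc <- orthogonal_analysis(const)
  expect_equal(unname(rc$R), rep(0, 3))

  bad <- tab
  bad$stage_color <- c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L)
  expect_error(orthogonal_analysis(bad), "unbalanced")
})
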