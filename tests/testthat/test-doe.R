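test_that("response normalisation spans 0-100 with background modes", {
  expect_equal(normalizeResponses(c(10, 20, 30)), c(0, 50, 100))
  # divide mode: background mean 2 rescales before min-max
  expect_equal(normalizeResponses(c(2, 4), negatives = c(1, 3),
                                  mode = "divide"), c(0, 100))
  # subtract mode clamps at zero
  expect_equal(normalizeResponses(c(3, 5, 15), negatives = 5,
                                  mode = "subtract"), c(0, 0, 100))
  # idempotence on an already-normalised vector without background
  x <- c(0, 12.5, 80, 100)
  expect_equal(normalizeResponses(x), x)
  expect_error(normalizeResponses(c(5, 5, 5)), "zero range")
  expect_error(normalizeResponses(c(1, 2), negatives = c(0, 0),
                                  mode = "divide"), "zero")
  expect_error(normalizeResponses(c(1, 2), mode = "divide"),
               "negative controls")
})

test_that("design expansion builds main, interaction and quadratic terms", {
  d <- data.frame(x1 = c(1, 2, 3, 4), x2 = c(0, 1, 0, 1))
  Xm <- expandDesign(d, order = "main")
  expect_identical(colnames(Xm), c("x1", "x2"))
  expect_equal(unname(colMeans(Xm)), c(0, 0))
  expect_equal(unname(apply(Xm, 2, sd)), c(1, 1))

  Xi <- expandDesign(d, order = "interactions")
  expect_identical(colnames(Xi), c("x1", "x2", "x1:x2"))
  expect_equal(Xi[, "x1:x2"], Xi[, "x1"] * Xi[, "x2"])

  Xq <- expandDesign(d, order = "quadratic")
  expect_identical(colnames(Xq), c("x1", "x2", "x1:x2", "x1^2", "x2^2"))

  # one categorical with 5 levels: 4 indicators against the first level
  d2 <- data.frame(chem = c("dNTP", "FA", "FT", "FAT", "FTGC", "dNTP"),
                   conc = c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
  X2 <- expandDesign(d2, order = "main")
  expect_equal(sum(startsWith(colnames(X2), "chem.")), 4)
  expect_false("chem.FA" %in% colnames(X2) && any(X2[d2$chem == "dNTP",
                startsWith(colnames(X2), "chem.")] != 0))

  expect_warning(expandDesign(data.frame(a = c(1, 1, 1), b = 1:3)),
                 "constant")
  expect_error(expandDesign(data.frame(a = c(1, NA, 2))), "missing")
})

test_that("lasso importance recovers noiseless and degenerate signals", {
  set.seed(1)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  # y depends on x1 only, no noise: x1 dominates, others ~ 0
  y <- 3 * X[, 1]
  fi <- lassoImportance(X, y, repeats = 10, cvFolds = 5, seed = 2)
  imp <- stats::setNames(fi$importance$meanAbsCoef, fi$importance$feature)
  expect_identical(fi$importance$feature[1], "x1")
  expect_gt(imp[["x1"]], 10 * max(imp[c("x2", "x3", "x4")]))
  expect_lt(max(imp[c("x2", "x3", "x4")]), 1e-2)

  # constant response: all coefficients zero
  fi0 <- lassoImportance(X, rep(5, 40), repeats = 5, seed = 3)
  expect_true(all(fi0$importance$meanAbsCoef == 0))
})

test_that("lasso importance ranks generative signals by sign and size", {
  # y = 2 x1 - 1 x3 + noise; top-2 coefficient signs match in >= 9/10 runs
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(36 * 5), 36, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- 2 * X[, 1] - 1 * X[, 3] + rnorm(36, sd = 0.1)
    fi <- lassoImportance(X, y, repeats = 20, cvFolds = 5, seed = s)
    top2 <- fi$importance$feature[1:2]
    co <- stats::setNames(fi$importance$meanCoef, fi$importance$feature)
    if (setequal(top2, c("x1", "x3")) && co[["x1"]] > 0 && co[["x3"]] < 0)
      ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("importance is reproducible and row-order invariant", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 2] + rnorm(30, sd = 0.2)
  f1 <- lassoImportance(X, y, repeats = 8, seed = 11)
  f2 <- lassoImportance(X, y, repeats = 8, seed = 11)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)

  perm <- sample(30)
  f3 <- lassoImportance(X[perm, ], y[perm], repeats = 8, seed = 11)
  expect_equal(colMeans(f3$coefficients), colMeans(f1$coefficients),
               tolerance = 0.05)

  # metrics consistency: R2 = 1 - MSE / var(y) on the same predictions
  mets <- stats::setNames(f1$metrics$mean, f1$metrics$metric)
  expect_equal(mets[["R2"]], 1 - mets[["MSE"]] / mean((y - mean(y))^2),
               tolerance = 1e-8)
})
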