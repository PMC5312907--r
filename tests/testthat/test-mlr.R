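test_that("OLS coefficients match an explicit normal-equations solve", {
  set.seed(42)
  X <- as.data.frame(matrix(rnorm(60), 20, 3,
                            dimnames = list(NULL, c("a", "b", "c"))))
  y <- 1 + 2 * X$a - 0.5 * X$b + rnorm(20, 0, 0.3)
  fit <- fit_ols(X, y)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)   # independent normal equations
  expect_equal(unname(fit$coefficients), unname(drop(beta)), tolerance = 1e-10)
  # R2 equals the squared correlation of observed and fitted values
  expect_equal(fit$stats$R2, cor(y, predict(fit, X))^2, tolerance = 1e-12)
  # F identity
  n <- 20; p <- 3
  expect_equal(fit$stats$F,
               (fit$stats$R2 / p) / ((1 - fit$stats$R2) / (n - p - 1)),
               tolerance = 1e-9)
})

test_that("perfect linear response gives R2 = 1, s = 0, Q2 = 1", {
  X <- data.frame(x = 1:10)
  fit <- fit_ols(X, 2 + 3 * (1:10))
  expect_equal(fit$stats$R2, 1)
  expect_equal(fit$stats$s, 0, tolerance = 1e-12)
  expect_equal(fit$stats$Q2, 1, tolerance = 1e-12)
  expect_equal(fit$stats$PRESS, 0, tolerance = 1e-18)
})

test_that("degenerate designs are rejected with the columns named", {
  X <- data.frame(a = rnorm(10), b = rep(2, 10))
  expect_error(fit_ols(X, rnorm(10)), "zero-variance.*b")
  X2 <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(X2, rnorm(10)), "collinear")
  expect_error(fit_ols(data.frame(a = 1:2), rnorm(2)), "n > p")
})

test_that("hat-matrix leave-one-out equals the explicit refit loop", {
  set.seed(7)
  for (p in 1:3) {
    X <- as.data.frame(matrix(rnorm(22 * p), 22, p))
    names(X) <- paste0("v", seq_len(p))
    y <- rnorm(22)
    a <- loo_crossvalidate(X, y, method = "hat")
    b <- loo_crossvalidate(X, y, method = "refit")
    expect_equal(a$PRESS, b$PRESS, tolerance = 1e-10)
    expect_equal(a$Q2, b$Q2, tolerance = 1e-10)
  }
})

test_that("SDEP degrees-of-freedom conventions are distinct and documented", {
  set.seed(1)
  X <- data.frame(x = rnorm(12)); y <- rnorm(12)
  l1 <- loo_crossvalidate(X, y, sdep_df = "n-1")
  l2 <- loo_crossvalidate(X, y, sdep_df = "n")
  expect_equal(l1$SDEP, sqrt(l1$PRESS / 11))
  expect_equal(l2$SDEP, sqrt(l2$PRESS / 12))
  expect_equal(l1$SPRESS, sqrt(l1$PRESS / 10))
})

test_that("fit statistics are invariant to affine predictor rescaling", {
  set.seed(3)
  X <- data.frame(a = rnorm(15, 100, 30), b = runif(15))
  y <- 0.01 * X$a - 2 * X$b + rnorm(15, 0, 0.2)
  f1 <- fit_ols(X, y)
  X2 <- transform(X, a = (a - 50) / 10)
  f2 <- fit_ols(X2, y)
  expect_equal(f1$stats$R2, f2$stats$R2, tolerance = 1e-12)
  expect_equal(f1$stats$F, f2$stats$F, tolerance = 1e-9)
  expect_equal(f1$stats$s, f2$stats$s, tolerance = 1e-12)
  expect_equal(f1$stats$Q2, f2$stats$Q2, tolerance = 1e-10)
  expect_equal(unname(f2$coefficients["a"]),
               unname(f1$coefficients["a"]) * 10, tolerance = 1e-9)
})

test_that("prediction is the affine form and validates columns", {
  set.seed(9)
  X <- data.frame(u = rnorm(10), v = rnorm(10))
  y <- rnorm(10)
  fit <- fit_ols(X, y)
  expect_equal(predict(fit, X), unname(fitted(fit$lm)), tolerance = 1e-12)
  zero <- data.frame(u = 0, v = 0)
  expect_equal(predict(fit, zero), unname(fit$coefficients[1]))
  expect_error(predict(fit, data.frame(u = 1)), "lacks column")
})

test_that("correlation matrix is symmetric with unit diagonal and flags degeneracy", {
  set.seed(4)
  df <- data.frame(x = rnorm(10))
  df$y <- -df$x
  df$z <- rnorm(10)
  m <- correlation_matrix(df)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(x = 1, y = 1, z = 1))
  expect_equal(m["x", "y"], -1)
  expect_true(all(abs(m) <= 1 + 1e-12))
  df$const <- 5
  expect_warning(m2 <- correlation_matrix(df), "zero-variance")
  expect_true(anyNA(m2["const", c("x", "y", "z")]))
  expect_error(correlation_matrix(df[1:2, ]), "3 observations")
})
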