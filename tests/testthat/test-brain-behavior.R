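test_that("simple screen reproduces the one-predictor identities", {
  set.seed(41)
  n <- 37
  X <- matrix(rnorm(n * 6), ncol = 6,
              dimnames = list(NULL, sprintf("node_%d", 1:6)))
  y <- X[, 3]  # behavior is an exact copy of node 3
  sc <- screen_simple(X, y)
  expect_equal(sc$beta[3], 1)
  expect_equal(sc$r2[3], 1)
  # beta^2 = R2 for every node; F = t^2 of the lm slope
  expect_equal(sc$beta^2, sc$r2, tolerance = 1e-12)
  for (j in c(1, 2, 4)) {
    fit <- summary(lm(y ~ X[, j]))
    expect_equal(sc$r2[j], fit$r.squared, tolerance = 1e-10)
    expect_equal(sc$f_stat[j], unname(coef(fit)[2, "t value"]^2),
                 tolerance = 1e-8)
    expect_equal(sc$p[j], unname(coef(fit)[2, "Pr(>|t|)"]),
                 tolerance = 1e-10)
    expect_equal(sc$adj_r2[j], fit$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("screen formulas reproduce printed single-regression statistics", {
  # worked example at n = 37: R2 = .134 gives adj R2 ~ .109, F(1;35) ~ 5.42
  n <- 37
  r2 <- 0.134
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  f <- r2 / (1 - r2) * (n - 2)
  expect_equal(adj, 0.109, tolerance = 0.01)
  expect_equal(f, 5.421, tolerance = 0.05)
  expect_equal(sqrt(r2), 0.366, tolerance = 0.005)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  expect_lt(abs(p - 0.026), 0.005)
})

test_that("constant columns are dropped from the screen with a warning", {
  set.seed(6)
  X <- cbind(a = rnorm(20), b = rep(1, 20), c = rnorm(20))
  expect_warning(sc <- screen_simple(X, rnorm(20)), "constant")
  expect_equal(sc$node, c("a", "c"))
})

test_that("tolerance filter matches a multiple-R2 oracle", {
  set.seed(17)
  n <- 50
  # orthogonalized (and centered) columns: tolerances 1, all kept
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 3), ncol = 3), scale = FALSE)))
  colnames(Q) <- c("q1", "q2", "q3")
  tf <- tolerance_filter(Q)
  expect_equal(unname(tf$tolerance), rep(1, 3), tolerance = 1e-10)
  expect_equal(tf$kept, colnames(Q))

  # duplicated column: zero tolerance, both copies dropped
  X <- cbind(a = rnorm(n), c = rnorm(n))
  X <- cbind(X, b = X[, "a"])
  tf2 <- tolerance_filter(X)
  expect_equal(unname(tf2$tolerance[c("a", "b")]), c(0, 0), tolerance = 1e-10)
  expect_false(any(c("a", "b") %in% tf2$kept))
  expect_true("c" %in% tf2$kept)

  # correlated triple: tolerances equal 1 - multiple R2 by normal equations
  z <- rnorm(n)
  X3 <- cbind(x1 = z + rnorm(n, 0, 0.5), x2 = z + rnorm(n, 0, 0.5),
              x3 = rnorm(n))
  tf3 <- tolerance_filter(X3)
  for (j in 1:3)
    expect_equal(unname(tf3$tolerance[j]), 1 - oracle_multiple_r2(X3, j),
                 tolerance = 1e-10)

  # single candidate kept by convention
  tf1 <- tolerance_filter(X3[, 1, drop = FALSE])
  expect_equal(unname(tf1$tolerance), 1)
})

test_that("forward stepwise selects a strong predictor among nulls", {
  set.seed(23)
  n <- 37
  hits <- vapply(1:20, function(rep) {
    X <- matrix(rnorm(n * 21), ncol = 21,
                dimnames = list(NULL, sprintf("c%02d", 1:21)))
    y <- X[, "c05"] + rnorm(n)  # true r2 about 0.5
    m <- forward_stepwise(X, y)
    length(m$selected) >= 1 && m$selected[1] == "c05"
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("two independent true predictors enter in descending marginal F", {
  set.seed(71)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1.0 * x1 + 0.5 * x2 + rnorm(n, 0, 0.6)
  X <- cbind(weak = x2, strong = x1)
  m <- forward_stepwise(X, y)
  expect_equal(m$selected, c("strong", "weak"))
  expect_true(all(m$entry_history$f_enter > 4))
  # model R2 non-decreasing across steps
  expect_true(all(diff(m$entry_history$model_r2) >= 0))
})

test_that("stepwise never admits a predictor at or below F-to-enter", {
  set.seed(92)
  for (rep in 1:10) {
    n <- 30
    X <- matrix(rnorm(n * 8), ncol = 8,
                dimnames = list(NULL, sprintf("v%d", 1:8)))
    y <- 0.8 * X[, 1] + rnorm(n)
    m <- forward_stepwise(X, y)
    if (nrow(m$entry_history))
      expect_true(all(m$entry_history$f_enter > 4))
  }
})

test_that("all-null entry rate matches its analytic calibration", {
  # 20 null candidates, n = 37: the first entry fails only if no candidate
  # exceeds F-to-enter; under independence that has probability
  # (1 - P(F(1,35) > 4))^20
  set.seed(37)
  n <- 37; reps <- 80
  empty <- vapply(seq_len(reps), function(rep) {
    X <- matrix(rnorm(n * 20), ncol = 20,
                dimnames = list(NULL, sprintf("n%02d", 1:20)))
    m <- forward_stepwise(X, rnorm(n))
    length(m$selected) == 0
  }, logical(1))
  expected <- (1 - pf(4, 1, n - 2, lower.tail = FALSE))^20
  mc_se <- sqrt(expected * (1 - expected) / reps)
  expect_lt(abs(mean(empty) - expected), 3.5 * mc_se)
})

test_that("final model statistics match a direct least-squares refit", {
  set.seed(61)
  n <- 40
  X <- matrix(rnorm(n * 5), ncol = 5,
              dimnames = list(NULL, sprintf("p%d", 1:5)))
  y <- X[, 1] - 0.7 * X[, 2] + rnorm(n, 0, 0.5)
  m <- forward_stepwise(X, y)
  expect_gte(length(m$selected), 1)
  ref <- summary(lm(scale(y) ~ scale(X[, m$selected])))
  expect_equal(m$r2, ref$r.squared, tolerance = 1e-10)
  expect_equal(m$adj_r2, ref$adj.r.squared, tolerance = 1e-10)
  expect_equal(unname(m$f_stat), unname(ref$fstatistic[1]), tolerance = 1e-8)
  # standardized betas agree with the scaled refit
  expect_equal(unname(coef(m)), unname(coef(ref)[-1, "Estimate"]),
               tolerance = 1e-8)
})

test_that("empty model predicts the behavioural mean", {
  set.seed(15)
  X <- matrix(rnorm(20 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20)
  m <- forward_stepwise(X, y, stepwise_config(f_enter = 1e6))
  expect_length(m$selected, 0)
  expect_equal(m$r2, 0)
  expect_equal(predict(m, X), rep(mean(y), 20))
})

test_that("brain_behavior_run chains screen, tolerance and stepwise", {
  set.seed(19)
  n <- 37
  z <- rnorm(n)
  X <- matrix(rnorm(n * 30), ncol = 30,
              dimnames = list(NULL, sprintf("roi%02d", 1:30)))
  X[, "roi07"] <- 0.8 * z + 0.4 * rnorm(n)
  run <- brain_behavior_run(X, z)
  expect_true("roi07" %in% run$screen$node[run$screen$passed])
  expect_true("roi07" %in% run$model$selected)
  # screened-but-collinear candidates never reach the model
  expect_true(all(run$model$selected %in% run$candidates))
})
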