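test_that("the intercept-only logistic fit is the sample proportion with its Wald interval", {
  d <- binary_from_counts(430, 1564)
  b <- logistic_baseline(y ~ 1, d)
  phat <- 430 / 1564
  expect_equal(b$proportion, phat, tolerance = 1e-10)
  half <- qnorm(0.975) * sqrt(phat * (1 - phat) / 1564)
  expect_equal(unname(b$prop_ci), c(phat - half, phat + half),
               tolerance = 1e-10)
  # printed rounding convention of the pooled analysis
  expect_equal(round(b$proportion, 2), 0.27)
  expect_equal(round(unname(b$prop_ci), 2), c(0.25, 0.30))
})

test_that("balanced data give a zero intercept and proportion one half", {
  d <- data.frame(y = rep(c(1, 0), each = 5))
  b <- logistic_baseline(y ~ 1, d)
  expect_equal(b$coefficients$estimate, 0, tolerance = 1e-10)
  expect_equal(b$proportion, 0.5)
})

test_that("the pooled proportion estimates the product omega * p, not either factor", {
  ex <- summary(zib_exact(430, 1564))
  b <- logistic_baseline(y ~ 1, binary_from_counts(430, 1564))
  expect_equal(b$proportion, ex["omega_p", "median"], tolerance = 0.01)
  # and it underestimates the occurrence probability among the exposed
  expect_lt(b$proportion, ex["p", "lower"])
})

test_that("exposed-only logistic regression is consistent for the occurrence part", {
  d <- zib_sim_regression(5000, theta = c(-0.5, -2, -3),
                          beta = c(0.5, 2, 3), seed = 77)
  expo <- attr(d, "exposure")
  b <- logistic_baseline(y ~ x3 + x4, d, subset = expo == 1)
  expect_true(all(abs(b$coefficients$estimate - c(0.5, 2, 3)) <= 0.15))
  expect_false(b$separation)
})

test_that("separation and rank deficiency are detected", {
  d <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 11, 12, 13))
  expect_warning(b <- logistic_baseline(y ~ x, d), "separation")
  expect_true(b$separation)

  d2 <- data.frame(y = rbinom(20, 1, 0.5), a = rnorm(20))
  d2$b <- 2 * d2$a
  expect_error(logistic_baseline(y ~ a + b, d2), "rank")
})

test_that("CSV reading codes categoricals by reference and drops incomplete rows", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(y = c(0, 1, 1, 0, 1, 0),
                   g = c("a", "b", "c", "a", "b", "c"),
                   x = c(1, 2, NA, 4, 5, 6))
  write.csv(df, f, row.names = FALSE)
  expect_message(r <- read_zib_data(f, outcome = "y", structural = "g",
                                    occurrence = "x"), "dropped 1")
  expect_equal(ncol(r$X), 2)          # 3 levels -> 2 indicators
  expect_equal(colnames(r$X), c("gb", "gc"))
  expect_equal(r$manifest$coding$g$reference, "a")
  expect_equal(r$manifest$dropped_rows, 1)
  expect_equal(r$manifest$n, 5)

  # reference override
  r2 <- suppressMessages(read_zib_data(f, outcome = "y", structural = "g",
                                       references = c(g = "b")))
  expect_equal(colnames(r2$X), c("ga", "gc"))

  expect_error(read_zib_data(f, outcome = "nope"), "unknown column")
  unlink(f)
})

test_that("write-then-read round-trips a simulated dataset exactly", {
  d <- zib_sim_regression(50, theta = c(-0.5, -2, -3), beta = c(0.5, 2, 3),
                          seed = 8)
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  r <- read_zib_data(f, outcome = "y", structural = c("x1", "x2"),
                     occurrence = c("x3", "x4"))
  expect_equal(r$y, d$y)
  expect_equal(unname(r$X[, "x1"]), d$x1)
  expect_equal(unname(r$Z[, "x4"]), d$x4)
  unlink(f)
})
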