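test_that("zib pmf matches the two-layer construction and normalizes", {
  expect_equal(dzib(1, 0.5, 0.5), 0.25)
  expect_equal(dzib(0, 1, 0.7), 0.3)      # omega = 1: plain Bernoulli(p)
  expect_equal(dzib(1, 0.37, 0.74), 0.2738)

  # P(0) decomposes into structural + sample zeros
  expect_equal(dzib(0, 0.4, 0.8), (1 - 0.4) + 0.4 * (1 - 0.8))

  # normalization over a parameter grid
  for (w in c(0, 0.13, 0.5, 0.99, 1))
    for (p in c(0, 0.5, 0.87, 1))
      expect_equal(dzib(0, w, p) + dzib(1, w, p), 1, tolerance = 1e-12)

  expect_error(dzib(2, 0.5, 0.5), "0 or 1")
  expect_error(dzib(1, 1.5, 0.5), "\\[0, 1\\]")
  expect_error(dzib(1, 0.5, -0.1), "\\[0, 1\\]")
})

test_that("aggregate log-likelihood depends on (omega, p) only through the product", {
  for (cnt in list(c(0, 10), c(3, 7), c(430, 1564))) {
    expect_equal(zib_loglik_aggregate(0.4, 0.8, cnt[1], cnt[2]),
                 zib_loglik_aggregate(0.8, 0.4, cnt[1], cnt[2]))
    expect_equal(zib_loglik_aggregate(0.32, 1, cnt[1], cnt[2]),
                 zib_loglik_aggregate(0.4, 0.8, cnt[1], cnt[2]))
  }

  # all-zeros case is a pure survival term
  expect_equal(zib_loglik_aggregate(0.5, 0.6, 0, 10), 10 * log(1 - 0.3))

  # the product MLE is the binomial proportion m/n
  opt <- optimize(function(t) zib_loglik_aggregate(t, 1, 430, 1564),
                  c(0.01, 0.99), maximum = TRUE)
  expect_equal(opt$maximum, 430 / 1564, tolerance = 1e-4)

  # impossible data at degenerate products return -Inf, not an error
  expect_identical(zib_loglik_aggregate(0, 0.5, 3, 10), -Inf)
  expect_identical(zib_loglik_aggregate(1, 1, 3, 10), -Inf)
  expect_error(zib_loglik_aggregate(0.5, 0.5, 11, 10), "m <= n")
})

test_that("regression log-likelihood reduces to the aggregate form and to invlogit(0) = 1/2", {
  y <- rep(c(1, 0), c(13, 27))
  expect_equal(zib_loglik_regression(logit(0.4), logit(0.8), y),
               zib_loglik_aggregate(0.4, 0.8, 13, 40), tolerance = 1e-9)

  # zero coefficients give per-observation log(1/4) and log(3/4)
  X <- matrix(rnorm(80), 40, 2); Z <- matrix(rnorm(80), 40, 2)
  expect_equal(zib_loglik_regression(c(0, 0, 0), c(0, 0, 0), y, X, Z),
               13 * log(0.25) + 27 * log(0.75), tolerance = 1e-9)

  expect_error(zib_loglik_regression(c(0, 0), c(0, 0, 0), y, X, Z),
               "length")
  Xbad <- X; Xbad[1] <- NA
  expect_error(zib_loglik_regression(c(0, 0, 0), c(0, 0, 0), y, Xbad, Z),
               "non-finite")
})

test_that("the likelihood surface peaks near the generating parameters", {
  theta <- c(-0.5, -2, -3); beta <- c(0.5, 2, 3)
  wins <- vapply(1:20, function(s) {
    d <- zib_sim_regression(1500, theta = theta, beta = beta, seed = 7000 + s)
    X <- as.matrix(d[c("x1", "x2")]); Z <- as.matrix(d[c("x3", "x4")])
    zib_loglik_regression(theta, beta, d$y, X, Z) >
      zib_loglik_regression(theta + 2, beta + 2, d$y, X, Z)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("invlogit is stable, increasing, and inverse to logit", {
  expect_equal(invlogit(0), 0.5)
  expect_equal(invlogit(logit(0.27)), 0.27, tolerance = 1e-12)
  expect_equal(invlogit(-800), 0, tolerance = 1e-300)
  expect_equal(invlogit(800), 1)
  x <- seq(-30, 30, length.out = 200)
  expect_true(all(diff(invlogit(x)) > 0))
})
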