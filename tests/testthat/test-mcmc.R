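test_that("fits are exactly reproducible from the seed", {
  f1 <- fast_aggregate(43, 156, iter = 600, seed = 9)
  f2 <- fast_aggregate(43, 156, iter = 600, seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- fast_aggregate(43, 156, iter = 600, seed = 10)
  expect_false(identical(f1$draws, f3$draws))

  d <- zib_sim_regression(150, theta = c(-0.5, -2, -3), beta = c(0.5, 2, 3),
                          seed = 1)
  g1 <- fast_fit(y ~ x1 + x2 | x3 + x4, data = d, iter = 400, seed = 4)
  g2 <- fast_fit(y ~ x1 + x2 | x3 + x4, data = d, iter = 400, seed = 4)
  expect_identical(g1$draws, g2$draws)
})

test_that("with no observations the posterior medians sit at the prior medians", {
  f <- fast_aggregate(0, 0, iter = 3000, seed = 2)
  s <- summary(f)
  expect_lt(abs(s["omega", "median"] - 0.25), 0.02)
  expect_lt(abs(s["p", "median"] - 0.75), 0.02)
})

test_that("intercept-only sampling agrees with the exact posterior", {
  ex <- summary(zib_exact(430, 1564))
  f <- fast_aggregate(430, 1564, iter = 4000, chains = 3, seed = 5)
  s <- summary(f)
  for (par in c("omega", "p")) {
    expect_lt(abs(s[par, "median"] - ex[par, "median"]), 0.02)
    expect_lt(abs(s[par, "lower"] - ex[par, "lower"]), 0.03)
    expect_lt(abs(s[par, "upper"] - ex[par, "upper"]), 0.03)
  }
})

test_that("the Metropolis fallback shares the draw contract and the target", {
  ex <- summary(zib_exact(430, 1564))
  f <- suppressWarnings(zib_aggregate(430, 1564, chains = 2, iter = 8000,
                                      sampler = "rwm", seed = 6))
  expect_equal(dim(f$draws), c(4000, 2, 2))
  s <- summary(f)
  expect_lt(abs(s["omega", "median"] - ex["omega", "median"]), 0.03)
  expect_lt(abs(s["p", "median"] - ex["p", "median"]), 0.03)
})

test_that("all-ones data pile omega and p against their upper prior bounds", {
  f <- fast_aggregate(200, 200, iter = 2000, seed = 7)
  s <- summary(f)
  expect_gt(s["omega", "median"], 0.45)
  expect_gt(s["p", "median"], 0.9)
})

test_that("a seeded regression fit recovers the generating coefficients in its 95% intervals", {
  truth <- c(0.5, 2, 3, -0.5, -2, -3)
  d <- zib_sim_regression(1500, theta = truth[4:6], beta = truth[1:3],
                          seed = 11)
  f <- fast_fit(y ~ x1 + x2 | x3 + x4, data = d, iter = 1500, seed = 2)
  s <- summary(f)
  ord <- c("beta_(Intercept)", "beta_x3", "beta_x4",
           "theta_(Intercept)", "theta_x1", "theta_x2")
  covered <- s[ord, "lower"] <= truth & truth <= s[ord, "upper"]
  expect_true(all(covered))
  # derived probability draws stay inside (0, 1) via the logit links
  expect_true(all(f$draws[, , "sigma_theta"] > 0))
})

test_that("a part without covariates keeps its uniform prior on the probability scale", {
  d <- zib_sim_regression(300, theta = c(-0.5, -2, -3), beta = c(0.5, 2, 3),
                          seed = 3)
  f <- fast_fit(y ~ x1 + x2 | 1, data = d, iter = 800, seed = 8)
  expect_true("p" %in% dimnames(f$draws)[[3]])
  expect_true(all(f$draws[, , "p"] >= 0.5 & f$draws[, , "p"] <= 1))
  expect_true(all(c("theta_(Intercept)", "theta_x1", "theta_x2") %in%
                    dimnames(f$draws)[[3]]))
})

test_that("overlapping prior supports in the covariate-free model trigger the identifiability warning", {
  expect_warning(
    zib_aggregate(10, 40, priors = zib_priors(omega = c(0, 0.7),
                                              p = c(0.3, 1)),
                  chains = 1, iter = 300, target_accept = 0.9, seed = 1),
    "weakly identified")
})

test_that("summarize_draws reports pooled percentiles and flags degeneracy", {
  # degenerate constant chains: all quantiles collapse, R-hat undefined
  const <- array(3.5, dim = c(100, 2, 1), dimnames = list(NULL, NULL, "c"))
  s <- summarize_draws(const)
  expect_equal(unlist(s[1, c("median", "lower", "upper")], use.names = FALSE),
               rep(3.5, 3))
  expect_true(is.nan(s$rhat))

  set.seed(1)
  norm <- array(rnorm(10000), dim = c(2500, 4, 1),
                dimnames = list(NULL, NULL, "z"))
  s <- summarize_draws(norm)
  expect_equal(s$median, 0, tolerance = 0.05)
  expect_equal(s$lower, -1.96, tolerance = 0.1)
  expect_equal(s$upper, 1.96, tolerance = 0.1)
  expect_lt(s$rhat, 1.01)

  expect_error(summarize_draws(array(1, c(10, 2, 1))), "at least 100")
})

test_that("check_convergence separates mixed from unmixed chains", {
  f <- fast_aggregate(430, 1564, iter = 4000, chains = 3, seed = 5)
  cc <- check_convergence(f, rhat_threshold = 1.02, ess_threshold = 200)
  expect_true(attr(cc, "ok"))

  # chains stuck at two different constants: maximal between-chain variance
  stuck <- array(rep(c(0, 1), each = 200), dim = c(200, 2, 1),
                 dimnames = list(NULL, NULL, "a"))
  cc <- check_convergence(stuck)
  expect_false(attr(cc, "ok"))
  expect_true(is.infinite(cc$rhat) | cc$rhat > 10)

  # a short single chain degrades to the ESS criterion with a warning
  set.seed(2)
  short <- array(rnorm(120), dim = c(120, 1, 1),
                 dimnames = list(NULL, NULL, "a"))
  expect_warning(cc <- check_convergence(short), "single chain")
  expect_false(attr(cc, "ok"))   # ESS < 400
})

test_that("posterior predictions and simulations respect the model structure", {
  d <- zib_sim_regression(300, theta = c(-0.5, -2, -3), beta = c(0.5, 2, 3),
                          seed = 5)
  f <- fast_fit(y ~ x1 + x2 | x3 + x4, data = d, iter = 600, seed = 3)
  pr <- predict(f)
  pw <- predict(f, type = "omega"); pp <- predict(f, type = "p")
  expect_equal(length(pr), 300)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(pr, pw * pp, tolerance = 0.15)  # averaging vs product of averages
  expect_equal(fitted(f) + residuals(f), d$y)

  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(300, 3))
  expect_true(all(unlist(sims) %in% 0:1))

  nd <- data.frame(x1 = 0, x2 = 0, x3 = 0, x4 = 0)
  p0 <- predict(f, newdata = nd)
  expect_length(p0, 1)
})
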