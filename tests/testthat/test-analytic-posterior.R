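test_that("joint log-posterior is the likelihood inside the prior box, -Inf outside", {
  expect_identical(zib_joint_log_posterior(0.6, 0.7, 430, 1564), -Inf)
  expect_identical(zib_joint_log_posterior(0.3, 0.4, 430, 1564), -Inf)
  expect_equal(zib_joint_log_posterior(0.3, 0.8, 430, 1564),
               zib_loglik_aggregate(0.3, 0.8, 430, 1564))
  # empty data: flat over the box
  expect_identical(zib_joint_log_posterior(0.3, 0.8, 0, 0), 0)
  expect_error(zib_joint_log_posterior(0.3, 0.8, 5, 3), "m <= n")
  expect_error(zib_priors(omega = c(0.5, 0.2)), "lo < hi")
})

test_that("joint normalizing constant matches the midpoint-grid oracle", {
  g <- grid_joint(430, 1564)
  lnc_grid <- max(g$lg) + log(sum(exp(g$lg - max(g$lg))) * g$hw * g$hp)
  ex <- zib_exact(430, 1564)
  expect_equal(lnc_grid, ex$log_norm_const, tolerance = 1e-3)
})

test_that("omega marginal matches its symbolic form for m = 0, n = 1", {
  # unnormalized density 1 - 3*omega/4 on [0, 1/2]; normalized value at 0
  # is 32/13
  w <- c(0, 0.1, 0.3, 0.5)
  expect_equal(zib_marginal_omega(w, 0, 1, normalize = FALSE),
               1 - 3 * w / 4, tolerance = 1e-12)
  expect_equal(zib_marginal_omega(0, 0, 1), 32 / 13, tolerance = 1e-9)
})

test_that("marginals are proper densities over a counts grid", {
  cases <- expand.grid(m = 0:5, n = 1:10)
  cases <- rbind(cases[cases$m <= cases$n, ], data.frame(m = 430, n = 1564))
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]; n <- cases$n[i]
    iw <- integrate(function(w) zib_marginal_omega(w, m, n), 0, 0.5,
                    rel.tol = 1e-9)$value
    ip <- integrate(function(p) zib_marginal_p(p, m, n), 0.5, 1,
                    rel.tol = 1e-9)$value
    expect_equal(iw, 1, tolerance = 1e-6)
    expect_equal(ip, 1, tolerance = 1e-6)
  }
})

test_that("closed-form marginals agree with the 2-d grid oracle", {
  for (cnt in list(c(430, 1564), c(3, 7))) {
    g <- grid_joint(cnt[1], cnt[2])
    G <- exp(g$lg - max(g$lg))
    mw <- rowSums(G) * g$hp; mw <- mw / (sum(mw) * g$hw)
    mp <- colSums(G) * g$hw; mp <- mp / (sum(mp) * g$hp)
    expect_lt(max(abs(mw - zib_marginal_omega(g$gw, cnt[1], cnt[2]))), 1e-3)
    expect_lt(max(abs(mp - zib_marginal_p(g$gp, cnt[1], cnt[2]))), 1e-3)
  }
})

test_that("marginals vanish outside the support and generalized priors reduce to the defaults", {
  expect_equal(zib_marginal_omega(c(-0.1, 0.7), 3, 10), c(0, 0))
  expect_equal(zib_marginal_p(c(0.3, 1.1), 3, 10), c(0, 0))
  pri <- zib_priors(omega = c(0, 0.5), p = c(0.5, 1))
  w <- seq(0, 0.5, by = 0.05); p <- seq(0.5, 1, by = 0.05)
  expect_equal(zib_marginal_omega(w, 7, 20, priors = pri),
               zib_marginal_omega(w, 7, 20))
  # a non-default box still integrates to 1
  pri2 <- zib_priors(omega = c(0.1, 0.8), p = c(0.2, 0.9))
  expect_equal(integrate(function(w)
    zib_marginal_omega(w, 7, 20, priors = pri2), 0.1, 0.8,
    rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
})

test_that("posterior quantiles are monotone and invert the CDF", {
  ex <- zib_exact(430, 1564)
  qs <- quantile(ex, c(0.1, 0.25, 0.5, 0.75, 0.9), param = "omega")
  expect_true(all(diff(qs) > 0))
  expect_true(all(qs > 0 & qs < 0.5))
  for (q in c(0.2, 0.5, 0.9)) {
    x <- ex$qf$omega(q)
    expect_equal(ex$cdf$omega(x), q, tolerance = 1e-6)
  }
  expect_error(quantile(ex, c(0, 0.5)), "\\(0, 1\\)")
})

test_that("exact posterior reproduces the real-data estimates at 2 decimals", {
  ex <- zib_exact(430, 1564)
  s <- summary(ex)
  expect_equal(round(s["omega", "median"], 2), 0.37)
  expect_equal(round(unlist(s["omega", c("lower", "upper")]), 2),
               c(lower = 0.27, upper = 0.49))
  expect_equal(round(s["p", "median"], 2), 0.74)
  expect_equal(round(unlist(s["p", c("lower", "upper")]), 2),
               c(lower = 0.55, upper = 0.99))
  # the identifiable product concentrates at the sample proportion
  expect_equal(s["omega_p", "median"], 430 / 1564, tolerance = 0.01)
})

test_that("with no data the posterior equals the prior", {
  ex <- zib_exact(0, 0)
  expect_equal(summary(ex)["omega", "median"], 0.25, tolerance = 1e-6)
  expect_equal(summary(ex)["p", "median"], 0.75, tolerance = 1e-6)
  # flat density 2 on [0.5, 1]
  expect_equal(zib_marginal_p(c(0.6, 0.9), 0, 0), c(2, 2), tolerance = 1e-9)
})

test_that("the posterior of the product concentrates as n grows at fixed m/n", {
  widths <- vapply(list(c(27, 100), c(430, 1564), c(2750, 10000)),
                   function(cnt) {
                     s <- summary(zib_exact(cnt[1], cnt[2]))
                     s["omega_p", "upper"] - s["omega_p", "lower"]
                   }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
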