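test_that("the empirical CCDF counts at-least-x fractions", {
  cc <- empirical_ccdf(c(1, 2, 3))
  expect_equal(cc$x, c(1, 2, 3))
  expect_equal(cc$prob, c(1, 2 / 3, 1 / 3))

  cc2 <- empirical_ccdf(c(5, 5, 5, 5))
  expect_equal(cc2$x, 5)
  expect_equal(cc2$prob, 1)

  cc3 <- empirical_ccdf(c(1, 1, 1, 9))
  expect_equal(cc3$prob[cc3$x == 9], 1 / 4)

  expect_error(empirical_ccdf(numeric(0)), class = "coprune_degenerate_error")
  expect_error(empirical_ccdf(c(0, 1)), class = "coprune_domain_error")
})

test_that("CCDFs start at 1 and never increase", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- rdegree(200, "log_normal", c(mu = 1, sigma = 0.8))
    cc <- empirical_ccdf(d)
    expect_equal(cc$prob[1], 1)
    expect_true(all(diff(cc$prob) < 0))
    expect_true(all(cc$prob > 0))
  }
})

test_that("family pmfs are proper distributions on {1, 2, ...}", {
  params <- list(exponential = c(lambda = 0.3),
                 power_law = c(gamma = 2.5),
                 truncated_power_law = c(gamma = 1.3, kappa = 0.05),
                 log_normal = c(mu = 1, sigma = 0.7))
  for (fam in names(params)) {
    p <- ddegree(1:50000, fam, params[[fam]])
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("maximum likelihood recovers generating parameters", {
  set.seed(101)
  d <- rdegree(2000, "exponential", c(lambda = 0.25))
  fit <- fit_degree_family(d, "exponential")
  expect_lt(abs(fit$params[["lambda"]] - 0.25) / 0.25, 0.05)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)

  set.seed(102)
  d2 <- rdegree(2000, "power_law", c(gamma = 2.5))
  fit2 <- fit_degree_family(d2, "power_law")
  expect_lt(abs(fit2$params[["gamma"]] - 2.5) / 2.5, 0.05)
})

test_that("the truncated power law never fits worse than the pure power law", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- rdegree(500, "power_law", c(gamma = 2.2))
    pl <- fit_degree_family(d, "power_law")
    tpl <- fit_degree_family(d, "truncated_power_law")
    expect_gte(tpl$loglik, pl$loglik - 1e-6)
  }
  # and never worse than the nested exponential (gamma = 0 boundary)
  set.seed(9)
  d <- rdegree(500, "exponential", c(lambda = 0.2))
  ex <- fit_degree_family(d, "exponential")
  tpl <- fit_degree_family(d, "truncated_power_law")
  expect_gte(tpl$loglik, ex$loglik - 1e-6)
})

test_that("AIC selection identifies clear generating families", {
  set.seed(11)
  d <- rdegree(2000, "exponential", c(lambda = 0.3))
  expect_identical(fit_degree_distribution(d)$best_family, "exponential")

  set.seed(103)
  d2 <- rdegree(2000, "power_law", c(gamma = 2.5))
  expect_true(fit_degree_distribution(d2)$best_family %in%
                c("power_law", "truncated_power_law"))
})

test_that("selection report is internally consistent", {
  set.seed(13)
  d <- rdegree(300, "truncated_power_law", c(gamma = 1.2, kappa = 0.08))
  rep <- fit_degree_distribution(d)
  expect_equal(min(rep$delta_aic), 0)
  expect_equal(rep$delta_aic[[rep$best_family]], 0)
  for (fam in names(rep$fits))
    expect_equal(rep$fits[[fam]]$aic - min(vapply(rep$fits, `[[`, numeric(1), "aic")),
                 rep$delta_aic[[fam]])
})

test_that("exact AIC ties break toward fewer parameters, then family order", {
  expect_identical(
    coprune:::pick_best_family(c(10, 10), c(1L, 2L),
                               c("truncated_power_law", "exponential")),
    "truncated_power_law")
  expect_identical(
    coprune:::pick_best_family(c(10, 10), c(1L, 1L),
                               c("power_law", "exponential")),
    "exponential")
  expect_identical(
    coprune:::pick_best_family(c(10, 10), c(2L, 2L),
                               c("truncated_power_law", "log_normal")),
    "log_normal")
})

test_that("degenerate samples raise typed fit errors", {
  expect_error(fit_degree_family(rep(3, 10), "truncated_power_law"),
               class = "coprune_fit_degenerate_error")
  expect_error(fit_degree_family(rep(3, 10), "log_normal"),
               class = "coprune_fit_degenerate_error")
  expect_error(fit_degree_family(rep(1, 10), "exponential"),
               class = "coprune_fit_degenerate_error")
  # one-parameter families still fit a constant sample above 1
  rep_ok <- fit_degree_distribution(rep(3, 10))
  expect_true(rep_ok$best_family %in% c("exponential", "power_law"))
  expect_true(all(c("truncated_power_law", "log_normal") %in%
                    names(rep_ok$failed)))
})

test_that("proportional rescaling cannot manufacture or destroy a power law", {
  # scale-free samples stay scale-free under degree rescaling
  set.seed(22)
  d2 <- rdegree(800, "power_law", c(gamma = 2.2))
  fam2 <- fit_degree_distribution(d2)$best_family
  scaled2 <- pmax(1, round(d2 * 3))
  fam2s <- fit_degree_distribution(scaled2)$best_family
  expect_true(fam2 %in% c("power_law", "truncated_power_law"))
  expect_true(fam2s %in% c("power_law", "truncated_power_law"))

  # thin-tailed samples never become fat-tailed: rounding a scaled geometric
  # puts the sample on a lattice the support-1 exponential pmf cannot track
  # exactly (the log-normal may absorb it), but no power law appears
  for (seed in 21:25) {
    set.seed(seed)
    d <- rdegree(800, "exponential", c(lambda = 0.15))
    scaled <- pmax(1, round(d * 3))
    expect_false(fit_degree_distribution(scaled)$best_family %in%
                   c("power_law", "truncated_power_law"))
  }
})

test_that("fitted CCDFs agree with the pmf tabulation", {
  fit <- structure(list(family = "exponential", params = c(lambda = 0.4),
                        loglik = 0, n_params = 1L, aic = 0, n = 1L),
                   class = "degree_fit")
  cc <- fitted_ccdf(fit, c(1, 3, 6))
  expect_equal(cc[1], 1)
  expect_equal(cc[2], 1 - sum(ddegree(1:2, "exponential", c(lambda = 0.4))))
  expect_true(all(diff(cc) < 0))
})
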