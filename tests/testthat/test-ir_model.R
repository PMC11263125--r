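test_that("pair-level interaction probability follows 1 - (1-p)^n", {
  expect_equal(interaction_probability(0.1, 1), 0.1)
  expect_equal(interaction_probability(0.5, 2), 0.75)
  expect_equal(interaction_probability(0.37, 0), 0)
  expect_equal(interaction_probability(1, 3), 1)
  expect_equal(interaction_probability(0.3, c(0, 1, 2)),
               c(0, 0.3, 1 - 0.49))
  expect_error(interaction_probability(1.2, 1), class = "coprune_domain_error")
  expect_error(interaction_probability(-0.1, 1), class = "coprune_domain_error")
  # stable for tiny rates and large exposure
  expect_equal(interaction_probability(1e-12, 1000L), 1e-9, tolerance = 1e-6)
})

test_that("conditional expected links match the printed formula on toys", {
  # one consumer with N = (2, 1), p = 0.5: (0.75 + 0.5) / (1 - 0.5^3)
  N <- matrix(c(2L, 1L), nrow = 1)
  expect_equal(expected_links(N, 0.5), 1.25 / 0.875)
  # a single possible partner is forced by the conditioning
  for (p in c(0.01, 0.3, 0.9, 1)) {
    expect_equal(expected_links(matrix(3L, 1, 1), p), 1)
  }
  expect_error(expected_links(rbind(c(1L, 1L), c(0L, 0L)), 0.5),
               class = "coprune_degenerate_error")
})

test_that("expected links agree with exhaustive enumeration on a toy", {
  N <- rbind(c(1L, 1L), c(0L, 1L))
  expect_equal(expected_links(N, 0.3), enumerate_expected_links(N, 0.3),
               tolerance = 1e-12)
})

test_that("expected links increase strictly with p between the floor and L_c", {
  for (seed in 1:5) {
    N <- random_freq_matrix(4, 5, seed = seed)
    ps <- seq(0.02, 1, by = 0.07)
    el <- vapply(ps, function(p) expected_links(N, p), numeric(1))
    expect_true(all(diff(el) > 0))
    expect_equal(expected_links(N, 1), sum(N >= 1))
    expect_equal(expected_links(N, 1e-9), nrow(N), tolerance = 1e-6)
  }
})

test_that("calibration solves the closed-form toy and the boundary exactly", {
  # one consumer, two singleton co-occurrences: E(L) = 2/(2-p) = 4/3 at p = 1/2
  N <- matrix(c(1L, 1L), nrow = 1)
  cal <- calibrate_p(N, f = 2 / 3)
  expect_true(cal$converged)
  expect_equal(cal$p, 0.5, tolerance = 1e-8)
  expect_equal(calibrate_p(N, f = 1)$p, 1)
})

test_that("infeasible calibration targets are rejected with the conditioning floor", {
  N <- rbind(c(3L, 2L), c(1L, 4L))
  # f * L_c = 0.25 * 4 = 1 < 2 consumers
  expect_error(calibrate_p(N, f = 0.25), class = "coprune_infeasible_error")
  expect_error(calibrate_p(N, f = 1.2), class = "coprune_domain_error")
})

test_that("IR realizations respect certainty, impossibility and conditioning", {
  N <- random_freq_matrix(6, 8, seed = 2)
  full <- realize_ir(N, p = 1, seed = 5)
  expect_identical(full$adjacency, N >= 1L)

  for (seed in 1:20) {
    r <- realize_ir(N, p = 0.05, seed = seed)
    expect_true(all(rowSums(r$adjacency) >= 1))
    expect_true(all(!r$adjacency[N == 0L]))
    expect_s3_class(r, "bipartite_network")
    expect_identical(r$kind, "ir_realization")
  }
  expect_error(realize_ir(N, p = 0), class = "coprune_domain_error")
})

test_that("Monte Carlo realization means match the conditional expectation", {
  N <- rbind(c(1L, 1L), c(0L, 1L))
  p <- 0.3
  set.seed(99)
  L <- replicate(2000, realize_ir(N, p)$L)
  expect_equal(mean(L), expected_links(N, p),
               tolerance = 3 * sd(L) / sqrt(length(L)) / expected_links(N, p))
})

test_that("random pruning keeps each link with probability f, unconditioned", {
  set.seed(7)
  adj <- matrix(runif(40 * 25) < 1, nrow = 40,
                dimnames = list(paste0("c", 1:40), paste0("r", 1:25)))
  cooc <- bipartite_network(adj, "cooccurrence")
  expect_identical(random_prune(cooc, 1, seed = 1)$adjacency, cooc$adjacency)

  kept <- replicate(200, random_prune(cooc, 0.2)$L)
  expect_equal(mean(kept), 0.2 * cooc$L,
               tolerance = 3 * sd(kept) / sqrt(200) / (0.2 * cooc$L))
  # with every frequency at 1 the IR keep probability collapses to f
  expect_equal(interaction_probability(0.2, 1), 0.2)
})

test_that("ensembles are reproducible and realization-wise conditioned", {
  N <- random_freq_matrix(5, 6, seed = 4)
  e1 <- prune_ensemble(N, 0.2, mode = "ir", n_realizations = 15, seed = 11)
  e2 <- prune_ensemble(N, 0.2, mode = "ir", n_realizations = 15, seed = 11)
  expect_identical(lapply(e1$realizations, `[[`, "adjacency"),
                   lapply(e2$realizations, `[[`, "adjacency"))
  expect_false(anyDuplicated(e1$seeds) > 0)
  for (r in e1$realizations) expect_true(all(rowSums(r$adjacency) >= 1))

  er <- prune_ensemble(N, 0.5, mode = "random", n_realizations = 300, seed = 3)
  L_c <- sum(N >= 1)
  fs <- vapply(er$realizations, `[[`, numeric(1), "L") / L_c
  expect_equal(mean(fs), 0.5, tolerance = 3 * sd(fs) / sqrt(300) / 0.5)
})

test_that("the fitted model object exposes the standard accessors coherently", {
  sm <- small_metacommunity(seed = 2)
  fit <- ir_fit(sm)
  expect_s3_class(fit, "ir_fit")
  expect_named(coef(fit), c("p", "f"))
  expect_equal(unname(coef(fit)["f"]), fit$L_int / fit$L_c)

  P <- fitted(fit)
  expect_equal(dim(P), dim(fit$freq$N))
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(P[fit$freq$N == 0L] == 0))

  ed <- predict(fit, "expected_degree")
  expect_equal(sum(ed), predict(fit, "expected_links"))
  expect_equal(sum(ed), fit$f * fit$L_c, tolerance = 1e-6)
  expect_true(all(ed >= 1 - 1e-9))

  res <- residuals(fit)
  expect_equal(unname(res),
               unname(rowSums(fit$inter$adjacency) - ed))

  ens <- simulate(fit, nsim = 5, seed = 2, mode = "ir")
  expect_length(ens$realizations, 5)
  expect_output(print(summary(fit)), "calibration")
})
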