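# The interaction-rate (IR) pruning model. A consumer-resource pair that
# co-occurs in N sites interacts with probability 1 - (1 - p)^N, where p is
# a single per-site interaction rate. Conditioning on every consumer keeping
# at least one resource gives the expected link count
#   E(L(p)) = sum_a sum_i [1 - (1-p)^N_ai] / [1 - (1-p)^N_a],  N_a = sum_i N_ai,
# and p is calibrated so E(L(p)) = f * L_c.

check_rate <- function(p, allow_zero = FALSE) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) ||
      p < 0 || p > 1 || (!allow_zero && p == 0))
    stop_coprune(sprintf("interaction rate p must lie in %s; got %s",
                         if (allow_zero) "[0, 1]" else "(0, 1]",
                         format(p)),
                 "coprune_domain_error")
  invisible(p)
}

#' Pair-level interaction probability under the IR model
#'
#' A pair co-occurring in `n` sites interacts somewhere with probability
#' `1 - (1 - p)^n`: one independent Bernoulli trial at rate `p` per shared
#' site. Vectorized over `n`, so it maps a whole co-occurrence frequency
#' matrix to a probability matrix.
#'
#' @param p per-site interaction rate in \[0, 1\].
#' @param n non-negative integer co-occurrence count(s).
#' @return Probability (same shape as `n`). Pairs with `n = 0` never
#'   interact.
#' @export
interaction_probability <- function(p, n) {
  check_rate(p, allow_zero = TRUE)
  if (any(n < 0) || any(n != round(n)))
    stop_coprune("co-occurrence counts must be non-negative integers",
                 "coprune_domain_error")
  # (1-p)^n via exp(n * log1p(-p)) to stay accurate for small p, large n
  out <- -expm1(n * log1p(-p))
  out[n == 0] <- 0       # covers p = 1 (log1p(-1) = -Inf) and n = 0
  out
}

#' Conditional expected link count of the IR model
#'
#' The expected number of links over random realizations of the model,
#' conditioned on every consumer retaining at least one resource (no
#' consumer can survive without one):
#' `E(L(p)) = sum_a sum_i (1-(1-p)^N_ai) / (1-(1-p)^N_a)`.
#' Strictly increasing in `p`, from the number of consumers as `p -> 0+`
#' (each consumer pinned to a single expected link) to `L_c` at `p = 1`.
#'
#' @param N a `cooc_freq` object or integer consumers x resources matrix;
#'   every consumer must co-occur with at least one resource.
#' @param p per-site interaction rate in (0, 1\].
#' @return Expected link count (scalar).
#' @export
expected_links <- function(N, p) {
  M <- as_freq_matrix(N)
  check_rate(p)
  N_alpha <- rowSums(M)
  if (any(N_alpha == 0))
    stop_coprune("consumer(s) with no co-occurring resource: conditional expectation undefined",
                 "coprune_degenerate_error")
  P <- interaction_probability(p, M)
  denom <- interaction_probability(p, N_alpha)
  sum(rowSums(P) / denom)
}

#' Calibrate the per-site interaction rate p
#'
#' Solves `E(L(p)) = f * L_c` for `p` by bisection on (0, 1\]. The target
#' must be feasible: as `p -> 0+` the conditional expectation tends to the
#' number of consumers (each consumer keeps exactly one expected link), so
#' `f * L_c` below that floor cannot be reached; above `L_c` it cannot
#' either. Monotonicity of `E(L(p))` makes the root unique.
#'
#' @param N a `cooc_freq` object or integer matrix.
#' @param f target realized-link fraction, or the list returned by
#'   [link_fraction()].
#' @param tolerance relative tolerance on `E(L(p))` (default `1e-10`).
#' @return List of class `ir_calibration`: `p`, `f_target`,
#'   `expected_L_at_p`, `L_c`, `converged`, `tolerance`.
#' @export
calibrate_p <- function(N, f, tolerance = 1e-10) {
  M <- as_freq_matrix(N)
  if (is.list(f)) f <- f$f
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop_coprune("f must be a single value in (0, 1]", "coprune_domain_error")
  L_c <- sum(M >= 1L)
  n_cons <- nrow(M)
  target <- f * L_c
  if (target > L_c + 1e-9)
    stop_coprune("target exceeds the number of co-occurrence links",
                 "coprune_infeasible_error")
  if (target < n_cons * (1 - 1e-12))
    stop_coprune(sprintf(
      "infeasible target: f * L_c = %.4g is below the conditioning floor of %d (as p -> 0 every consumer still keeps one expected link, so E(L) cannot drop below the number of consumers)",
      target, n_cons), "coprune_infeasible_error")

  g <- function(p) expected_links(M, p) - target
  hi <- 1
  if (g(hi) <= tolerance * L_c && g(hi) >= -tolerance * L_c) {
    p <- 1
  } else {
    lo <- 1e-12
    if (g(lo) > 0) {
      # target sits at (or numerically below) the conditioning floor
      p <- lo
    } else {
      p <- NA_real_
      for (iter in seq_len(200)) {
        mid <- (lo + hi) / 2
        gm <- g(mid)
        p <- mid
        if (abs(gm) <= tolerance * max(target, 1)) break
        if (gm > 0) hi <- mid else lo <- mid
      }
    }
  }
  eL <- expected_links(M, p)
  structure(list(p = p, f_target = f, expected_L_at_p = eL, L_c = L_c,
                 converged = abs(eL - target) <= max(tolerance, 1e-8) * max(target, 1),
                 tolerance = tolerance),
            class = "ir_calibration")
}

#' @export
print.ir_calibration <- function(x, ...) {
  cat(sprintf("<ir_calibration> p = %.6g (target f = %.4g, L_c = %d, E(L) = %.4f, %s)\n",
              x$p, x$f_target, x$L_c, x$expected_L_at_p,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' One random realization of the IR pruning model
#'
#' Each consumer draws a link to each resource independently with
#' probability `1 - (1-p)^N_ai`; a consumer whose row comes up empty is
#' redrawn until it keeps at least one resource (rejection sampling of the
#' conditional distribution whose expectation [expected_links()] computes).
#'
#' @param N a `cooc_freq` object or integer matrix; every consumer must
#'   co-occur with at least one resource.
#' @param p per-site interaction rate in (0, 1\].
#' @param seed optional integer; if supplied, the draw is reproducible.
#' @return A `bipartite_network` of kind `"ir_realization"`; every consumer
#'   has degree >= 1 and links only where `N >= 1`.
#' @export
realize_ir <- function(N, p, seed = NULL) {
  M <- as_freq_matrix(N)
  check_rate(p)
  if (any(rowSums(M) == 0))
    stop_coprune("consumer(s) with no co-occurring resource cannot satisfy the degree >= 1 condition",
                 "coprune_degenerate_error")
  if (!is.null(seed)) set.seed(seed)
  P <- interaction_probability(p, M)
  A <- matrix(runif(length(P)) < P, nrow = nrow(P))
  empty <- which(rowSums(A) == 0L)
  while (length(empty) > 0L) {
    for (a in empty) A[a, ] <- runif(ncol(P)) < P[a, ]
    empty <- empty[rowSums(A[empty, , drop = FALSE]) == 0L]
  }
  if (is.null(rownames(M)))
    dimnames(M) <- list(paste0("c", seq_len(nrow(M))),
                        paste0("r", seq_len(ncol(M))))
  dimnames(A) <- dimnames(M)
  bipartite_network(A, kind = "ir_realization")
}

#' Random (frequency-blind) pruning of a co-occurrence network
#'
#' The null model: every co-occurrence link is kept independently with the
#' same probability `f`, regardless of how often the pair co-occurs, and no
#' consumer-level conditioning is applied. Equivalent to the IR model with
#' all co-occurrence frequencies set to 1 and `p = f`.
#'
#' @param cooc a `bipartite_network` (kind `"cooccurrence"` typically).
#' @param f keep probability in (0, 1\], or the list from [link_fraction()].
#' @param seed optional integer for reproducibility.
#' @return A `bipartite_network` of kind `"random_pruned"`.
#' @export
random_prune <- function(cooc, f, seed = NULL) {
  stopifnot(inherits(cooc, "bipartite_network"))
  if (is.list(f)) f <- f$f
  check_rate(f)
  if (!is.null(seed)) set.seed(seed)
  A <- cooc$adjacency & (matrix(runif(length(cooc$adjacency)),
                                nrow = nrow(cooc$adjacency)) < f)
  dimnames(A) <- dimnames(cooc$adjacency)
  bipartite_network(A, kind = "random_pruned")
}

# deterministic per-realization seeds derived from a master seed; keeps
# ensembles reproducible and order-independent
spawn_seed <- function(master, i) {
  as.integer((as.double(master %% 65536L) * 32749 + i * 2654435) %% 2147483647)
}

#' Ensemble of pruned-network realizations
#'
#' Runs [realize_ir()] or [random_prune()] repeatedly with per-realization
#' seeds derived deterministically from the master seed, so the ensemble is
#' reproducible and each realization independent of the others' order.
#'
#' @param N a `cooc_freq` object or integer matrix.
#' @param p_or_f calibrated rate `p` (mode `"ir"`) or keep fraction `f`
#'   (mode `"random"`).
#' @param mode `"ir"` or `"random"`.
#' @param n_realizations ensemble size (default 100).
#' @param seed master seed.
#' @return An object of class `prune_ensemble`: `realizations` (list of
#'   `bipartite_network`), `seeds`, `mode`, `rate`,
#'   `consumer_mean_degree`, `resource_mean_degree`.
#' @export
prune_ensemble <- function(N, p_or_f, mode = c("ir", "random"),
                           n_realizations = 100L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_realizations >= 1L)
  M <- as_freq_matrix(N)
  cooc <- cooccurrence_network(M)
  seeds <- vapply(seq_len(n_realizations), function(i) spawn_seed(seed, i),
                  integer(1))
  realizations <- lapply(seeds, function(s) {
    if (mode == "ir") realize_ir(M, p_or_f, seed = s)
    else random_prune(cooc, p_or_f, seed = s)
  })
  cons_deg <- vapply(realizations, function(r) rowSums(r$adjacency),
                     numeric(nrow(M)))
  res_deg <- vapply(realizations, function(r) colSums(r$adjacency),
                    numeric(ncol(M)))
  structure(list(realizations = realizations, seeds = seeds, mode = mode,
                 rate = p_or_f,
                 consumer_mean_degree = rowMeans(matrix(cons_deg, nrow = nrow(M))),
                 resource_mean_degree = rowMeans(matrix(res_deg, nrow = ncol(M)))),
            class = "prune_ensemble")
}

#' @export
print.prune_ensemble <- function(x, ...) {
  L <- vapply(x$realizations, `[[`, numeric(1), "L")
  cat(sprintf("<prune_ensemble> mode=%s, rate=%.4g: %d realizations, links %.1f +/- %.1f\n",
              x$mode, x$rate, length(x$realizations), mean(L), sd(L)))
  invisible(x)
}
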