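# The user-facing model fit: from a validated dataset to a calibrated IR
# model, with the usual accessor methods.

#' Fit the interaction-rate pruning model to a dataset
#'
#' Builds the co-occurrence frequency matrix, the binary co-occurrence and
#' interaction networks, measures the realized link fraction
#' `f = L_int / L_c`, and calibrates the single per-site interaction rate
#' `p` so that the model's conditional expected link count equals the
#' observed interaction link count ([calibrate_p()]).
#'
#' The fitted object supports `coef()` (p and f), `fitted()` (the pair-level
#' interaction probability matrix), `predict()` (per-consumer expected
#' degrees, conditional on degree >= 1), `residuals()` (observed minus
#' expected consumer degree), `simulate()` (ensembles of pruned networks,
#' IR or random null) and `plot()` (degree CCDFs).
#'
#' @param ds a `cooc_dataset` from [load_dataset()], [cooc_dataset()] or
#'   [simulate_metacommunity()].
#' @param tolerance relative calibration tolerance, see [calibrate_p()].
#' @return An object of class `ir_fit`.
#' @export
ir_fit <- function(ds, tolerance = 1e-10) {
  if (inherits(ds, "synthetic_metacommunity")) ds <- ds$dataset
  stopifnot(inherits(ds, "cooc_dataset"))
  freq <- cooccurrence_frequencies(ds$consumers, ds$resources)
  cooc <- cooccurrence_network(freq)
  inter <- interaction_network(ds)
  lf <- link_fraction(cooc, inter)
  cal <- calibrate_p(freq, lf, tolerance = tolerance)
  structure(list(dataset = ds$name, interaction_type = ds$interaction_type,
                 freq = freq, cooc = cooc, inter = inter,
                 L_c = lf$L_c, L_int = lf$L_int, f = lf$f,
                 p = cal$p, calibration = cal,
                 call = match.call()),
            class = "ir_fit")
}

#' @export
print.ir_fit <- function(x, ...) {
  cat(sprintf("Interaction-rate pruning model fit: '%s' (%s)\n",
              x$dataset, x$interaction_type))
  cat(sprintf("  %d consumers x %d resources over %d sites\n",
              length(x$freq$consumers), length(x$freq$resources),
              x$freq$n_sites))
  cat(sprintf("  co-occurrence links L_c = %d, interaction links L_int = %d\n",
              x$L_c, x$L_int))
  cat(sprintf("  realized link fraction f = %.4f\n", x$f))
  cat(sprintf("  calibrated per-site interaction rate p = %.5f\n", x$p))
  invisible(x)
}

#' @export
coef.ir_fit <- function(object, ...) c(p = object$p, f = object$f)

#' @export
fitted.ir_fit <- function(object, ...) {
  interaction_probability(object$p, object$freq$N)
}

#' Predicted quantities from a fitted IR model
#'
#' @param object an `ir_fit`.
#' @param type `"expected_degree"`: per-consumer conditional expected
#'   interaction degree `sum_i P_ai / (1 - (1-p)^N_a)`;
#'   `"link_probability"`: the pair-level probability matrix;
#'   `"expected_links"`: the scalar conditional expected link count.
#' @param ... unused.
#' @export
predict.ir_fit <- function(object,
                           type = c("expected_degree", "link_probability",
                                    "expected_links"), ...) {
  type <- match.arg(type)
  P <- interaction_probability(object$p, object$freq$N)
  switch(type,
    link_probability = P,
    expected_degree = {
      denom <- interaction_probability(object$p, object$freq$N_alpha)
      setNames(rowSums(P) / denom, object$freq$consumers)
    },
    expected_links = expected_links(object$freq, object$p))
}

#' @export
residuals.ir_fit <- function(object, ...) {
  obs <- rowSums(object$inter$adjacency)
  obs - predict(object, "expected_degree")
}

#' Simulate ensembles of pruned networks from a fitted IR model
#'
#' @param object an `ir_fit`.
#' @param nsim ensemble size.
#' @param seed master seed (per-realization seeds are derived from it).
#' @param mode `"ir"` for the frequency-based model at the calibrated `p`,
#'   `"random"` for the frequency-blind null at keep probability `f`.
#' @param ... unused.
#' @return A `prune_ensemble`.
#' @export
simulate.ir_fit <- function(object, nsim = 100L, seed = 1L,
                            mode = c("ir", "random"), ...) {
  mode <- match.arg(mode)
  rate <- if (mode == "ir") object$p else object$f
  prune_ensemble(object$freq, rate, mode = mode,
                 n_realizations = nsim, seed = seed)
}

#' @export
summary.ir_fit <- function(object, ...) {
  deg_c <- degree_sequences(object$cooc)
  deg_i <- degree_sequences(object$inter)
  out <- list(fit = object,
              consumer_cooc = summary(deg_c$consumer_degrees),
              consumer_inter = summary(deg_i$consumer_degrees),
              expected_L = object$calibration$expected_L_at_p,
              converged = object$calibration$converged)
  class(out) <- "summary.ir_fit"
  out
}

#' @export
print.summary.ir_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  calibration: E(L(p)) = %.4f (target %.4f), %s\n",
              x$expected_L, x$fit$f * x$fit$L_c,
              if (x$converged) "converged" else "NOT converged"))
  cat("  consumer co-occurrence degrees:\n")
  print(x$consumer_cooc)
  cat("  consumer interaction degrees:\n")
  print(x$consumer_inter)
  invisible(x)
}

#' Plot degree CCDFs of a fitted IR model
#'
#' Log-log complementary cumulative degree distributions of the
#' co-occurrence network, the empirical interaction network, and (if
#' supplied) an ensemble of model realizations.
#'
#' @param x an `ir_fit`.
#' @param ensemble optional `prune_ensemble` to overlay.
#' @param guild `"consumer"` or `"resource"` degrees.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ir_fit <- function(x, ensemble = NULL,
                        guild = c("consumer", "resource"), ...) {
  guild <- match.arg(guild)
  pick <- function(net) {
    d <- degree_sequences(net)
    d <- if (guild == "consumer") d$consumer_degrees else d$resource_degrees
    d[d >= 1]
  }
  cc_cooc <- empirical_ccdf(pick(x$cooc))
  cc_int <- empirical_ccdf(pick(x$inter))
  plot(cc_cooc$x, cc_cooc$prob, log = "xy", type = "s", col = "red",
       xlab = "degree x", ylab = "P(K >= x)",
       ylim = c(min(cc_cooc$prob, cc_int$prob), 1), ...)
  if (!is.null(ensemble)) {
    for (r in ensemble$realizations) {
      d <- pick(r)
      if (length(d)) {
        cc <- empirical_ccdf(d)
        lines(cc$x, cc$prob, type = "s",
              col = grDevices::adjustcolor("forestgreen", alpha.f = 0.15))
      }
    }
  }
  lines(cc_int$x, cc_int$prob, type = "s", col = "goldenrod", lwd = 2)
  legend("bottomleft", bty = "n", lty = 1, lwd = c(1, 2, 1),
         col = c("red", "goldenrod", "forestgreen"),
         legend = c("co-occurrence", "interaction", "model realizations"))
  invisible(x)
}
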