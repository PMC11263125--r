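# Discrete degree-distribution families on support {1, 2, ...} (x_min = 1),
# fitted by maximum likelihood, compared by AIC. Families:
#   exponential           P(k) = (1 - e^-lambda) e^(-lambda (k-1))
#   power_law             P(k) = k^-gamma / zeta(gamma),            gamma > 1
#   truncated_power_law   P(k) = k^-gamma e^(-kappa k) / Z,         kappa > 0
#   log_normal            P(k) = (F(k+1/2) - F(k-1/2)) / (1 - F(1/2)),
#                         F the lognormal CDF
# Isolated species (degree 0) are excluded upstream; support starts at 1.

FAMILIES <- c("exponential", "power_law", "truncated_power_law", "log_normal")
# tie-break order when AIC and parameter counts tie
FAMILY_RANK <- c(exponential = 1, power_law = 2, log_normal = 3,
                 truncated_power_law = 4)
N_PARAMS <- c(exponential = 1L, power_law = 1L, truncated_power_law = 2L,
              log_normal = 2L)

check_degrees <- function(degrees) {
  if (length(degrees) == 0L)
    stop_coprune("empty degree sample", "coprune_degenerate_error")
  if (any(degrees < 1) || any(degrees != round(degrees)))
    stop_coprune("degrees must be integers >= 1 (drop isolated species first)",
                 "coprune_domain_error")
  as.numeric(degrees)
}

#' Empirical complementary cumulative degree distribution
#'
#' `prob[j]` is the fraction of species with degree at least `x[j]`; by
#' construction the curve starts at 1 for the smallest observed degree and
#' is non-increasing.
#'
#' @param degrees integer degrees, all >= 1.
#' @return Data frame with columns `x` (sorted unique degrees) and `prob`.
#' @export
empirical_ccdf <- function(degrees) {
  degrees <- check_degrees(degrees)
  x <- sort(unique(degrees))
  n <- length(degrees)
  prob <- vapply(x, function(v) sum(degrees >= v) / n, numeric(1))
  data.frame(x = x, prob = prob)
}

# -- normalizing constant of the truncated power law ------------------------
# Z(gamma, kappa) = sum_{k>=1} k^-gamma e^(-kappa k), computed as a partial
# sum plus an integral tail correction; accurate to ~1e-10 for the parameter
# ranges the optimizer visits.
.tpl_K <- 10000L
.tpl_logk <- log(seq_len(.tpl_K))
.tpl_k <- as.numeric(seq_len(.tpl_K))

tpl_logZ <- function(gamma, kappa) {
  if (kappa < 0) return(NA_real_)
  if (kappa < 1e-12 && gamma <= 1) return(Inf)
  s <- sum(exp(-gamma * .tpl_logk - kappa * .tpl_k))
  # tail beyond K matters only when the exponential cutoff is still mild
  tail <- 0
  if (kappa * .tpl_K < 30) {
    tail <- tryCatch(
      integrate(function(x) exp(-gamma * log(x) - kappa * x),
                lower = .tpl_K + 0.5, upper = Inf,
                rel.tol = 1e-10, abs.tol = 1e-300)$value,
      error = function(e) 0)
  }
  log(s + tail)
}

log_pmf <- function(x, family, params) {
  switch(family,
    exponential = {
      lambda <- params[["lambda"]]
      log1p(-exp(-lambda)) - lambda * (x - 1)
    },
    power_law = {
      gamma <- params[["gamma"]]
      -gamma * log(x) - log(pracma::zeta(gamma))
    },
    truncated_power_law = {
      gamma <- params[["gamma"]]; kappa <- params[["kappa"]]
      -gamma * log(x) - kappa * x - tpl_logZ(gamma, kappa)
    },
    log_normal = {
      mu <- params[["mu"]]; sigma <- params[["sigma"]]
      p <- plnorm(x + 0.5, mu, sigma) - plnorm(x - 0.5, mu, sigma)
      log(p) - log1p(-plnorm(0.5, mu, sigma))
    },
    stop_coprune(paste("unknown family:", family), "coprune_domain_error"))
}

#' Probability mass of a degree-distribution family
#'
#' @param x integer degrees >= 1.
#' @param family one of `"exponential"`, `"power_law"`,
#'   `"truncated_power_law"`, `"log_normal"`.
#' @param params named vector: `lambda`; `gamma`; `gamma`,`kappa`; or
#'   `mu`,`sigma`.
#' @return P(K = x) on the discrete support starting at 1.
#' @export
ddegree <- function(x, family = FAMILIES, params) {
  family <- match.arg(family)
  exp(log_pmf(x, family, params))
}

#' Sample degrees from a degree-distribution family
#'
#' Used by the simulation-based recovery tests and the synthetic generator
#' diagnostics. The power-law sampler is Devroye's rejection method for the
#' zeta distribution; the bounded-tail families sample from the tabulated
#' mass function.
#'
#' @inheritParams ddegree
#' @param n sample size.
#' @return Integer vector of degrees >= 1.
#' @export
rdegree <- function(n, family = FAMILIES, params) {
  family <- match.arg(family)
  switch(family,
    exponential = {
      lambda <- params[["lambda"]]
      1L + rgeom(n, prob = -expm1(-lambda))
    },
    power_law = rzeta(n, params[["gamma"]]),
    truncated_power_law = ,
    log_normal = {
      # tabulate the pmf far enough into the tail that the missing mass is
      # negligible, then sample from the table
      kmax <- 1000L
      repeat {
        p <- ddegree(seq_len(kmax), family, params)
        if (sum(p) > 1 - 1e-9 || kmax > 1e7) break
        kmax <- kmax * 10L
      }
      sample.int(length(p), n, replace = TRUE, prob = p)
    })
}

# Devroye's rejection sampler for the zeta (discrete power-law) distribution
rzeta <- function(n, gamma) {
  stopifnot(gamma > 1)
  b <- 2^(gamma - 1)
  out <- integer(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 64L)
    u1 <- runif(m); u2 <- runif(m)
    x <- floor(u1^(-1 / (gamma - 1)))
    ok <- is.finite(x) & x >= 1
    x <- x[ok]; u2 <- u2[ok]
    t <- (1 + 1 / x)^(gamma - 1)
    acc <- u2 * x * (t - 1) / (b - 1) <= t / b
    out <- c(out, as.integer(x[acc]))
  }
  out[seq_len(n)]
}

# -- per-family maximum likelihood ------------------------------------------

fit_exponential <- function(degrees) {
  m <- mean(degrees)
  if (m <= 1)
    stop_coprune("all degrees equal 1: exponential rate unbounded",
                 "coprune_fit_degenerate_error")
  # geometric MLE: success probability 1/mean, lambda = -log(1 - 1/mean)
  lambda <- -log1p(-1 / m)
  list(params = c(lambda = lambda),
       loglik = sum(log_pmf(degrees, "exponential", c(lambda = lambda))))
}

fit_power_law <- function(degrees) {
  if (all(degrees == 1))
    stop_coprune("all degrees equal 1: power-law exponent unbounded",
                 "coprune_fit_degenerate_error")
  slog <- sum(log(degrees)); n <- length(degrees)
  nll <- function(gamma) gamma * slog + n * log(pracma::zeta(gamma))
  opt <- optimize(nll, interval = c(1 + 1e-6, 25), tol = 1e-10)
  list(params = c(gamma = opt$minimum), loglik = -opt$objective)
}

fit_truncated_power_law <- function(degrees) {
  if (length(unique(degrees)) < 2L)
    stop_coprune("single distinct degree value: 2-parameter fit degenerate",
                 "coprune_fit_degenerate_error")
  n <- length(degrees); slog <- sum(log(degrees)); sx <- sum(degrees)
  # exponent constrained non-negative: a "truncated power law" with an
  # increasing head is not a power law, and the constraint keeps the
  # exponential family (gamma = 0) on the boundary rather than interior
  nll <- function(par) {
    gamma <- exp(par[1L]) - 1e-4; kappa <- exp(par[2L])
    if (gamma > 25 || kappa > 50) return(1e12)
    v <- gamma * slog + kappa * sx + n * tpl_logZ(gamma, kappa)
    if (!is.finite(v)) 1e12 else v
  }
  # fixed starting points: around the pure power-law solution and around an
  # exponential-like regime (gamma near 0)
  gpl <- tryCatch(fit_power_law(degrees)$params[["gamma"]], error = function(e) 2)
  tg <- function(g) log(g + 1e-4)  # inverse of the gamma transform
  starts <- list(c(tg(min(gpl, 24)), log(1e-4)),
                 c(tg(1.2), log(0.1)),
                 c(tg(0), log(max(1 / mean(degrees), 1e-3))))
  fits <- lapply(starts, function(s)
    optim(s, nll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  # boundary candidates: kappa -> 0 reproduces the nested pure power law,
  # gamma = 0 the nested exponential
  lam0 <- -log1p(-1 / mean(degrees))
  for (cand in list(c(tg(gpl), log(1e-10)), c(tg(0), log(lam0)))) {
    if (nll(cand) < best$value) best <- list(par = cand, value = nll(cand))
  }
  params <- c(gamma = max(exp(best$par[1L]) - 1e-4, 0),
              kappa = exp(best$par[2L]))
  list(params = params, loglik = -best$value)
}

fit_log_normal <- function(degrees) {
  if (length(unique(degrees)) < 2L)
    stop_coprune("single distinct degree value: 2-parameter fit degenerate",
                 "coprune_fit_degenerate_error")
  lx <- log(degrees)
  nll <- function(par) {
    v <- -sum(log_pmf(degrees, "log_normal",
                      c(mu = par[1L], sigma = exp(par[2L]))))
    if (!is.finite(v)) 1e12 else v
  }
  start <- c(mean(lx), log(max(sd(lx), 0.1)))
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(params = c(mu = opt$par[1L], sigma = exp(opt$par[2L])),
       loglik = -opt$value)
}

#' Fit one degree-distribution family by maximum likelihood
#'
#' Fits the discrete distribution on support `{1, 2, ...}` (`x_min = 1`).
#' Optimization uses fixed starting points and tolerances, so the fit is
#' deterministic given the sample.
#'
#' @param degrees integer degrees >= 1 (isolated species excluded).
#' @param family family name, see [ddegree()].
#' @return An object of class `degree_fit`: `family`, `params`, `loglik`,
#'   `n_params`, `aic` (`2 n_params - 2 loglik`), `n`.
#' @export
fit_degree_family <- function(degrees, family = FAMILIES) {
  family <- match.arg(family)
  degrees <- check_degrees(degrees)
  fit <- switch(family,
    exponential = fit_exponential(degrees),
    power_law = fit_power_law(degrees),
    truncated_power_law = fit_truncated_power_law(degrees),
    log_normal = fit_log_normal(degrees))
  k <- N_PARAMS[[family]]
  structure(list(family = family, params = fit$params, loglik = fit$loglik,
                 n_params = k, aic = 2 * k - 2 * fit$loglik,
                 n = length(degrees)),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("<degree_fit> %s: %s | logLik %.3f, AIC %.3f (n = %d)\n",
              x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$loglik, x$aic, x$n))
  invisible(x)
}

#' @export
logLik.degree_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

# minimum AIC; exact ties to fewer parameters, then fixed family order
pick_best_family <- function(aic, n_params, families) {
  families[order(aic, n_params, FAMILY_RANK[families])][1L]
}

#' Fit all candidate families and select the best by AIC
#'
#' Fits the exponential, power-law, truncated power-law and log-normal
#' families and selects the most parsimonious by minimum AIC. Exact AIC ties
#' go to the family with fewer parameters, then to a fixed family order.
#' Families that are degenerate on the sample (for example a single distinct
#' degree value for a two-parameter family) are recorded and excluded from
#' selection.
#'
#' @param degrees integer degrees >= 1.
#' @param families subset of families to fit.
#' @return An object of class `degree_fit_report`: `fits` (named list of
#'   `degree_fit`), `failed` (named character of error messages),
#'   `best_family`, `delta_aic`, `n`.
#' @export
fit_degree_distribution <- function(degrees, families = FAMILIES) {
  degrees <- check_degrees(degrees)
  families <- match.arg(families, several.ok = TRUE)
  fits <- list(); failed <- character(0)
  for (fam in families) {
    res <- tryCatch(fit_degree_family(degrees, fam), error = function(e) e)
    if (inherits(res, "error")) failed[[fam]] <- conditionMessage(res)
    else fits[[fam]] <- res
  }
  if (length(fits) == 0L)
    stop_coprune("no degree-distribution family could be fitted",
                 "coprune_fit_degenerate_error")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  best <- pick_best_family(aic, vapply(fits, `[[`, integer(1), "n_params"),
                           names(fits))
  structure(list(fits = fits, failed = failed, best_family = best,
                 delta_aic = aic - min(aic), n = length(degrees)),
            class = "degree_fit_report")
}

#' @export
print.degree_fit_report <- function(x, ...) {
  cat(sprintf("Degree-distribution model selection (n = %d)\n", x$n))
  for (fam in names(x$fits)) {
    f <- x$fits[[fam]]
    cat(sprintf("  %-20s AIC %10.3f  dAIC %8.3f  %s%s\n",
                fam, f$aic, x$delta_aic[[fam]],
                paste(sprintf("%s = %.4g", names(f$params), f$params),
                      collapse = ", "),
                if (fam == x$best_family) "  <- best" else ""))
  }
  for (fam in names(x$failed))
    cat(sprintf("  %-20s not fitted (%s)\n", fam, x$failed[[fam]]))
  invisible(x)
}

#' Theoretical CCDF of a fitted family
#'
#' @param fit a `degree_fit`.
#' @param x integer degrees at which to evaluate P(K >= x).
#' @return Numeric vector of upper-tail probabilities.
#' @export
fitted_ccdf <- function(fit, x) {
  stopifnot(inherits(fit, "degree_fit"))
  kmax <- max(x)
  pmf <- ddegree(seq_len(kmax), fit$family, fit$params)
  lower <- c(0, cumsum(pmf))[x]  # P(K < x) over the tabulated head
  pmax(1 - lower, 0)
}

#' Plot empirical and fitted degree CCDFs
#'
#' Log-log plot of the empirical complementary cumulative degree
#' distribution with each fitted family overlaid.
#'
#' @param x a `degree_fit_report`.
#' @param degrees the degree sample the report was fitted to.
#' @param ... passed to [graphics::plot()].
#' @export
plot.degree_fit_report <- function(x, degrees, ...) {
  cc <- empirical_ccdf(degrees)
  plot(cc$x, cc$prob, log = "xy", pch = 16,
       xlab = "degree x", ylab = "P(K >= x)", ...)
  grid_x <- seq_len(max(cc$x))
  cols <- setNames(c("#d95f02", "#1b9e77", "#7570b3", "#e7298a"),
                   FAMILIES)
  for (fam in names(x$fits))
    lines(grid_x, fitted_ccdf(x$fits[[fam]], grid_x), col = cols[[fam]])
  legend("bottomleft", bty = "n",
         legend = paste0(names(x$fits),
                         ifelse(names(x$fits) == x$best_family, " (best)", "")),
         col = cols[names(x$fits)], lty = 1)
  invisible(x)
}
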