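# Per-dataset orchestration: fit the IR model, simulate IR and random-null
# ensembles, fit degree distributions to the empirical networks and to every
# realization, and summarize the species-level potential/realized relation.

#' Species-level summary table
#'
#' One row per consumer: potential degree (co-occurrence partners), realized
#' degree (interaction partners), mean co-occurrence frequency over
#' potential partners, and the IR-ensemble mean realized degree.
#'
#' @param fit an `ir_fit`.
#' @param ensemble optional IR `prune_ensemble` supplying
#'   `predicted_degree`.
#' @return Data frame with columns `species`, `guild`, `potential_degree`,
#'   `realized_degree`, `mean_cooc_frequency`, `predicted_degree`.
#' @export
species_summaries <- function(fit, ensemble = NULL) {
  stopifnot(inherits(fit, "ir_fit"))
  N <- fit$freq$N
  potential <- rowSums(N >= 1L)
  realized <- rowSums(fit$inter$adjacency)
  mean_freq <- ifelse(potential > 0, rowSums(N) / pmax(potential, 1), NA_real_)
  predicted <- if (!is.null(ensemble)) ensemble$consumer_mean_degree
               else rep(NA_real_, length(potential))
  data.frame(species = fit$freq$consumers, guild = "consumer",
             potential_degree = as.integer(potential),
             realized_degree = as.integer(realized),
             mean_cooc_frequency = mean_freq,
             predicted_degree = predicted,
             row.names = NULL)
}

#' Superlinearity exponent of the potential-to-realized relation
#'
#' Ordinary least-squares slope of `log(realized_degree)` on
#' `log(potential_degree)` over species with at least one realized link.
#' A slope of 1 means realized links are proportional to potential links
#' (pure rescaling of the degree distribution); a slope above 1 means
#' generalists realize a disproportionately large share of their potential
#' links.
#'
#' @param summaries data frame from [species_summaries()], or any frame with
#'   `potential_degree` and `realized_degree` columns.
#' @return OLS slope (scalar).
#' @export
superlinearity_exponent <- function(summaries) {
  keep <- summaries$realized_degree >= 1
  x <- summaries$potential_degree[keep]
  y <- summaries$realized_degree[keep]
  if (length(x) < 3L || length(unique(x)) < 2L)
    stop_coprune("need >= 3 species with realized links and >= 2 distinct potential degrees",
                 "coprune_degenerate_error")
  unname(coef(lm(log(y) ~ log(x)))[2L])
}

#' Frequency-generalism coupling statistic
#'
#' Spearman rank correlation between consumers' potential degree (number of
#' potential partners) and their mean co-occurrence frequency with those
#' partners. A positive value means wide-ranging generalists also share more
#' sites with each partner — the coupling that lets frequency-based pruning
#' reshape the degree distribution.
#'
#' @param summaries data frame from [species_summaries()].
#' @return Spearman's rho (scalar).
#' @export
frequency_generalism_stat <- function(summaries) {
  ok <- summaries$potential_degree >= 1
  x <- summaries$potential_degree[ok]
  y <- summaries$mean_cooc_frequency[ok]
  if (length(x) < 3L)
    stop_coprune("need >= 3 species", "coprune_degenerate_error")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_coprune("constant input: rank correlation undefined",
                 "coprune_degenerate_error")
  unname(cor(x, y, method = "spearman"))
}

#' Correlation between calibrated p and f across datasets
#'
#' @param reports list of `dataset_report` (or `ir_fit`) objects, length
#'   >= 3.
#' @return Pearson correlation between the calibrated per-site rates and
#'   the realized link fractions.
#' @export
p_vs_f_correlation <- function(reports) {
  if (length(reports) < 3L)
    stop_coprune("need >= 3 datasets", "coprune_degenerate_error")
  p <- vapply(reports, function(r) r$p, numeric(1))
  f <- vapply(reports, function(r) r$f, numeric(1))
  if (sd(p) == 0 || sd(f) == 0)
    stop_coprune("degenerate: no variation in p or f across datasets",
                 "coprune_degenerate_error")
  cor(p, f)
}

guild_degrees <- function(net, guild) {
  d <- degree_sequences(net)
  d <- if (guild == "consumer") d$consumer_degrees else d$resource_degrees
  d[d >= 1]
}

best_family_of <- function(degrees) {
  if (length(degrees) < 3L) return(NA_character_)
  tryCatch(fit_degree_distribution(degrees)$best_family,
           error = function(e) NA_character_)
}

#' Run the full co-occurrence-pruning analysis on one dataset
#'
#' Pipeline: co-occurrence and interaction networks, realized link fraction
#' f, calibration of the per-site rate p, IR and random-pruning ensembles,
#' degree-distribution model selection on the empirical networks (both
#' guilds) and on every realization, species summaries, and the
#' superlinearity and frequency-generalism statistics. Fully reproducible
#' given the seed.
#'
#' @param ds a `cooc_dataset` or `synthetic_metacommunity`.
#' @param n_realizations ensemble size for each pruning mode.
#' @param seed master seed.
#' @param fit_ensembles fit degree distributions to every realization
#'   (consumer guild); disable to save time when only the fit and
#'   statistics are needed.
#' @return An object of class `dataset_report`.
#' @export
run_pipeline <- function(ds, n_realizations = 100L, seed = 1L,
                         fit_ensembles = TRUE) {
  fit <- ir_fit(ds)
  ens_ir <- simulate(fit, nsim = n_realizations, seed = seed, mode = "ir")
  ens_rand <- simulate(fit, nsim = n_realizations, seed = seed + 1L,
                       mode = "random")

  fit_reports <- list()
  for (guild in c("consumer", "resource")) {
    fit_reports[[guild]] <- list(
      cooccurrence = fit_degree_distribution(guild_degrees(fit$cooc, guild)),
      interaction = fit_degree_distribution(guild_degrees(fit$inter, guild)))
  }

  ensemble_best <- NULL
  if (fit_ensembles) {
    ensemble_best <- list(
      ir = vapply(ens_ir$realizations,
                  function(r) best_family_of(guild_degrees(r, "consumer")),
                  character(1)),
      random = vapply(ens_rand$realizations,
                      function(r) best_family_of(guild_degrees(r, "consumer")),
                      character(1)))
  }

  summaries <- species_summaries(fit, ens_ir)
  slope <- tryCatch(superlinearity_exponent(summaries),
                    coprune_degenerate_error = function(e) NA_real_)
  rho <- tryCatch(frequency_generalism_stat(summaries),
                  coprune_degenerate_error = function(e) NA_real_)

  structure(list(name = fit$dataset, f = fit$f, p = fit$p,
                 L_c = fit$L_c, L_int = fit$L_int,
                 fit = fit, ensemble_ir = ens_ir, ensemble_random = ens_rand,
                 fit_reports = fit_reports, ensemble_best = ensemble_best,
                 species_summaries = summaries,
                 superlinearity_exponent = slope,
                 frequency_generalism = rho,
                 n_realizations = n_realizations, seed = seed),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(sprintf("Dataset report: '%s'\n", x$name))
  cat(sprintf("  L_c = %d, L_int = %d, f = %.4f, calibrated p = %.5f\n",
              x$L_c, x$L_int, x$f, x$p))
  for (guild in names(x$fit_reports))
    cat(sprintf("  %s degrees: co-occurrence best = %s, interaction best = %s\n",
                guild,
                x$fit_reports[[guild]]$cooccurrence$best_family,
                x$fit_reports[[guild]]$interaction$best_family))
  cat(sprintf("  superlinearity exponent = %.3f, frequency-generalism rho = %.3f\n",
              x$superlinearity_exponent, x$frequency_generalism))
  if (!is.null(x$ensemble_best)) {
    tab <- function(v) paste(sprintf("%s: %d", names(table(v)), table(v)),
                             collapse = ", ")
    cat(sprintf("  IR ensemble best families: %s\n", tab(x$ensemble_best$ir)))
    cat(sprintf("  random ensemble best families: %s\n",
                tab(x$ensemble_best$random)))
  }
  invisible(x)
}

#' Write a dataset report to disk
#'
#' Emits `report.json` (scalar results and per-family fit tables), a
#' species-summary CSV and per-network CCDF CSVs under `dir`.
#'
#' @param report a `dataset_report`.
#' @param dir output directory, created if needed.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fits_json <- lapply(report$fit_reports, function(by_kind)
    lapply(by_kind, function(fr) list(
      best_family = fr$best_family,
      families = lapply(fr$fits, function(f)
        list(params = as.list(f$params), loglik = f$loglik, aic = f$aic,
             delta_aic = fr$delta_aic[[f$family]])))))
  out <- list(dataset = report$name, f = report$f, p = report$p,
              L_c = report$L_c, L_int = report$L_int,
              superlinearity_exponent = report$superlinearity_exponent,
              frequency_generalism = report$frequency_generalism,
              n_realizations = report$n_realizations, seed = report$seed,
              fits = fits_json, ensemble_best = report$ensemble_best)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  write.csv(report$species_summaries,
            file.path(dir, "species_summaries.csv"), row.names = FALSE)
  for (guild in names(report$fit_reports)) {
    for (kind in c("cooc", "inter")) {
      net <- if (kind == "cooc") report$fit$cooc else report$fit$inter
      d <- guild_degrees(net, guild)
      if (length(d))
        write.csv(empirical_ccdf(d),
                  file.path(dir, sprintf("ccdf_%s_%s.csv", guild, kind)),
                  row.names = FALSE)
    }
  }
  invisible(report)
}
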