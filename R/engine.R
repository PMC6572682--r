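#' Per-year population summary
#'
#' All rates are computed among living agents; counts (blindness, MI and
#' stroke history, cumulative deaths) are absolute. If every agent is dead
#' the rates are reported as `NA`, not zero.
#'
#' @param pop An `agent_population`.
#' @return A one-row `data.frame` with columns `living`, `diabetes_rate`,
#'   `prediabetes_rate`, `overweight_rate`, `smoking_rate`, `active_rate`,
#'   `healthy_diet_rate`, `hypertension_rate`, `hypercholesterolemia_rate`,
#'   `nephropathy_rate`, `blindness_count`, `mi_count`, `stroke_count`,
#'   `deaths_cumulative`.
#' @examples
#' set.seed(1)
#' summarize_population(generate_population(population_spec(n = 500)))
#' @export
summarize_population <- function(pop) {
  stopifnot(nrow(pop) > 0)
  alive <- pop$cvd != "death"
  n_alive <- sum(alive)
  rate <- function(x) if (n_alive == 0) NA_real_ else sum(x & alive) / n_alive
  data.frame(
    living = n_alive,
    diabetes_rate = rate(pop$glycemic == "diabetes"),
    prediabetes_rate = rate(pop$glycemic == "prediabetes"),
    overweight_rate = rate(pop$weight == "overweight"),
    smoking_rate = rate(pop$smoking == "smoking"),
    active_rate = rate(pop$activity == "active"),
    healthy_diet_rate = rate(pop$diet == "healthy"),
    hypertension_rate = rate(pop$hypertension == "yes"),
    hypercholesterolemia_rate = rate(pop$hypercholesterolemia == "yes"),
    nephropathy_rate = rate(pop$nephropathy == "yes"),
    blindness_count = sum(pop$retina == "blindness" & alive),
    mi_count = sum(pop$cvd == "mi_history"),
    stroke_count = sum(pop$cvd == "stroke_history"),
    deaths_cumulative = sum(!alive)
  )
}

scenario_metrics <- c("diabetes_rate", "prediabetes_rate", "overweight_rate",
                      "smoking_rate", "active_rate", "healthy_diet_rate",
                      "hypertension_rate", "hypercholesterolemia_rate",
                      "nephropathy_rate", "blindness_count", "mi_count",
                      "stroke_count", "deaths_cumulative")

#' Run a replicated simulation scenario
#'
#' For each replication `r` the RNG is seeded with `base_seed + r`; the
#' population is generated (afresh per replication, or once from `base_seed`
#' when `resample_population = FALSE`), the social network is built, the
#' optional baseline intervention is applied, and [step_year()] is iterated
#' `years` times with an annual summary after every year (year 0 is the
#' post-intervention baseline). Summaries are aggregated as mean and
#' standard deviation across replications.
#'
#' @param config A [run_config()]; its `engine` section supplies defaults
#'   for the remaining arguments.
#' @param years,replications,base_seed Optional overrides of the config's
#'   engine settings.
#' @param label Scenario label carried into the result.
#' @param trace Optional path: per-agent states of every replication-year
#'   are appended as CSV (columns `replication`, `year`, then agent fields).
#' @return A `scenario_result`: list with `label`, `years` (0..years),
#'   `mean` and `sd` (year x metric matrices), `replication_metrics`
#'   (year x metric x replication array), `n_replications`, `seeds`.
#' @export
run_scenario <- function(config = run_config(), years = NULL,
                         replications = NULL, base_seed = NULL,
                         label = NULL, trace = NULL) {
  stopifnot(inherits(config, "run_config"))
  eng <- config$engine
  if (is.null(years)) years <- eng$years
  if (is.null(replications)) replications <- eng$replications
  if (is.null(base_seed)) base_seed <- eng$base_seed
  if (is.null(label)) {
    label <- if (is.null(config$intervention)) "control" else {
      paste0(config$intervention$target, "@", config$intervention$intensity)
    }
  }
  fixed_pop <- NULL
  fixed_net <- NULL
  if (!isTRUE(eng$resample_population)) {
    set.seed(base_seed)
    fixed_pop <- generate_population(config$population)
    fixed_net <- build_small_world(config$population$n, config$network$k,
                                   config$network$beta)
  }
  res <- array(NA_real_,
               dim = c(years + 1, length(scenario_metrics), replications),
               dimnames = list(paste0("year", 0:years), scenario_metrics,
                               NULL))
  seeds <- base_seed + seq_len(replications)
  if (!is.null(trace) && file.exists(trace)) file.remove(trace)
  for (r in seq_len(replications)) {
    set.seed(seeds[r])
    if (isTRUE(eng$resample_population)) {
      pop <- generate_population(config$population)
      net <- build_small_world(config$population$n, config$network$k,
                               config$network$beta)
    } else {
      pop <- fixed_pop
      net <- fixed_net
    }
    if (!is.null(config$intervention)) {
      pop <- apply_intervention(pop, config$intervention)
    }
    res[1, , r] <- unlist(summarize_population(pop)[scenario_metrics])
    if (!is.null(trace)) write_trace(pop, r, 0L, trace)
    for (y in seq_len(years)) {
      pop <- step_year(pop, net, config$transitions, config$influence)
      res[y + 1, , r] <- unlist(summarize_population(pop)[scenario_metrics])
      if (!is.null(trace)) write_trace(pop, r, y, trace)
    }
  }
  structure(
    list(label = label,
         years = 0:years,
         mean = apply(res, c(1, 2), mean),
         sd = apply(res, c(1, 2), stats::sd),
         replication_metrics = res,
         n_replications = replications,
         seeds = seeds),
    class = "scenario_result"
  )
}

write_trace <- function(pop, replication, year, path) {
  df <- cbind(replication = replication, year = year, as.data.frame(pop))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario '", x$label, "': ", max(x$years), " years, ",
      x$n_replications, " replications\n", sep = "")
  show <- x$years[x$years %% 5 == 0]
  tab <- data.frame(
    year = show,
    diabetes = x$mean[show + 1, "diabetes_rate"],
    overweight = x$mean[show + 1, "overweight_rate"],
    smoking = x$mean[show + 1, "smoking_rate"],
    active = x$mean[show + 1, "active_rate"]
  )
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Scenario '", object$label, "' (", object$n_replications,
      " replications; mean [sd])\n", sep = "")
  print(utils::head(df[, c("year", "diabetes_rate_mean", "diabetes_rate_sd",
                           "overweight_rate_mean", "deaths_cumulative_mean")],
                    length(object$years)),
        row.names = FALSE, digits = 4)
  invisible(df)
}

#' @export
as.data.frame.scenario_result <- function(x, ...) {
  df <- data.frame(scenario = x$label, year = x$years)
  for (m in scenario_metrics) {
    df[[paste0(m, "_mean")]] <- x$mean[, m]
    df[[paste0(m, "_sd")]] <- x$sd[, m]
  }
  df
}

#' @export
plot.scenario_result <- function(x, metrics = c("diabetes_rate",
                                                "overweight_rate",
                                                "smoking_rate",
                                                "active_rate"), ...) {
  graphics::matplot(x$years, x$mean[, metrics, drop = FALSE], type = "l",
                    lty = 1, xlab = "year", ylab = "rate",
                    main = paste("Scenario", x$label), ...)
  graphics::legend("topleft", legend = metrics, lty = 1,
                   col = seq_along(metrics), bty = "n", cex = 0.8)
  invisible(x)
}

#' Compare the control scenario with lifestyle interventions
#'
#' Runs the no-intervention control plus one scenario per target behavior at
#' the given intensity, and tabulates mean diabetes rates at the requested
#' horizons.
#'
#' @param config A [run_config()]; its `intervention` section is ignored.
#' @param intensity Intervention intensity shared by the three programs.
#' @param horizons Years at which diabetes rates are reported.
#' @param targets Intervention targets to include.
#' @return A list with `results` (named list of `scenario_result`) and
#'   `table` (`data.frame`: scenario x horizon mean diabetes rates).
#' @export
compare_interventions <- function(config = run_config(), intensity = 0.5,
                                  horizons = c(5, 10, 15, 20),
                                  targets = c("smoking", "diet", "activity")) {
  years <- max(horizons)
  base <- config
  base$intervention <- NULL
  results <- list(control = run_scenario(base, years = years))
  for (tg in targets) {
    cfg <- config
    cfg$intervention <- intervention(tg, intensity)
    results[[tg]] <- run_scenario(cfg, years = years)
  }
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(scenario = nm, horizon = horizons,
               diabetes_rate = r$mean[horizons + 1, "diabetes_rate"],
               diabetes_rate_sd = r$sd[horizons + 1, "diabetes_rate"])
  }))
  rownames(tab) <- NULL
  list(results = results, table = tab)
}

#' Sweep one intervention over intensity levels
#'
#' Runs one scenario per intensity (plus the control at intensity 0) and
#' reports mean diabetes rates at each horizon — the sensitivity analysis of
#' intervention dose.
#'
#' @param config A [run_config()].
#' @param target Intervention target behavior.
#' @param intensities Intensity levels.
#' @param horizons Reporting horizons (years).
#' @return A `data.frame` with columns `target`, `intensity`, `horizon`,
#'   `diabetes_rate`, `diabetes_rate_sd`.
#' @export
sweep_intensities <- function(config = run_config(), target = "smoking",
                              intensities = seq(0.1, 0.5, by = 0.1),
                              horizons = c(5, 10, 15, 20)) {
  years <- max(horizons)
  rows <- lapply(c(0, intensities), function(int) {
    cfg <- config
    cfg$intervention <- if (int > 0) intervention(target, int) else NULL
    r <- run_scenario(cfg, years = years)
    data.frame(target = target, intensity = int, horizon = horizons,
               diabetes_rate = r$mean[horizons + 1, "diabetes_rate"],
               diabetes_rate_sd = r$sd[horizons + 1, "diabetes_rate"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Medical-cost savings from a diabetes-rate reduction
#'
#' Scales a percentage-point reduction in the population diabetes rate to a
#' national case count and annual medical-cost saving. Because published
#' summaries sometimes round the case count to two significant figures
#' before costing it, both the exact and the rounded-cases savings are
#' reported.
#'
#' @param rate_reduction Diabetes-rate reduction in percentage points.
#' @param population_size Number of people the reduction applies to.
#' @param annual_cost Annual medical cost per diabetic (currency units).
#' @return A list: `cases` (averted diabetics), `cases_rounded` (2
#'   significant figures), `savings` (= cases x annual_cost) and
#'   `savings_rounded` (= cases_rounded x annual_cost).
#' @examples
#' cost_savings(0.69, 1.39e9, 465)
#' @export
cost_savings <- function(rate_reduction, population_size, annual_cost) {
  stopifnot(rate_reduction >= 0, population_size >= 0, annual_cost >= 0)
  cases <- rate_reduction / 100 * population_size
  cases_rounded <- signif(cases, 2)
  list(cases = cases,
       cases_rounded = cases_rounded,
       savings = cases * annual_cost,
       savings_rounded = cases_rounded * annual_cost)
}
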