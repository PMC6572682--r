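#' Run configuration
#'
#' Bundles every tunable of a simulation run: the population specification,
#' network parameters, influence settings, the transition table, an optional
#' baseline intervention and the engine settings (horizon, replications,
#' base seed, whether the population is resampled per replication). All
#' fields default to the documented model defaults, so `run_config()` with
#' no arguments is a complete runnable configuration.
#'
#' @param population A [population_spec()].
#' @param network List with `k` (even mean degree, default 6) and `beta`
#'   (rewiring probability, default 0.1).
#' @param influence An [influence_config()].
#' @param transitions A [transition_table()].
#' @param intervention An [intervention()] or `NULL`.
#' @param engine List with `years` (default 20), `replications` (default
#'   30), `base_seed` (default 42) and `resample_population` (default
#'   `TRUE`: a fresh population and network per replication).
#' @param output_dir Directory for command outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(population = population_spec(),
                       network = list(k = 6, beta = 0.1),
                       influence = influence_config(),
                       transitions = transition_table(),
                       intervention = NULL,
                       engine = list(years = 20, replications = 30,
                                     base_seed = 42,
                                     resample_population = TRUE),
                       output_dir = ".") {
  net_def <- list(k = 6, beta = 0.1)
  net_def[names(network)] <- network
  check_known(names(network), names(net_def), "network")
  eng_def <- list(years = 20, replications = 30, base_seed = 42,
                  resample_population = TRUE)
  eng_def[names(engine)] <- engine
  check_known(names(engine), names(eng_def), "engine")
  if (net_def$k %% 2 != 0 || net_def$k < 0) {
    stop("network.k must be a nonnegative even integer", call. = FALSE)
  }
  if (net_def$beta < 0 || net_def$beta > 1) {
    stop("network.beta must be in [0, 1]", call. = FALSE)
  }
  if (eng_def$years < 0 || eng_def$replications < 1) {
    stop("engine.years must be >= 0 and engine.replications >= 1",
         call. = FALSE)
  }
  stopifnot(inherits(population, "population_spec"),
            inherits(influence, "influence_config"),
            inherits(transitions, "transition_table"),
            is.null(intervention) || inherits(intervention, "intervention"))
  structure(list(population = population, network = net_def,
                 influence = influence, transitions = transitions,
                 intervention = intervention, engine = eng_def,
                 output_dir = output_dir),
            class = "run_config")
}

check_known <- function(given, known, section) {
  bad <- setdiff(given, known)
  if (length(bad) > 0) {
    stop("unknown key", if (length(bad) > 1) "s", " in '", section, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat("  population: n =", x$population$n, "\n")
  cat("  network: k =", x$network$k, ", beta =", x$network$beta, "\n")
  cat("  influence:", x$influence$smoothing, "smoothing, cap",
      x$influence$f_cap, "\n")
  cat("  intervention:",
      if (is.null(x$intervention)) "none" else
        paste0(x$intervention$target, "@", x$intervention$intensity), "\n")
  cat("  engine:", x$engine$years, "years x", x$engine$replications,
      "replications, seed", x$engine$base_seed, "\n")
  invisible(x)
}

band_to_list <- function(df) lapply(as.list(df), function(col) unname(col))

list_to_band <- function(lst, name) {
  df <- as.data.frame(lst, stringsAsFactors = FALSE)
  df
}

#' Serialize a run configuration
#'
#' Writes the configuration as a nested key-value YAML document; every field
#' omitted from a document loaded by [load_config()] falls back to the
#' documented default, and `save_config(load_config(x))` round-trips
#' exactly.
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  pop <- unclass(config$population)
  pop <- pop[!vapply(pop, is.null, logical(1))]
  trans <- unclass(config$transitions)
  band_fields <- c("smoking_start", "smoking_quit", "htn_age_mult",
                   "chol_age_mult", "dm_age_mult", "cvd_event")
  for (f in band_fields) trans[[f]] <- band_to_list(trans[[f]])
  doc <- list(
    population = pop,
    network = config$network,
    influence = list(smoothing = config$influence$smoothing,
                     f_cap = config$influence$f_cap,
                     enabled = as.list(config$influence$enabled)),
    transitions = trans,
    engine = config$engine,
    output_dir = config$output_dir
  )
  if (!is.null(config$intervention)) {
    doc$intervention <- list(target = config$intervention$target,
                             intensity = config$intervention$intensity)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML document with sections `population`, `network`, `influence`,
#' `transitions`, `intervention`, `engine`, `output_dir` — all optional;
#' omitted fields take the documented defaults. Unknown keys anywhere are
#' rejected with a message naming the offending key; out-of-range
#' probabilities fail validation with the field name.
#'
#' @param path Path to the YAML configuration.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  check_known(names(doc),
              c("population", "network", "influence", "transitions",
                "intervention", "engine", "output_dir"),
              "config")
  pop_args <- doc$population
  check_known(names(pop_args),
              setdiff(names(formals(population_spec)), "preset"),
              "population")
  population <- do.call(population_spec, as_args(pop_args))
  infl_args <- doc$influence
  check_known(names(infl_args), names(formals(influence_config)), "influence")
  if (!is.null(infl_args$enabled)) {
    infl_args$enabled <- unlist(infl_args$enabled)
  }
  influence <- do.call(influence_config, as_args(infl_args))
  trans_args <- doc$transitions
  check_known(names(trans_args), names(formals(transition_table)),
              "transitions")
  band_fields <- c("smoking_start", "smoking_quit", "htn_age_mult",
                   "chol_age_mult", "dm_age_mult", "cvd_event")
  for (f in intersect(band_fields, names(trans_args))) {
    trans_args[[f]] <- list_to_band(trans_args[[f]], f)
  }
  transitions <- do.call(transition_table, as_args(trans_args))
  iv <- NULL
  if (!is.null(doc$intervention)) {
    check_known(names(doc$intervention), c("target", "intensity"),
                "intervention")
    iv <- do.call(intervention, as_args(doc$intervention))
  }
  args <- list(population = population, influence = influence,
               transitions = transitions, intervention = iv)
  if (!is.null(doc$network)) args$network <- doc$network
  if (!is.null(doc$engine)) args$engine <- doc$engine
  if (!is.null(doc$output_dir)) args$output_dir <- doc$output_dir
  do.call(run_config, args)
}

as_args <- function(x) if (is.null(x)) list() else x

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}
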