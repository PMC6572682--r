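# Shared test utilities: hand-built cohorts, binomial interval checks, and
# igraph conversion (igraph serves as the independent graph-metric oracle).

# a population of n identical agents with chosen states
make_cohort <- function(n, age = 45, sex = "male", smoking = "not_smoking",
                        diet = "unhealthy", activity = "inactive",
                        weight = "normal", hypertension = "no",
                        hypercholesterolemia = "no", nephropathy = "no",
                        glycemic = "none", retina = "normal", cvd = "none") {
  pop <- data.frame(
    id = seq_len(n) - 1L, age = as.integer(age), sex = sex,
    smoking = smoking, diet = diet, activity = activity, weight = weight,
    hypertension = hypertension, hypercholesterolemia = hypercholesterolemia,
    nephropathy = nephropathy, glycemic = glycemic, retina = retina,
    cvd = cvd, hba1c = 5.5, stringsAsFactors = FALSE
  )
  class(pop) <- c("agent_population", "data.frame")
  pop
}

# empty network over n agents (no social influence pathway at all)
empty_network <- function(n) build_ring_lattice(n, 0)

# exact two-sided binomial acceptance interval for an observed count
expect_binomial_rate <- function(observed_count, n, p, level = 0.99) {
  a <- (1 - level) / 2
  lo <- stats::qbinom(a, n, p)
  hi <- stats::qbinom(1 - a, n, p)
  expect_gte(observed_count, lo)
  expect_lte(observed_count, hi)
}

as_igraph <- function(net) {
  igraph::graph_from_edgelist(net$edges + 1L, directed = FALSE)
}

# influence config with all behaviors pinned to F = 1
influence_off <- function() {
  influence_config(enabled = c(smoking = FALSE, diet = FALSE,
                               activity = FALSE))
}
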