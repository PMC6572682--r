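#' Annual state-chart progression
#'
#' One simulated year advances every living agent through seven fixed
#' stages: (1) behavior signals are counted from start-of-year states;
#' (2) the three behaviors toggle with influence-adjusted probabilities;
#' (3) body weight responds to the (updated) behaviors; (4) hypertension and
#' hypercholesterolemia; (5) glycemic status; (6) complications
#' (nephropathy, retinopathy, cardiovascular events and death); (7) age
#' increments for survivors. Each stage is synchronous — it reads only the
#' states left by the previous stage — so update order within a stage cannot
#' matter. Death (via the CVD chart, the model's only mortality source),
#' diabetes and blindness are absorbing.
#'
#' @name progression
NULL

# Bernoulli draw helper: one uniform per agent, guarded probability range.
draw <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::runif(length(p)) < p
}

clamp01 <- function(p) pmin(1, pmax(0, p))

behavior_healthy <- function(pop, behavior) {
  switch(behavior,
         smoking = pop$smoking == "not_smoking",
         diet = pop$diet == "healthy",
         activity = pop$activity == "active",
         stop("unknown behavior: ", behavior))
}

#' Toggle the three lifestyle behaviors
#'
#' For each behavior the applicable base rate (age-banded for smoking) is
#' multiplied by the agent's influence factor — F(m, n) on the
#' unhealthy-to-healthy transition, F(n, m) on the reverse — clamped to
#' \[0, 1\], and a single Bernoulli draw decides the toggle. The three
#' behaviors update independently.
#'
#' @param pop An `agent_population`.
#' @param signals Named list (`smoking`, `diet`, `activity`) of signal-count
#'   lists as returned by [count_signals()].
#' @param tab A [transition_table()].
#' @param cfg An [influence_config()].
#' @return The updated population.
#' @export
step_behaviors <- function(pop, signals, tab, cfg = influence_config()) {
  alive <- pop$cvd != "death"
  for (b in c("smoking", "diet", "activity")) {
    healthy <- behavior_healthy(pop, b)
    sig <- signals[[b]]
    if (isTRUE(cfg$enabled[[b]])) {
      f_to_healthy <- influence_factor(sig$positive, sig$negative, cfg)
      f_to_unhealthy <- influence_factor(sig$negative, sig$positive, cfg)
    } else {
      f_to_healthy <- f_to_unhealthy <- rep(1, nrow(pop))
    }
    p_heal <- switch(b,
                     smoking = band_lookup(tab$smoking_quit, pop$age),
                     diet = rep(tab$diet_to_healthy, nrow(pop)),
                     activity = rep(tab$activity_to_active, nrow(pop)))
    p_unheal <- switch(b,
                       smoking = band_lookup(tab$smoking_start, pop$age),
                       diet = rep(tab$diet_to_unhealthy, nrow(pop)),
                       activity = rep(tab$activity_to_inactive, nrow(pop)))
    p <- ifelse(healthy,
                adjust_probability(p_unheal, f_to_unhealthy),
                adjust_probability(p_heal, f_to_healthy))
    toggle <- alive & draw(p)
    new_healthy <- xor(healthy, toggle)
    states <- switch(b,
                     smoking = c("not_smoking", "smoking"),
                     diet = c("healthy", "unhealthy"),
                     activity = c("active", "inactive"))
    pop[[b]] <- ifelse(new_healthy, states[1], states[2])
  }
  pop
}

#' Body-weight transition
#'
#' Normal-weight agents gain with probability
#' `weight_gain_base * mult_unhealthy_diet^(diet unhealthy) *
#' mult_inactive^(inactive)`; overweight agents lose with the mirrored
#' healthy-behavior multipliers. Probabilities are clamped to \[0, 1\].
#'
#' @inheritParams step_behaviors
#' @return The updated population.
#' @export
step_weight <- function(pop, tab) {
  alive <- pop$cvd != "death"
  normal <- pop$weight == "normal"
  p_gain <- clamp01(tab$weight_gain_base *
                      ifelse(pop$diet == "unhealthy",
                             tab$weight_gain_mult_unhealthy_diet, 1) *
                      ifelse(pop$activity == "inactive",
                             tab$weight_gain_mult_inactive, 1))
  p_loss <- clamp01(tab$weight_loss_base *
                      ifelse(pop$diet == "healthy",
                             tab$weight_loss_mult_healthy_diet, 1) *
                      ifelse(pop$activity == "active",
                             tab$weight_loss_mult_active, 1))
  p <- ifelse(normal, p_gain, p_loss)
  toggle <- alive & draw(p)
  pop$weight <- ifelse(xor(!normal, toggle), "overweight", "normal")
  pop
}

comorbidity_step <- function(state, age, overweight, alive,
                             base, age_mult, ow_mult, remit) {
  p_on <- clamp01(base * band_lookup(age_mult, age, value = "mult") *
                    ifelse(overweight, ow_mult, 1))
  onset <- alive & state == "no" & draw(p_on)
  remits <- alive & state == "yes" & draw(rep(remit, length(state)))
  state[onset] <- "yes"
  state[remits] <- "no"
  state
}

#' Hypertension and hypercholesterolemia transitions
#'
#' Onset probability is base rate x age-band multiplier x overweight
#' multiplier (clamped); remission applies a flat annual probability.
#' The two charts draw independently.
#'
#' @inheritParams step_behaviors
#' @return The updated population.
#' @export
step_comorbidity <- function(pop, tab) {
  alive <- pop$cvd != "death"
  ow <- pop$weight == "overweight"
  pop$hypertension <- comorbidity_step(pop$hypertension, pop$age, ow, alive,
                                       tab$htn_base, tab$htn_age_mult,
                                       tab$htn_overweight_mult, tab$htn_remit)
  pop$hypercholesterolemia <- comorbidity_step(
    pop$hypercholesterolemia, pop$age, ow, alive,
    tab$chol_base, tab$chol_age_mult, tab$chol_overweight_mult,
    tab$chol_remit)
  pop
}

#' Glycemic-status transition
#'
#' Normal agents progress to prediabetes and prediabetic agents to diabetes
#' with base rate x age-band multiplier x overweight multiplier; prediabetes
#' may also revert to normal. Diabetes is absorbing and an agent makes at
#' most one glycemic transition per year.
#'
#' @inheritParams step_behaviors
#' @return The updated population.
#' @export
step_glycemic <- function(pop, tab) {
  alive <- pop$cvd != "death"
  mult <- band_lookup(tab$dm_age_mult, pop$age, value = "mult") *
    ifelse(pop$weight == "overweight", tab$dm_overweight_mult, 1)
  p_pre <- clamp01(tab$dm_none_to_pre_base * mult)
  p_dm <- clamp01(tab$dm_pre_to_dm_base * mult)
  was_none <- pop$glycemic == "none"
  was_pre <- pop$glycemic == "prediabetes"
  to_pre <- alive & was_none & draw(p_pre)
  to_dm <- alive & was_pre & draw(p_dm)
  to_none <- alive & was_pre & !to_dm &
    draw(rep(tab$dm_pre_to_none, nrow(pop)))
  pop$glycemic[to_pre] <- "prediabetes"
  pop$glycemic[to_dm] <- "diabetes"
  pop$glycemic[to_none] <- "none"
  pop
}

#' Complication transitions: nephropathy, retinopathy, CVD and death
#'
#' Nephropathy onsets/remits with flat annual rates. Retinopathy initiates
#' only in diabetics and can progress to blindness (absorbing). Agents
#' without cardiovascular history have a first event with an age- and
#' sex-specific probability; the event is an MI with probability
#' `cvd_mi_share` (else stroke) and immediately fatal with probability
#' `cvd_fatality`. Agents with event history face an annual
#' `post_event_mortality` draw. Death ends all further updates.
#'
#' @inheritParams step_behaviors
#' @return The updated population.
#' @export
step_complications <- function(pop, tab) {
  alive <- pop$cvd != "death"
  n <- nrow(pop)

  neph_on <- alive & pop$nephropathy == "no" & draw(rep(tab$neph_onset, n))
  neph_off <- alive & pop$nephropathy == "yes" & draw(rep(tab$neph_remit, n))
  pop$nephropathy[neph_on] <- "yes"
  pop$nephropathy[neph_off] <- "no"

  diabetic <- pop$glycemic == "diabetes"
  ret_on <- alive & diabetic & pop$retina == "normal" &
    draw(rep(tab$retina_onset, n))
  ret_blind <- alive & pop$retina == "diabetic_retina" &
    draw(rep(tab$retina_to_blind, n))
  pop$retina[ret_on] <- "diabetic_retina"
  pop$retina[ret_blind] <- "blindness"

  p_event <- band_lookup(tab$cvd_event, pop$age, pop$sex)
  event <- alive & pop$cvd == "none" & draw(p_event)
  is_mi <- event & draw(rep(tab$cvd_mi_share, n))
  pop$cvd[event] <- ifelse(is_mi[event], "mi_history", "stroke_history")
  fatal_event <- event & draw(rep(tab$cvd_fatality, n))
  post_death <- alive & !event &
    pop$cvd %in% c("mi_history", "stroke_history") &
    draw(rep(tab$post_event_mortality, n))
  pop$cvd[fatal_event | post_death] <- "death"
  pop
}

#' Advance the population by one simulated year
#'
#' Runs the seven-stage annual cycle described in [progression]. Signals are
#' counted from start-of-year behavior states before anything changes;
#' later stages see earlier stages' outputs (behavior changes affect
#' same-year weight transitions).
#'
#' @param pop An `agent_population`.
#' @param net A `social_network` over the same agents.
#' @param tab A [transition_table()].
#' @param cfg An [influence_config()].
#' @return The population after one year.
#' @export
step_year <- function(pop, net, tab, cfg = influence_config()) {
  stopifnot(nrow(pop) == net$n_nodes)
  alive0 <- pop$cvd != "death"
  signals <- lapply(
    stats::setNames(nm = c("smoking", "diet", "activity")),
    function(b) count_signals(behavior_healthy(pop, b), alive0, net))
  pop <- step_behaviors(pop, signals, tab, cfg)
  pop <- step_weight(pop, tab)
  pop <- step_comorbidity(pop, tab)
  pop <- step_glycemic(pop, tab)
  pop <- step_complications(pop, tab)
  survivors <- pop$cvd != "death"
  pop$age[survivors] <- pop$age[survivors] + 1L
  pop
}
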