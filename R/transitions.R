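#' Annual transition probabilities and their modifiers
#'
#' Collects every per-year transition probability of the eleven state charts
#' together with its modifiers (age band, sex, body weight, behaviors). The
#' published model prints only a subset of its rates: diet 0.03/0.03,
#' activity 0.049/0.049 and nephropathy 0.01/0.0003 are literature values;
#' every remaining default below is a NON-CALIBRATED placeholder, chosen to
#' be epidemiologically plausible (rising diabetes prevalence, weight
#' mediating the behavior effect) and fully overridable through the
#' configuration file.
#'
#' Age-banded rates are data frames with columns `age_lo`, `age_hi`, `p`
#' (or `mult`); bands must tile the age range without overlap. The CVD event
#' table additionally has a `sex` column.
#'
#' @param smoking_start,smoking_quit Age-banded annual probabilities of
#'   starting / quitting smoking (`data.frame(age_lo, age_hi, p)`).
#' @param diet_to_healthy,diet_to_unhealthy Annual diet transition rates.
#' @param activity_to_active,activity_to_inactive Annual activity rates.
#' @param weight_gain_base,weight_loss_base Base annual probabilities of
#'   normal-to-overweight and overweight-to-normal transitions.
#' @param weight_gain_mult_unhealthy_diet,weight_gain_mult_inactive
#'   Multipliers on weight gain for unhealthy diet / physical inactivity.
#' @param weight_loss_mult_healthy_diet,weight_loss_mult_active Multipliers
#'   on weight loss for healthy diet / activity.
#' @param htn_base,htn_age_mult,htn_overweight_mult,htn_remit Hypertension
#'   onset base rate, age-band multipliers (`data.frame(age_lo, age_hi,
#'   mult)`), overweight multiplier, and annual remission probability.
#' @param chol_base,chol_age_mult,chol_overweight_mult,chol_remit As above
#'   for hypercholesterolemia.
#' @param dm_none_to_pre_base,dm_pre_to_dm_base,dm_age_mult,
#'   dm_overweight_mult,dm_pre_to_none Glycemic chart: normal-to-prediabetes
#'   and prediabetes-to-diabetes base rates with age-band and overweight
#'   multipliers; prediabetes reversal rate (default 0). Diabetes is
#'   absorbing.
#' @param neph_onset,neph_remit Nephropathy onset / remission.
#' @param retina_onset,retina_to_blind Retinopathy onset (diabetics only)
#'   and progression to blindness (absorbing).
#' @param cvd_event Age- and sex-specific annual probability of a first
#'   cardiovascular event (`data.frame(sex, age_lo, age_hi, p)`).
#' @param cvd_mi_share Probability an event is a myocardial infarction
#'   (otherwise stroke).
#' @param cvd_fatality Probability an event is immediately fatal.
#' @param post_event_mortality Annual mortality for agents with MI/stroke
#'   history.
#' @return An object of class `transition_table`.
#' @export
transition_table <- function(
    smoking_start = age_band_table(c(20, 40, 60), c(39, 59, 200),
                                   c(0.020, 0.010, 0.005)),
    smoking_quit = age_band_table(c(20, 40, 60), c(39, 59, 200),
                                  c(0.020, 0.030, 0.040)),
    diet_to_healthy = 0.03, diet_to_unhealthy = 0.03,
    activity_to_active = 0.049, activity_to_inactive = 0.049,
    weight_gain_base = 0.08,
    weight_gain_mult_unhealthy_diet = 1.1,
    weight_gain_mult_inactive = 2.75,
    weight_loss_base = 0.06,
    weight_loss_mult_healthy_diet = 1.1,
    weight_loss_mult_active = 2.75,
    htn_base = 0.01,
    htn_age_mult = age_band_table(c(20, 40, 60), c(39, 59, 200),
                                  c(1, 2, 3), value = "mult"),
    htn_overweight_mult = 1.6,
    htn_remit = 0.01,
    chol_base = 0.01,
    chol_age_mult = age_band_table(c(20, 40, 60), c(39, 59, 200),
                                   c(1, 2, 3), value = "mult"),
    chol_overweight_mult = 1.5,
    chol_remit = 0.01,
    dm_none_to_pre_base = 0.01,
    dm_pre_to_dm_base = 0.012,
    dm_age_mult = age_band_table(c(20, 40, 60), c(39, 59, 200),
                                 c(1, 1.5, 2), value = "mult"),
    dm_overweight_mult = 3.0,
    dm_pre_to_none = 0,
    neph_onset = 0.01, neph_remit = 0.0003,
    retina_onset = 0.02, retina_to_blind = 0.02,
    cvd_event = cvd_event_table(),
    cvd_mi_share = 0.6,
    cvd_fatality = 0.3,
    post_event_mortality = 0.05) {
  tab <- list(
    smoking_start = smoking_start, smoking_quit = smoking_quit,
    diet_to_healthy = diet_to_healthy, diet_to_unhealthy = diet_to_unhealthy,
    activity_to_active = activity_to_active,
    activity_to_inactive = activity_to_inactive,
    weight_gain_base = weight_gain_base,
    weight_gain_mult_unhealthy_diet = weight_gain_mult_unhealthy_diet,
    weight_gain_mult_inactive = weight_gain_mult_inactive,
    weight_loss_base = weight_loss_base,
    weight_loss_mult_healthy_diet = weight_loss_mult_healthy_diet,
    weight_loss_mult_active = weight_loss_mult_active,
    htn_base = htn_base, htn_age_mult = htn_age_mult,
    htn_overweight_mult = htn_overweight_mult, htn_remit = htn_remit,
    chol_base = chol_base, chol_age_mult = chol_age_mult,
    chol_overweight_mult = chol_overweight_mult, chol_remit = chol_remit,
    dm_none_to_pre_base = dm_none_to_pre_base,
    dm_pre_to_dm_base = dm_pre_to_dm_base,
    dm_age_mult = dm_age_mult, dm_overweight_mult = dm_overweight_mult,
    dm_pre_to_none = dm_pre_to_none,
    neph_onset = neph_onset, neph_remit = neph_remit,
    retina_onset = retina_onset, retina_to_blind = retina_to_blind,
    cvd_event = cvd_event, cvd_mi_share = cvd_mi_share,
    cvd_fatality = cvd_fatality,
    post_event_mortality = post_event_mortality
  )
  class(tab) <- "transition_table"
  validate_transition_table(tab)
  tab
}

#' Build an age-band rate table
#'
#' @param age_lo,age_hi Inclusive band bounds in years.
#' @param values Rate or multiplier per band.
#' @param value Name of the value column, `"p"` or `"mult"`.
#' @param sex Optional sex column (recycled), for sex-specific tables.
#' @return A `data.frame` usable in [transition_table()].
#' @export
age_band_table <- function(age_lo, age_hi, values, value = "p", sex = NULL) {
  tab <- data.frame(age_lo = age_lo, age_hi = age_hi)
  tab[[value]] <- values
  if (!is.null(sex)) tab <- cbind(sex = sex, tab)
  tab
}

#' Default age- and sex-specific first-CVD-event probabilities
#'
#' NON-CALIBRATED placeholder table (the published model cites external risk
#' equations without printing them): male rates roughly double female rates,
#' both rising steeply with age.
#'
#' @return A `data.frame(sex, age_lo, age_hi, p)`.
#' @export
cvd_event_table <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 3),
    age_lo = rep(c(20, 40, 60), 2),
    age_hi = rep(c(39, 59, 200), 2),
    p = c(0.001, 0.005, 0.020, 0.0005, 0.003, 0.015)
  )
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("transition_table: '", name, "' must be a probability in [0, 1]",
         call. = FALSE)
  }
}

check_bands <- function(tab, name, value = "p") {
  need <- c("age_lo", "age_hi", value)
  if (!all(need %in% names(tab))) {
    stop("transition_table: '", name, "' needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tab$age_lo > tab$age_hi)) {
    stop("transition_table: '", name, "' has age_lo > age_hi", call. = FALSE)
  }
  split_by <- if ("sex" %in% names(tab)) split(tab, tab$sex) else list(tab)
  for (sub in split_by) {
    sub <- sub[order(sub$age_lo), ]
    if (nrow(sub) > 1 && any(sub$age_lo[-1] <= sub$age_hi[-nrow(sub)])) {
      stop("transition_table: '", name, "' has overlapping age bands",
           call. = FALSE)
    }
  }
  if (value == "p") check_prob(tab$p, name)
  if (value == "mult" && any(tab$mult <= 0)) {
    stop("transition_table: '", name, "' multipliers must be > 0",
         call. = FALSE)
  }
}

validate_transition_table <- function(tab) {
  scalar_probs <- c("diet_to_healthy", "diet_to_unhealthy",
                    "activity_to_active", "activity_to_inactive",
                    "weight_gain_base", "weight_loss_base",
                    "htn_base", "htn_remit", "chol_base", "chol_remit",
                    "dm_none_to_pre_base", "dm_pre_to_dm_base",
                    "dm_pre_to_none", "neph_onset", "neph_remit",
                    "retina_onset", "retina_to_blind", "cvd_mi_share",
                    "cvd_fatality", "post_event_mortality")
  for (f in scalar_probs) check_prob(tab[[f]], f)
  mults <- c("weight_gain_mult_unhealthy_diet", "weight_gain_mult_inactive",
             "weight_loss_mult_healthy_diet", "weight_loss_mult_active",
             "htn_overweight_mult", "chol_overweight_mult",
             "dm_overweight_mult")
  for (f in mults) {
    if (!is.numeric(tab[[f]]) || tab[[f]] <= 0) {
      stop("transition_table: '", f, "' must be > 0", call. = FALSE)
    }
  }
  check_bands(tab$smoking_start, "smoking_start")
  check_bands(tab$smoking_quit, "smoking_quit")
  check_bands(tab$htn_age_mult, "htn_age_mult", "mult")
  check_bands(tab$chol_age_mult, "chol_age_mult", "mult")
  check_bands(tab$dm_age_mult, "dm_age_mult", "mult")
  check_bands(tab$cvd_event, "cvd_event")
  invisible(tab)
}

#' @export
print.transition_table <- function(x, ...) {
  cat("Annual transition table\n")
  cat(sprintf("  diet %.3f/%.3f | activity %.3f/%.3f | nephropathy %.4f/%.4f\n",
              x$diet_to_unhealthy, x$diet_to_healthy,
              x$activity_to_inactive, x$activity_to_active,
              x$neph_onset, x$neph_remit))
  cat(sprintf("  weight gain %.3f (diet x%.2f, inactive x%.2f); loss %.3f (diet x%.2f, active x%.2f)\n",
              x$weight_gain_base, x$weight_gain_mult_unhealthy_diet,
              x$weight_gain_mult_inactive, x$weight_loss_base,
              x$weight_loss_mult_healthy_diet, x$weight_loss_mult_active))
  cat(sprintf("  glycemic none->pre %.3f, pre->dm %.3f (overweight x%.2f)\n",
              x$dm_none_to_pre_base, x$dm_pre_to_dm_base,
              x$dm_overweight_mult))
  invisible(x)
}

#' Zero out every transition rate
#'
#' Returns a copy of `tab` with all probabilities 0 except those named in
#' `keep`. Used to isolate a single chart in rate-recovery experiments.
#'
#' @param tab A [transition_table()].
#' @param keep Character vector of field names to leave untouched.
#' @return A `transition_table`.
#' @export
zero_transition_table <- function(tab = transition_table(), keep = character()) {
  scalar_probs <- c("diet_to_healthy", "diet_to_unhealthy",
                    "activity_to_active", "activity_to_inactive",
                    "weight_gain_base", "weight_loss_base",
                    "htn_base", "htn_remit", "chol_base", "chol_remit",
                    "dm_none_to_pre_base", "dm_pre_to_dm_base",
                    "dm_pre_to_none", "neph_onset", "neph_remit",
                    "retina_onset", "retina_to_blind",
                    "cvd_fatality", "post_event_mortality")
  for (f in setdiff(scalar_probs, keep)) tab[[f]] <- 0
  if (!("smoking_start" %in% keep)) tab$smoking_start$p <- 0
  if (!("smoking_quit" %in% keep)) tab$smoking_quit$p <- 0
  if (!("cvd_event" %in% keep)) tab$cvd_event$p <- 0
  tab
}

# Look up an age-banded value for each agent; ages outside every band get
# the nearest band's value (agents may outlive age_max).
band_lookup <- function(tab, age, sex = NULL, value = "p") {
  out <- numeric(length(age))
  if (!is.null(sex) && "sex" %in% names(tab)) {
    for (s in unique(tab$sex)) {
      sel <- sex == s
      if (any(sel)) {
        out[sel] <- band_lookup(tab[tab$sex == s, , drop = FALSE], age[sel],
                                NULL, value)
      }
    }
    return(out)
  }
  ord <- order(tab$age_lo)
  lo <- tab$age_lo[ord]; vals <- tab[[value]][ord]
  idx <- findInterval(age, lo)
  idx[idx < 1] <- 1L
  vals[idx]
}
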