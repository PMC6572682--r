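#' Baseline lifestyle intervention
#'
#' A one-shot program applied before the first simulated year: a fraction
#' `intensity` of the agents currently in the unhealthy state of the target
#' behavior is flipped to the healthy state ("control smoking" at intensity
#' 0.5 halves the smoking proportion). Flipped agents remain subject to
#' ordinary relapse transitions afterwards; the program is not sustained.
#'
#' @param target One of `"smoking"`, `"diet"`, `"activity"`.
#' @param intensity Fraction of the unhealthy pool to flip, in (0, 1\].
#' @return An object of class `intervention`.
#' @export
intervention <- function(target = c("smoking", "diet", "activity"),
                         intensity = 0.5) {
  target <- match.arg(target)
  if (!is.numeric(intensity) || length(intensity) != 1 ||
      is.na(intensity) || intensity <= 0 || intensity > 1) {
    stop("intensity must be in (0, 1]", call. = FALSE)
  }
  structure(list(target = target, intensity = intensity, timing = "baseline"),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat("Baseline intervention: ", x$target, " at intensity ",
      x$intensity, "\n", sep = "")
  invisible(x)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Apply a baseline intervention to a population
#'
#' Exactly `round(intensity * |U|)` agents (half away from zero) are sampled
#' uniformly without replacement from the unhealthy pool U of the target
#' behavior and flipped to the healthy state; nothing else changes.
#'
#' @param pop An `agent_population` (before the first simulated year).
#' @param iv An [intervention()].
#' @return The modified population.
#' @export
apply_intervention <- function(pop, iv) {
  stopifnot(inherits(iv, "intervention"))
  unhealthy <- which(!behavior_healthy(pop, iv$target) & pop$cvd != "death")
  n_flip <- round_half_up(iv$intensity * length(unhealthy))
  if (n_flip > 0) {
    flip <- sample(unhealthy, n_flip)
    healthy_state <- switch(iv$target, smoking = "not_smoking",
                            diet = "healthy", activity = "active")
    pop[[iv$target]][flip] <- healthy_state
  }
  pop
}
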