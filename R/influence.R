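#' Social-influence configuration
#'
#' The influence factor F converts the balance of positive (m) and negative
#' (n) signals an agent receives into a multiplier on its behavior-transition
#' probabilities: the unhealthy-to-healthy transition is multiplied by
#' F(m, n) and the reverse transition by the reciprocal influence F(n, m).
#'
#' @param smoothing `"laplace"` (default) uses F = (m + 1) / (n + 1), which
#'   is 1 for isolated agents and antisymmetric (F(m, n) * F(n, m) = 1);
#'   `"raw"` uses m / n with F = 1 when both counts are zero and F = f_cap
#'   when n = 0 < m.
#' @param f_cap Upper clamp on F (and 1/f_cap the lower clamp); must be
#'   >= 1. Prevents adjusted probabilities from saturating at 1 in uniformly
#'   healthy neighborhoods.
#' @param enabled Named logical vector switching influence per behavior;
#'   any of `smoking`, `diet`, `activity` may be set to `FALSE` to pin
#'   F = 1 for that behavior.
#' @return An object of class `influence_config`.
#' @export
influence_config <- function(smoothing = c("laplace", "raw"), f_cap = 5,
                             enabled = c(smoking = TRUE, diet = TRUE,
                                         activity = TRUE)) {
  smoothing <- match.arg(smoothing)
  if (!is.numeric(f_cap) || f_cap < 1) {
    stop("f_cap must be >= 1", call. = FALSE)
  }
  full <- c(smoking = TRUE, diet = TRUE, activity = TRUE)
  full[names(enabled)] <- enabled
  structure(list(smoothing = smoothing, f_cap = f_cap, enabled = full),
            class = "influence_config")
}

#' Social-influence factor from signal counts
#'
#' Vectorized over `m` and `n`. With Laplace smoothing,
#' F = clamp((m + 1) / (n + 1), 1/f_cap, f_cap); with raw counts,
#' F = clamp(m / n, 1/f_cap, f_cap), defined as 1 when m = n = 0 and as
#' f_cap when n = 0 < m.
#'
#' @param m,n Nonnegative counts of positive and negative signals.
#' @param cfg An [influence_config()].
#' @return Positive numeric vector of influence factors.
#' @export
influence_factor <- function(m, n, cfg = influence_config()) {
  stopifnot(all(m >= 0), all(n >= 0))
  if (cfg$smoothing == "laplace") {
    f <- (m + 1) / (n + 1)
  } else {
    f <- ifelse(n == 0, ifelse(m == 0, 1, cfg$f_cap), m / n)
  }
  pmin(pmax(f, 1 / cfg$f_cap), cfg$f_cap)
}

#' Adjust a transition probability by an influence factor
#'
#' Implements p* = min(1, p * F).
#'
#' @param p Base probability (or vector), each in \[0, 1\].
#' @param F Positive influence factor (scalar or vector).
#' @return Adjusted probability vector.
#' @export
adjust_probability <- function(p, F) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must be in [0, 1]", call. = FALSE)
  }
  stopifnot(all(F > 0))
  pmin(1, p * F)
}
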