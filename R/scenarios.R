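#' Specify a perturbation scenario
#'
#' Encodes the perturbation experiments the model is confronted with:
#' genetic knockouts of the methylation machinery, vitamin-C treatment,
#' the serum-to-2i medium switch time, and per-interval division times
#' for in vivo stage series.
#'
#' Knockout labels and their parameter effects:
#' \describe{
#'   \item{`none`}{no change.}
#'   \item{`dnmt1_or_uhrf1`}{loss of the maintenance machinery:
#'     `p2 = 0`.}
#'   \item{`dnmt3ab`}{loss of de novo methylation: `p1 = 0` (initial and
#'     final).}
#'   \item{`tet_any`}{loss of oxidation: `p3 = 0`.}
#'   \item{`aicda_or_tdg`}{no parameter change — deaminase/glycosylase
#'     loss leaves global kinetics untouched, encoded as an identity.}
#' }
#'
#' @param knockout One of the labels above.
#' @param vitc_p3_multiplier Fold scaling of `p3` by vitamin C, >= 1
#'   (1 = untreated); applied after the knockout, capped at 1.
#' @param switch_time Hours at which the serum parameters hand over to
#'   the 2i parameters (>= 0; default 0 = switch at experiment start).
#' @param division_times Optional numeric vector of per-phase
#'   hours-per-division overrides (e.g. in vivo stage intervals), all
#'   > 0.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(knockout = "none", vitc_p3_multiplier = 1,
                          switch_time = 0, division_times = NULL) {
  knockout <- match.arg(knockout,
                        c("none", "dnmt1_or_uhrf1", "dnmt3ab", "tet_any",
                          "aicda_or_tdg"))
  if (!is.numeric(vitc_p3_multiplier) || length(vitc_p3_multiplier) != 1L ||
      is.na(vitc_p3_multiplier) || vitc_p3_multiplier < 1)
    stop("vitc_p3_multiplier must be a single number >= 1", call. = FALSE)
  if (!is.numeric(switch_time) || length(switch_time) != 1L ||
      is.na(switch_time) || switch_time < 0)
    stop("switch_time must be a single nonnegative number of hours",
         call. = FALSE)
  if (!is.null(division_times) &&
      (!is.numeric(division_times) || anyNA(division_times) ||
       any(division_times <= 0)))
    stop("division_times must all be positive", call. = FALSE)
  structure(list(knockout = knockout,
                 vitc_p3_multiplier = vitc_p3_multiplier,
                 switch_time = switch_time,
                 division_times = division_times),
            class = "scenario_spec")
}

#' Apply a scenario's parameter transformation
#'
#' Transforms a base [rate_params()] according to the scenario: the
#' knockout zeroes the corresponding parameter (`aicda_or_tdg` changes
#' nothing), then vitamin C scales `p3` by the multiplier, capped at 1.
#'
#' @param base A [rate_params()].
#' @param spec A [scenario_spec()].
#' @return A transformed [rate_params()].
#' @examples
#' apply_scenario(serum_params(), scenario_spec("dnmt1_or_uhrf1"))
#' @export
apply_scenario <- function(base, spec) {
  validate_rate_params(base)
  stopifnot(inherits(spec, "scenario_spec"))
  p <- base
  switch(spec$knockout,
         none = NULL,
         dnmt1_or_uhrf1 = { p$p2 <- 0 },
         dnmt3ab = {
           p$p1 <- 0
           if (!is.null(p$p1_final)) p$p1_final <- 0
         },
         tet_any = { p$p3 <- 0 },
         aicda_or_tdg = NULL)
  p$p3 <- min(1, p$p3 * spec$vitc_p3_multiplier)
  p
}

#' Predict a trajectory under a perturbation scenario
#'
#' Builds the serum/2i phase schedule (serum parameters before
#' `switch_time`, 2i after), applies the scenario's transformation to
#' both phases, optionally overrides per-phase division times, and
#' delegates to [simulate_trajectory()].
#'
#' @param initial [dyad_state()] at time 0 (typically the serum steady
#'   state, [steady_state_dyads()]).
#' @param serum,two_i [rate_params()] for the two phases (see
#'   [serum_params()], [two_i_params()]).
#' @param spec A [scenario_spec()].
#' @param times Requested observation times, hours.
#' @param scale_mode Optional rescaling of the output levels
#'   (`"none"` or `"to_initial"`).
#' @return A `trajectory` (see [simulate_trajectory()]); its `levels`
#'   are rescaled when `scale_mode = "to_initial"`.
#' @export
predict_scenario <- function(initial, serum, two_i, spec, times,
                             scale_mode = "none") {
  stopifnot(inherits(spec, "scenario_spec"))
  scale_mode <- match.arg(scale_mode, c("none", "to_initial"))
  phases <- if (spec$switch_time <= 0) list(apply_scenario(two_i, spec))
    else list(apply_scenario(serum, spec), apply_scenario(two_i, spec))
  if (!is.null(spec$division_times)) {
    if (length(spec$division_times) != length(phases))
      stop("division_times must have one entry per phase", call. = FALSE)
    for (i in seq_along(phases))
      phases[[i]]$division_time <- spec$division_times[i]
  }
  sched <- if (length(phases) == 1L) phase_schedule(phases[[1]])
    else phase_schedule(phases, switch_times = spec$switch_time)
  tr <- simulate_trajectory(initial, sched, times)
  if (scale_mode == "to_initial") {
    ref <- tr$levels$five_mC[1L]
    if (ref <= 0) stop("initial 5mC level is zero; cannot scale",
                       call. = FALSE)
    tr$levels$five_mC <- tr$levels$five_mC / ref
    tr$levels$five_hmC <- tr$levels$five_hmC / ref
  }
  tr
}

#' Compare the demethylation kinetics of two trajectories
#'
#' Reports, per shared time point, the sign of the 5mC difference
#' `a - b`, and for each trajectory the time at which its 5mC level
#' first crosses fixed fractions (0.75, 0.5, 0.25) of its own initial
#' level (linear interpolation; `NA` when never crossed).
#'
#' @param a,b `trajectory` objects on the same requested time grid.
#' @param fractions Crossing fractions of the initial level.
#' @return List with `per_time` (data frame: `time_h`, `five_mC_a`,
#'   `five_mC_b`, `diff`, `sign`) and `crossings` (data frame:
#'   `fraction`, `time_a`, `time_b`).
#' @export
compare_rates <- function(a, b, fractions = c(0.75, 0.5, 0.25)) {
  stopifnot(inherits(a, "trajectory"), inherits(b, "trajectory"))
  if (length(a$times) != length(b$times) ||
      any(a$times != b$times))
    stop("trajectories must share the same time grid", call. = FALSE)
  d <- a$levels$five_mC - b$levels$five_mC
  per_time <- data.frame(time_h = a$times,
                         five_mC_a = a$levels$five_mC,
                         five_mC_b = b$levels$five_mC,
                         diff = d, sign = sign(d))
  cross_time <- function(tr, frac) {
    lv <- tr$boundary_levels[, "five_mC"]
    tt <- tr$boundary_times
    target <- lv[1L] * frac
    below <- which(lv <= target)
    if (length(below) == 0L) return(NA_real_)
    i <- below[1L]
    if (i == 1L) return(tt[1L])
    # linear interpolation inside the bracketing division interval
    t0 <- tt[i - 1L]; t1 <- tt[i]; y0 <- lv[i - 1L]; y1 <- lv[i]
    if (y0 == y1) return(t1)
    t0 + (target - y0) / (y1 - y0) * (t1 - t0)
  }
  crossings <- data.frame(
    fraction = fractions,
    time_a = vapply(fractions, function(fr) cross_time(a, fr), numeric(1)),
    time_b = vapply(fractions, function(fr) cross_time(b, fr), numeric(1)))
  list(per_time = per_time, crossings = crossings)
}
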