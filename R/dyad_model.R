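#' Construct a CpG dyad state vector
#'
#' Population fractions of the six unordered strand-pair states of a CpG
#' dyad, where each strand carries either no modification (u),
#' 5-methylcytosine (m) or 5-hydroxymethylcytosine (h). `mm` is the fully
#' methylated dyad (mCpG/GpCm), `um` the hemi-methylated dyad (mCpG/GpC,
#' both orientations pooled) and `uu` the unmethylated dyad (CpG/GpC);
#' `uh`, `mh` and `hh` carry hydroxymethylated strands.
#'
#' @param uu,um,mm,uh,mh,hh Population fractions in `[0, 1]`. Must sum to 1
#'   within `tol`.
#' @param tol Tolerance on the sum-to-one invariant for user-supplied
#'   states (default `1e-9`).
#' @return An object of class `dyad_state`: a named numeric vector with
#'   elements `uu`, `um`, `mm`, `uh`, `mh`, `hh`.
#' @examples
#' dyad_state(mm = 0.6, um = 0.25, uu = 0.15)
#' @export
dyad_state <- function(uu = 0, um = 0, mm = 0, uh = 0, mh = 0, hh = 0,
                       tol = 1e-9) {
  s <- c(uu = uu, um = um, mm = mm, uh = uh, mh = mh, hh = hh)
  validate_dyad_state(s, tol = tol)
  structure(s, class = "dyad_state")
}

#' @rdname dyad_state
#' @param state Object to validate.
#' @export
validate_dyad_state <- function(state, tol = 1e-9) {
  nm <- c("uu", "um", "mm", "uh", "mh", "hh")
  if (!is.numeric(state) || length(state) != 6L ||
      !all(nm %in% names(state)))
    stop("dyad state must be a named numeric vector with fields ",
         paste(nm, collapse = ", "), call. = FALSE)
  if (anyNA(state))
    stop("dyad state contains NA", call. = FALSE)
  if (any(state < -tol) || any(state > 1 + tol))
    stop("dyad state fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(state) - 1) > tol)
    stop(sprintf("dyad state fractions must sum to 1 (got %.12g)",
                 sum(state)), call. = FALSE)
  invisible(state)
}

#' @export
print.dyad_state <- function(x, ...) {
  cat("CpG dyad state (population fractions)\n")
  print(round(unclass(x), 6))
  lv <- strand_summary(x)
  cat(sprintf("strand 5mC = %.4f, strand 5hmC = %.4f\n",
              lv["five_mC"], lv["five_hmC"]))
  invisible(x)
}

#' Construct a per-division rate parameter set
#'
#' The three proportionality parameters of the model, each expressed per
#' average cell division: `p1`, the proportion of unmethylated CpG dyads
#' that acquire one methyl group (de novo methylation, DNMT3A/B); `p2`,
#' the proportion of hemi-methylated dyads restored to fully methylated
#' (maintenance methylation, DNMT1/UHRF1); and `p3`, the proportion of
#' 5mC strands oxidized to 5hmC (TET activity).
#'
#' `p1` may change gradually over a condition: when `p1_final` and
#' `p1_half_life` are supplied, `p1` relaxes exponentially from `p1`
#' (its initial value) to `p1_final` with the given half-life in hours;
#' see [p1_at()].
#'
#' @param p1 De novo methylation proportion per division, in `[0, 1]`.
#'   When a schedule is present this is the initial value.
#' @param p2 Maintenance methylation proportion per division, in `[0, 1]`.
#' @param p3 Oxidation (5mC to 5hmC) proportion per division, in `[0, 1]`.
#' @param division_time Hours per average cell division (> 0). Default 16 h
#'   (two rounds of replication in roughly 32 h).
#' @param p1_final Optional asymptotic `p1` for a gradual transition.
#' @param p1_half_life Optional half-life of the `p1` transition, hours
#'   (> 0). Required together with `p1_final`.
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(p1 = 0.4, p2 = 0.9, p3 = 0.02)
#' rate_params(p1 = 0.4, p2 = 0.8, p3 = 0.05,
#'             p1_final = 0.06, p1_half_life = 36)
#' @export
rate_params <- function(p1, p2, p3, division_time = 16,
                        p1_final = NULL, p1_half_life = NULL) {
  chk01 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(what, " must be a single value in [0, 1]", call. = FALSE)
  }
  chk01(p1, "p1"); chk01(p2, "p2"); chk01(p3, "p3")
  if (!is.numeric(division_time) || length(division_time) != 1L ||
      is.na(division_time) || division_time <= 0)
    stop("division_time must be a single positive number of hours",
         call. = FALSE)
  if (is.null(p1_final) != is.null(p1_half_life))
    stop("p1_final and p1_half_life must be supplied together",
         call. = FALSE)
  if (!is.null(p1_final)) {
    chk01(p1_final, "p1_final")
    if (!is.numeric(p1_half_life) || length(p1_half_life) != 1L ||
        is.na(p1_half_life) || p1_half_life <= 0)
      stop("p1_half_life must be a single positive number of hours",
           call. = FALSE)
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3,
                 division_time = division_time,
                 p1_final = p1_final, p1_half_life = p1_half_life),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  if (is.null(x$p1_final)) {
    cat(sprintf("rates per division: p1 = %g, p2 = %g, p3 = %g (T = %g h)\n",
                x$p1, x$p2, x$p3, x$division_time))
  } else {
    cat(sprintf(
      "rates per division: p1 = %g -> %g (t1/2 = %g h), p2 = %g, p3 = %g (T = %g h)\n",
      x$p1, x$p1_final, x$p1_half_life, x$p2, x$p3, x$division_time))
  }
  invisible(x)
}

validate_rate_params <- function(p) {
  if (!inherits(p, "rate_params"))
    stop("expected a rate_params object", call. = FALSE)
  invisible(p)
}

#' De novo methylation rate at a given time
#'
#' Evaluates the (possibly time-varying) de novo methylation proportion
#' `p1` at time `t` hours after the start of the condition. With a
#' schedule (`p1_final`, `p1_half_life`) set, `p1` relaxes exponentially:
#' `p1(t) = p1_final + (p1 - p1_final) * 2^(-t / p1_half_life)`. Without
#' a schedule the constant `p1` is returned.
#'
#' @param t Time in hours since the condition began (vectorized, >= 0).
#' @param p A [rate_params()] object.
#' @return Numeric vector of `p1` values, same length as `t`.
#' @examples
#' p <- rate_params(0.4, 0.8, 0.05, p1_final = 0.06, p1_half_life = 36)
#' p1_at(c(0, 36, 360), p)
#' @export
p1_at <- function(t, p) {
  validate_rate_params(p)
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("t must be nonnegative hours", call. = FALSE)
  if (is.null(p$p1_final)) return(rep(p$p1, length(t)))
  p$p1_final + (p$p1 - p$p1_final) * 2^(-t / p$p1_half_life)
}

#' Advance a dyad state by one cell division
#'
#' Applies, in order, the four per-division processes to the expected
#' population state: (1) oxidation — each 5mC strand becomes 5hmC with
#' probability `p3`; (2) semiconservative replication — each dyad is
#' replaced, in expectation, by a daughter pairing one parent strand
#' (drawn uniformly) with a nascent unmethylated strand; (3) maintenance —
#' post-replication hemi-methylated (m,u) dyads become fully methylated
#' with probability `p2` (hydroxymethylated (h,u) dyads are never
#' maintained); (4) de novo — post-replication unmethylated (u,u) dyads
#' become hemi-methylated with probability `p1`.
#'
#' With the default event order, no process creates `mh` or `hh` dyads
#' post-replication, so these fractions are zero in the output. As a
#' sensitivity option, `event_order = "oxidize_last"` applies oxidation
#' to the post-division pool instead (replication, maintenance, de novo,
#' then oxidation), which leaves `mh`/`hh` mass in the output.
#'
#' @param state A [dyad_state()].
#' @param p A [rate_params()] object giving `p2`, `p3` and (by default)
#'   `p1`; a time-varying `p1` can be supplied via `p1_value`.
#' @param p1_value The `p1` value to use for this division; defaults to
#'   `p$p1`. Use [p1_at()] to evaluate a schedule.
#' @param event_order `"oxidize_first"` (default: oxidation acts on the
#'   pre-replication methylated pool) or `"oxidize_last"`.
#' @return The expected [dyad_state()] after one division.
#' @examples
#' division_step(dyad_state(mm = 1), rate_params(0, 0, 0))  # replication only
#' @export
division_step <- function(state, p, p1_value = p$p1,
                          event_order = c("oxidize_first",
                                          "oxidize_last")) {
  validate_dyad_state(state)
  validate_rate_params(p)
  event_order <- match.arg(event_order)
  if (!is.numeric(p1_value) || length(p1_value) != 1L || is.na(p1_value) ||
      p1_value < 0 || p1_value > 1)
    stop("p1_value must be a single value in [0, 1]", call. = FALSE)
  p3 <- p$p3
  oxidize <- function(s) {
    # each m strand -> h with probability p3
    c(uu = s[["uu"]],
      um = s[["um"]] * (1 - p3),
      mm = s[["mm"]] * (1 - p3)^2,
      uh = s[["uh"]] + s[["um"]] * p3,
      mh = s[["mh"]] * (1 - p3) + s[["mm"]] * 2 * p3 * (1 - p3),
      hh = s[["hh"]] + s[["mh"]] * p3 + s[["mm"]] * p3^2)
  }
  replicate_and_methylate <- function(s) {
    # replication: daughter dyad pairs a uniformly drawn parent strand
    # with a nascent u strand
    m1 <- s[["mm"]] + (s[["um"]] + s[["mh"]]) / 2  # P(parent strand m)
    h1 <- s[["hh"]] + (s[["uh"]] + s[["mh"]]) / 2  # P(parent strand h)
    u1 <- s[["uu"]] + (s[["um"]] + s[["uh"]]) / 2  # P(parent strand u)
    # maintenance on (m,u), de novo on (u,u); (h,u) untouched
    c(uu = u1 * (1 - p1_value),
      um = m1 * (1 - p$p2) + u1 * p1_value,
      mm = m1 * p$p2,
      uh = h1, mh = 0, hh = 0)
  }
  out <- if (event_order == "oxidize_first")
    replicate_and_methylate(oxidize(unclass(state)))
  else oxidize(replicate_and_methylate(unclass(state)))
  # guard against tiny negative drift from floating cancellation
  out[out < 0 & out > -1e-12] <- 0
  out <- out / sum(out)
  structure(out, class = "dyad_state")
}

#' Strand-level global modification levels of a dyad state
#'
#' Maps a dyad state to the per-cytosine global fractions measured by
#' LC-MS: `five_mC = mm + um/2 + mh/2` and `five_hmC = hh + uh/2 + mh/2`
#' (each strand of a dyad counts once).
#'
#' @param state A [dyad_state()].
#' @return Named numeric vector `c(five_mC = , five_hmC = )`.
#' @examples
#' strand_summary(dyad_state(um = 1))  # one methylated strand of two
#' @export
strand_summary <- function(state) {
  validate_dyad_state(state)
  s <- unclass(state)
  c(five_mC = s[["mm"]] + 0.5 * s[["um"]] + 0.5 * s[["mh"]],
    five_hmC = s[["hh"]] + 0.5 * s[["uh"]] + 0.5 * s[["mh"]])
}

#' Closed-form steady state of the strand-level recursion
#'
#' For constant parameters (no `p1` schedule) the strand 5mC fraction `f`
#' and 5hmC fraction `h` obey the exact per-division recursion
#' `f' = (f (1 - p3)(1 + p2) + (1 - f - h) p1) / 2`,
#' `h' = (h + f p3) / 2`, whose fixed point is
#' `f* = p1 / (2 - (1 - p3)(1 + p2) + p1 (1 + p3))` and `h* = p3 f*`.
#'
#' @param p A [rate_params()] without a `p1` schedule.
#' @return Named numeric vector `c(five_mC = f*, five_hmC = h*)`.
#' @examples
#' steady_state(rate_params(0.4, 0.9, 0))  # f* = p1 / (1 - p2 + p1) = 0.8
#' @export
steady_state <- function(p) {
  validate_rate_params(p)
  if (!is.null(p$p1_final) && p$p1_final != p$p1)
    stop("steady_state requires constant parameters (no p1 schedule)",
         call. = FALSE)
  denom <- 2 - (1 - p$p3) * (1 + p$p2) + p$p1 * (1 + p$p3)
  f <- if (p$p1 == 0) 0 else p$p1 / denom
  c(five_mC = f, five_hmC = p$p3 * f)
}

#' Steady-state dyad state for constant parameters
#'
#' Full six-state fixed point of [division_step()] under constant
#' parameters, obtained by iterating the step to convergence. Useful for
#' initializing a condition at its equilibrium (e.g. serum ESCs) and for
#' generating equilibrium hairpin data.
#'
#' @param p A [rate_params()] without a `p1` schedule.
#' @param tol Convergence tolerance on the state (default `1e-13`).
#' @param max_iter Iteration cap.
#' @return A [dyad_state()].
#' @export
steady_state_dyads <- function(p, tol = 1e-13, max_iter = 5000L) {
  validate_rate_params(p)
  if (!is.null(p$p1_final) && p$p1_final != p$p1)
    stop("steady_state_dyads requires constant parameters", call. = FALSE)
  s <- dyad_state(uu = 1)
  for (i in seq_len(max_iter)) {
    s2 <- division_step(s, p)
    if (max(abs(s2 - s)) < tol) return(s2)
    s <- s2
  }
  warning("steady_state_dyads did not converge to ", tol, " in ",
          max_iter, " iterations")
  s
}

#' Build a contiguous phase schedule
#'
#' A schedule is a list of phases, each a list with elements `start`
#' (hours), `end` (hours or `Inf`) and `params` (a [rate_params()]).
#' Phases must tile `[0, Inf)` contiguously. `p1` schedules inside a
#' phase are evaluated relative to the phase start.
#'
#' @param ... [rate_params()] objects, one per phase in order.
#' @param switch_times Numeric vector of phase boundaries in hours
#'   (length one less than the number of phases), strictly increasing.
#' @return A list of phases, class `phase_schedule`.
#' @examples
#' serum <- rate_params(0.4, 0.9, 0.02)
#' two_i <- rate_params(0.4, 0.8, 0.05, p1_final = 0.06, p1_half_life = 36)
#' phase_schedule(serum, two_i, switch_times = 0)
#' @export
phase_schedule <- function(..., switch_times = numeric(0)) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "rate_params"))
    ps <- ps[[1]]
  if (length(ps) == 0L) stop("schedule needs at least one phase", call. = FALSE)
  lapply(ps, validate_rate_params)
  if (length(switch_times) != length(ps) - 1L)
    stop("need one switch time per phase boundary", call. = FALSE)
  if (length(switch_times) && (any(switch_times < 0) ||
      any(diff(c(0, switch_times)) < 0)))
    stop("switch times must be nonnegative and increasing", call. = FALSE)
  bounds <- c(0, switch_times, Inf)
  sched <- lapply(seq_along(ps), function(i)
    list(start = bounds[i], end = bounds[i + 1L], params = ps[[i]]))
  structure(sched, class = "phase_schedule")
}

phase_at <- function(schedule, t) {
  for (ph in schedule) if (t >= ph$start && t < ph$end) return(ph)
  schedule[[length(schedule)]]
}

#' Simulate a dyad-state trajectory across cell divisions
#'
#' Advances the expected dyad state division by division. Divisions occur
#' every `division_time` hours of the phase in which they start; the
#' parameters for a division (including `p1` evaluated via [p1_at()] at
#' the division's start, relative to its phase start) are those of that
#' phase. A division in progress at a phase switch completes under the
#' old phase's parameters; the new phase's division clock then starts at
#' that boundary. Global levels at arbitrary requested times are linearly
#' interpolated between division-boundary levels (the population is
#' unsynchronized, so interpolation stands in for the within-cycle
#' average).
#'
#' @param initial A [dyad_state()] at time 0.
#' @param schedule A [phase_schedule()] (or a single [rate_params()],
#'   treated as one phase from time 0).
#' @param times Nonnegative, sorted times (hours) at which to report
#'   global levels.
#' @param event_order Within-division event order, passed to
#'   [division_step()].
#' @return A `trajectory` object: list with `times`, `levels` (data frame
#'   with `time_h`, `five_mC`, `five_hmC` at the requested times),
#'   `boundary_times`, `states` (6-column matrix of dyad states at each
#'   division boundary, including time 0) and `boundary_levels`.
#' @examples
#' tr <- simulate_trajectory(dyad_state(mm = 1), rate_params(0, 0, 0),
#'                           times = c(0, 16, 32))
#' tr$levels
#' @export
simulate_trajectory <- function(initial, schedule, times,
                                event_order = "oxidize_first") {
  validate_dyad_state(initial)
  if (inherits(schedule, "rate_params")) schedule <- phase_schedule(schedule)
  if (!inherits(schedule, "phase_schedule") || length(schedule) == 0L)
    stop("schedule must be a non-empty phase_schedule", call. = FALSE)
  if (!is.numeric(times) || length(times) == 0L || anyNA(times) ||
      any(times < 0))
    stop("times must be nonnegative hours", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE))
    stop("times must be sorted increasing", call. = FALSE)
  t_end <- max(times)
  t <- 0
  state <- initial
  b_times <- 0
  states <- matrix(unclass(initial), nrow = 1,
                   dimnames = list(NULL, names(initial)))
  lv <- strand_summary(initial)
  b_levels <- matrix(lv, nrow = 1, dimnames = list(NULL, names(lv)))
  while (t < t_end) {
    ph <- phase_at(schedule, t)
    p1v <- p1_at(t - ph$start, ph$params)
    state <- division_step(state, ph$params, p1_value = p1v,
                           event_order = event_order)
    # a division in progress at a phase switch completes under the phase
    # in which it started; the next division uses the new phase
    t <- t + ph$params$division_time
    b_times <- c(b_times, t)
    states <- rbind(states, unclass(state))
    b_levels <- rbind(b_levels, strand_summary(state))
  }
  five_mC <- stats::approx(b_times, b_levels[, "five_mC"], xout = times,
                           rule = 2)$y
  five_hmC <- stats::approx(b_times, b_levels[, "five_hmC"], xout = times,
                            rule = 2)$y
  structure(list(times = times,
                 levels = data.frame(time_h = times, five_mC = five_mC,
                                     five_hmC = five_hmC),
                 boundary_times = b_times,
                 states = states,
                 boundary_levels = b_levels,
                 schedule = schedule),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d divisions over %g h, %d reported times\n",
              length(x$boundary_times) - 1L, max(x$boundary_times),
              length(x$times)))
  print(utils::head(x$levels, 8))
  if (nrow(x$levels) > 8) cat("...\n")
  invisible(x)
}

# Exact strand-level recursion used as the fast path for fitting.
# f' = (f (1-p3)(1+p2) + (1 - f - h) p1) / 2 ; h' = (h + f p3) / 2.
# Vectorized over parameter sets: p1sets is a function(t_phase) -> vector
# of p1 values (one per parameter set); p2, p3 are vectors.
# Returns levels at the requested times by the same boundary interpolation
# as simulate_trajectory, for a single-phase schedule starting at 0.
strand_levels_grid <- function(f0, h0, p2, p3, division_time, p1_fun, times) {
  n <- length(p2)
  t_end <- max(times)
  n_div <- if (t_end <= 0) 0L else ceiling(t_end / division_time - 1e-9)
  b_times <- seq(0, by = division_time, length.out = n_div + 1L)
  f <- rep(f0, n); h <- rep(h0, n)
  F <- matrix(0, nrow = n_div + 1L, ncol = n)
  H <- matrix(0, nrow = n_div + 1L, ncol = n)
  F[1L, ] <- f; H[1L, ] <- h
  for (k in seq_len(n_div)) {
    p1v <- p1_fun(b_times[k])
    fn <- (f * (1 - p3) * (1 + p2) + (1 - f - h) * p1v) / 2
    h <- (h + f * p3) / 2
    f <- fn
    F[k + 1L, ] <- f
    H[k + 1L, ] <- h
  }
  interp <- function(M) {
    out <- vapply(seq_len(n), function(j)
      stats::approx(b_times, M[, j], xout = times, rule = 2)$y,
      numeric(length(times)))
    matrix(out, nrow = length(times), ncol = n)
  }
  list(five_mC = interp(F), five_hmC = interp(H))
}
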