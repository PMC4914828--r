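#' Additive measurement-noise model for global levels
#'
#' Stands in for LC-MS replicate error: i.i.d. Gaussian noise of
#' standard deviation `sd` (level units; one percentage point = 0.01)
#' added to each measured level, clipped at 0.
#'
#' @param sd Standard deviation, >= 0. Default 0.01 (one percentage
#'   point).
#' @param seed Integer seed; every generator in the package is a pure
#'   function of its inputs and this seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sd = 0.01, seed = 1L) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("sd must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a noisy global 5mC/5hmC time course
#'
#' Simulates the true serum-to-2i trajectory (serum parameters before
#' `switch_time`, 2i parameters after) and adds i.i.d. Gaussian
#' measurement noise to both channels, clipping at 0. Deterministic
#' given the noise model's seed.
#'
#' @param serum,two_i [rate_params()] for the two phases.
#' @param switch_time Hours at which the medium switches (0 = series
#'   starts in 2i).
#' @param times Sampling times, hours.
#' @param noise A [noise_model()].
#' @param initial Optional [dyad_state()] at time 0; defaults to the
#'   serum steady state.
#' @param condition Label stored on the series.
#' @return An [observation_series()] with both channels.
#' @export
generate_timecourse <- function(serum, two_i, switch_time = 0, times,
                                noise = noise_model(),
                                initial = NULL, condition = "synthetic") {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(initial)) initial <- steady_state_dyads(serum)
  spec <- scenario_spec(switch_time = switch_time)
  tr <- predict_scenario(initial, serum, two_i, spec, times)
  with_seed(noise$seed, {
    mc <- pmax(0, tr$levels$five_mC +
                 stats::rnorm(length(times), 0, noise$sd))
    hmc <- pmax(0, tr$levels$five_hmC +
                  stats::rnorm(length(times), 0, noise$sd))
  })
  observation_series(times, mc, hmc, condition = condition)
}

#' Construct a hairpin-bisulfite dyad count table
#'
#' Read counts supporting the three bisulfite-observable dyad
#' categories: fully methylated (mCpG/GpCm), hemi-methylated (mCpG/GpC,
#' both orientations pooled) and unmethylated (CpG/GpC), together with
#' the conversion error rates of the assay. Bisulfite cannot
#' distinguish 5mC from 5hmC, so hydroxymethylated strands read as
#' methylated.
#'
#' @param n_full,n_hemi,n_unmeth Nonnegative integer counts, total > 0.
#' @param conversion_rate Probability a truly modified strand reads
#'   methylated, in `[0.9, 1]`.
#' @param nonconversion_rate Probability a truly unmethylated strand
#'   erroneously reads methylated, in `[0, 0.05]`.
#' @return A `hairpin_counts` object.
#' @export
hairpin_counts <- function(n_full, n_hemi, n_unmeth,
                           conversion_rate = 1, nonconversion_rate = 0) {
  counts <- c(n_full = n_full, n_hemi = n_hemi, n_unmeth = n_unmeth)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) <= 0) stop("total count must be > 0", call. = FALSE)
  if (!is.numeric(conversion_rate) || conversion_rate < 0.9 ||
      conversion_rate > 1)
    stop("conversion_rate must lie in [0.9, 1]", call. = FALSE)
  if (!is.numeric(nonconversion_rate) || nonconversion_rate < 0 ||
      nonconversion_rate > 0.05)
    stop("nonconversion_rate must lie in [0, 0.05]", call. = FALSE)
  structure(list(n_full = as.integer(n_full), n_hemi = as.integer(n_hemi),
                 n_unmeth = as.integer(n_unmeth),
                 conversion_rate = conversion_rate,
                 nonconversion_rate = nonconversion_rate),
            class = "hairpin_counts")
}

#' @export
print.hairpin_counts <- function(x, ...) {
  n <- x$n_full + x$n_hemi + x$n_unmeth
  cat(sprintf(
    "hairpin dyad counts (n = %d): full %d, hemi %d, unmeth %d (c = %g, e = %g)\n",
    n, x$n_full, x$n_hemi, x$n_unmeth, x$conversion_rate,
    x$nonconversion_rate))
  invisible(x)
}

# P(observed category | true category) for one dyad under per-strand
# misreads. Columns: true full / hemi / unmeth (methylated strands
# include 5hmC). Rows: observed full / hemi / unmeth.
hairpin_confusion <- function(c_rate, e_rate) {
  matrix(c(
    c_rate^2,           c_rate * e_rate,                       e_rate^2,
    2 * c_rate * (1 - c_rate),
    c_rate * (1 - e_rate) + (1 - c_rate) * e_rate,
    2 * e_rate * (1 - e_rate),
    (1 - c_rate)^2,     (1 - c_rate) * (1 - e_rate),           (1 - e_rate)^2
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("full", "hemi", "unmeth"),
                  c("full", "hemi", "unmeth")))
}

#' Simulate hairpin-bisulfite dyad counts from a dyad state
#'
#' Draws `n_reads` dyads from the population state, applies the
#' per-strand bisulfite misread model (a truly modified strand — 5mC or
#' 5hmC — reads methylated with probability `conversion_rate`; a truly
#' unmethylated strand reads methylated with probability
#' `nonconversion_rate`) and tallies the observed categories.
#' Deterministic given `seed`.
#'
#' @param state A [dyad_state()].
#' @param n_reads Number of dyad reads, > 0.
#' @param conversion_rate,nonconversion_rate Per-strand rates (see
#'   [hairpin_counts()]).
#' @param seed Integer seed.
#' @return A [hairpin_counts()] carrying the rates used.
#' @export
generate_hairpin_counts <- function(state, n_reads,
                                    conversion_rate = 1,
                                    nonconversion_rate = 0, seed = 1L) {
  validate_dyad_state(state)
  if (!is.numeric(n_reads) || length(n_reads) != 1L || n_reads < 1)
    stop("n_reads must be a positive count", call. = FALSE)
  # true category probabilities; h strands count as modified
  p_true <- c(full = state[["mm"]] + state[["mh"]] + state[["hh"]],
              hemi = state[["um"]] + state[["uh"]],
              unmeth = state[["uu"]])
  M <- hairpin_confusion(conversion_rate, nonconversion_rate)
  p_obs <- as.numeric(M %*% p_true)
  draw <- with_seed(seed,
                    stats::rmultinom(1L, size = as.integer(n_reads),
                                     prob = p_obs)[, 1L])
  hairpin_counts(draw[1L], draw[2L], draw[3L],
                 conversion_rate = conversion_rate,
                 nonconversion_rate = nonconversion_rate)
}

#' Estimate a dyad state from hairpin-bisulfite counts
#'
#' Inverts the per-strand misread model by a plug-in moment correction:
#' the observed category proportions are multiplied by the inverse of
#' the 3x3 misread confusion matrix built from the table's
#' `conversion_rate` and `nonconversion_rate`. Components pushed
#' negative by the correction are clipped at 0 (with a warning) and the
#' result renormalized. With perfect rates (1, 0) this reduces to the
#' plain proportion estimate.
#'
#' Bisulfite cannot separate 5hmC from 5mC, so by default all modified
#' mass is returned in the `mm`/`um` components. When an external
#' strand-level 5hmC fraction is supplied (e.g. from TAB-seq), each
#' modified strand is reassigned to 5hmC with the corresponding
#' probability, distributing mass into `uh`, `mh` and `hh`.
#'
#' @param counts A [hairpin_counts()].
#' @param five_hmC_level Optional strand 5hmC fraction used to apportion
#'   the modified-strand mass.
#' @return A [dyad_state()].
#' @export
estimate_state_from_counts <- function(counts, five_hmC_level = NULL) {
  stopifnot(inherits(counts, "hairpin_counts"))
  n <- counts$n_full + counts$n_hemi + counts$n_unmeth
  if (n <= 0) stop("total count must be > 0", call. = FALSE)
  obs <- c(counts$n_full, counts$n_hemi, counts$n_unmeth) / n
  M <- hairpin_confusion(counts$conversion_rate, counts$nonconversion_rate)
  est <- as.numeric(solve(M, obs))
  if (any(est < -1e-9))
    warning("moment correction produced negative fractions; clipped at 0")
  est[est < 0] <- 0
  est <- est / sum(est)
  s <- dyad_state(mm = est[1L], um = est[2L], uu = est[3L])
  if (!is.null(five_hmC_level)) {
    if (!is.numeric(five_hmC_level) || five_hmC_level < 0 ||
        five_hmC_level > 1)
      stop("five_hmC_level must lie in [0, 1]", call. = FALSE)
    mod_strand <- s[["mm"]] + s[["um"]] / 2     # modified-strand fraction
    if (mod_strand > 0 && five_hmC_level > 0) {
      rho <- min(1, five_hmC_level / mod_strand)  # P(modified strand is h)
      s <- dyad_state(
        uu = s[["uu"]],
        um = s[["um"]] * (1 - rho),
        uh = s[["um"]] * rho,
        mm = s[["mm"]] * (1 - rho)^2,
        mh = s[["mm"]] * 2 * rho * (1 - rho),
        hh = s[["mm"]] * rho^2)
    }
  }
  s
}

#' Stochastic per-dyad Monte-Carlo simulator
#'
#' Brute-force oracle for [division_step()]: follows `n_dyads`
#' individual dyads (one daughter per dyad, chosen uniformly at
#' replication) through the per-division processes — oxidation,
#' replication, maintenance, de novo — as independent Bernoulli events,
#' and tallies the six dyad states after each division. Deterministic
#' given `seed`.
#'
#' @param n_dyads Number of dyads, >= 1.
#' @param initial A [dyad_state()]; the starting dyads are drawn from
#'   it multinomially.
#' @param schedule A [phase_schedule()] or single [rate_params()].
#' @param divisions Number of divisions to simulate.
#' @param seed Integer seed.
#' @return Integer matrix, `(divisions + 1)` rows (including the
#'   initial tally) by 6 state columns.
#' @export
stochastic_dyad_simulator <- function(n_dyads, initial, schedule,
                                      divisions, seed = 1L) {
  validate_dyad_state(initial)
  if (inherits(schedule, "rate_params")) schedule <- phase_schedule(schedule)
  if (!is.numeric(n_dyads) || n_dyads < 1)
    stop("n_dyads must be >= 1", call. = FALSE)
  n_dyads <- as.integer(n_dyads)
  states <- c("uu", "um", "mm", "uh", "mh", "hh")
  # strand codes: 0 = u, 1 = m, 2 = h; column per strand
  strand_of <- list(uu = c(0, 0), um = c(0, 1), mm = c(1, 1),
                    uh = c(0, 2), mh = c(1, 2), hh = c(2, 2))
  with_seed(seed, {
    draw <- stats::rmultinom(1L, n_dyads, prob = unclass(initial)[states])
    s1 <- integer(n_dyads); s2 <- integer(n_dyads)
    at <- 0L
    for (k in seq_along(states)) {
      cnt <- draw[k, 1L]
      if (cnt > 0) {
        idx <- (at + 1L):(at + cnt)
        s1[idx] <- strand_of[[k]][1L]
        s2[idx] <- strand_of[[k]][2L]
        at <- at + cnt
      }
    }
    tally <- function(s1, s2) {
      lo <- pmin(s1, s2); hi <- pmax(s1, s2)
      c(uu = sum(lo == 0 & hi == 0), um = sum(lo == 0 & hi == 1),
        mm = sum(lo == 1 & hi == 1), uh = sum(lo == 0 & hi == 2),
        mh = sum(lo == 1 & hi == 2), hh = sum(lo == 2 & hi == 2))
    }
    out <- matrix(0L, nrow = divisions + 1L, ncol = 6L,
                  dimnames = list(NULL, states))
    out[1L, ] <- tally(s1, s2)
    t <- 0
    for (d in seq_len(divisions)) {
      ph <- phase_at(schedule, t)
      p <- ph$params
      p1v <- p1_at(t - ph$start, p)
      # oxidation: each m strand -> h w.p. p3
      ox1 <- s1 == 1L & stats::runif(n_dyads) < p$p3
      ox2 <- s2 == 1L & stats::runif(n_dyads) < p$p3
      s1[ox1] <- 2L; s2[ox2] <- 2L
      # replication: keep one parent strand uniformly, pair with u
      keep1 <- stats::runif(n_dyads) < 0.5
      parent <- ifelse(keep1, s1, s2)
      s1 <- parent; s2 <- integer(n_dyads)   # nascent strand unmethylated
      # maintenance: (m,u) -> (m,m) w.p. p2
      maint <- s1 == 1L & stats::runif(n_dyads) < p$p2
      s2[maint] <- 1L
      # de novo: (u,u) -> (m,u) w.p. p1
      denovo <- s1 == 0L & s2 == 0L & stats::runif(n_dyads) < p1v
      s2[denovo] <- 1L
      out[d + 1L, ] <- tally(s1, s2)
      t <- t + p$division_time
    }
    out
  })
}
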