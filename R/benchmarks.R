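#' Synthetic-recovery benchmarks of the fitting pipeline
#'
#' Three end-to-end benchmarks that generate synthetic data under the
#' default study conditions and measure how well the MMSE fit recovers
#' what went in. They are the package's reproducible analogs of the
#' headline fit-quality and parameter estimates: the serum-to-2i
#' refit quality (R^2), the serum maintenance efficiency (p2, expected
#' ~90%), and the vitamin-C fold-increase of oxidation (p3 ratio,
#' expected ~4).
#'
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @param n_seeds Number of noise replicates for the R^2 benchmark.
#' @param noise_sd Gaussian measurement noise sd (level units).
#' @param times Sampling times in hours.
#' @param grid_n Grid resolution for the free axes.
#' @return `benchmark_fit_quality()`: list with `r2` (per-replicate
#'   R^2) and `median_r2`. `benchmark_p2_recovery()`: list with
#'   `p2_percent` (recovered maintenance efficiency, percent),
#'   `p2_true_percent` and the fit. `benchmark_vitc_p3_ratio()`: list
#'   with `ratio`, per-condition fitted `p3`, and the true multiplier.
#' @name benchmarks
NULL

#' @rdname benchmarks
#' @export
benchmark_fit_quality <- function(seed = 1L, n_seeds = 10L,
                                  noise_sd = 0.01,
                                  times = c(0, 4, 8, 16, 24, 32, 48, 72,
                                            96, 168, 240, 336),
                                  grid_n = 41L) {
  serum <- serum_params()
  two_i <- two_i_params()
  init <- steady_state_dyads(serum)
  spec <- fit_spec(c("p1_final", "p2"), base = two_i, grid_n = grid_n)
  r2 <- vapply(seq_len(n_seeds), function(k) {
    obs <- generate_timecourse(
      serum, two_i, times = times,
      noise = noise_model(sd = noise_sd, seed = seed * 1000L + k),
      initial = init)
    grid_search(obs, init, spec)$r_squared
  }, numeric(1))
  list(r2 = r2, median_r2 = stats::median(r2))
}

#' @rdname benchmarks
#' @param n_reads Hairpin read depth used to estimate the initial dyad
#'   state.
#' @export
benchmark_p2_recovery <- function(seed = 1L, noise_sd = 0.01,
                                  times = seq(0, 168, by = 24),
                                  n_reads = 1e5, grid_n = 101L) {
  serum <- serum_params()
  truth_state <- steady_state_dyads(serum)
  # initial dyad state as measured by (simulated) hairpin bisulfite
  hp <- generate_hairpin_counts(truth_state, n_reads,
                                seed = seed * 1000L + 1L)
  init <- estimate_state_from_counts(
    hp, five_hmC_level = strand_summary(truth_state)[["five_hmC"]])
  # steady-state serum course: cells are held in serum
  obs <- generate_timecourse(
    serum, serum, times = times,
    noise = noise_model(sd = noise_sd, seed = seed * 1000L + 2L),
    initial = truth_state)
  spec <- fit_spec("p2", base = serum, grid_n = grid_n)
  fit <- grid_search(obs, init, spec)
  list(p2_percent = 100 * fit$params$p2,
       p2_true_percent = 100 * serum$p2,
       fit = fit)
}

#' @rdname benchmarks
#' @param multiplier True fold increase of `p3` applied to the vitamin-C
#'   condition's generator.
#' @export
benchmark_vitc_p3_ratio <- function(seed = 1L, noise_sd = 0.005,
                                    times = c(0, 4, 8, 16, 24, 32, 48,
                                              72, 96, 168, 240, 336),
                                    multiplier = 4, grid_n = 101L) {
  serum <- serum_params()
  two_i <- two_i_params()
  vitc <- vitc_params(two_i, multiplier)
  init <- steady_state_dyads(serum)
  fit_one <- function(cond_params, k) {
    obs <- generate_timecourse(
      serum, cond_params, times = times,
      noise = noise_model(sd = noise_sd, seed = seed * 1000L + k),
      initial = init)
    spec <- fit_spec("p3", base = two_i, grid_n = grid_n,
                     channels = c("five_mC", "five_hmC"))
    grid_search(obs, init, spec)$params$p3
  }
  p3_2i <- fit_one(two_i, 11L)
  p3_vitc <- fit_one(vitc, 12L)
  list(ratio = p3_vitc / p3_2i, p3_2i = p3_2i, p3_vitc = p3_vitc,
       multiplier_true = multiplier)
}
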