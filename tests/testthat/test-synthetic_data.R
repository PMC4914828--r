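test_that("noiseless generated time courses equal the model trajectory", {
  times <- course_times()
  obs <- generate_timecourse(serum_params(), two_i_params(),
                             times = times, noise = noise_model(sd = 0))
  init <- steady_state_dyads(serum_params())
  tr <- predict_scenario(init, serum_params(), two_i_params(),
                         scenario_spec(), times)
  expect_equal(obs$five_mC, tr$levels$five_mC)
  expect_equal(obs$five_hmC, tr$levels$five_hmC)
})

test_that("generators are pure functions of inputs and seed", {
  times <- course_times()
  nm <- noise_model(sd = 0.01, seed = 42)
  a <- generate_timecourse(serum_params(), two_i_params(), times = times,
                           noise = nm)
  b <- generate_timecourse(serum_params(), two_i_params(), times = times,
                           noise = nm)
  expect_identical(a, b)
  c <- generate_timecourse(serum_params(), two_i_params(), times = times,
                           noise = noise_model(sd = 0.01, seed = 43))
  expect_false(identical(a$five_mC, c$five_mC))
  s <- steady_state_dyads(serum_params())
  h1 <- generate_hairpin_counts(s, 1000, seed = 7)
  h2 <- generate_hairpin_counts(s, 1000, seed = 7)
  expect_identical(h1, h2)
  t1 <- stochastic_dyad_simulator(500, s, serum_params(), 3, seed = 5)
  t2 <- stochastic_dyad_simulator(500, s, serum_params(), 3, seed = 5)
  expect_identical(t1, t2)
  # generators do not disturb the caller RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_timecourse(
    serum_params(), two_i_params(), times = times, noise = nm))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("replicate means of noisy courses converge to the model value", {
  times <- c(0, 48, 336)
  init <- steady_state_dyads(serum_params())
  truth <- predict_scenario(init, serum_params(), two_i_params(),
                            scenario_spec(), times)$levels$five_mC
  n_rep <- 400
  sd <- 0.01
  sims <- vapply(seq_len(n_rep), function(r)
    generate_timecourse(serum_params(), two_i_params(), times = times,
                        noise = noise_model(sd = sd, seed = r))$five_mC,
    numeric(length(times)))
  means <- rowMeans(sims)
  expect_true(all(abs(means - truth) < 3 * sd / sqrt(n_rep)))
})

test_that("hairpin counts from a pure state with perfect chemistry are pure", {
  hp <- generate_hairpin_counts(dyad_state(mm = 1), 1000, seed = 3)
  expect_equal(hp$n_full, 1000L)
  expect_equal(hp$n_hemi + hp$n_unmeth, 0L)
})

test_that("nonconversion inflates hemi reads as 2e(1-e) per dyad", {
  e <- 0.01
  n <- 2e5
  hp <- generate_hairpin_counts(dyad_state(uu = 1), n,
                                nonconversion_rate = e, seed = 11)
  p_hemi <- 2 * e * (1 - e)
  se <- sqrt(p_hemi * (1 - p_hemi) / n)
  expect_lt(abs(hp$n_hemi / n - p_hemi), 3 * se)
  expect_lt(hp$n_full / n, 1e-3)  # e^2 = 1e-4
})

test_that("hairpin category proportions converge to the dyad fractions", {
  s <- dyad_state(mm = 0.6, um = 0.25, uu = 0.15)
  n <- 1e6
  hp <- generate_hairpin_counts(s, n, seed = 13)
  p <- c(0.6, 0.25, 0.15)
  obs <- c(hp$n_full, hp$n_hemi, hp$n_unmeth) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(obs - p) < 3 * se))
})

test_that("state estimation inverts perfect-chemistry counts exactly", {
  est <- estimate_state_from_counts(hairpin_counts(1000, 0, 0))
  expect_equal(est[["mm"]], 1)
  est2 <- estimate_state_from_counts(hairpin_counts(600, 250, 150))
  expect_equal(unclass(est2)[c("mm", "um", "uu")],
               c(mm = 0.6, um = 0.25, uu = 0.15))
})

test_that("hairpin round trip recovers the generating state within 3 SE", {
  s <- dyad_state(mm = 0.6, um = 0.25, uu = 0.15)
  n <- 1e5
  hp <- generate_hairpin_counts(s, n, seed = 29)
  est <- estimate_state_from_counts(hp)
  se <- sqrt(c(0.6, 0.25, 0.15) * (1 - c(0.6, 0.25, 0.15)) / n)
  expect_true(all(abs(unclass(est)[c("mm", "um", "uu")] -
                        c(0.6, 0.25, 0.15)) < 3 * se))
})

test_that("round-trip estimation error shrinks as 1/sqrt(n)", {
  s <- dyad_state(mm = 0.5, um = 0.3, uu = 0.2)
  tv_err <- function(n, seeds) {
    mean(vapply(seeds, function(sd) {
      hp <- generate_hairpin_counts(s, n, conversion_rate = 0.98,
                                    nonconversion_rate = 0.01, seed = sd)
      est <- estimate_state_from_counts(hp)
      sum(abs(unclass(est) - unclass(s))) / 2
    }, numeric(1)))
  }
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) tv_err(n, 1:30),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  # consistent estimator: error at n = 1e5 close to sqrt(100)-fold
  # smaller than at n = 1e3 (within a factor of 3 of the exact scaling)
  expect_lt(errs[3], errs[1] / sqrt(100) * 3)
})

test_that("moment correction beats raw proportions under imperfect chemistry", {
  s <- dyad_state(mm = 0.6, um = 0.25, uu = 0.15)
  n <- 1e5
  hp <- generate_hairpin_counts(s, n, conversion_rate = 0.95,
                                nonconversion_rate = 0.02, seed = 31)
  est <- estimate_state_from_counts(hp)
  raw <- c(hp$n_full, hp$n_hemi, hp$n_unmeth) /
    (hp$n_full + hp$n_hemi + hp$n_unmeth)
  truth <- c(0.6, 0.25, 0.15)
  tv_corrected <- sum(abs(unclass(est)[c("mm", "um", "uu")] - truth)) / 2
  tv_raw <- sum(abs(raw - truth)) / 2
  expect_lt(tv_corrected, tv_raw)
})

test_that("hydroxymethylated strands read as methylated and can be re-apportioned", {
  s <- dyad_state(mm = 0.4, mh = 0.2, uh = 0.1, uu = 0.3)
  hp <- generate_hairpin_counts(s, 1e5, seed = 37)
  # full reads = mm + mh + hh mass, hemi = um + uh
  expect_lt(abs(hp$n_full / 1e5 - 0.6), 0.01)
  expect_lt(abs(hp$n_hemi / 1e5 - 0.1), 0.01)
  est_plain <- estimate_state_from_counts(hp)
  expect_equal(est_plain[["uh"]] + est_plain[["mh"]] + est_plain[["hh"]], 0)
  # supplying the true strand 5hmC level moves mass into h states
  h_level <- strand_summary(s)[["five_hmC"]]
  est_h <- estimate_state_from_counts(hp, five_hmC_level = h_level)
  expect_equal(strand_summary(est_h)[["five_hmC"]], h_level,
               tolerance = 0.02)
  expect_equal(strand_summary(est_h)[["five_mC"]],
               strand_summary(s)[["five_mC"]], tolerance = 0.02)
})

test_that("all-zero rates turn fully methylated dyads into hemi tallies", {
  out <- stochastic_dyad_simulator(1000, dyad_state(mm = 1),
                                   rate_params(0, 0, 0), 1, seed = 41)
  expect_equal(unname(out[2, "um"]), 1000L)
})

test_that("stochastic dyad simulator agrees with the deterministic step", {
  # multinomial goodness-of-fit of the tallies against the expectation
  # step, per replicate at the 0.1% level (a per-category 3-SE rule
  # applied to 20 x 6 marginals would false-alarm by construction)
  set.seed(97)
  n <- 1e5
  for (rep in 1:20) {
    s0 <- random_dyad_state()
    p <- random_rate_params()
    divisions <- 3L
    tall <- stochastic_dyad_simulator(n, s0, p, divisions,
                                      seed = 1000 + rep)
    s <- s0
    for (d in seq_len(divisions)) s <- division_step(s, p)
    expected <- unclass(s) * n
    keep <- expected > 5          # structurally-zero categories excluded
    expect_true(all(tall[divisions + 1L, !keep] <= 10))
    chisq <- sum((tall[divisions + 1L, keep] - expected[keep])^2 /
                   expected[keep])
    expect_lt(chisq, stats::qchisq(0.999, df = sum(keep) - 1L))
  }
})

test_that("count table validation rejects malformed input", {
  expect_error(hairpin_counts(0, 0, 0), "> 0")
  expect_error(hairpin_counts(-1, 2, 3), "nonnegative")
  expect_error(hairpin_counts(1, 2, 3, conversion_rate = 0.5),
               "conversion_rate")
  expect_error(hairpin_counts(1, 2, 3, nonconversion_rate = 0.2),
               "nonconversion_rate")
  expect_error(noise_model(sd = -1), "nonnegative")
})
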