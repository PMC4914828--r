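make_obs <- function(params, initial, times = course_times(),
                     noise_sd = 0, seed = 1, with_hmc = TRUE) {
  tr <- simulate_trajectory(initial, params, times)
  set.seed(seed)
  mc <- pmax(0, tr$levels$five_mC + stats::rnorm(length(times), 0, noise_sd))
  hmc <- pmax(0, tr$levels$five_hmC +
                stats::rnorm(length(times), 0, noise_sd))
  observation_series(times, mc, if (with_hmc) hmc else NULL)
}

test_that("mmse objective is zero for noiseless self-generated data", {
  p <- two_i_params()
  init <- steady_state_dyads(serum_params())
  obs <- make_obs(p, init)
  expect_lt(mmse_objective(p, obs, init), 1e-12)
})

test_that("a constant prediction offset yields mse = d^2", {
  p <- rate_params(0, 1, 0)  # perfect maintenance: prediction constant
  f0 <- 0.5
  init <- dyad_state(mm = f0, uu = 1 - f0)
  d <- 0.03
  obs <- observation_series(c(0, 16, 32), rep(f0 + d, 3))
  expect_equal(mmse_objective(p, obs, init), d^2, tolerance = 1e-12)
})

test_that("mse of noisy self-generated data approaches the noise variance", {
  p <- two_i_params()
  init <- steady_state_dyads(serum_params())
  n <- 400
  times <- seq(0, 336, length.out = n)
  sigma <- 0.01
  obs <- make_obs(p, init, times = times, noise_sd = sigma, seed = 3)
  mse <- mmse_objective(p, obs, init)
  # chi^2_n spread: sd of the mean of n squared residuals is sigma^2*sqrt(2/n)
  expect_lt(abs(mse - sigma^2), 3 * sigma^2 * sqrt(2 / n))
})

test_that("grid search recovers on-grid truth exactly from noiseless data", {
  init <- steady_state_dyads(serum_params())
  truth <- rate_params(0.05, 0.75, 0.05, division_time = 16)
  obs <- make_obs(truth, init)
  spec <- fit_spec(c("p2", "p3"), base = truth, grid_n = 21L,
                   refine = FALSE)
  fit <- grid_search(obs, init, spec)
  expect_equal(fit$params$p2, 0.75)
  expect_equal(fit$params$p3, 0.05)
  expect_lt(fit$mmse, 1e-12)
})

test_that("a halving curve identifies complete maintenance loss", {
  init <- steady_state_dyads(serum_params())
  truth <- rate_params(0, 0, 0)
  obs <- make_obs(truth, init, times = c(0, 16, 32, 48, 64))
  spec <- fit_spec("p2", base = rate_params(0, 0.5, 0), grid_n = 101L)
  fit <- grid_search(obs, init, spec)
  expect_equal(fit$params$p2, 0, tolerance = 1e-6)
})

test_that("grid search is deterministic and ties break lexicographically", {
  init <- steady_state_dyads(serum_params())
  truth <- rate_params(0.05, 0.75, 0.05)
  obs <- make_obs(truth, init, noise_sd = 0.01, seed = 9)
  spec <- fit_spec(c("p2", "p3"), base = truth, grid_n = 15L)
  f1 <- grid_search(obs, init, spec)
  f2 <- grid_search(obs, init, spec)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$surface$mmse, f2$surface$mmse)
  # all-flat surface: p2 has no effect when there is nothing to maintain
  flat_obs <- observation_series(c(0, 16, 32), c(0, 0, 0))
  flat_spec <- fit_spec("p2", base = rate_params(0, 0.5, 0), grid_n = 11L,
                        refine = FALSE)
  flat <- grid_search(flat_obs, dyad_state(uu = 1), flat_spec)
  expect_true(flat$degenerate)
  expect_equal(flat$params$p2, 0)  # smallest tuple wins the tie
})

test_that("an empty free set returns the evaluation at the fixed point", {
  p <- two_i_params()
  init <- steady_state_dyads(serum_params())
  obs <- make_obs(p, init)
  spec <- fit_spec(character(0), base = p)
  fit <- grid_search(obs, init, spec)
  expect_lt(fit$mmse, 1e-12)
  expect_equal(fit$params$p2, p$p2)
})

test_that("r_squared matches its definition and rejects degenerate input", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 4), obs), 0)
  pred <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(r_squared(pred, obs),
               1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2))
  expect_error(r_squared(c(1, 2), c(3, 3)), "constant")
  expect_error(r_squared(1, 1), "length")
})

test_that("refit of a realistically noisy conversion course explains >= 99% of variance", {
  init <- steady_state_dyads(serum_params())
  obs <- make_obs(two_i_params(), init, noise_sd = 0.01, seed = 5)
  spec <- fit_spec(c("p1_final", "p2"), base = two_i_params(),
                   grid_n = 41L)
  fit <- grid_search(obs, init, spec)
  expect_gte(fit$r_squared, 0.99)
})

test_that("parameter recovery: median error of p2 and p1_final below 0.05", {
  init <- steady_state_dyads(serum_params())
  truth <- two_i_params()
  err_p2 <- err_p1f <- numeric(20)
  spec <- fit_spec(c("p1_final", "p2"), base = truth, grid_n = 21L)
  for (r in 1:20) {
    obs <- make_obs(truth, init, noise_sd = 0.01, seed = 100 + r)
    fit <- grid_search(obs, init, spec)
    err_p2[r] <- abs(fit$params$p2 - truth$p2)
    err_p1f[r] <- abs(fit$params$p1_final - truth$p1_final)
  }
  expect_lte(median(err_p2), 0.05)
  expect_lte(median(err_p1f), 0.05)
})

test_that("noiseless MMSE profile along p2 is unimodal about the truth", {
  init <- steady_state_dyads(serum_params())
  truth <- rate_params(0.05, 0.75, 0.05)
  obs <- make_obs(truth, init)
  spec <- fit_spec("p2", base = truth, grid_n = 101L, refine = FALSE)
  fit <- grid_search(obs, init, spec)
  mmse <- fit$surface$mmse
  i_min <- which.min(mmse)
  expect_equal(fit$surface$p2[i_min], 0.75)
  expect_true(all(diff(mmse[seq_len(i_min)]) <= 1e-15))
  expect_true(all(diff(mmse[i_min:length(mmse)]) >= -1e-15))
})

test_that("local minima detection matches a brute-force neighbor scan", {
  # constructed 2D surface with two hand-placed basins
  ax <- seq(0, 1, length.out = 21)
  grid <- expand.grid(p2 = ax, p3 = ax, KEEP.OUT.ATTRS = FALSE)
  grid$mmse <- with(grid, pmin((p2 - 0.2)^2 + (p3 - 0.2)^2 + 0.001,
                               (p2 - 0.8)^2 + (p3 - 0.7)^2))
  attr(grid, "axes") <- list(p2 = ax, p3 = ax)
  minima <- find_local_minima(grid)
  expect_equal(nrow(minima), 2L)
  # sorted by mmse ascending: deeper basin (at 0.8, 0.7) first
  expect_equal(minima$p2, c(0.8, 0.2))
  expect_equal(minima$p3, c(0.7, 0.2))
  expect_true(all(diff(minima$mmse) >= 0))
  # brute-force oracle: enumerate all grid points and their neighbors
  brute <- sapply(seq_len(nrow(grid)), function(i) {
    nb <- abs(grid$p2 - grid$p2[i]) < 1e-9 &
      abs(abs(grid$p3 - grid$p3[i]) - diff(ax)[1]) < 1e-9
    nb <- nb | (abs(grid$p3 - grid$p3[i]) < 1e-9 &
                  abs(abs(grid$p2 - grid$p2[i]) - diff(ax)[1]) < 1e-9)
    all(grid$mmse[i] <= grid$mmse[nb])
  })
  expect_setequal(
    paste(minima$p2, minima$p3),
    paste(grid$p2[brute], grid$p3[brute]))
  # a single-basin surface yields exactly one minimum
  grid1 <- expand.grid(p2 = ax, p3 = ax, KEEP.OUT.ATTRS = FALSE)
  grid1$mmse <- with(grid1, (p2 - 0.5)^2 + (p3 - 0.5)^2)
  attr(grid1, "axes") <- list(p2 = ax, p3 = ax)
  expect_equal(nrow(find_local_minima(grid1)), 1L)
})

test_that("adjacent plateau minima are merged into one reported minimum", {
  ax <- seq(0, 1, length.out = 11)
  grid <- expand.grid(p2 = ax, KEEP.OUT.ATTRS = FALSE)
  mmse <- rep(1, 11)
  mmse[4:6] <- 0.1  # three-cell flat valley floor
  grid$mmse <- mmse
  attr(grid, "axes") <- list(p2 = ax)
  minima <- find_local_minima(grid)
  expect_equal(nrow(minima), 1L)
  expect_equal(minima$p2, ax[4])  # lexicographically smallest of the floor
})

test_that("series normalization rescales and preserves the argmin", {
  obs <- observation_series(c(0, 16, 32), c(0.8, 0.6, 0.5),
                            c(0.02, 0.03, 0.02))
  sc <- normalize_series(obs, "to_initial")
  expect_equal(sc$five_mC, c(1, 0.75, 0.625))
  expect_equal(sc$five_hmC, c(0.025, 0.0375, 0.025))
  expect_identical(normalize_series(obs, "none"), obs)
  expect_error(normalize_series(observation_series(0:2, c(0, 1, 2)),
                                "to_initial"), "positive")
  sr <- normalize_series(obs, "to_reference", reference = 0.4)
  expect_equal(sr$five_mC, c(2, 1.5, 1.25))
  # scale invariance of the fit: scaled and unscaled data give the same
  # best parameters when predictions are scaled consistently
  init <- steady_state_dyads(serum_params())
  truth <- rate_params(0.05, 0.75, 0.05)
  raw <- make_obs(truth, init, noise_sd = 0.005, seed = 21)
  scaled <- normalize_series(raw, "to_initial")
  spec <- fit_spec("p2", base = truth, grid_n = 41L, refine = FALSE)
  fit_raw <- grid_search(raw, init, spec)
  fit_scaled <- grid_search(scaled, init, spec)
  expect_equal(fit_scaled$params$p2, fit_raw$params$p2, tolerance = 0.03)
})

test_that("fast-decay 5mC-only fits are degenerate: p2 trades against p3", {
  # PGC-like series: steep decay fitted on 5mC alone admits multiple
  # local minima along the ridge (1 - p3)(1 + p2) ~ const whose 5hmC
  # predictions differ strongly
  init <- steady_state_dyads(serum_params())
  truth <- rate_params(0.02, 0.30, 0.05, division_time = 16)
  times <- seq(0, 96, by = 12)
  obs <- make_obs(truth, init, times = times, noise_sd = 0.01, seed = 17,
                  with_hmc = FALSE)
  spec <- fit_spec(c("p2", "p3"), base = truth, grid_n = 41L,
                   refine = FALSE)
  fit <- grid_search(obs, init, spec)
  minima <- fit$minima
  expect_gte(nrow(minima), 2L)
  # the minima mimic 5mC equally well...
  top <- minima[1:2, ]
  preds <- lapply(seq_len(nrow(top)), function(i) {
    p <- rate_params(truth$p1, top$p2[i], top$p3[i])
    simulate_trajectory(init, p, times)$levels
  })
  rmse_mC <- vapply(preds, function(lv)
    sqrt(mean((lv$five_mC - obs$five_mC)^2)), numeric(1))
  expect_true(all(rmse_mC < 0.03))
  # ...but predict different 5hmC dynamics (>2-fold at peak between the
  # extreme-p3 minima)
  lo <- which.min(minima$p3); hi <- which.max(minima$p3)
  peak <- vapply(c(lo, hi), function(i) {
    p <- rate_params(truth$p1, minima$p2[i], minima$p3[i])
    max(simulate_trajectory(init, p, times)$levels$five_hmC)
  }, numeric(1))
  expect_gt(max(peak) / min(peak), 2)
})
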