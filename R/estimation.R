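#' Construct an observation series of global modification levels
#'
#' A measured (or synthetic) time course of global 5mC — and optionally
#' 5hmC — levels, as produced by LC-MS quantification. Levels are
#' fractions of CpG-context cytosines (a "percentage point" of level is
#' 0.01 on this scale), or arbitrary scaled units when `scale_mode` is
#' not `"none"`.
#'
#' @param times Strictly increasing times in hours.
#' @param five_mC Observed global 5mC levels, >= 0, same length.
#' @param five_hmC Optional observed global 5hmC levels, >= 0.
#' @param condition Condition label (single string).
#' @param scale_mode One of `"none"`, `"to_initial"`, `"to_reference"`;
#'   records how the levels have been / should be scaled before fitting.
#' @return An `observation_series` object (list).
#' @export
observation_series <- function(times, five_mC, five_hmC = NULL,
                               condition = "obs", scale_mode = "none") {
  scale_mode <- match.arg(scale_mode, c("none", "to_initial", "to_reference"))
  if (!is.numeric(times) || length(times) < 1L || anyNA(times))
    stop("times must be numeric and non-empty", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.numeric(five_mC) || length(five_mC) != length(times) ||
      anyNA(five_mC) || any(five_mC < 0))
    stop("five_mC must be nonnegative and match times in length",
         call. = FALSE)
  if (!is.null(five_hmC)) {
    if (!is.numeric(five_hmC) || length(five_hmC) != length(times) ||
        anyNA(five_hmC) || any(five_hmC < 0))
      stop("five_hmC must be nonnegative and match times in length",
           call. = FALSE)
  }
  structure(list(times = as.numeric(times), five_mC = as.numeric(five_mC),
                 five_hmC = if (is.null(five_hmC)) NULL else
                   as.numeric(five_hmC),
                 condition = as.character(condition)[1L],
                 scale_mode = scale_mode),
            class = "observation_series")
}

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf("observation series '%s': %d points over %g-%g h (scale: %s)\n",
              x$condition, length(x$times), min(x$times), max(x$times),
              x$scale_mode))
  invisible(x)
}

#' Rescale an observation series
#'
#' `to_initial` divides the levels by the series' earliest `five_mC`
#' value (both the 5mC and 5hmC channels are divided by that same 5mC
#' reference, so channel ratios are preserved); `to_reference` divides by
#' a supplied reference level; `none` returns the series unchanged.
#'
#' @param obs An [observation_series()].
#' @param mode `"none"`, `"to_initial"` or `"to_reference"`.
#' @param reference Reference level for `"to_reference"` (> 0).
#' @return A rescaled [observation_series()] with `scale_mode` recorded.
#' @export
normalize_series <- function(obs, mode = obs$scale_mode, reference = NULL) {
  stopifnot(inherits(obs, "observation_series"))
  mode <- match.arg(mode, c("none", "to_initial", "to_reference"))
  if (mode == "none") return(obs)
  ref <- if (mode == "to_initial") obs$five_mC[1L] else reference
  if (is.null(ref) || !is.numeric(ref) || length(ref) != 1L ||
      is.na(ref) || ref <= 0)
    stop("scaling reference level must be a single positive number",
         call. = FALSE)
  obs$five_mC <- obs$five_mC / ref
  if (!is.null(obs$five_hmC)) obs$five_hmC <- obs$five_hmC / ref
  obs$scale_mode <- mode
  obs
}

#' Specify a model fit
#'
#' Declares which rate parameters are free, their bounds, the grid
#' resolution per free axis and whether the best grid point is polished
#' by a bounded derivative-free local search. All other parameters are
#' taken from `base`. By default only the 5mC channel enters the
#' objective — 5hmC is reserved as a held-out prediction — but
#' `channels = c("five_mC", "five_hmC")` requests a joint fit.
#'
#' @param free Character vector naming the free parameters, a subset of
#'   `p1` (alias `p1_initial`), `p1_final`, `p1_half_life`, `p2`, `p3`.
#' @param base A [rate_params()] supplying the fixed values.
#' @param bounds Named list of `c(lower, upper)` per free parameter.
#'   Defaults: `[0, 1]` for the proportions, `[1, 500]` h for
#'   `p1_half_life`.
#' @param grid_n Grid points per free axis (single value or named
#'   vector), >= 2. Default 101.
#' @param refine Polish the best grid point with bounded
#'   Nelder-Mead/L-BFGS-B local search (default `TRUE`).
#' @param channels Objective channels, `"five_mC"` and/or `"five_hmC"`.
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(free, base, bounds = list(), grid_n = 101L,
                     refine = TRUE, channels = "five_mC") {
  canonical <- c(p1_initial = "p1", p1 = "p1", p1_final = "p1_final",
                 p1_half_life = "p1_half_life", p2 = "p2", p3 = "p3")
  if (length(free) < 0L || anyNA(free) || !all(free %in% names(canonical)))
    stop("free parameters must be among: ",
         paste(unique(names(canonical)), collapse = ", "), call. = FALSE)
  free <- unique(unname(canonical[free]))
  validate_rate_params(base)
  channels <- match.arg(channels, c("five_mC", "five_hmC"),
                        several.ok = TRUE)
  default_bounds <- list(p1 = c(0, 1), p1_final = c(0, 1),
                         p1_half_life = c(1, 500), p2 = c(0, 1),
                         p3 = c(0, 1))
  b <- default_bounds
  for (nm in names(bounds)) {
    cn <- canonical[[nm]]
    if (is.null(cn)) stop("unknown bound: ", nm, call. = FALSE)
    v <- bounds[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] >= v[2])
      stop("bounds for ", nm, " must be c(lower, upper)", call. = FALSE)
    if (cn != "p1_half_life" && (v[1] < 0 || v[2] > 1))
      stop("bounds for ", cn, " must lie within [0, 1]", call. = FALSE)
    b[[cn]] <- v
  }
  if (is.null(names(grid_n))) {
    grid_n <- stats::setNames(rep(as.integer(grid_n), length(free)), free)
  } else {
    gn <- stats::setNames(rep(101L, length(free)), free)
    gn[unname(canonical[names(grid_n)])] <- as.integer(grid_n)
    grid_n <- gn
  }
  if (length(free) && any(grid_n[free] < 2L))
    stop("grid resolution must be >= 2 per free axis", call. = FALSE)
  structure(list(free = free, base = base, bounds = b[free],
                 grid_n = grid_n, refine = isTRUE(refine),
                 channels = channels),
            class = "fit_spec")
}

# Resolve a matrix of free-parameter values (rows = candidate sets) plus
# the fixed base into the per-set vectors the strand recursion needs.
resolve_param_sets <- function(theta, spec) {
  base <- spec$base
  n <- nrow(theta)
  get <- function(nm, default) {
    if (nm %in% colnames(theta)) theta[, nm] else rep(default, n)
  }
  p1i <- get("p1", base$p1)
  has_sched <- !is.null(base$p1_final) || "p1_final" %in% colnames(theta) ||
    "p1_half_life" %in% colnames(theta)
  p1f <- get("p1_final", if (is.null(base$p1_final)) base$p1 else
    base$p1_final)
  hl <- get("p1_half_life",
            if (is.null(base$p1_half_life)) 1 else base$p1_half_life)
  list(p1_initial = p1i,
       p1_fun = if (has_sched)
         function(t) p1f + (p1i - p1f) * 2^(-t / hl)
       else function(t) p1i,
       p2 = get("p2", base$p2), p3 = get("p3", base$p3))
}

# Scale predicted/observed channels per scale_mode, identically on both
# sides: to_initial divides each side by its own value at the earliest
# observation time (5mC channel as reference).
apply_scale <- function(obs_mC, obs_hmC, pred_mC, pred_hmC, scale_mode,
                        reference = NULL) {
  if (scale_mode == "none")
    return(list(obs_mC = obs_mC, obs_hmC = obs_hmC,
                pred_mC = pred_mC, pred_hmC = pred_hmC))
  if (scale_mode == "to_initial") {
    oref <- obs_mC[1L]
    pref <- pred_mC[1L, , drop = TRUE]
  } else {
    if (is.null(reference) || reference <= 0)
      stop("to_reference scaling needs a positive reference", call. = FALSE)
    oref <- reference
    pref <- rep(reference, ncol(pred_mC))
  }
  if (oref <= 0) stop("initial observed level is zero; cannot scale",
                      call. = FALSE)
  if (any(pref <= 0)) pref[pref <= 0] <- NA_real_
  list(obs_mC = obs_mC / oref,
       obs_hmC = if (is.null(obs_hmC)) NULL else obs_hmC / oref,
       pred_mC = sweep(pred_mC, 2, pref, "/"),
       pred_hmC = sweep(pred_hmC, 2, pref, "/"))
}

# Vectorized objective over a matrix of free-parameter candidates.
mmse_eval <- function(theta, obs, initial, spec) {
  ps <- resolve_param_sets(theta, spec)
  lv0 <- strand_summary(initial)
  pred <- strand_levels_grid(lv0[["five_mC"]], lv0[["five_hmC"]],
                             ps$p2, ps$p3, spec$base$division_time,
                             ps$p1_fun, obs$times)
  sc <- apply_scale(obs$five_mC, obs$five_hmC, pred$five_mC, pred$five_hmC,
                    obs$scale_mode)
  res2 <- (sc$pred_mC - sc$obs_mC)^2
  n_res <- length(obs$times)
  if ("five_hmC" %in% spec$channels) {
    if (is.null(obs$five_hmC))
      stop("joint objective requested but series has no five_hmC",
           call. = FALSE)
    res2 <- rbind(res2, (sc$pred_hmC - sc$obs_hmC)^2)
    n_res <- n_res * 2L
  }
  colSums(res2) / n_res
}

#' Mean square error of a parameter set against an observation series
#'
#' Mean over observation times of the squared difference between the
#' model-predicted and observed global 5mC level (and 5hmC when a joint
#' objective is requested), after applying the series' `scale_mode`
#' identically to prediction and observation. This is the quantity
#' minimized by [grid_search()].
#'
#' @param params A [rate_params()] candidate.
#' @param obs An [observation_series()] (>= 1 point).
#' @param initial [dyad_state()] at the first model time (t = 0).
#' @param channels Objective channels, as in [fit_spec()].
#' @return Nonnegative scalar (squared level units).
#' @export
mmse_objective <- function(params, obs, initial, channels = "five_mC") {
  validate_rate_params(params)
  stopifnot(inherits(obs, "observation_series"))
  if (length(obs$times) < 1L)
    stop("need at least one observation", call. = FALSE)
  spec <- fit_spec(character(0), base = params, channels = channels)
  unname(mmse_eval(matrix(numeric(0), nrow = 1L, ncol = 0L),
                   obs, initial, spec))
}

#' Coefficient of determination of predicted vs observed levels
#'
#' `1 - SS_res / SS_tot` with `SS_tot` taken about the observed mean.
#'
#' @param predicted,observed Equal-length numeric vectors (>= 2 points);
#'   `observed` must not be constant.
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2L)
    stop("predicted and observed must have equal length >= 2",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed series is constant; R^2 undefined", call. = FALSE)
  1 - sum((predicted - observed)^2) / ss_tot
}

#' Fit rate parameters by exhaustive MMSE grid search
#'
#' Evaluates the mean-square-error objective over the full Cartesian grid
#' of the free parameters, optionally polishes the best grid point with a
#' bounded derivative-free local search, and scans the retained error
#' surface for distinct local minima (parameter-identifiability
#' diagnostics). Deterministic: ties among equal-MMSE grid points are
#' broken toward the lexicographically smallest parameter tuple (in the
#' order `p1`, `p1_final`, `p1_half_life`, `p2`, `p3`).
#'
#' @param obs An [observation_series()] with >= 3 points.
#' @param initial A [dyad_state()] at the series start.
#' @param spec A [fit_spec()].
#' @return A `fit_result` list: `params` (best-fit [rate_params()]),
#'   `mmse`, `r_squared` (on the fitted channels, at the fit scale),
#'   `surface` (long-format data frame: free-parameter columns + `mmse`),
#'   `minima` (data frame of distinct local minima, MMSE-ascending),
#'   `spec`, `degenerate` (`TRUE` when the whole surface is flat).
#' @export
grid_search <- function(obs, initial, spec) {
  stopifnot(inherits(obs, "observation_series"), inherits(spec, "fit_spec"))
  validate_dyad_state(initial)
  if (length(obs$times) < 3L)
    stop("fitting needs at least 3 observations", call. = FALSE)
  par_order <- c("p1", "p1_final", "p1_half_life", "p2", "p3")
  free <- intersect(par_order, spec$free)
  if (length(free) == 0L) {
    theta <- matrix(numeric(0), nrow = 1L, ncol = 0L)
    mmse <- mmse_eval(theta, obs, initial, spec)
    surface <- data.frame(mmse = mmse)
    best_free <- stats::setNames(numeric(0), character(0))
  } else {
    axes <- lapply(free, function(nm)
      seq(spec$bounds[[nm]][1], spec$bounds[[nm]][2],
          length.out = spec$grid_n[[nm]]))
    names(axes) <- free
    grid <- do.call(expand.grid,
                    c(axes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE))
    theta <- as.matrix(grid)
    mmse <- mmse_eval(theta, obs, initial, spec)
    surface <- cbind(grid, mmse = mmse)
    attr(surface, "axes") <- axes
    ord <- do.call(order, c(list(mmse), unname(grid[free])))
    best_free <- stats::setNames(as.numeric(theta[ord[1L], free]), free)
  }
  degenerate <- length(mmse) > 1L &&
    diff(range(mmse[is.finite(mmse)])) < .Machine$double.eps * 100
  best_mmse <- min(mmse)
  if (spec$refine && length(free) > 0L) {
    obj1 <- function(x) {
      th <- matrix(x, nrow = 1L, dimnames = list(NULL, free))
      mmse_eval(th, obs, initial, spec)
    }
    lower <- vapply(spec$bounds[free], `[`, numeric(1), 1L)
    upper <- vapply(spec$bounds[free], `[`, numeric(1), 2L)
    opt <- stats::optim(best_free, obj1, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e4))
    if (is.finite(opt$value) && opt$value <= best_mmse) {
      best_free <- stats::setNames(opt$par, free)
      best_mmse <- opt$value
    }
  }
  best_params <- realize_params(best_free, spec)
  pred <- predict_levels(best_params, obs, initial, spec$base$division_time)
  sc <- apply_scale(obs$five_mC, obs$five_hmC,
                    matrix(pred$five_mC, ncol = 1),
                    matrix(pred$five_hmC, ncol = 1), obs$scale_mode)
  pred_v <- sc$pred_mC[, 1L]; obs_v <- sc$obs_mC
  if ("five_hmC" %in% spec$channels && !is.null(obs$five_hmC)) {
    pred_v <- c(pred_v, sc$pred_hmC[, 1L]); obs_v <- c(obs_v, sc$obs_hmC)
  }
  r2 <- if (stats::var(obs_v) > 0) r_squared(pred_v, obs_v) else NA_real_
  minima <- if (length(free) > 0L) find_local_minima(surface) else
    surface
  structure(list(params = best_params, mmse = best_mmse, r_squared = r2,
                 surface = surface, minima = minima, spec = spec,
                 degenerate = degenerate),
            class = "fit_result")
}

# Turn a named vector of free-parameter values + fit_spec base into a
# full rate_params object.
realize_params <- function(values, spec) {
  base <- spec$base
  v <- function(nm, default) if (nm %in% names(values))
    unname(values[[nm]]) else default
  has_sched <- !is.null(base$p1_final) ||
    any(c("p1_final", "p1_half_life") %in% names(values))
  rate_params(
    p1 = v("p1", base$p1),
    p2 = v("p2", base$p2),
    p3 = v("p3", base$p3),
    division_time = base$division_time,
    p1_final = if (has_sched)
      v("p1_final", if (is.null(base$p1_final)) base$p1 else base$p1_final)
      else NULL,
    p1_half_life = if (has_sched)
      v("p1_half_life",
        if (is.null(base$p1_half_life)) 1 else base$p1_half_life)
      else NULL)
}

# Model levels for one parameter set at the observation times.
predict_levels <- function(params, obs, initial, division_time) {
  lv0 <- strand_summary(initial)
  sp <- fit_spec(character(0), base = params)
  ps <- resolve_param_sets(matrix(numeric(0), nrow = 1L, ncol = 0L), sp)
  pr <- strand_levels_grid(lv0[["five_mC"]], lv0[["five_hmC"]],
                           ps$p2, ps$p3, params$division_time,
                           ps$p1_fun, obs$times)
  list(five_mC = pr$five_mC[, 1L], five_hmC = pr$five_hmC[, 1L])
}

#' @export
print.fit_result <- function(x, ...) {
  cat("MMSE fit\n  best: ")
  print(x$params)
  cat(sprintf("  mmse = %.6g, R^2 = %.4f, %d local minim%s on the grid\n",
              x$mmse, x$r_squared, nrow(x$minima),
              if (nrow(x$minima) == 1L) "um" else "a"))
  invisible(x)
}

#' Locate distinct local minima on a gridded error surface
#'
#' A grid point is a candidate local minimum when its MMSE is less than
#' or equal to every axis-neighbor (one step along each free-parameter
#' axis). Grid-adjacent candidates (flat plateaus and one-cell-wide
#' valley floors) are merged into a single component, represented by its
#' lowest, lexicographically smallest point; a flat component is kept
#' only when every neighbor outside it is strictly higher (a plateau
#' that leaks downhill is not a minimum). Multiple surviving minima
#' signal parameter degeneracy: distinct parameter combinations that
#' explain the fitted 5mC data equally well while predicting different
#' (testable) 5hmC dynamics.
#'
#' @param surface Long-format surface from [grid_search()]:
#'   free-parameter columns plus `mmse`, carrying an `axes` attribute.
#' @return Data frame of minima (free-parameter columns + `mmse`),
#'   sorted by MMSE ascending.
#' @export
find_local_minima <- function(surface) {
  axes <- attr(surface, "axes")
  free <- setdiff(names(surface), "mmse")
  if (is.null(axes))
    axes <- lapply(surface[free], function(x) sort(unique(x)))
  dims <- vapply(axes, length, integer(1))
  idx <- mapply(function(col, ax) match(col, ax),
                surface[free], axes, SIMPLIFY = FALSE)
  arr <- array(NA_real_, dim = dims)
  pos <- as.matrix(as.data.frame(idx))
  arr[pos] <- surface$mmse
  nd <- length(dims)
  tol <- max(1e-15,
             1e-12 * diff(range(c(surface$mmse[is.finite(surface$mmse)],
                                  0))))
  n_pts <- nrow(surface)
  mult <- cumprod(c(1L, dims[-nd]))
  lin <- as.integer(1L + (pos - 1L) %*% mult)  # linear grid index per row
  row_of <- integer(prod(dims)); row_of[lin] <- seq_len(n_pts)
  # candidate minima and, per row, the linear indices of axis neighbors
  is_min <- rep(TRUE, n_pts)
  nb_lin <- matrix(NA_integer_, nrow = n_pts, ncol = 2L * nd)
  slot <- 0L
  for (d in seq_len(nd)) {
    for (step in c(-1L, 1L)) {
      nb <- pos
      nb[, d] <- nb[, d] + step
      ok <- nb[, d] >= 1L & nb[, d] <= dims[d]
      nb_val <- rep(Inf, n_pts)
      nb_val[ok] <- arr[nb[ok, , drop = FALSE]]
      is_min <- is_min & surface$mmse <= nb_val + tol
      slot <- slot + 1L
      nb_lin[ok, slot] <- as.integer(1L + (nb[ok, , drop = FALSE] - 1L)
                                     %*% mult)
    }
  }
  min_rows <- which(is_min)
  if (length(min_rows) == 0L)
    return(surface[integer(0), , drop = FALSE])
  # merge grid-adjacent candidates (Chebyshev distance 1) into
  # components via union-find over direct neighbors
  cand_of <- integer(prod(dims))          # linear index -> candidate id
  cand_of[lin[min_rows]] <- seq_along(min_rows)
  parent <- seq_along(min_rows)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1L:1L), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0L, , drop = FALSE]
  for (i in seq_along(min_rows)) {
    p0 <- pos[min_rows[i], ]
    for (o in seq_len(nrow(offsets))) {
      q <- p0 + offsets[o, ]
      if (any(q < 1L) || any(q > dims)) next
      j <- cand_of[as.integer(1L + (q - 1L) %*% mult)]
      if (j > 0L) {
        ri <- find_root(i); rj <- find_root(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_along(min_rows), find_root, integer(1))
  # a component is a minimum only if every axis neighbor outside it is
  # strictly higher than the component's level (a flat plateau leaking
  # into non-minimal terrain is rejected)
  in_min_set <- logical(n_pts); in_min_set[min_rows] <- TRUE
  keep <- vapply(unique(comp), function(cc) {
    rows <- min_rows[comp == cc]
    v <- min(surface$mmse[rows])
    for (r in rows) {
      for (q in nb_lin[r, ]) {
        if (is.na(q)) next
        qr <- row_of[q]
        if (qr > 0L && in_min_set[qr] && comp[match(qr, min_rows)] == cc)
          next  # internal neighbor
        qv <- if (qr > 0L) surface$mmse[qr] else Inf
        if (qv <= v + tol) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  comps <- unique(comp)[keep]
  if (length(comps) == 0L)
    return(surface[integer(0), , drop = FALSE])
  reps <- vapply(comps, function(cc) {
    rows <- min_rows[comp == cc]
    sub <- surface[rows, , drop = FALSE]
    ord <- do.call(order, c(list(sub$mmse), unname(sub[free])))
    rows[ord[1L]]
  }, integer(1))
  out <- surface[reps, , drop = FALSE]
  out <- out[order(out$mmse), , drop = FALSE]
  rownames(out) <- NULL
  out
}
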