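#' Read and write global-level time-course TSV files
#'
#' UTF-8 tab-separated files with header columns `time_h`, `five_mC` and
#' optionally `five_hmC` and `condition`; decimal points, no thousands
#' separators. Times in days are accepted on read via a `time_d` column
#' and converted to hours. Values are written with `%.10g` formatting,
#' so write-then-read round-trips are exact for values of up to 10
#' significant digits.
#'
#' @param path File path.
#' @return `read_timecourse_tsv()` returns an [observation_series()]
#'   sorted by time; `write_timecourse_tsv()` returns `path`
#'   invisibly.
#' @export
read_timecourse_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  classes <- stats::setNames(rep(NA, length(hdr)), hdr)
  if ("condition" %in% hdr) classes[["condition"]] <- "character"
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = classes,
                          stringsAsFactors = FALSE)
  if ("time_d" %in% names(df) && !"time_h" %in% names(df))
    df$time_h <- df$time_d * 24
  for (col in c("time_h", "five_mC"))
    if (!col %in% names(df))
      stop("time-course file is missing required column '", col, "'",
           call. = FALSE)
  if (anyDuplicated(df$time_h))
    stop("duplicate times in time-course file: ",
         paste(unique(df$time_h[duplicated(df$time_h)]), collapse = ", "),
         call. = FALSE)
  df <- df[order(df$time_h), , drop = FALSE]
  if (any(df$five_mC < 0) ||
      ("five_hmC" %in% names(df) && any(df$five_hmC < 0)))
    stop("levels must be nonnegative", call. = FALSE)
  observation_series(
    times = df$time_h, five_mC = df$five_mC,
    five_hmC = if ("five_hmC" %in% names(df)) df$five_hmC else NULL,
    condition = if ("condition" %in% names(df))
      as.character(df$condition[1L]) else "obs")
}

#' @rdname read_timecourse_tsv
#' @param obs An [observation_series()] (or a `trajectory`, whose
#'   `levels` are written).
#' @export
write_timecourse_tsv <- function(obs, path) {
  if (inherits(obs, "trajectory")) {
    df <- data.frame(time_h = fmt_num(obs$levels$time_h),
                     five_mC = fmt_num(obs$levels$five_mC),
                     five_hmC = fmt_num(obs$levels$five_hmC))
  } else {
    stopifnot(inherits(obs, "observation_series"))
    df <- data.frame(time_h = fmt_num(obs$times),
                     five_mC = fmt_num(obs$five_mC))
    if (!is.null(obs$five_hmC)) df$five_hmC <- fmt_num(obs$five_hmC)
    df$condition <- obs$condition
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Read and write hairpin dyad count TSV files
#'
#' Two-line tab-separated format: a header line and one data line with
#' columns `n_full`, `n_hemi`, `n_unmeth`, `conversion_rate`,
#' `nonconversion_rate`.
#'
#' @param path File path.
#' @return `read_hairpin_tsv()` returns a [hairpin_counts()];
#'   `write_hairpin_tsv()` returns `path` invisibly.
#' @export
read_hairpin_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("n_full", "n_hemi", "n_unmeth")
  for (col in need)
    if (!col %in% names(df))
      stop("hairpin file is missing required column '", col, "'",
           call. = FALSE)
  hairpin_counts(
    df$n_full[1L], df$n_hemi[1L], df$n_unmeth[1L],
    conversion_rate = if ("conversion_rate" %in% names(df))
      df$conversion_rate[1L] else 1,
    nonconversion_rate = if ("nonconversion_rate" %in% names(df))
      df$nonconversion_rate[1L] else 0)
}

#' @rdname read_hairpin_tsv
#' @param counts A [hairpin_counts()].
#' @export
write_hairpin_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "hairpin_counts"))
  df <- data.frame(n_full = counts$n_full, n_hemi = counts$n_hemi,
                   n_unmeth = counts$n_unmeth,
                   conversion_rate = fmt_num(counts$conversion_rate),
                   nonconversion_rate = fmt_num(counts$nonconversion_rate))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an MMSE error surface as long-format TSV
#'
#' One row per evaluated grid point: the free-parameter columns followed
#' by the `mmse` value, `%.10g`-formatted.
#'
#' @param surface The `surface` element of a [grid_search()] result.
#' @param path File path.
#' @export
write_surface_tsv <- function(surface, path) {
  df <- as.data.frame(lapply(surface, fmt_num))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a fit result as a flat key-value report
#'
#' @param fit A [grid_search()] result.
#' @param path File path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  p <- fit$params
  kv <- c(p1 = p$p1,
          p1_final = if (is.null(p$p1_final)) p$p1 else p$p1_final,
          p1_half_life = if (is.null(p$p1_half_life)) NA else
            p$p1_half_life,
          p2 = p$p2, p3 = p$p3, division_time = p$division_time,
          mmse = fit$mmse, r_squared = fit$r_squared,
          n_local_minima = nrow(fit$minima))
  writeLines(sprintf("%s\t%s", names(kv), fmt_num(unname(kv))), path)
  invisible(path)
}

read_params_block <- function(block, what) {
  need <- c("p1", "p2", "p3")
  for (nm in need)
    if (is.null(block[[nm]]))
      stop("config: parameter set '", what, "' is missing field '", nm,
           "'", call. = FALSE)
  rate_params(p1 = block$p1, p2 = block$p2, p3 = block$p3,
              division_time = if (is.null(block$division_time)) 16
                else block$division_time,
              p1_final = block$p1_final,
              p1_half_life = block$p1_half_life)
}

#' Read a run configuration (YAML)
#'
#' The configuration is a YAML document with sections:
#' \describe{
#'   \item{`params`}{named parameter sets (e.g. `serum`, `two_i`), each
#'     with `p1`, `p2`, `p3` and optional `division_time`, `p1_final`,
#'     `p1_half_life`.}
#'   \item{`scenario`}{optional [scenario_spec()] fields.}
#'   \item{`fit`}{optional [fit_spec()] fields: `free`, `grid_n`,
#'     `refine`, `channels`, `bounds` (named lower/upper pairs) and
#'     `base` (name of a parameter set).}
#'   \item{`times`}{sampling times; `times_h` (hours) or `times_d`
#'     (days, converted).}
#'   \item{`noise`}{`sd` and `seed` for the generators.}
#'   \item{`seed`}{global integer seed; `scale_mode`; `switch_time_h`.}
#' }
#' Config format version 1; the version is recorded under `config_version`.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list", call. = FALSE)
  out <- list(config_version = if (is.null(cfg$config_version)) 1L else
    cfg$config_version)
  if (is.null(cfg$params) || !length(cfg$params))
    stop("config: missing 'params' section", call. = FALSE)
  out$params <- lapply(stats::setNames(names(cfg$params),
                                       names(cfg$params)),
                       function(nm) read_params_block(cfg$params[[nm]], nm))
  if (!is.null(cfg$times_h)) out$times <- as.numeric(cfg$times_h)
  else if (!is.null(cfg$times_d)) out$times <- as.numeric(cfg$times_d) * 24
  else if (!is.null(cfg$times)) out$times <- as.numeric(cfg$times)
  if (!is.null(out$times) &&
      (anyNA(out$times) || any(out$times < 0) || is.unsorted(out$times)))
    stop("config: field 'times' must be sorted nonnegative hours",
         call. = FALSE)
  out$seed <- if (is.null(cfg$seed)) 1L else {
    if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
      stop("config: field 'seed' must be an integer", call. = FALSE)
    as.integer(cfg$seed)
  }
  out$scale_mode <- if (is.null(cfg$scale_mode)) "none" else
    match.arg(cfg$scale_mode, c("none", "to_initial", "to_reference"))
  out$switch_time <- if (is.null(cfg$switch_time_h)) 0 else {
    if (!is.numeric(cfg$switch_time_h) || cfg$switch_time_h < 0)
      stop("config: field 'switch_time_h' must be >= 0", call. = FALSE)
    cfg$switch_time_h
  }
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    out$scenario <- scenario_spec(
      knockout = if (is.null(sc$knockout)) "none" else sc$knockout,
      vitc_p3_multiplier = if (is.null(sc$vitc_p3_multiplier)) 1 else
        sc$vitc_p3_multiplier,
      switch_time = out$switch_time,
      division_times = sc$division_times)
  }
  if (!is.null(cfg$noise)) {
    out$noise <- noise_model(
      sd = if (is.null(cfg$noise$sd)) 0.01 else cfg$noise$sd,
      seed = if (is.null(cfg$noise$seed)) out$seed else cfg$noise$seed)
  }
  out$fit <- cfg$fit
  out$input <- cfg$input
  structure(out, class = "run_config")
}

resolve_fit_spec <- function(cfg) {
  f <- cfg$fit
  if (is.null(f) || is.null(f$free))
    stop("config: 'fit' section with 'free' is required for fitting",
         call. = FALSE)
  base_name <- if (is.null(f$base)) names(cfg$params)[1L] else f$base
  base <- cfg$params[[base_name]]
  if (is.null(base))
    stop("config: fit base parameter set '", base_name, "' not found",
         call. = FALSE)
  bounds <- if (is.null(f$bounds)) list() else
    lapply(f$bounds, as.numeric)
  fit_spec(free = unlist(f$free), base = base, bounds = bounds,
           grid_n = if (is.null(f$grid_n)) 101L else
             unlist(f$grid_n),
           refine = if (is.null(f$refine)) TRUE else isTRUE(f$refine),
           channels = if (is.null(f$channels)) "five_mC" else
             unlist(f$channels))
}

run_log <- function(out_dir, command, cfg, elapsed) {
  lines <- c(sprintf("command\t%s", command),
             sprintf("seed\t%d", cfg$seed),
             sprintf("config_version\t%s", cfg$config_version),
             sprintf("package_version\t%s",
                     as.character(utils::packageVersion("dyadkin"))),
             sprintf("r_version\t%s", R.version.string),
             sprintf("wall_time_s\t%.3f", elapsed))
  writeLines(lines, file.path(out_dir, paste0(command, ".log")))
  message("[dyadkin] ", command, " finished in ",
          sprintf("%.2f s", elapsed))
  invisible(lines)
}

#' Run a pipeline command
#'
#' Single entry point tying the modules together. Commands:
#' \describe{
#'   \item{`simulate`}{simulate the configured schedule; writes
#'     `trajectory.tsv`.}
#'   \item{`fit`}{fit the configured free parameters to the input
#'     series; writes `fit_report.tsv` and `surface.tsv`.}
#'   \item{`scan`}{grid evaluation only (no refinement); writes
#'     `surface.tsv`.}
#'   \item{`scenario`}{scenario prediction vs base; writes
#'     `scenario.tsv`, `base.tsv` and `rate_comparison.tsv`.}
#'   \item{`synth`}{generate synthetic inputs; writes
#'     `timecourse.tsv` and `hairpin.tsv`.}
#'   \item{`recover`}{end-to-end synthetic generation + fit +
#'     truth-vs-estimate report; writes `recovery_report.tsv`.}
#' }
#' Every run writes a `<command>.log` recording the seed, config and
#' package versions, and wall time.
#'
#' @param command One of `simulate`, `fit`, `scan`, `scenario`, `synth`,
#'   `recover`.
#' @param config A `run_config` (see [read_run_config()]) or the path
#'   to one.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of computed objects (command-specific).
#' @export
run_command <- function(command, config, out_dir = ".") {
  command <- match.arg(command, c("simulate", "fit", "scan", "scenario",
                                  "synth", "recover"))
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  two_phase <- function() {
    serum <- cfg$params$serum
    two_i <- cfg$params$two_i
    if (is.null(serum) || is.null(two_i))
      stop("config: parameter sets 'serum' and 'two_i' are required ",
           "for this command", call. = FALSE)
    list(serum = serum, two_i = two_i)
  }
  times <- if (is.null(cfg$times))
    c(0, 4, 8, 16, 24, 32, 48, 72, 96, 168, 240, 336) else cfg$times
  result <- switch(command,
    simulate = {
      pp <- two_phase()
      init <- steady_state_dyads(pp$serum)
      tr <- predict_scenario(init, pp$serum, pp$two_i,
                             scenario_spec(switch_time = cfg$switch_time),
                             times,
                             scale_mode = if (cfg$scale_mode ==
                                              "to_initial") "to_initial"
                               else "none")
      write_timecourse_tsv(tr, file.path(out_dir, "trajectory.tsv"))
      list(trajectory = tr)
    },
    fit = ,
    scan = {
      if (is.null(cfg$input) || is.null(cfg$input$timecourse))
        stop("config: 'input: timecourse:' path is required", call. = FALSE)
      obs <- read_timecourse_tsv(cfg$input$timecourse)
      obs$scale_mode <- cfg$scale_mode
      spec <- resolve_fit_spec(cfg)
      if (command == "scan") spec$refine <- FALSE
      init <- if (!is.null(cfg$input$hairpin))
        estimate_state_from_counts(read_hairpin_tsv(cfg$input$hairpin))
      else steady_state_dyads(spec$base)
      fit <- grid_search(obs, init, spec)
      write_surface_tsv(fit$surface, file.path(out_dir, "surface.tsv"))
      if (command == "fit")
        write_fit_report(fit, file.path(out_dir, "fit_report.tsv"))
      list(fit = fit)
    },
    scenario = {
      pp <- two_phase()
      if (is.null(cfg$scenario))
        stop("config: 'scenario' section is required", call. = FALSE)
      init <- steady_state_dyads(pp$serum)
      base_spec <- scenario_spec(switch_time = cfg$switch_time)
      tr_base <- predict_scenario(init, pp$serum, pp$two_i, base_spec,
                                  times)
      tr_sc <- predict_scenario(init, pp$serum, pp$two_i, cfg$scenario,
                                times)
      cmp <- compare_rates(tr_sc, tr_base)
      write_timecourse_tsv(tr_sc, file.path(out_dir, "scenario.tsv"))
      write_timecourse_tsv(tr_base, file.path(out_dir, "base.tsv"))
      utils::write.table(cmp$per_time,
                         file.path(out_dir, "rate_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(scenario = tr_sc, base = tr_base, comparison = cmp)
    },
    synth = {
      pp <- two_phase()
      noise <- if (is.null(cfg$noise)) noise_model(seed = cfg$seed) else
        cfg$noise
      obs <- generate_timecourse(pp$serum, pp$two_i,
                                 switch_time = cfg$switch_time,
                                 times = times, noise = noise)
      hp <- generate_hairpin_counts(steady_state_dyads(pp$serum),
                                    n_reads = 1e5, seed = cfg$seed)
      write_timecourse_tsv(obs, file.path(out_dir, "timecourse.tsv"))
      write_hairpin_tsv(hp, file.path(out_dir, "hairpin.tsv"))
      list(timecourse = obs, hairpin = hp)
    },
    recover = {
      pp <- two_phase()
      noise <- if (is.null(cfg$noise)) noise_model(seed = cfg$seed) else
        cfg$noise
      obs <- generate_timecourse(pp$serum, pp$two_i,
                                 switch_time = cfg$switch_time,
                                 times = times, noise = noise)
      init <- steady_state_dyads(pp$serum)
      spec <- if (!is.null(cfg$fit) && !is.null(cfg$fit$free))
        resolve_fit_spec(cfg)
      else fit_spec(c("p1_final", "p2"), base = pp$two_i, grid_n = 41L)
      fit <- grid_search(obs, init, spec)
      truth <- pp$two_i
      est <- fit$params
      rows <- data.frame(
        parameter = c("p1_final", "p2", "p3"),
        truth = c(if (is.null(truth$p1_final)) truth$p1 else
          truth$p1_final, truth$p2, truth$p3),
        estimate = c(if (is.null(est$p1_final)) est$p1 else est$p1_final,
                     est$p2, est$p3))
      rows$abs_error <- abs(rows$estimate - rows$truth)
      utils::write.table(
        cbind(rows[1L], lapply(rows[-1L], fmt_num)),
        file.path(out_dir, "recovery_report.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(fit = fit, truth = truth, report = rows)
    })
  run_log(out_dir, command, cfg, proc.time()[["elapsed"]] - t0)
  invisible(result)
}
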