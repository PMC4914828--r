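#' Default rate parameters for serum and 2i ESC conditions
#'
#' Package defaults describing primed (serum) and naive (2i) mouse ESC
#' culture. Serum cells sit at a hypermethylated steady state maintained
#' by efficient maintenance methylation (`p2 = 0.90`, i.e. ~90% of
#' hemi-methylated dyads restored per division) and strong de novo
#' activity (`p1 = 0.40`), with low TET oxidation (`p3 = 0.02`). On
#' switching to 2i, maintenance is impaired (`p2 = 0.75`), de novo
#' activity relaxes gradually toward an ~8-fold lower level
#' (`p1: 0.40 -> 0.05`, half-life 24 h, tracking DNMT3A/B loss) and
#' oxidation rises modestly (`p3 = 0.05`). With a 16 h division time
#' these values reproduce the canonical serum-to-2i phenotype: rapid
#' demethylation over the first ~32 h (two divisions), a transient 5hmC
#' rise peaking near 72 h, and a hypomethylated steady state reached
#' (within about one percentage point) by day 14 at roughly a fifth of
#' the serum 5mC level.
#'
#' @param division_time Hours per average division (default 16).
#' @return A [rate_params()] object.
#' @seealso [vitc_params()] for vitamin-C-treated 2i.
#' @export
serum_params <- function(division_time = 16) {
  rate_params(p1 = 0.40, p2 = 0.90, p3 = 0.02,
              division_time = division_time)
}

#' @rdname serum_params
#' @export
two_i_params <- function(division_time = 16) {
  rate_params(p1 = 0.40, p2 = 0.75, p3 = 0.05,
              division_time = division_time,
              p1_final = 0.05, p1_half_life = 24)
}

#' Vitamin-C-treated 2i parameters
#'
#' Vitamin C stimulates TET catalytic activity; the treatment is modeled
#' purely as a multiplicative increase of the oxidation parameter `p3`
#' (default 4-fold), capped at 1, with `p1` and `p2` untouched.
#'
#' @param base 2i-condition [rate_params()] (default [two_i_params()]).
#' @param multiplier Fold increase of `p3`, >= 1 (default 4).
#' @return A [rate_params()] object.
#' @export
vitc_params <- function(base = two_i_params(), multiplier = 4) {
  validate_rate_params(base)
  if (!is.numeric(multiplier) || length(multiplier) != 1L ||
      is.na(multiplier) || multiplier < 1)
    stop("multiplier must be a single number >= 1", call. = FALSE)
  base$p3 <- min(1, base$p3 * multiplier)
  base
}
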