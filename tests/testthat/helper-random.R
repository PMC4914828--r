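# Shared generators for property-style tests.

random_dyad_state <- function() {
  w <- stats::rexp(6)
  w <- w / sum(w)
  dyad_state(uu = w[1], um = w[2], mm = w[3],
             uh = w[4], mh = w[5], hh = w[6])
}

random_rate_params <- function(division_time = 16) {
  rate_params(p1 = stats::runif(1), p2 = stats::runif(1),
              p3 = stats::runif(1, 0, 0.5),
              division_time = division_time)
}

# default sampling times for a 0-14 day course, hours
course_times <- function() c(0, 4, 8, 16, 24, 32, 48, 72, 96, 168, 240, 336)
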