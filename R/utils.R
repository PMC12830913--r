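# Internal helpers.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Signed circular difference a - b in hours, mapped to (-12, 12].
circ_diff_hours <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

# Circular mean of angles (radians); NA when the resultant is numerically 0.
circ_mean_angle <- function(theta) {
  C <- sum(cos(theta)); S <- sum(sin(theta))
  if (sqrt(C^2 + S^2) < 1e-12 * max(1, length(theta))) return(NA_real_)
  atan2(S, C) %% (2 * pi)
}

hours_to_angle <- function(h) 2 * pi * h / 24
angle_to_hours <- function(a) (a %% (2 * pi)) * 24 / (2 * pi)
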