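# Shared builders for hand-crafted fixtures.

# Session records at given UTC hours of one day, minimal but valid.
mk_records <- function(hours, date = as.Date("2024-01-01"),
                       delays = NULL, keys = NULL,
                       upright = NULL, moving = NULL, offset = 0) {
  n <- length(hours)
  if (is.null(delays)) delays <- replicate(n, c(150, 250), simplify = FALSE)
  if (is.null(keys)) keys <- rep(3L, n)
  if (is.null(upright)) upright <- rep(TRUE, n)
  if (is.null(moving)) moving <- rep(FALSE, n)
  session_records(
    start_time = as.POSIXct(paste(date, "00:10:00"), tz = "UTC") +
      hours * 3600,
    utc_offset = offset, ikd_ms = delays, n_keypresses = keys,
    upright = upright, moving = moving)
}

# Laplacian of the day-hour lattice with `hours` bins per day, built edge by
# edge from the stated rule -- an independent construction for small oracles.
mk_lattice_laplacian <- function(n_days, hours) {
  n <- n_days * hours
  A <- matrix(0, n, n)
  idx <- function(d, h) (d - 1L) * hours + h + 1L
  for (d in seq_len(n_days)) {
    for (h in 0:(hours - 2)) {
      A[idx(d, h), idx(d, h + 1)] <- A[idx(d, h + 1), idx(d, h)] <- 1
    }
    if (d < n_days) {
      A[idx(d, hours - 1), idx(d + 1, 0)] <-
        A[idx(d + 1, 0), idx(d, hours - 1)] <- 1
      for (h in 0:(hours - 1)) {
        A[idx(d, h), idx(d + 1, h)] <- A[idx(d + 1, h), idx(d, h)] <- 1
      }
    }
  }
  diag(rowSums(A)) - A
}

# A phase series with one given phase (hours) per consecutive day.
mk_phases <- function(phase_hours, start = as.Date("2024-03-01")) {
  n <- length(phase_hours)
  structure(data.frame(
    date = start + seq_len(n) - 1,
    phase_angle = phase_hours * 2 * pi / 24,
    phase_hours = phase_hours,
    resultant_length = 0.9,
    defined = !is.na(phase_hours)),
    class = c("phase_series", "data.frame"))
}
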