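# Daily activity phase, time-zone transitions, and east/west comparisons.

#' Daily activity phase by weighted circular mean
#'
#' Each day's score row is reinterpreted in polar coordinates: the angle is
#' given by the hour (bin centre, so hour h maps to 2*pi*(h + 0.5)/24) and
#' the vector length by the score. The weighted circular mean of these
#' vectors points at the time of peak activity; its angle is the phase of
#' the daily typing rhythm and the normalised resultant length measures how
#' concentrated activity is around that time. Scores are mapped to
#' non-negative weights first (a vector length cannot be negative).
#'
#' @param scores day-by-24 score matrix (rows named by date where available).
#' @param weights how to map scores to weights: `"clip"` (negative scores
#'   become 0; default), `"shift-min"` (subtract the row minimum), or
#'   `"softplus"` (`log(1 + exp(s))`).
#' @param bin_centre logical; `TRUE` (default) uses bin-centre angles
#'   (h + 0.5), `FALSE` uses bin edges (h).
#' @return A `phase_series` data.frame with `date`, `phase_angle` (radians
#'   in \[0, 2pi)), `phase_hours` (= angle * 24 / 2pi), `resultant_length`,
#'   and `defined` (`FALSE` when all weights are zero or the vectors cancel).
#' @export
daily_phase <- function(scores, weights = c("clip", "shift-min", "softplus"),
                        bin_centre = TRUE) {
  weights <- match.arg(weights)
  stopifnot(ncol(scores) == 24, all(is.finite(scores)))
  W <- switch(weights,
              "clip" = pmax(scores, 0),
              "shift-min" = scores - apply(scores, 1, min),
              "softplus" = log1p(exp(scores)))
  theta <- hours_to_angle((0:23) + if (bin_centre) 0.5 else 0)
  C <- as.numeric(W %*% cos(theta))
  S <- as.numeric(W %*% sin(theta))
  wsum <- rowSums(W)
  res <- sqrt(C^2 + S^2)
  defined <- wsum > 0 & res > 1e-12 * pmax(wsum, 1)
  angle <- ifelse(defined, atan2(S, C) %% (2 * pi), NA_real_)
  dates <- rownames(scores)
  out <- data.frame(
    date = if (is.null(dates)) seq_len(nrow(scores)) else as.Date(dates),
    phase_angle = angle,
    phase_hours = angle_to_hours(angle),
    resultant_length = ifelse(defined, res / wsum, 0),
    defined = defined)
  class(out) <- c("phase_series", "data.frame")
  out
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("Daily activity phases: %d day(s), %d defined\n",
              nrow(x), sum(x$defined)))
  if (any(x$defined)) {
    m <- circ_mean_angle(x$phase_angle[x$defined])
    cat(sprintf("  circular mean phase: %.2f h (UTC)\n", angle_to_hours(m)))
  }
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more day(s)\n")
  invisible(x)
}

#' Detect time-zone transitions in a daily offset series
#'
#' A transition is a day whose UTC offset differs from the previous day's
#' and whose new offset persists for at least `min_persist` days (including
#' the transition day). Short-lived changes — an offset reverted within the
#' persistence window — are discarded, which also resolves overlapping
#' candidates. Eastward travel increases the offset, westward decreases it.
#'
#' @param dates consecutive `Date` vector (one entry per day).
#' @param offsets signed UTC offsets in minutes, aligned with `dates`;
#'   `NA` offsets break candidate runs.
#' @param min_persist minimum days the new offset must hold (default 7).
#' @param min_magnitude_hours discard transitions smaller than this many
#'   hours (default 0, i.e. keep all).
#' @return A `data.frame` with one row per transition: `date` (first day at
#'   the new offset), `from_offset`, `to_offset` (minutes), `direction`
#'   (`"east"`/`"west"`), `magnitude_hours`, `persisted_days`.
#' @export
detect_transitions <- function(dates, offsets, min_persist = 7,
                               min_magnitude_hours = 0) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(offsets))
  o <- order(dates)
  dates <- dates[o]; offsets <- offsets[o]
  n <- length(dates)
  out <- list()
  for (i in seq_len(n)[-1]) {
    consecutive <- dates[i] == dates[i - 1] + 1
    if (!consecutive || is.na(offsets[i]) || is.na(offsets[i - 1]) ||
        offsets[i] == offsets[i - 1]) next
    # length of the run of the new offset starting at i (consecutive days)
    run <- 1L
    j <- i + 1L
    while (j <= n && dates[j] == dates[j - 1] + 1 &&
           !is.na(offsets[j]) && offsets[j] == offsets[i]) {
      run <- run + 1L
      j <- j + 1L
    }
    if (run < min_persist) next
    mag <- abs(offsets[i] - offsets[i - 1]) / 60
    if (mag < min_magnitude_hours) next
    out[[length(out) + 1]] <- data.frame(
      date = dates[i], from_offset = offsets[i - 1], to_offset = offsets[i],
      direction = if (offsets[i] > offsets[i - 1]) "east" else "west",
      magnitude_hours = mag, persisted_days = run)
  }
  if (!length(out)) {
    return(data.frame(date = as.Date(character()), from_offset = integer(),
                      to_offset = integer(), direction = character(),
                      magnitude_hours = numeric(), persisted_days = integer()))
  }
  do.call(rbind, out)
}

#' Centre phases around a transition on the pre-transition baseline
#'
#' For one transition, takes the daily phases from `pre_days` days before to
#' `post_days` days after, computes the (unweighted) circular mean phase of
#' the pre-transition days as the baseline, and reports every day's signed
#' circular difference from that baseline in hours, mapped to (-12, +12].
#' Wrapping is circular: a baseline of 23 h followed by a phase of 1 h is a
#' +2 h change, not -22 h.
#'
#' @param phases a `phase_series` (see [daily_phase()]).
#' @param transition one row of [detect_transitions()] output (or a list
#'   with `date`).
#' @param pre_days days before the transition forming the baseline window
#'   (default 3).
#' @param post_days days after the transition to report (default 7).
#' @return A `data.frame` with `offset_day` (-pre_days..post_days, 0 = first
#'   day at the new offset), `centred_hours`, `defined`; or `NULL` (with a
#'   message) when no defined phase exists in the pre-transition window.
#' @export
centre_transition_phases <- function(phases, transition, pre_days = 3,
                                     post_days = 7) {
  t0 <- as.Date(transition$date[1])
  rel_days <- seq(-pre_days, post_days)
  idx <- match(t0 + rel_days, as.Date(phases$date))
  ph <- phases$phase_angle[idx]
  ok <- !is.na(idx) & !is.na(ph) & phases$defined[idx]
  pre <- rel_days < 0
  if (!any(ok & pre)) {
    message("transition at ", format(t0),
            " skipped: no defined phase in the pre-transition window")
    return(NULL)
  }
  baseline <- circ_mean_angle(ph[ok & pre])
  centred <- circ_diff_hours(angle_to_hours(ph), angle_to_hours(baseline))
  data.frame(offset_day = rel_days,
             centred_hours = ifelse(ok, centred, NA_real_),
             defined = ok)
}

#' Pooled centred-phase table over many transitions
#'
#' Applies [centre_transition_phases()] to every detected transition and
#' stacks the results, labelling each row with the transition's id and
#' direction of travel — the long table behind box-plot-per-day summaries
#' and the east/west tests.
#'
#' @param phases a `phase_series`.
#' @param transitions output of [detect_transitions()].
#' @param pre_days,post_days window, as in [centre_transition_phases()].
#' @return A `data.frame` with `transition` (index), `direction`,
#'   `magnitude_hours`, `offset_day`, `centred_hours`, `defined`.
#' @export
transition_phase_table <- function(phases, transitions, pre_days = 3,
                                   post_days = 7) {
  rows <- lapply(seq_len(nrow(transitions)), function(i) {
    ct <- centre_transition_phases(phases, transitions[i, ], pre_days,
                                   post_days)
    if (is.null(ct)) return(NULL)
    cbind(data.frame(transition = i,
                     direction = transitions$direction[i],
                     magnitude_hours = transitions$magnitude_hours[i]),
          ct)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(transition = integer(), direction = character(),
                      magnitude_hours = numeric(), offset_day = integer(),
                      centred_hours = numeric(), defined = logical()))
  }
  do.call(rbind, rows)
}

#' Welch's t-test of east vs west centred phases at one offset day
#'
#' Compares the centred phases of east- and westward transitions at a given
#' day relative to the transition with Welch's unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom), the two groups being all
#' east/west transition-day observations pooled across transitions.
#'
#' @param centred a pooled table from [transition_phase_table()].
#' @param day the offset day to test at.
#' @return A one-row `data.frame`: `offset_day`, `n_east`, `n_west`,
#'   `mean_east`, `mean_west`, `t`, `df`, `p`, `stars`, `computable`.
#' @export
compare_directions <- function(centred, day) {
  sub <- centred[centred$offset_day == day & centred$defined, ]
  east <- sub$centred_hours[sub$direction == "east"]
  west <- sub$centred_hours[sub$direction == "west"]
  base <- data.frame(offset_day = day, n_east = length(east),
                     n_west = length(west),
                     mean_east = if (length(east)) mean(east) else NA_real_,
                     mean_west = if (length(west)) mean(west) else NA_real_)
  if (length(east) < 2 || length(west) < 2 ||
      (stats::sd(east) == 0 && stats::sd(west) == 0 &&
       mean(east) == mean(west))) {
    # degenerate or too small: identical constant groups get t = 0, p = 1
    if (length(east) >= 2 && length(west) >= 2) {
      return(cbind(base, t = 0, df = length(east) + length(west) - 2, p = 1,
                   stars = "", computable = TRUE))
    }
    return(cbind(base, t = NA_real_, df = NA_real_, p = NA_real_,
                 stars = NA_character_, computable = FALSE))
  }
  tt <- tryCatch(stats::t.test(east, west, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    return(cbind(base, t = NA_real_, df = NA_real_, p = NA_real_,
                 stars = NA_character_, computable = FALSE))
  }
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else {
    if (p < 0.05) "*" else ""
  }
  cbind(base, t = unname(tt$statistic), df = unname(tt$parameter), p = p,
        stars = stars, computable = TRUE)
}

#' East/west tests across a range of offset days
#'
#' @param centred a pooled table from [transition_phase_table()].
#' @param days offset days to test (default: all present in `centred`).
#' @return A `data.frame`, one row per day, as in [compare_directions()].
#' @export
transition_tests <- function(centred, days = sort(unique(centred$offset_day))) {
  do.call(rbind, lapply(days, function(d) compare_directions(centred, d)))
}
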