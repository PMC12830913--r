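# Synthetic session streams with known ground truth.
#
# Emulates the data-generating assumptions behind the framework: a stable
# per-user sleep-wake rhythm with a chronotype, diurnal modulation of typing
# speed, Poisson hourly session counts thinned by wake-hour missingness,
# whole missing days, and time-zone shift schedules with gradual (or
# instant) re-entrainment — alongside the exact per-day sleep and phase
# truth, so every pipeline stage can be checked against a known answer.

#' Define a synthetic single-user scenario
#'
#' @param n_days number of simulated days.
#' @param start_date first UTC calendar day.
#' @param chronotype_midsleep midpoint of the sleep window, local clock hours
#'   (default 3.5 = 03:30, a typical intermediate chronotype).
#' @param sleep_mean_hours,sleep_sd_hours nightly sleep duration
#'   distribution (hours).
#' @param wake_missingness probability that an awake hour produces no typing
#'   sessions at all.
#' @param missing_day_prob probability that a whole day's sessions are lost.
#' @param sessions_per_active_hour mean session count of an active hour.
#'   Active hours emit `1 + NegBin(mean - 1)` sessions — the shift keeps the
#'   hour-observed probability exactly `1 - wake_missingness`, and the
#'   negative binomial gives the overdispersion (burstiness) real hourly
#'   phone-use counts show.
#' @param activity_amplitude relative amplitude (0..1) of a mild sinusoidal
#'   modulation of session counts and key presses, peaked at the wake
#'   midpoint (phone use peaks mid-wake). Boundary hours are additionally
#'   damped in session count by their awake fraction (typing continues at a
#'   normal rate until lights out, but only during the awake part of the
#'   hour), giving the near-square-wave activity profile whose edges the
#'   decomposition's imputation rides through the night.
#' @param ikd_base_ms baseline median inter-key delay (ms).
#' @param diurnal_amplitude relative amplitude of the sinusoidal diurnal
#'   typing-speed modulation (slowest around 03:00 local, fastest around
#'   15:00).
#' @param session_ikd_sd standard deviation (log scale) of a per-session
#'   random effect on typing speed: sessions differ by context, app and
#'   posture, so hourly medians are noisy around the diurnal curve.
#' @param upright_day,upright_night,movement_day,movement_night Bernoulli
#'   rates of the orientation/movement flags far from ("day") and within
#'   30 min of ("night") the sleep window: phone use just before and after
#'   sleep happens lying down and stationary, following the person's rhythm
#'   rather than the wall clock.
#' @param insomnia_prob probability per sleep hour of a brief awakening
#'   with a single, short, slow typing session — the sparse nocturnal
#'   observations real keyboards record; they leave the day's sleep truth
#'   unchanged.
#' @param nap_prob,nap_hours probability and length of an afternoon nap
#'   (local 14:00).
#' @param initial_offset starting UTC offset, minutes.
#' @param shift_schedule `data.frame` with columns `day` (1-based index) and
#'   `utc_offset` (minutes): the offset in force from that day on.
#' @param entrain_rate_east,entrain_rate_west re-entrainment speed, hours of
#'   phase realignment per day, after east/westward shifts (eastward slower
#'   by default; set both >= the shift magnitude for instant entrainment).
#' @param seed integer; generation is bit-for-bit reproducible given the
#'   seed.
#' @return A validated `user_scenario` list.
#' @export
user_scenario <- function(n_days = 60, start_date = as.Date("2024-01-01"),
                          chronotype_midsleep = 3.5,
                          sleep_mean_hours = 8, sleep_sd_hours = 0.5,
                          wake_missingness = 0.2, missing_day_prob = 0.02,
                          sessions_per_active_hour = 3,
                          activity_amplitude = 0.2,
                          ikd_base_ms = 250, diurnal_amplitude = 0.15,
                          session_ikd_sd = 0.25,
                          upright_day = 0.8, upright_night = 0.4,
                          movement_day = 0.3, movement_night = 0.1,
                          insomnia_prob = 0.1,
                          nap_prob = 0, nap_hours = 1,
                          initial_offset = 0,
                          shift_schedule = NULL,
                          entrain_rate_east = 1, entrain_rate_west = 1.5,
                          seed = 1L) {
  sc <- list(n_days = as.integer(n_days), start_date = as.Date(start_date),
             chronotype_midsleep = chronotype_midsleep,
             sleep_mean_hours = sleep_mean_hours,
             sleep_sd_hours = sleep_sd_hours,
             wake_missingness = wake_missingness,
             missing_day_prob = missing_day_prob,
             sessions_per_active_hour = sessions_per_active_hour,
             activity_amplitude = activity_amplitude,
             ikd_base_ms = ikd_base_ms,
             diurnal_amplitude = diurnal_amplitude,
             session_ikd_sd = session_ikd_sd,
             upright_day = upright_day, upright_night = upright_night,
             movement_day = movement_day, movement_night = movement_night,
             insomnia_prob = insomnia_prob,
             nap_prob = nap_prob, nap_hours = nap_hours,
             initial_offset = as.integer(initial_offset),
             shift_schedule = shift_schedule,
             entrain_rate_east = entrain_rate_east,
             entrain_rate_west = entrain_rate_west,
             seed = as.integer(seed))
  probs <- c(sc$wake_missingness, sc$missing_day_prob, sc$upright_day,
             sc$upright_night, sc$movement_day, sc$movement_night,
             sc$nap_prob, sc$insomnia_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (sc$sleep_mean_hours <= 0 || sc$sleep_mean_hours >= 24) {
    stop("sleep_mean_hours must lie in (0, 24)")
  }
  if (sc$sleep_mean_hours + 4 * sc$sleep_sd_hours >= 24) {
    stop("infeasible sleep window: mean + 4 sd must stay below 24 h")
  }
  if (sc$n_days < 1) stop("n_days must be >= 1")
  if (sc$sessions_per_active_hour < 1) {
    stop("sessions_per_active_hour must be >= 1")
  }
  if (sc$activity_amplitude < 0 || sc$activity_amplitude > 1) {
    stop("activity_amplitude must lie in [0, 1]")
  }
  class(sc) <- "user_scenario"
  sc
}

#' Simulate a user's typing sessions with ground truth
#'
#' Each day has a sleep window centred on the chronotype midsleep (in local
#' time, hence shifted in UTC by the day's offset). After each offset change
#' the realised midsleep initially keeps its old UTC timing and then moves
#' toward the new local target by the direction-specific entrainment rate,
#' so travel shows up as a phase displacement that decays over days. Awake
#' hours emit sessions whose pooled inter-key-delay median follows a
#' sinusoidal diurnal performance curve; orientation and movement flags are
#' Bernoulli with day/night rates; whole days are dropped at random.
#'
#' @param scenario a [user_scenario()].
#' @return A list with `records` (session records, see [session_records()]),
#'   `truth` (per-day `date`, `sleep_hours` incl. naps, `night_hours`,
#'   `nap_hours`, `midsleep_utc`, `phase_utc_hours` = wake midpoint,
#'   `dropped`), and `offsets` (per-day `date`, `utc_offset` minutes).
#' @export
simulate_user <- function(scenario) {
  stopifnot(inherits(scenario, "user_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    nd <- sc$n_days
    dates <- sc$start_date + (seq_len(nd) - 1L)

    offsets <- rep(sc$initial_offset, nd)
    if (!is.null(sc$shift_schedule) && nrow(sc$shift_schedule) > 0) {
      ss <- sc$shift_schedule[order(sc$shift_schedule$day), ]
      for (i in seq_len(nrow(ss))) {
        d0 <- ss$day[i]
        if (d0 <= nd) offsets[d0:nd] <- as.integer(ss$utc_offset[i])
      }
    }

    # phase displacement (hours) relative to the local target, decaying at
    # the entrainment rate; the transition day itself keeps the old timing
    disp <- numeric(nd)
    d_cur <- 0
    for (d in seq_len(nd)) {
      if (d > 1) {
        if (offsets[d] != offsets[d - 1]) {
          d_cur <- d_cur + (offsets[d] - offsets[d - 1]) / 60
        } else if (d_cur != 0) {
          rate <- if (d_cur > 0) sc$entrain_rate_east else sc$entrain_rate_west
          d_cur <- sign(d_cur) * max(0, abs(d_cur) - rate)
        }
      }
      disp[d] <- d_cur
    }
    midsleep_utc <- (sc$chronotype_midsleep - offsets / 60 + disp) %% 24

    dur <- pmin(23, pmax(0.5, stats::rnorm(nd, sc$sleep_mean_hours,
                                           sc$sleep_sd_hours)))
    nap_today <- stats::runif(nd) < sc$nap_prob
    dropped <- stats::runif(nd) < sc$missing_day_prob

    # sleep intervals on a continuous hour timeline (0 = start of day 1);
    # virtual windows one day before/after avoid edge artefacts
    mk_win <- function(d, mid, len) {
      c((d - 1) * 24 + mid - len / 2, (d - 1) * 24 + mid + len / 2)
    }
    night_win <- lapply(seq_len(nd), function(d) {
      mk_win(d, midsleep_utc[d], dur[d])
    })
    night_win <- c(night_win,
                   list(mk_win(0, midsleep_utc[1], dur[1]),
                        mk_win(nd + 1, midsleep_utc[nd], dur[nd])))
    nap_win <- lapply(which(nap_today), function(d) {
      mk_win(d, (14 - offsets[d] / 60) %% 24, sc$nap_hours)
    })

    in_any <- function(t, wins) {
      for (w in wins) if (t >= w[1] && t < w[2]) return(TRUE)
      FALSE
    }
    dist_any <- function(t, wins) {
      d <- Inf
      for (w in wins) {
        d <- min(d, if (t < w[1]) w[1] - t else if (t >= w[2]) t - w[2] else 0)
      }
      d
    }
    awake_frac <- function(g, wins) {
      covered <- 0
      for (w in wins) {
        covered <- covered + max(0, min(g + 1, w[2]) - max(g, w[1]))
      }
      max(0, 1 - covered)
    }
    gh <- seq_len(nd * 24) - 1L        # global hour index
    mid_t <- gh + 0.5
    asleep_night <- vapply(mid_t, in_any, logical(1), wins = night_win)
    asleep_nap <- vapply(mid_t, in_any, logical(1), wins = nap_win)
    asleep <- asleep_night | asleep_nap
    all_win <- c(night_win, nap_win)
    sleep_dist <- vapply(mid_t, dist_any, numeric(1), wins = all_win)
    frac_awake <- vapply(gh, awake_frac, numeric(1), wins = all_win)

    day_of <- gh %/% 24L + 1L
    truth <- data.frame(
      date = dates,
      sleep_hours = as.integer(tapply(asleep, day_of, sum)),
      night_hours = as.integer(tapply(asleep_night, day_of, sum)),
      nap_hours = as.integer(tapply(asleep_nap & !asleep_night, day_of, sum)),
      midsleep_utc = midsleep_utc,
      phase_utc_hours = (midsleep_utc + 12) %% 24,
      dropped = dropped)

    recs <- list()
    for (g in gh) {
      d <- g %/% 24L + 1L
      h <- g %% 24L
      if (dropped[d]) next
      local_h <- (h + offsets[d] / 60) %% 24
      med_target <- sc$ikd_base_ms *
        (1 + sc$diurnal_amplitude * cos(2 * pi * (local_h - 3) / 24))
      is_day <- sleep_dist[g + 1L] > 0.5
      if (asleep[g + 1L]) {
        # brief awakening: one short, slow session; sleep truth unchanged
        if (stats::runif(1) >= sc$insomnia_prob) next
        n_sess <- 1L
        nk_mean <- 4
        med_target <- med_target * 1.3
      } else {
        if (stats::runif(1) < sc$wake_missingness) next
        # mild midday peak; boundary hours thinned by their awake fraction
        wake_peak <- (sc$chronotype_midsleep + 12) %% 24
        act <- (1 + sc$activity_amplitude *
                  cos(2 * pi * (local_h - wake_peak) / 24)) *
          frac_awake[g + 1L]
        n_sess <- 1L + as.integer(stats::rnbinom(1, size = 3,
          mu = max(0, sc$sessions_per_active_hour * act - 1)))
        nk_mean <- 28
      }
      for (s in seq_len(n_sess)) {
        nk <- 2L + as.integer(stats::rnbinom(1, size = 5, mu = nk_mean))
        sess_eff <- stats::rnorm(1, 0, sc$session_ikd_sd)
        delays <- stats::rlnorm(nk - 1L, meanlog = log(med_target) + sess_eff,
                                sdlog = 0.4)
        recs[[length(recs) + 1L]] <- list(
          time = g * 3600 + stats::runif(1, 0, 3599),
          offset = offsets[d], delays = delays, nk = nk,
          upright = stats::runif(1) <
            (if (is_day) sc$upright_day else sc$upright_night),
          moving = stats::runif(1) <
            (if (is_day) sc$movement_day else sc$movement_night))
      }
    }
    if (!length(recs)) stop("scenario produced no sessions")
    t0 <- as.POSIXct(paste(sc$start_date, "00:00:00"), tz = "UTC")
    records <- session_records(
      start_time = t0 + vapply(recs, `[[`, numeric(1), "time"),
      utc_offset = vapply(recs, `[[`, numeric(1), "offset"),
      ikd_ms = lapply(recs, `[[`, "delays"),
      n_keypresses = vapply(recs, `[[`, integer(1), "nk"),
      upright = vapply(recs, `[[`, logical(1), "upright"),
      moving = vapply(recs, `[[`, logical(1), "moving"))

    list(records = records, truth = truth,
         offsets = data.frame(date = dates, utc_offset = offsets))
  })
}

#' Simulate a wearable-style sleep reference
#'
#' Adds Gaussian noise to the nighttime sleep truth, clipped to \[0, 24\].
#' Daytime naps are excluded by default, mirroring ring-style devices that
#' only record bedtime sleep.
#'
#' @param truth the `truth` table from [simulate_user()].
#' @param noise_sd measurement noise, hours.
#' @param record_naps include nap hours in the measure.
#' @param seed integer seed.
#' @return A `data.frame` with `date` and `sleep_hours`.
#' @export
simulate_wearable <- function(truth, noise_sd = 0.5, record_naps = FALSE,
                              seed = 1L) {
  stopifnot(noise_sd >= 0)
  base <- truth$night_hours + if (record_naps) truth$nap_hours else 0
  with_seed(seed, {
    meas <- pmin(24, pmax(0, base + stats::rnorm(nrow(truth), 0, noise_sd)))
    data.frame(date = truth$date, sleep_hours = meas)
  })
}

#' Simulate hourly-Likert self-reported sleep
#'
#' Truth rounded to the nearest hour and top-coded at 10 (the scale's
#' maximal response being "10+ hours"), with optional reporting noise and
#' missing responses.
#'
#' @param truth the `truth` table from [simulate_user()].
#' @param noise_sd reporting noise (hours) added before rounding.
#' @param attrition probability a day's response is missing.
#' @param seed integer seed.
#' @return A `data.frame` with `date` and integer `response` (`NA` when
#'   missing).
#' @export
simulate_selfreport <- function(truth, noise_sd = 0, attrition = 0,
                                seed = 1L) {
  stopifnot(noise_sd >= 0, attrition >= 0, attrition <= 1)
  with_seed(seed, {
    resp <- round(truth$sleep_hours + stats::rnorm(nrow(truth), 0, noise_sd))
    resp <- pmin(10L, pmax(0L, as.integer(resp)))
    resp[stats::runif(nrow(truth)) < attrition] <- NA_integer_
    data.frame(date = truth$date, response = resp)
  })
}

#' Per-user scenario variations for a cohort
#'
#' Draws per-user random effects on chronotype and mean sleep around a base
#' scenario — a desk-scale stand-in for a multi-participant sample.
#'
#' @param n_users number of users.
#' @param base a [user_scenario()] serving as the population mean.
#' @param chronotype_sd,sleep_mean_sd between-user standard deviations
#'   (hours).
#' @param seed integer seed (per-user seeds are derived from it).
#' @return A list of `user_scenario` objects.
#' @export
cohort_scenarios <- function(n_users, base = user_scenario(),
                             chronotype_sd = 1, sleep_mean_sd = 0.5,
                             seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_users), function(i) {
      sc <- base
      sc$chronotype_midsleep <-
        (base$chronotype_midsleep + stats::rnorm(1, 0, chronotype_sd)) %% 24
      sc$sleep_mean_hours <- max(2, min(
        base$sleep_mean_hours + stats::rnorm(1, 0, sleep_mean_sd),
        23 - 4 * base$sleep_sd_hours))
      sc$seed <- base$seed + i * 1000L
      sc
    })
  })
}
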