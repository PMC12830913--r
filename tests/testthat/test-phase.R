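test_that("weighted circular mean follows the bin-centre convention", {
  s <- matrix(-1, 1, 24)
  s[1, 13] <- 1  # hour 12 only
  ph <- daily_phase(s)
  expect_equal(ph$phase_hours, 12.5)  # bin centre of hour 12
  expect_true(ph$defined)

  s2 <- matrix(0, 1, 24)
  s2[1, c(11, 15)] <- 1  # hours 10 and 14, symmetric about 12.5
  expect_equal(daily_phase(s2)$phase_hours, 12.5)

  s3 <- matrix(0, 1, 24)
  s3[1, c(1, 13)] <- 1  # antipodal hours 0 and 12 cancel
  ph3 <- daily_phase(s3)
  expect_false(ph3$defined)
  expect_equal(ph3$resultant_length, 0)
})

test_that("phase matches a long-hand trigonometric oracle on random rows", {
  set.seed(14)
  for (i in 1:100) {
    w <- runif(24)
    s <- matrix(w, 1, 24)
    ph <- daily_phase(s)
    C <- 0; S <- 0; wsum <- 0
    for (h in 0:23) {
      a <- 2 * pi * (h + 0.5) / 24
      C <- C + w[h + 1] * cos(a)
      S <- S + w[h + 1] * sin(a)
      wsum <- wsum + w[h + 1]
    }
    expect_lt(abs(ph$phase_angle - atan2(S, C) %% (2 * pi)), 1e-9)
    expect_lt(abs(ph$resultant_length - sqrt(C^2 + S^2) / wsum), 1e-9)
  }
})

test_that("rotating a score row by k hours rotates its phase by k", {
  set.seed(15)
  w <- runif(24)
  base <- daily_phase(matrix(w, 1, 24))$phase_hours
  for (k in c(1, 5, 13, 23)) {
    w_rot <- w[((0:23 - k) %% 24) + 1]  # weight of hour h moves to h + k
    rot <- daily_phase(matrix(w_rot, 1, 24))$phase_hours
    expect_lt(abs(((base + k) - rot + 12) %% 24 - 12), 1e-9)
  }
})

test_that("weight conventions map scores to non-negative weights", {
  s <- matrix(rnorm(24), 1, 24)
  for (wm in c("clip", "shift-min", "softplus")) {
    ph <- daily_phase(s, weights = wm)
    expect_true(is.finite(ph$phase_angle) || !ph$defined)
  }
  # bin-edge convention shifts the single-vector phase to the edge
  s1 <- matrix(0, 1, 24)
  s1[1, 13] <- 1
  expect_equal(daily_phase(s1, bin_centre = FALSE)$phase_hours, 12)
})

test_that("transition detection requires persistence and consecutive days", {
  d0 <- as.Date("2024-05-01")
  # clean change: -6 h to +9 h after 10 days, held 10 days
  tr <- detect_transitions(d0 + 0:19, c(rep(-360, 10), rep(540, 10)))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$direction, "east")
  expect_equal(tr$magnitude_hours, 15)
  expect_equal(tr$persisted_days, 10L)
  expect_equal(tr$date, d0 + 10)

  # change reverting after 3 days is not a transition
  tr2 <- detect_transitions(d0 + 0:16, c(rep(0, 10), rep(60, 3), rep(0, 4)))
  expect_equal(nrow(tr2), 0)

  # magnitude filter: keep only transitions of at least 2 h
  off <- c(rep(0, 10), rep(60, 10), rep(180, 10), rep(360, 10))
  tr3 <- detect_transitions(d0 + 0:39, off, min_magnitude_hours = 2)
  expect_equal(sort(tr3$magnitude_hours), c(2, 3))
})

test_that("phases are centred on the pre-transition circular baseline", {
  tr <- data.frame(date = as.Date("2024-03-11"), direction = "west")
  # identical phases centre to zero everywhere
  ph <- mk_phases(rep(6, 20), start = as.Date("2024-03-01"))
  ct <- centre_transition_phases(ph, tr)
  expect_equal(ct$offset_day, -3:7)
  expect_equal(ct$centred_hours[ct$defined], rep(0, 11))

  # baseline 23 h, post-transition 1 h: +2 h through midnight, not -22
  ph2 <- mk_phases(c(rep(23, 10), rep(1, 10)), start = as.Date("2024-03-01"))
  ct2 <- centre_transition_phases(ph2, tr)
  expect_equal(ct2$centred_hours[ct2$offset_day >= 0], rep(2, 8))
  expect_equal(ct2$centred_hours[ct2$offset_day < 0], rep(0, 3))

  # adding a constant angle to every phase leaves centred values unchanged
  ph3 <- mk_phases((c(rep(23, 10), rep(1, 10)) + 5.25) %% 24,
                   start = as.Date("2024-03-01"))
  ct3 <- centre_transition_phases(ph3, tr)
  expect_equal(ct3$centred_hours, ct2$centred_hours, tolerance = 1e-9)

  # no defined pre-window phase: transition excluded with a message
  ph4 <- mk_phases(c(NA, NA, NA, rep(5, 17)), start = as.Date("2024-03-08"))
  expect_message(out <- centre_transition_phases(ph4, tr), "skipped")
  expect_null(out)
})

test_that("Welch comparison matches the closed-form oracle", {
  tab <- data.frame(
    transition = rep(1:6, each = 1),
    direction = rep(c("east", "west"), each = 3),
    magnitude_hours = 6,
    offset_day = 1,
    centred_hours = c(1, 2, 3, 4, 5, 6),
    defined = TRUE)
  res <- compare_directions(tab, 1)
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)
  expect_equal(res$stars, "*")

  # identical groups: t = 0, p = 1
  tab2 <- tab
  tab2$centred_hours <- rep(c(1, 2, 3), 2)
  res2 <- compare_directions(tab2, 1)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  # equal variances and equal n: Welch equals Student's t with df 2n-2
  x <- c(2.1, 3.3, 4.0, 5.2)
  y <- c(1.0, 2.2, 2.9, 4.1)
  tab3 <- data.frame(transition = 1:8,
                     direction = rep(c("east", "west"), each = 4),
                     magnitude_hours = 6, offset_day = 0,
                     centred_hours = c(x, y), defined = TRUE)
  res3 <- compare_directions(tab3, 0)
  st <- t.test(x, y, var.equal = TRUE)
  expect_equal(res3$t, unname(st$statistic), tolerance = 1e-10)
  expect_equal(res3$df, unname(st$parameter), tolerance = 1e-10)

  # insufficient group size flags not-computable
  res4 <- compare_directions(tab[tab$direction == "east", ], 1)
  expect_false(res4$computable)
})

test_that("simulated 6 h shifts recover magnitude and sign of the phase change", {
  # alternating -6 h west / back east, instant re-entrainment; single-day
  # phase estimates carry ~1-1.5 h noise (broad activity arcs give small
  # resultants), so the contract is on the per-direction means
  nper <- 12
  sched <- data.frame(day = (1:8) * nper + 1, utc_offset = rep(c(-360, 0), 4))
  sc <- user_scenario(n_days = 9 * nper, seed = 6, missing_day_prob = 0,
                      shift_schedule = sched,
                      entrain_rate_east = 24, entrain_rate_west = 24)
  sim <- simulate_user(sc)
  run <- suppressMessages(
    run_pipeline(sim$records, pipeline_config(lambda = 0.3, seed = 6),
                 offsets = sim$offsets))
  expect_equal(sum(run$transitions$direction == "west"), 4)
  expect_equal(sum(run$transitions$direction == "east"), 4)
  post <- run$tests[run$tests$offset_day >= 1, ]
  expect_true(all(abs(post$mean_west - 6) <= 1))
  expect_true(all(abs(post$mean_east + 6) <= 1))
})
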