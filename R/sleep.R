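# Sleep-duration extraction from the typing-activity score matrix.

#' Estimate the sleep/wake binarisation threshold
#'
#' The score matrix of a user with a stable rest-activity rhythm is bimodal:
#' a low mode (sleep) and a high mode (wake). The threshold separating them
#' can be set by hand (`manual`), at the density valley between the two
#' largest modes of a kernel density estimate (`valley`, the default: the
#' automatic analogue of placing a line in the histogram's gap by eye), or
#' by Otsu's classical between-class-variance criterion on the value
#' histogram (`otsu`).
#'
#' @param scores day-by-24 score matrix (finite values).
#' @param method `"valley"`, `"otsu"`, or `"manual"`.
#' @param value the threshold itself, for `method = "manual"`.
#' @param n_breaks histogram bins for Otsu's method.
#' @return The threshold (numeric scalar).
#' @export
estimate_threshold <- function(scores, method = c("valley", "otsu", "manual"),
                               value = NULL, n_breaks = 256) {
  method <- match.arg(method)
  x <- as.vector(scores)
  stopifnot(all(is.finite(x)))
  switch(method,
         manual = {
           if (is.null(value) || !is.finite(value)) {
             stop("manual thresholding needs a finite `value`")
           }
           value
         },
         otsu = otsu_threshold(x, n_breaks),
         valley = valley_threshold(x))
}

# Otsu's method: split maximising the between-class variance
# w0 w1 (mu0 - mu1)^2 over histogram bin boundaries.
otsu_threshold <- function(x, n_breaks = 256) {
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold constant scores")
  br <- seq(rng[1], rng[2], length.out = n_breaks + 1)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[length(mu_cum)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, length(p))
  between[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  br[k + 1]  # upper edge of the last bin assigned to the low class
}

# Valley of the KDE between its two largest modes. Spurious bumps in the
# tails (under 5% of the main mode's height) are not counted as modes.
valley_threshold <- function(x) {
  d <- stats::density(x)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  peaks <- which(is_max)
  peaks <- peaks[y[peaks] >= 0.05 * max(y[peaks])]
  if (length(peaks) < 2) {
    stop("score density looks unimodal; use method = 'otsu' or 'manual'")
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Binarise scores and count daily sleep hours
#'
#' Matrix cells with a score strictly below the threshold are classified as
#' sleep, everything else as wakeful; sleep labels are counted per day. No
#' contiguity is required, so unrestricted chronotypes, split sleep and naps
#' all count.
#'
#' @param scores day-by-24 score matrix (rows named by date where available).
#' @param threshold finite binarisation threshold (see
#'   [estimate_threshold()]).
#' @param observed optional day-by-24 logical mask; supplies the per-day
#'   observed-hour counts reported alongside the estimates.
#' @return A `data.frame` (`sleep_series`) with `date`, `sleep_hours`
#'   (integer, 0..24), `n_observed_hours`, and `threshold_used`.
#' @export
binarise_and_count <- function(scores, threshold, observed = NULL) {
  stopifnot(is.finite(threshold), ncol(scores) == 24)
  asleep <- scores < threshold
  n_obs <- if (is.null(observed)) rep(NA_integer_, nrow(scores)) else {
    as.integer(rowSums(observed))
  }
  dates <- rownames(scores)
  out <- data.frame(
    date = if (is.null(dates)) seq_len(nrow(scores)) else as.Date(dates),
    sleep_hours = as.integer(rowSums(asleep)),
    n_observed_hours = n_obs,
    threshold_used = threshold)
  class(out) <- c("sleep_series", "data.frame")
  out
}

#' Daily sleep durations from a GRSVD fit
#'
#' Convenience wrapper: thresholds the component-1 score matrix of a fit and
#' counts sleep hours per day, optionally dropping days with too few
#' observed hours (extreme estimates tend to come from days with little
#' data).
#'
#' @param fit a `grsvd` object from [grsvd()].
#' @param method,value threshold method and manual value, as in
#'   [estimate_threshold()]; when the default valley method finds no
#'   bimodal structure it falls back to Otsu's criterion with a message.
#' @param min_observed_hours days with fewer observed hours are dropped
#'   (default 4; set to 0 to keep all days).
#' @return A `sleep_series` data.frame; see [binarise_and_count()].
#' @export
sleep_series <- function(fit, method = "valley", value = NULL,
                         min_observed_hours = 4) {
  stopifnot(inherits(fit, "grsvd"))
  s <- score_matrix(fit, 1)
  thr <- if (identical(method, "valley")) {
    tryCatch(estimate_threshold(s, method = "valley"),
             error = function(e) {
               message("valley threshold unavailable (", conditionMessage(e),
                       "); falling back to otsu")
               estimate_threshold(s, method = "otsu")
             })
  } else {
    estimate_threshold(s, method = method, value = value)
  }
  out <- binarise_and_count(s, thr, observed = fit$observed)
  if (min_observed_hours > 0) {
    out <- out[out$n_observed_hours >= min_observed_hours, , drop = FALSE]
  }
  out
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf("Daily sleep estimates: %d day(s), threshold %.4g\n",
              nrow(x), x$threshold_used[1]))
  cat(sprintf("  median %.1f h, IQR [%.1f, %.1f] h\n",
              stats::median(x$sleep_hours),
              stats::quantile(x$sleep_hours, 0.25),
              stats::quantile(x$sleep_hours, 0.75)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more day(s)\n")
  invisible(x)
}
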