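# Session-level records and hourly aggregation into day-by-hour matrices.

MODALITIES <- c("median_ikd", "key_count", "upright_rate", "movement_rate")

# Inter-key delays above this are treated as pauses, not typing, and are
# dropped before the hourly median.
IKD_PAUSE_MS <- 5000

#' Construct a table of typing-session records
#'
#' A session record holds one typing session: its start instant (UTC), the
#' UTC offset of the local clock at that moment, the inter-key delays between
#' consecutive alphanumeric key presses, the number of key presses, and two
#' context flags (phone upright, phone moving).
#'
#' @param start_time `POSIXct` (UTC) or ISO-8601 strings parseable by
#'   [as.POSIXct()]; stored in UTC.
#' @param utc_offset signed local-clock offset in minutes, in
#'   \[-720, 840\] and a multiple of 15.
#' @param ikd_ms list of numeric vectors of inter-key delays (ms), one per
#'   session, or a character vector of `";"`-separated values.
#' @param n_keypresses non-negative integer key-press counts.
#' @param upright,moving logical flags per session.
#' @param session_id optional unique identifiers; generated if missing.
#' @return A `data.frame` with one row per session and a list-column
#'   `ikd_ms`, validated against the session invariants.
#' @examples
#' session_records(
#'   start_time = "2024-01-01T13:05:00Z", utc_offset = 0,
#'   ikd_ms = list(c(100, 200)), n_keypresses = 3,
#'   upright = TRUE, moving = FALSE
#' )
#' @export
session_records <- function(start_time, utc_offset, ikd_ms, n_keypresses,
                            upright, moving, session_id = NULL) {
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                            "%Y-%m-%dT%H:%M:%OS%z",
                                            "%Y-%m-%d %H:%M:%OS"))
  }
  attr(start_time, "tzone") <- "UTC"
  if (is.character(ikd_ms)) {
    ikd_ms <- lapply(strsplit(ikd_ms, ";", fixed = TRUE),
                     function(s) as.numeric(s[nzchar(s)]))
  }
  if (!is.list(ikd_ms)) ikd_ms <- list(as.numeric(ikd_ms))
  n <- length(start_time)
  if (is.null(session_id)) session_id <- seq_len(n)
  rec <- data.frame(session_id = session_id,
                    start_time = start_time,
                    utc_offset = as.integer(utc_offset),
                    n_keypresses = as.integer(n_keypresses),
                    upright = as.logical(upright),
                    moving = as.logical(moving))
  rec$ikd_ms <- ikd_ms
  validate_sessions(rec)
  rec
}

validate_sessions <- function(rec) {
  stopifnot(is.data.frame(rec))
  needed <- c("session_id", "start_time", "utc_offset", "ikd_ms",
              "n_keypresses", "upright", "moving")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols)) {
    stop("session records lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(rec$session_id)) {
    stop("duplicate session_id values: records must be unique")
  }
  if (any(rec$n_keypresses < 0)) stop("n_keypresses must be non-negative")
  off <- rec$utc_offset
  if (any(off < -720 | off > 840) || any(off %% 15 != 0)) {
    stop("utc_offset must lie in [-720, 840] minutes and be a multiple of 15")
  }
  bad_delay <- vapply(seq_len(nrow(rec)), function(i) {
    d <- rec$ikd_ms[[i]]
    (rec$n_keypresses[i] >= 2 && length(d) == 0) || any(d <= 0)
  }, logical(1))
  if (any(bad_delay)) {
    stop("sessions with >= 2 key presses need positive inter-key delays")
  }
  invisible(rec)
}

#' Read session records from CSV
#'
#' Expects columns `session_id`, `start_time` (ISO-8601), `utc_offset`,
#' `ikd_ms` (`";"`-separated delays), `n_keypresses`, `upright`, `moving`.
#'
#' @param path CSV file path.
#' @return A validated session-record `data.frame` (see [session_records()]).
#' @export
read_sessions_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(ikd_ms = "character"))
  session_records(start_time = raw$start_time,
                  utc_offset = raw$utc_offset,
                  ikd_ms = raw$ikd_ms,
                  n_keypresses = raw$n_keypresses,
                  upright = raw$upright != 0,
                  moving = raw$moving != 0,
                  session_id = raw$session_id)
}

#' Write session records to CSV
#'
#' @param rec session records (see [session_records()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sessions_csv <- function(rec, path) {
  out <- rec
  out$ikd_ms <- vapply(rec$ikd_ms, paste, character(1), collapse = ";")
  out$start_time <- format(rec$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$upright <- as.integer(out$upright)
  out$moving <- as.integer(out$moving)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Aggregate typing sessions into hourly day-by-hour modality matrices
#'
#' Sessions are binned by the UTC hour of their start time. For every
#' (day, hour) cell with at least one session the four modalities are:
#' `median_ikd`, the median of the pooled inter-key delays of that hour's
#' sessions (delays above 5000 ms are dropped as pauses); `key_count`, the
#' summed key presses; `upright_rate` and `movement_rate`, the fractions of
#' sessions with the respective flag set. Hours with no sessions are missing
#' in all four modalities: absence of typing may mean sleep, so it is left
#' for the decomposition to impute rather than asserted as zero activity.
#'
#' @param rec session records (see [session_records()]).
#' @param grid optional `Date` vector of UTC days to aggregate over; defaults
#'   to the full range spanned by `rec`. Records outside the grid are dropped
#'   with a message.
#' @return A `modality_tensor`: list with `days` (Date), `values` (named list
#'   of four day-by-24 matrices), `observed` (day-by-24 logical mask shared
#'   across modalities), and `offsets` (per-day modal UTC offset, minutes;
#'   `NA` on days without sessions).
#' @examples
#' rec <- session_records(
#'   start_time = c("2024-01-01T13:10:00Z", "2024-01-01T13:40:00Z"),
#'   utc_offset = 0, ikd_ms = list(c(100, 200), 300),
#'   n_keypresses = c(3, 2), upright = c(TRUE, FALSE),
#'   moving = c(FALSE, TRUE)
#' )
#' tens <- aggregate_sessions(rec)
#' tens$values$median_ikd[1, 14]  # hour 13 -> 200
#' @export
aggregate_sessions <- function(rec, grid = NULL) {
  validate_sessions(rec)
  day <- as.Date(rec$start_time, tz = "UTC")
  hour <- as.integer(format(rec$start_time, "%H", tz = "UTC"))
  if (is.null(grid)) {
    grid <- seq(min(day), max(day), by = "day")
  } else {
    grid <- sort(as.Date(grid))
    if (anyDuplicated(grid)) stop("grid contains duplicate dates")
    outside <- !(day %in% grid)
    if (any(outside)) {
      message(sum(outside), " record(s) outside the day grid dropped")
      rec <- rec[!outside, , drop = FALSE]
      day <- day[!outside]
      hour <- hour[!outside]
    }
    if (nrow(rec) == 0) stop("no records fall inside the day grid")
  }
  nd <- length(grid)
  mk <- function() matrix(NA_real_, nd, 24,
                          dimnames = list(as.character(grid), 0:23))
  values <- list(median_ikd = mk(), key_count = mk(),
                 upright_rate = mk(), movement_rate = mk())
  observed <- matrix(FALSE, nd, 24, dimnames = dimnames(mk()))

  di <- match(day, grid)
  cell <- (di - 1L) * 24L + hour + 1L
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    d <- ((cl - 1L) %/% 24L) + 1L
    h <- ((cl - 1L) %% 24L) + 1L
    pooled <- unlist(rec$ikd_ms[idx], use.names = FALSE)
    pooled <- pooled[pooled <= IKD_PAUSE_MS]
    values$median_ikd[d, h] <- if (length(pooled)) stats::median(pooled) else NA
    values$key_count[d, h] <- sum(rec$n_keypresses[idx])
    values$upright_rate[d, h] <- mean(rec$upright[idx])
    values$movement_rate[d, h] <- mean(rec$moving[idx])
    observed[d, h] <- TRUE
  }
  # An hour whose delays were all pauses has no usable median; treat the
  # cell as missing everywhere to keep the mask shared across modalities.
  empty_med <- observed & is.na(values$median_ikd)
  if (any(empty_med)) {
    observed[empty_med] <- FALSE
    for (m in MODALITIES) values[[m]][empty_med] <- NA_real_
  }

  offsets <- rep(NA_integer_, nd)
  tab <- tapply(rec$utc_offset, di, function(x) {
    as.integer(names(which.max(table(x))))
  })
  offsets[as.integer(names(tab))] <- unlist(tab)

  structure(list(days = grid, values = values, observed = observed,
                 offsets = offsets),
            class = "modality_tensor")
}

#' @export
print.modality_tensor <- function(x, ...) {
  nd <- length(x$days)
  cat("Day-by-hour modality tensor\n")
  cat(sprintf("  days: %d (%s to %s)\n", nd,
              format(x$days[1]), format(x$days[nd])))
  cat(sprintf("  modalities: %s\n", paste(names(x$values), collapse = ", ")))
  cat(sprintf("  observed cells: %d of %d (%.1f%%)\n",
              sum(x$observed), nd * 24, 100 * mean(x$observed)))
  if (!is.null(attr(x, "standardised"))) {
    cat("  standardised (median_ikd negated)\n")
  }
  invisible(x)
}

#' Standardise tensor modalities to a common scale
#'
#' Each modality is z-scored over its observed cells (population standard
#' deviation, denominator n), so that modalities of incommensurate units can
#' share one decomposition. The median inter-key delay is additionally
#' negated, since a short delay means fast typing: after standardisation,
#' larger values mean more (or faster) activity for every modality.
#'
#' @param tensor a `modality_tensor` from [aggregate_sessions()].
#' @return The tensor with standardised values; the mask is unchanged.
#' @export
standardise_modalities <- function(tensor) {
  stopifnot(inherits(tensor, "modality_tensor"))
  obs <- tensor$observed
  if (sum(obs) < 2) stop("need at least 2 observed cells")
  already <- isTRUE(attr(tensor, "standardised"))
  for (m in names(tensor$values)) {
    v <- tensor$values[[m]][obs]
    mu <- mean(v)
    sd_n <- sqrt(mean((v - mu)^2))
    if (sd_n == 0) stop("modality '", m, "' has zero variance over observed cells")
    z <- (tensor$values[[m]] - mu) / sd_n
    # the sign flip happens once: re-standardising is then a no-op
    if (m == "median_ikd" && !already) z <- -z
    z[!obs] <- NA_real_
    tensor$values[[m]] <- z
  }
  attr(tensor, "standardised") <- TRUE
  tensor
}

#' Serialise a modality tensor to tidy CSV
#'
#' One row per (date, hour, modality) with `value` and `observed` columns.
#'
#' @param tensor a `modality_tensor`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tensor_csv <- function(tensor, path) {
  nd <- length(tensor$days)
  rows <- do.call(rbind, lapply(names(tensor$values), function(m) {
    data.frame(date = rep(tensor$days, 24),
               hour = rep(0:23, each = nd),
               modality = m,
               value = as.vector(tensor$values[[m]]),
               observed = as.vector(tensor$observed))
  }))
  rows <- rows[order(rows$modality, rows$date, rows$hour), ]
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a modality tensor from tidy CSV
#'
#' Inverse of [write_tensor_csv()]. Per-day offsets are not stored in the
#' tidy file and come back as `NA`.
#'
#' @param path CSV path written by [write_tensor_csv()].
#' @return A `modality_tensor`.
#' @export
read_tensor_csv <- function(path) {
  tidy <- utils::read.csv(path, stringsAsFactors = FALSE)
  days <- sort(unique(as.Date(tidy$date)))
  nd <- length(days)
  values <- list()
  observed <- NULL
  for (m in unique(tidy$modality)) {
    sub <- tidy[tidy$modality == m, ]
    v <- matrix(NA_real_, nd, 24, dimnames = list(as.character(days), 0:23))
    v[cbind(match(as.Date(sub$date), days), sub$hour + 1L)] <- sub$value
    values[[m]] <- v
    if (is.null(observed)) {
      observed <- matrix(FALSE, nd, 24, dimnames = dimnames(v))
      observed[cbind(match(as.Date(sub$date), days), sub$hour + 1L)] <- sub$observed
    }
  }
  structure(list(days = days, values = values[MODALITIES], observed = observed,
                 offsets = rep(NA_integer_, nd)),
            class = "modality_tensor")
}
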