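# End-to-end pipeline: aggregate -> graph -> GRSVD -> sleep + phase ->
# summary metrics, reproducible from a single config and seed.

#' Pipeline configuration
#'
#' Collects every tunable of the full pipeline in one serialisable list, so
#' that a run is reproducible from config + inputs alone.
#'
#' @param lambda GRSVD regularisation weight; `NULL` selects it by
#'   [select_lambda()].
#' @param rank number of GRSVD components.
#' @param tol,max_iter GRSVD convergence control.
#' @param threshold_method,threshold_value sleep binarisation threshold (see
#'   [estimate_threshold()]).
#' @param min_observed_hours drop days with fewer observed hours from the
#'   sleep series.
#' @param phase_weights,bin_centre phase conventions (see [daily_phase()]).
#' @param min_persist,pre_days,post_days,min_magnitude_hours transition
#'   analysis parameters (see [detect_transitions()],
#'   [centre_transition_phases()]).
#' @param seed integer; the single source of randomness of a run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lambda = NULL, rank = 1, tol = 1e-8,
                            max_iter = 500,
                            threshold_method = "valley", threshold_value = NULL,
                            min_observed_hours = 4,
                            phase_weights = "clip", bin_centre = TRUE,
                            min_persist = 7, pre_days = 3, post_days = 7,
                            min_magnitude_hours = 0,
                            seed = 1L) {
  structure(list(lambda = lambda, rank = rank, tol = tol,
                 max_iter = max_iter,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_observed_hours = min_observed_hours,
                 phase_weights = phase_weights, bin_centre = bin_centre,
                 min_persist = min_persist, pre_days = pre_days,
                 post_days = post_days,
                 min_magnitude_hours = min_magnitude_hours,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline config as JSON
#'
#' `read_config(write_config(cfg, path))` returns a config equal to `cfg`.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `path` invisibly (write) / a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full typing-rhythm pipeline
#'
#' Aggregates session records on a UTC day grid, builds the temporal graph,
#' fits the graph-regularised SVD, extracts daily sleep durations and
#' activity phases, detects time-zone transitions from the per-day offsets
#' and runs the east/west phase comparisons. Optionally compares the sleep
#' estimates against a reference series and writes all artefacts to a
#' directory.
#'
#' @param records session records (see [session_records()]).
#' @param config a [pipeline_config()].
#' @param offsets optional per-day `data.frame(date, utc_offset)` (minutes);
#'   defaults to the per-day modal offsets of the records, gap-filled
#'   forward.
#' @param grid optional `Date` vector for the day grid.
#' @param reference optional `data.frame(date, sleep_hours)` reference sleep
#'   series (e.g. a wearable) for [compare_to_reference()].
#' @param out_dir optional directory; when given, all module outputs (tensor
#'   CSV, edge list, GRSVD scores + sidecar, sleep/phase/transition CSVs,
#'   summary JSON) are written there.
#' @return A `typerhythm_run` list: `fit` (the `grsvd` object), `sleep`,
#'   `phases`, `transitions`, `transition_table`, `tests`, `comparison`,
#'   `config`, `summary`.
#' @export
run_pipeline <- function(records, config = pipeline_config(), offsets = NULL,
                         grid = NULL, reference = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tensor <- aggregate_sessions(records, grid = grid)
  graph <- build_time_graph(tensor$days)
  fit <- grsvd(tensor, lambda = config$lambda, rank = config$rank,
               graph = graph, tol = config$tol, max_iter = config$max_iter,
               seed = config$seed)
  sleep <- sleep_series(fit, method = config$threshold_method,
                        value = config$threshold_value,
                        min_observed_hours = config$min_observed_hours)
  phases <- daily_phase(fit$score_matrix, weights = config$phase_weights,
                        bin_centre = config$bin_centre)

  if (is.null(offsets)) {
    off <- fit$offsets
    off <- fill_gaps(off)
    offsets <- data.frame(date = fit$days, utc_offset = off)
  }
  transitions <- detect_transitions(offsets$date, offsets$utc_offset,
                                    min_persist = config$min_persist,
                                    min_magnitude_hours =
                                      config$min_magnitude_hours)
  tab <- transition_phase_table(phases, transitions,
                                pre_days = config$pre_days,
                                post_days = config$post_days)
  tests <- if (nrow(tab)) transition_tests(tab) else NULL

  comparison <- if (!is.null(reference)) {
    compare_to_reference(sleep[, c("date", "sleep_hours")], reference)
  } else NULL

  summary <- list(
    n_days = length(fit$days),
    n_sessions = nrow(records),
    observed_cell_fraction = mean(fit$observed),
    lambda = as.numeric(fit$lambda),
    converged = fit$converged,
    threshold = sleep$threshold_used[1],
    median_sleep_hours = stats::median(sleep$sleep_hours),
    n_transitions = nrow(transitions),
    seed = config$seed,
    comparison = comparison)

  run <- structure(list(fit = fit, sleep = sleep, phases = phases,
                        transitions = transitions, transition_table = tab,
                        tests = tests, comparison = comparison,
                        config = config, summary = summary),
                   class = "typerhythm_run")
  if (!is.null(out_dir)) write_run(run, tensor, graph, out_dir)
  run
}

# forward-fill NAs, then backward-fill any leading gap
fill_gaps <- function(x) {
  if (all(is.na(x))) return(x)
  out <- x
  last <- NA
  for (i in seq_along(out)) {
    if (!is.na(out[i])) last <- out[i] else if (!is.na(last)) out[i] <- last
  }
  out[is.na(out)] <- out[which(!is.na(out))[1]]
  out
}

write_run <- function(run, tensor, graph, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_tensor_csv(tensor, fp("tensor.csv"))
  write_edges_csv(graph, fp("timegraph_edges.csv"))
  write_grsvd(run$fit, fp("grsvd_scores.csv"), fp("grsvd_fit.json"))
  utils::write.csv(as.data.frame(run$sleep), fp("sleep.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$phases), fp("phases.csv"),
                   row.names = FALSE)
  utils::write.csv(run$transitions, fp("transitions.csv"), row.names = FALSE)
  if (nrow(run$transition_table)) {
    utils::write.csv(run$transition_table, fp("transition_phases.csv"),
                     row.names = FALSE)
    utils::write.csv(run$tests, fp("transition_tests.csv"), row.names = FALSE)
  }
  write_config(run$config, fp("config.json"))
  jsonlite::write_json(run$summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.typerhythm_run <- function(x, ...) {
  s <- x$summary
  cat("Typing-rhythm pipeline run\n")
  cat(sprintf("  %d days, %d sessions, %.1f%% of hour cells observed\n",
              s$n_days, s$n_sessions, 100 * s$observed_cell_fraction))
  cat(sprintf("  lambda = %g, threshold = %.4g, median sleep %.1f h\n",
              s$lambda, s$threshold, s$median_sleep_hours))
  cat(sprintf("  %d time-zone transition(s)\n", s$n_transitions))
  if (!is.null(x$comparison)) {
    cat(sprintf("  vs reference: rho = %.3f, RMSE = %.2f, MAE = %.2f (n = %d)\n",
                x$comparison$spearman_rho, x$comparison$rmse,
                x$comparison$mae, x$comparison$n))
  }
  invisible(x)
}

#' Compare a daily estimate series to a reference series
#'
#' Inner-joins the two series on date and reports Spearman's rank
#' correlation (mid-ranks for ties), root-mean-square error and mean
#' absolute error.
#'
#' @param estimates `data.frame` whose first two columns are date and value.
#' @param reference same layout.
#' @return A list `spearman_rho`, `rmse`, `mae`, `n`, `computable`; the
#'   metrics are `NA` with `computable = FALSE` below 3 paired days.
#' @export
compare_to_reference <- function(estimates, reference) {
  a <- stats::setNames(estimates[, 1:2], c("date", "est"))
  b <- stats::setNames(reference[, 1:2], c("date", "ref"))
  m <- merge(a, b, by = "date")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) {
    return(list(spearman_rho = NA_real_, rmse = NA_real_, mae = NA_real_,
                n = nrow(m), computable = FALSE))
  }
  list(spearman_rho = stats::cor(m$est, m$ref, method = "spearman"),
       rmse = sqrt(mean((m$est - m$ref)^2)),
       mae = mean(abs(m$est - m$ref)),
       n = nrow(m), computable = TRUE)
}

#' Model-ready long table for estimate-vs-reference modelling
#'
#' Joins per-user sleep estimates and reference series into the long format
#' expected by mixed-effects tooling (one row per user-day, estimates
#' standardised across all observations). The model fit itself is left to
#' standard packages.
#'
#' @param runs named list of `typerhythm_run` objects (names = user ids).
#' @param references named list of reference `data.frame(date, sleep_hours)`.
#' @return A `data.frame` with `user`, `date`, `estimate`, `estimate_std`,
#'   `reference`.
#' @export
export_model_table <- function(runs, references) {
  stopifnot(length(runs) == length(references))
  users <- names(runs)
  if (is.null(users)) users <- as.character(seq_along(runs))
  rows <- do.call(rbind, lapply(seq_along(runs), function(i) {
    est <- runs[[i]]$sleep
    ref <- stats::setNames(references[[i]][, 1:2], c("date", "reference"))
    m <- merge(data.frame(date = est$date, estimate = est$sleep_hours), ref,
               by = "date")
    if (!nrow(m)) return(NULL)
    cbind(user = users[i], m)
  }))
  rows$estimate_std <- as.numeric(scale(rows$estimate))
  rows[, c("user", "date", "estimate", "estimate_std", "reference")]
}
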