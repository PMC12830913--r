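# Masked graph-regularised SVD of stacked modality matrices.
#
# Model: per component, on the current residual R (modalities x time bins),
#   minimise  F(u, v) = sum_{(m,t) observed} (R_mt - u_m v_t)^2 + lambda v'Lv
#   subject to ||u|| = 1
# by alternating exact coordinate updates. The constraint matters: with u
# unconstrained the penalty could be dodged by shrinking v and growing u.
# Internally the equivalent scale-invariant objective
#   sum_obs (R - u v')^2 + lambda ||u||^2 v'Lv
# is minimised (its value along the ray u*c, v/c is constant and equals F at
# ||u|| = 1), which keeps both updates closed-form. Only observed cells enter
# the fit term; the Laplacian term propagates information into unobserved
# bins, which is what makes the imputation selective.

#' Fit a graph-regularised SVD to a modality tensor
#'
#' The four day-by-hour matrices are vectorised row-major by (day, hour) and
#' stacked into one modalities-by-timebins matrix sharing a single time
#' factor, which the temporal graph regularises: the fitted time scores vary
#' smoothly across graph-adjacent bins (adjacent hours, same hour on
#' adjacent days) and are defined at every bin, including unobserved ones.
#' The first component captures the dominant mode of variation across the
#' modalities and its reshaped score matrix is a general measure of typing
#' activity, the input to sleep and phase extraction.
#'
#' @param tensor a `modality_tensor` (see [aggregate_sessions()]); it is
#'   standardised with [standardise_modalities()] first unless it already was.
#' @param lambda regularisation weight (>= 0). `NULL` (default) selects it by
#'   the built-in re-masking heuristic, [select_lambda()]; pass a number to
#'   override by hand.
#' @param rank number of components K >= 1. Components beyond the first are
#'   fitted by deflation (subtracting the fitted component from the observed
#'   residual entries).
#' @param graph optional `time_graph`; defaults to
#'   `build_time_graph(tensor$days)`.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum alternating iterations per component.
#' @param sign_anchor modality whose loading is constrained >= 0 in every
#'   component, fixing the sign indeterminacy (default `"key_count"`, so
#'   higher scores mean more typing).
#' @param seed integer; only used when `lambda = NULL` (for the re-masking
#'   heuristic; the solver itself is deterministic).
#' @return An object of class `grsvd` with components `u` (modality loadings,
#'   4 x K, unit columns), `v` (time scores, T x K, unit columns), `sigma`
#'   (scales), `score_matrix` (day-by-24 reshape of `sigma[1] * v[, 1]`),
#'   `objective_trace`, `converged`, `n_iter`, `lambda`, plus the days, mask
#'   and graph. Methods: [print()], [summary()], [coef()], [fitted()],
#'   [residuals()], [predict()], [plot()].
#' @seealso [grsvd_fit()] for the matrix-level interface, [score_matrix()],
#'   [sleep_series()], [daily_phase()].
#' @export
grsvd <- function(tensor, lambda = NULL, rank = 1, graph = NULL,
                  tol = 1e-8, max_iter = 500, sign_anchor = "key_count",
                  seed = 1L) {
  stopifnot(inherits(tensor, "modality_tensor"))
  if (is.null(attr(tensor, "standardised"))) {
    tensor <- standardise_modalities(tensor)
  }
  if (is.null(graph)) graph <- build_time_graph(tensor$days)
  stopifnot(identical(graph$days, tensor$days))
  nd <- length(tensor$days)
  X <- do.call(rbind, lapply(tensor$values, function(m) as.vector(t(m))))
  rownames(X) <- names(tensor$values)
  M <- matrix(rep(as.vector(t(tensor$observed)), each = nrow(X)),
              nrow = nrow(X))
  L <- laplacian(graph)
  if (is.null(lambda)) {
    lambda <- select_lambda(X, M, L, rank = 1, seed = seed)
  }
  fit <- grsvd_fit(X, M, L, lambda = lambda, rank = rank, tol = tol,
                   max_iter = max_iter,
                   sign_anchor = match(sign_anchor, rownames(X)))
  fit$days <- tensor$days
  fit$offsets <- tensor$offsets
  fit$observed <- tensor$observed
  fit$graph <- graph
  fit$score_matrix <- score_matrix(fit, 1)
  fit
}

#' Matrix-level graph-regularised SVD
#'
#' Low-level masked alternating least squares with a Laplacian penalty on
#' the time factor. Per component on the current residual R it minimises
#' `sum_observed (R_mt - u_m v_t)^2 + lambda * v'Lv`: the v-update solves
#' the sparse normal equations `(diag(a) + lambda L) v = b` with
#' `a_t = sum_{m observed} u_m^2` and `b_t = sum_{m observed} u_m R_mt`, and
#' the u-update is masked least squares against v. Both updates are exact
#' coordinate minimisers, so the objective is non-increasing. Factors are
#' normalised afterwards with the scale absorbed into `sigma`.
#'
#' @param X modality-by-timebin matrix (finite on observed cells).
#' @param M logical mask of the same shape (`TRUE` = observed).
#' @param L time-graph Laplacian (timebins x timebins, sparse ok).
#' @param lambda penalty weight >= 0.
#' @param rank number of components.
#' @param tol,max_iter convergence control (relative objective change).
#' @param sign_anchor row index whose loading is kept >= 0 per component.
#' @return A `grsvd` object (without tensor/graph metadata); see [grsvd()].
#' @export
grsvd_fit <- function(X, M, L, lambda, rank = 1, tol = 1e-8, max_iter = 500,
                      sign_anchor = 1L) {
  stopifnot(lambda >= 0, rank >= 1, tol > 0,
            all(dim(X) == dim(M)), nrow(L) == ncol(X))
  M <- M & is.finite(X)
  if (!any(M)) stop("no observed cells")
  nm <- nrow(X); Tn <- ncol(X)
  R <- X; R[!M] <- 0

  U <- matrix(0, nm, rank, dimnames = list(rownames(X), NULL))
  V <- matrix(0, Tn, rank)
  sigma <- numeric(rank)
  traces <- vector("list", rank)
  conv <- logical(rank)
  iters <- integer(rank)

  for (k in seq_len(rank)) {
    comp <- grsvd_component(R, M, L, lambda, tol, max_iter)
    u <- comp$u; v <- comp$v
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) {
      sigma[k] <- 0
    } else {
      if (u[sign_anchor] < 0) { u <- -u; v <- -v }
      sigma[k] <- nu * nv
      U[, k] <- u / nu
      V[, k] <- v / nv
    }
    traces[[k]] <- comp$trace
    conv[k] <- comp$converged
    iters[k] <- comp$n_iter
    if (!comp$converged) {
      warning("GRSVD component ", k, " did not converge in ", max_iter,
              " iterations")
    }
    R[M] <- R[M] - (sigma[k] * (U[, k] %o% V[, k]))[M]
  }

  structure(list(u = U, v = V, sigma = sigma, lambda = lambda, rank = rank,
                 objective_trace = traces[[1]], objective_traces = traces,
                 converged = all(conv), n_iter = iters, mask = M,
                 X = X),
            class = "grsvd")
}

# One component of the masked, Laplacian-penalised rank-1 fit.
grsvd_component <- function(R, M, L, lambda, tol, max_iter) {
  Tn <- ncol(R)
  Rm <- R; Rm[!M] <- 0
  # objectives at rounding-noise level (e.g. exactly rank-1 data) count as
  # converged: the relative test can never fire on a jittering zero
  noise_floor <- 100 * .Machine$double.eps * (sum(Rm^2) + 1)
  cnt <- colSums(M)
  v <- ifelse(cnt > 0, colSums(Rm) / pmax(cnt, 1L), 0)
  u <- update_u(Rm, M, v)
  if (all(u == 0)) u <- rep(1 / sqrt(nrow(R)), nrow(R))

  obj <- grsvd_objective(R, M, L, lambda, u, v)
  trace <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # v-step: (diag(a) + lambda ||u||^2 L) v = b, exact minimiser given u
    a <- colSums(M * u^2)
    b <- colSums(Rm * u)
    lam_eff <- lambda * sum(u^2)
    if (lambda > 0) {
      A <- Matrix::Diagonal(Tn, a) + lam_eff * L
      v <- tryCatch(as.numeric(Matrix::solve(A, b)),
                    error = function(e) {
                      stop("singular smoothing system (a whole graph ",
                           "component may be unobserved): increase lambda ",
                           "or drop the affected days", call. = FALSE)
                    })
    } else {
      if (any(a == 0)) {
        stop("with lambda = 0 every time bin must be observed in at least ",
             "one modality; set lambda > 0 or remove empty bins",
             call. = FALSE)
      }
      v <- b / a
    }
    # u-step: u_m = b_m / (a_m + lambda v'Lv), exact minimiser given v
    u <- update_u(Rm, M, v, lambda * as.numeric(v %*% (L %*% v)))
    obj_new <- grsvd_objective(R, M, L, lambda, u, v)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(abs(obj), 1e-12) ||
        abs(obj_new) <= noise_floor) {
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  list(u = u, v = v, trace = trace, converged = converged, n_iter = it)
}

update_u <- function(Rm, M, v, ridge = 0) {
  num <- as.numeric(Rm %*% v)
  den <- as.numeric(M %*% v^2) + ridge
  ifelse(den > 0, num / den, 0)
}

# Scale-invariant objective; equals the constrained (||u|| = 1) objective
# sum_obs (R - sigma u v')^2 + lambda (sigma v)'L(sigma v) after rescaling.
grsvd_objective <- function(R, M, L, lambda, u, v) {
  fit <- u %o% v
  sum((R[M] - fit[M])^2) + lambda * sum(u^2) * as.numeric(v %*% (L %*% v))
}

#' Select the regularisation weight by re-masked imputation error
#'
#' Hides a fraction of the observed time bins, fits the decomposition at
#' each weight of a log-spaced grid, and measures the root-mean-square error
#' of the reconstruction on the hidden cells. Returns the smallest weight
#' attaining the minimum error — an automatic stand-in for tuning the
#' smoothing by hand, which remains available via the `lambda` argument of
#' [grsvd()].
#'
#' @param X,M,L as in [grsvd_fit()].
#' @param grid candidate weights (positive; log-spaced by default).
#' @param frac fraction of observed time bins to hide.
#' @param rank rank used during selection.
#' @param rtol relative tolerance: the smallest weight whose error is within
#'   `rtol` of the minimum is returned (the error profile is often flat over
#'   orders of magnitude; undersmoothing is the conservative choice).
#' @param seed integer seed for the re-masking draw.
#' @return The selected weight, with the error profile attached as attribute
#'   `"rmse"`.
#' @export
select_lambda <- function(X, M, L, grid = 10^seq(-2, 2, by = 0.5),
                          frac = 0.2, rank = 1, rtol = 0.01, seed = 1L) {
  stopifnot(all(grid > 0))
  obs_bins <- which(colSums(M) > 0)
  n_hide <- max(1L, round(frac * length(obs_bins)))
  hide <- with_seed(seed, sample(obs_bins, n_hide))
  M2 <- M
  M2[, hide] <- FALSE
  held <- M & !M2
  rmse <- vapply(grid, function(lam) {
    f <- grsvd_fit(X, M2, L, lambda = lam, rank = rank)
    rec <- reconstruct(f)
    sqrt(mean((X[held] - rec[held])^2))
  }, numeric(1))
  lam <- grid[which(rmse <= min(rmse) * (1 + rtol))[1]]
  structure(lam, rmse = stats::setNames(rmse, signif(grid, 3)))
}

reconstruct <- function(fit, components = seq_len(fit$rank)) {
  out <- matrix(0, nrow(fit$u), nrow(fit$v))
  for (k in components) {
    out <- out + fit$sigma[k] * (fit$u[, k] %o% fit$v[, k])
  }
  dimnames(out) <- dimnames(fit$X)
  out
}

#' Day-by-hour score matrix of a fitted component
#'
#' Reshapes `sigma_k * v_k` row-major into a day-by-24 matrix. The scores
#' are defined at every cell: missing hours carry the smoothly imputed
#' factor value.
#'
#' @param fit a `grsvd` object.
#' @param component component index (<= rank).
#' @param days optional `Date` vector labelling the rows; taken from the fit
#'   when present.
#' @return A day-by-24 numeric matrix.
#' @export
score_matrix <- function(fit, component = 1, days = fit$days) {
  stopifnot(inherits(fit, "grsvd"))
  if (component > fit$rank) stop("component ", component, " out of range")
  s <- fit$sigma[component] * fit$v[, component]
  out <- matrix(s, ncol = 24, byrow = TRUE)
  if (!is.null(days)) rownames(out) <- as.character(days)
  colnames(out) <- 0:23
  out
}

#' Impute by per-hour-of-day means
#'
#' Baseline imputation: every cell of a modality is replaced by the mean of
#' that modality's observed values at the same hour of day (falling back to
#' the modality's overall observed mean for hours never observed). Used as
#' the natural comparison point for the graph-based imputation.
#'
#' @param X modality-by-timebin matrix (bins ordered day-major).
#' @param M logical observation mask.
#' @return A matrix of the same shape, defined everywhere.
#' @export
impute_hour_mean <- function(X, M) {
  hod <- ((seq_len(ncol(X)) - 1L) %% 24L)
  out <- X
  for (m in seq_len(nrow(X))) {
    obs <- M[m, ]
    overall <- mean(X[m, obs])
    mu <- tapply(X[m, obs], hod[obs], mean)
    fill <- mu[as.character(hod)]
    fill[is.na(fill)] <- overall
    out[m, ] <- as.numeric(fill)
  }
  out
}

# ---- methods -------------------------------------------------------------

#' @export
print.grsvd <- function(x, ...) {
  cat("Graph-regularised SVD fit\n")
  cat(sprintf("  rank %d, lambda = %g, %s (%s iterations)\n",
              x$rank, x$lambda,
              if (x$converged) "converged" else "NOT converged",
              paste(x$n_iter, collapse = "/")))
  cat(sprintf("  time bins: %d (%d observed)\n", nrow(x$v), sum(x$mask[1, ])))
  cat("  component scales:", paste(signif(x$sigma, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.grsvd <- function(object, ...) {
  res <- object$X - reconstruct(object)
  sse <- sum(res[object$mask]^2)
  sst <- sum(object$X[object$mask]^2)
  out <- list(loadings = coef(object), sigma = object$sigma,
              lambda = object$lambda,
              prop_observed_var = 1 - sse / sst,
              penalty = vapply(seq_len(object$rank), function(k) {
                v <- object$v[, k] * object$sigma[k]
                if (!is.null(object$graph)) {
                  as.numeric(v %*% (laplacian(object$graph) %*% v))
                } else NA_real_
              }, numeric(1)),
              converged = object$converged, n_iter = object$n_iter)
  class(out) <- "summary.grsvd"
  out
}

#' @export
print.summary.grsvd <- function(x, ...) {
  cat("Graph-regularised SVD\n\nModality loadings (unit columns):\n")
  print(round(x$loadings, 3))
  cat("\nScales:", paste(signif(x$sigma, 4), collapse = ", "), "\n")
  cat(sprintf("lambda = %g; observed variance explained: %.1f%%\n",
              x$lambda, 100 * x$prop_observed_var))
  cat(sprintf("Smoothness penalty v'Lv per component: %s\n",
              paste(signif(x$penalty, 4), collapse = ", ")))
  cat(if (x$converged) "Converged" else "Not converged",
      sprintf("(%s iterations)\n", paste(x$n_iter, collapse = "/")))
  invisible(x)
}

#' Modality loadings of a GRSVD fit
#'
#' @param object a `grsvd` object.
#' @param ... unused.
#' @return The modalities-by-components loading matrix (unit columns).
#' @export
coef.grsvd <- function(object, ...) {
  out <- object$u
  colnames(out) <- paste0("comp", seq_len(ncol(out)))
  out
}

#' @export
fitted.grsvd <- function(object, ...) reconstruct(object)

#' Observed-cell residuals of a GRSVD fit
#'
#' @param object a `grsvd` object.
#' @param ... unused.
#' @return Modality-by-timebin matrix; `NA` at unobserved cells.
#' @export
residuals.grsvd <- function(object, ...) {
  r <- object$X - reconstruct(object)
  r[!object$mask] <- NA_real_
  r
}

#' Predict from a GRSVD fit
#'
#' @param object a `grsvd` object.
#' @param type `"scores"` returns the day-by-24 score matrix of `component`;
#'   `"fitted"` the full low-rank reconstruction (modalities x bins);
#'   `"imputed"` the data matrix with unobserved cells filled from the
#'   reconstruction and observed cells left as given.
#' @param component component index for `type = "scores"`.
#' @param ... unused.
#' @return A matrix; see `type`.
#' @export
predict.grsvd <- function(object, type = c("scores", "fitted", "imputed"),
                          component = 1, ...) {
  type <- match.arg(type)
  switch(type,
         scores = score_matrix(object, component),
         fitted = reconstruct(object),
         imputed = {
           out <- reconstruct(object)
           out[object$mask] <- object$X[object$mask]
           out
         })
}

#' Actogram-style raster of GRSVD scores
#'
#' Days as rows (top to bottom), hours as columns; colour encodes the typing
#' activity score. Unobserved (imputed) cells can be marked with dots.
#'
#' @param x a `grsvd` object.
#' @param component component to display.
#' @param mark_missing draw a dot in cells that were imputed.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.grsvd <- function(x, component = 1, mark_missing = TRUE, ...) {
  s <- score_matrix(x, component)
  nd <- nrow(s)
  graphics::image(x = 0:24, y = seq_len(nd + 1) - 0.5, z = t(s[nd:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "hour (UTC)", ylab = "day",
                  yaxt = "n", ...)
  graphics::axis(2, at = pretty(seq_len(nd)),
                 labels = rev(seq_len(nd))[pretty(seq_len(nd))])
  if (mark_missing && !is.null(x$observed)) {
    miss <- which(!x$observed, arr.ind = TRUE)
    if (nrow(miss)) {
      graphics::points(miss[, 2] - 0.5, nd - miss[, 1] + 1,
                       pch = 16, cex = 0.3, col = "grey30")
    }
  }
  invisible(x)
}

#' Serialise a GRSVD fit
#'
#' Writes the score matrix as tidy CSV (date, hour, component, score) and a
#' JSON sidecar with loadings, scales, lambda and convergence diagnostics.
#'
#' @param fit a `grsvd` object (from [grsvd()], so day labels are present).
#' @param csv_path,json_path output paths.
#' @return `csv_path`, invisibly.
#' @export
write_grsvd <- function(fit, csv_path, json_path) {
  rows <- do.call(rbind, lapply(seq_len(fit$rank), function(k) {
    s <- score_matrix(fit, k)
    data.frame(date = rep(fit$days, 24), hour = rep(0:23, each = nrow(s)),
               component = k, score = as.vector(s))
  }))
  rows <- rows[order(rows$component, rows$date, rows$hour), ]
  utils::write.csv(rows, csv_path, row.names = FALSE)
  side <- list(loadings = as.data.frame(coef(fit)), sigma = fit$sigma,
               lambda = fit$lambda, converged = fit$converged,
               n_iter = fit$n_iter)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
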