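# The solver's contract: with the regulariser off it is a plain (masked)
# SVD; with it on, it minimises the Laplacian-penalised objective
#   sum_obs (R - u v')^2 + lambda v'Lv,  ||u|| = 1.

test_that("with lambda = 0 and full data the fit is the leading SVD triplet", {
  set.seed(1)
  X <- matrix(rnorm(4 * 240), 4, 240)
  M <- matrix(TRUE, 4, 240)
  L <- Matrix::Diagonal(240, 0)
  fit <- grsvd_fit(X, M, L, lambda = 0, tol = 1e-16, max_iter = 50000)
  sv <- svd(X)
  flip <- sign(sum(fit$u[, 1] * sv$u[, 1]))
  expect_lt(max(abs(fit$u[, 1] - flip * sv$u[, 1])), 1e-6)
  expect_lt(max(abs(fit$v[, 1] - flip * sv$v[, 1])), 1e-6)
  expect_lt(abs(fit$sigma[1] - sv$d[1]) / sv$d[1], 1e-6)
})

test_that("rank-1 data with constant time factor is recovered for any lambda", {
  u0 <- c(0.5, 0.5, 0.5, 0.5)
  v0 <- rep(2, 48)  # constant: v'Lv = 0 on a connected graph
  X <- u0 %o% v0
  M <- matrix(TRUE, 4, 48)
  L <- laplacian(build_time_graph(as.Date("2024-01-01") + 0:1))
  for (lam in c(0, 1, 100)) {
    fit <- grsvd_fit(X, M, L, lambda = lam, tol = 1e-12)
    expect_lt(max(abs(fitted(fit) - X)), 1e-8)
  }
})

test_that("toy masked problem matches a generic numerical minimiser", {
  # 2 modalities x (2 days x 4 hours), 2 masked cells, lambda = 0.5
  set.seed(7)
  X <- matrix(rnorm(16), 2, 8)
  M <- matrix(TRUE, 2, 8)
  M[1, 3] <- M[2, 6] <- FALSE
  L <- mk_lattice_laplacian(2, 4)
  lam <- 0.5

  fit <- grsvd_fit(X, M, Matrix::Matrix(L, sparse = TRUE), lambda = lam,
                   tol = 1e-14, max_iter = 10000)

  # independent oracle: generic optimiser on the identical objective,
  # parameterised by the angle of the unit loading vector and free v
  obj <- function(par) {
    u <- c(cos(par[1]), sin(par[1]))
    v <- par[2:9]
    sum(((X - u %o% v)[M])^2) + lam * as.numeric(v %*% (L %*% v))
  }
  best <- Inf
  for (th in seq(0, pi, length.out = 13)) {
    o <- stats::optim(c(th, rnorm(8, sd = 0.5)), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) {
      best <- o$value
      par_best <- o$par
    }
  }
  expect_lt(abs(min(fit$objective_trace) - best), 1e-4)

  v_fit <- fit$sigma[1] * fit$v[, 1]
  v_opt <- par_best[2:9]
  flip <- sign(sum(v_fit * v_opt))
  expect_lt(max(abs(v_fit - flip * v_opt)), 1e-4)
})

test_that("the objective trace is non-increasing", {
  set.seed(3)
  X <- matrix(rnorm(4 * 48), 4, 48)
  M <- matrix(runif(4 * 48) > 0.3, 4, 48)
  L <- laplacian(build_time_graph(as.Date("2024-01-01") + 0:1))
  for (lam in c(0.5, 5)) {
    fit <- grsvd_fit(X, M, L, lambda = lam)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("smoothness penalty decreases and scores flatten as lambda grows", {
  set.seed(5)
  days <- as.Date("2024-01-01") + 0:5
  L <- laplacian(build_time_graph(days))
  v_true <- sin(2 * pi * (seq_len(144) %% 24) / 24)
  X <- outer(c(1, 0.8, 0.6, 0.4), v_true) + matrix(rnorm(4 * 144, sd = 0.3),
                                                   4, 144)
  M <- matrix(TRUE, 4, 144)
  pen <- sapply(c(0.01, 0.1, 1, 10, 100), function(lam) {
    f <- grsvd_fit(X, M, L, lambda = lam, tol = 1e-12)
    v <- f$sigma[1] * f$v[, 1]
    as.numeric(v %*% (L %*% v))
  })
  expect_true(all(diff(pen) <= 1e-8 + 1e-8 * abs(pen[-length(pen)])))

  var0 <- var(grsvd_fit(X, M, L, lambda = 0)$v[, 1])
  var_inf <- var(grsvd_fit(X, M, L, lambda = 1e6, tol = 1e-12)$v[, 1])
  expect_lt(var_inf / var0, 1e-3)
})

test_that("graph imputation beats per-hour-of-day mean imputation", {
  # low-rank, diurnally smooth signal whose amplitude drifts across days:
  # the hour-mean baseline cannot track the drift, the graph fit can
  set.seed(42)
  nd <- 20
  L <- laplacian(build_time_graph(as.Date("2024-01-01") + seq_len(nd) - 1))
  hrs <- (seq_len(nd * 24) - 1) %% 24
  day <- (seq_len(nd * 24) - 1) %/% 24
  v_true <- sin(2 * pi * (hrs - 8) / 24) * (1 + 0.6 * sin(2 * pi * day / nd))
  X <- outer(c(1, 0.9, 0.7, 0.5), v_true) +
    matrix(rnorm(4 * nd * 24, sd = 0.2), 4)
  M <- matrix(TRUE, 4, nd * 24)
  hide <- sample(nd * 24, round(0.2 * nd * 24))
  M2 <- M
  M2[, hide] <- FALSE
  fit <- grsvd_fit(X, M2, L, lambda = 1, tol = 1e-10)
  held <- M & !M2
  rmse_graph <- sqrt(mean((X[held] - fitted(fit)[held])^2))
  base <- impute_hour_mean(X * M2, M2)
  rmse_base <- sqrt(mean((X[held] - base[held])^2))
  expect_lt(rmse_graph, rmse_base)
})

test_that("scores in one graph component ignore data in another", {
  # single-modality problem: the fitted row u * v is block-separable across
  # disconnected components, so perturbing one block leaves the other alone
  days <- as.Date("2024-01-01") + c(0:2, 10:12)  # two components
  L <- laplacian(build_time_graph(days))
  set.seed(8)
  x <- rnorm(144)
  M <- matrix(runif(144) > 0.2, 1, 144)
  f1 <- grsvd_fit(matrix(x, 1), M, L, lambda = 1, tol = 1e-12)
  x2 <- x
  x2[73:144] <- x[73:144] + rnorm(72, sd = 2)  # perturb second block only
  f2 <- grsvd_fit(matrix(x2, 1), M, L, lambda = 1, tol = 1e-12)
  s1 <- f1$sigma[1] * f1$v[1:72, 1] * sign(f1$u[1, 1])
  s2 <- f2$sigma[1] * f2$v[1:72, 1] * sign(f2$u[1, 1])
  expect_lt(max(abs(s1 - s2)), 1e-5)
})

test_that("lambda = 0 with a fully unobserved bin is rejected", {
  X <- matrix(rnorm(4 * 24), 4, 24)
  M <- matrix(TRUE, 4, 24)
  M[, 5] <- FALSE
  L <- laplacian(build_time_graph(as.Date("2024-01-01")))
  expect_error(grsvd_fit(X, M, L, lambda = 0), "lambda")
  expect_silent(grsvd_fit(X, M, L, lambda = 0.1))
})

test_that("score_matrix reshapes row-major and imputes masked night cells", {
  set.seed(9)
  days <- as.Date("2024-01-01") + 0:1
  X <- matrix(rnorm(4 * 48), 4, 48)
  M <- matrix(TRUE, 4, 48)
  L <- laplacian(build_time_graph(days))
  fit <- grsvd_fit(X, M, L, lambda = 0.1)
  fit$days <- days
  s <- score_matrix(fit, 1)
  expect_equal(dim(s), c(2, 24))
  expect_equal(s[2, 1], (fit$sigma[1] * fit$v[, 1])[25])  # cell (d2, h0)
  expect_equal(as.vector(t(s)), fit$sigma[1] * fit$v[, 1])
  expect_error(score_matrix(fit, 3), "out of range")

  # a masked cell inside a low-activity night block imputes low:
  # square-wave activity, night hours 0-7 low, one night cell re-masked
  nd <- 8
  v_sq <- rep(ifelse(0:23 %in% 0:7, -1, 1), nd)
  Xs <- outer(c(1, 1, 1, 1), v_sq)
  Ms <- matrix(TRUE, 4, nd * 24)
  Ms[, 24 * 4 + 4] <- FALSE  # hour 3 of day 5
  Ls <- laplacian(build_time_graph(as.Date("2024-01-01") + seq_len(nd) - 1))
  fs <- grsvd_fit(Xs, Ms, Ls, lambda = 1, tol = 1e-12)
  fs$days <- as.Date("2024-01-01") + seq_len(nd) - 1
  sm <- score_matrix(fs, 1)
  expect_lt(sm[5, 4], mean(sm[5, ]))  # imputed night cell below day mean
  expect_lt(rank(sm[5, ])[4], 9)      # among the low block of its day
})

test_that("the tensor-level interface wires mask, anchor and methods", {
  sim <- simulate_user(user_scenario(n_days = 8, seed = 2))
  tens <- aggregate_sessions(sim$records)
  fit <- grsvd(tens, lambda = 0.5)
  expect_s3_class(fit, "grsvd")
  expect_equal(colnames(coef(fit)), "comp1")
  expect_gte(coef(fit)["key_count", 1], 0)       # sign anchor
  expect_equal(sum(coef(fit)[, 1]^2), 1)          # unit loading
  expect_equal(dim(fit$score_matrix), c(8, 24))
  expect_true(all(is.finite(fit$score_matrix)))  # imputed everywhere

  r <- residuals(fit)
  expect_true(all(is.na(r[!fit$mask])))
  expect_false(anyNA(r[fit$mask]))
  imp <- predict(fit, "imputed")
  expect_equal(imp[fit$mask], fit$X[fit$mask])
  expect_output(print(fit), "Graph-regularised SVD")
  expect_output(print(summary(fit)), "Modality loadings")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))

  expect_warning(grsvd(tens, lambda = 0.5, max_iter = 1), "did not converge")
})

test_that("rank-2 deflation yields a second component with unit loading", {
  set.seed(12)
  days <- as.Date("2024-01-01") + 0:3
  t_idx <- seq_len(96)
  v1 <- sin(2 * pi * t_idx / 24)
  v2 <- cos(2 * pi * t_idx / 48)
  X <- outer(c(1, 1, 1, 1) / 2, 3 * v1) + outer(c(1, -1, 1, -1) / 2, v2) +
    matrix(rnorm(4 * 96, sd = 0.05), 4)
  M <- matrix(TRUE, 4, 96)
  L <- laplacian(build_time_graph(days))
  fit <- grsvd_fit(X, M, L, lambda = 0.1, rank = 2)
  expect_equal(colSums(fit$u^2), c(1, 1), tolerance = 1e-10)
  expect_gte(fit$sigma[1], fit$sigma[2])
  # residual shrinks when the second component is added
  r1 <- X - fit$sigma[1] * (fit$u[, 1] %o% fit$v[, 1])
  r2 <- r1 - fit$sigma[2] * (fit$u[, 2] %o% fit$v[, 2])
  expect_lt(sum(r2[M]^2), sum(r1[M]^2))
})
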