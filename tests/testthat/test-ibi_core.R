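test_that("the average sample is the per-gene group mean", {
  expr <- make_expr(rbind(c(2, 4, 7), c(1, 3, 9)),
                    labels = c("+", "+", "-"))
  avg <- compute_average_sample(expr, "+")
  expect_equal(unname(avg$u), c(3, 2))
  # a single-sample group reproduces that sample exactly
  avg_m <- compute_average_sample(expr, "-")
  expect_identical(unname(avg_m$u), unname(expr$values[, 3]))
  # a constant group reproduces the shared vector
  const <- make_expr(matrix(c(1, 5, 1, 5), nrow = 2), labels = c("+", "+"))
  expect_identical(unname(compute_average_sample(const, "+")$u), c(1, 5))
})

test_that("per-sample OLS matches the normal-equations oracle and lm", {
  u <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  fit <- fit_sample_regression(y, u)
  orc <- oracle_ols(u, y)
  expect_equal(fit$beta0, orc$beta0, tolerance = 1e-12)
  expect_equal(fit$beta1, orc$beta1, tolerance = 1e-12)
  lmfit <- stats::lm(y ~ u)
  expect_equal(fit$beta1, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(fit$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)

  # 100 random pairs against the brute-force oracle
  set.seed(77)
  for (rep in 1:100) {
    q <- sample(5:50, 1)
    u <- rnorm(q, 10, 3)
    y <- 0.5 + 1.5 * u + rnorm(q)
    fit <- fit_sample_regression(y, u)
    orc <- oracle_ols(u, y)
    expect_equal(fit$beta0, orc$beta0, tolerance = 1e-10)
    expect_equal(fit$beta1, orc$beta1, tolerance = 1e-10)
    prof <- compute_residuals(y, fit, u)
    scale <- q * max(abs(y))
    expect_lt(abs(sum(prof$residuals)), 1e-8 * scale)
    expect_lt(abs(sum(prof$residuals * u)), 1e-8 * scale * max(abs(u)))
    expect_equal(unname(prof$residuals), orc$residuals, tolerance = 1e-10)
  }
})

test_that("exact fits and degenerate regressors behave as contracted", {
  u <- c(1, 2, 3, 4)
  fit_self <- fit_sample_regression(u, u)
  expect_equal(fit_self$beta0, 0, tolerance = 1e-12)
  expect_equal(fit_self$beta1, 1, tolerance = 1e-12)
  expect_equal(fit_self$r_squared, 1, tolerance = 1e-12)

  fit_aff <- fit_sample_regression(2 * u + 1, u)
  expect_equal(fit_aff$beta0, 1, tolerance = 1e-12)
  expect_equal(fit_aff$beta1, 2, tolerance = 1e-12)
  prof <- compute_residuals(2 * u + 1, fit_aff, u)
  expect_equal(max(abs(prof$residuals)), 0, tolerance = 1e-12)

  # adding a constant is absorbed into the intercept
  set.seed(8)
  y <- rnorm(10)
  u10 <- rnorm(10)
  r1 <- compute_residuals(y, fit_sample_regression(y, u10), u10)
  r2 <- compute_residuals(y + 7, fit_sample_regression(y + 7, u10), u10)
  expect_equal(unname(r1$residuals), unname(r2$residuals),
               tolerance = 1e-10)

  expect_error(fit_sample_regression(c(1, 2, 3), c(4, 4, 4)),
               "degenerate regressor")
  expect_error(compute_residuals(1:3, fit_self, u),
               "4 values|3 values")
})

test_that("Silverman bandwidth matches hand formula, bw.nrd0, and scales", {
  e <- c(-1, 0, 1)
  expect_equal(select_bandwidth(e), oracle_silverman(e), tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:10) {
    e <- rnorm(sample(10:200, 1))
    h <- select_bandwidth(e)
    expect_equal(h, stats::bw.nrd0(e), tolerance = 1e-12)
    a <- runif(1, 0.1, 10)
    expect_equal(select_bandwidth(a * e), a * h, tolerance = 1e-10)
  }
  expect_error(select_bandwidth(rep(2, 5)), "degenerate residuals")
  # zero IQR with positive spread falls back to the sd
  heavy_ties <- c(rep(0, 20), 5)
  expect_gt(select_bandwidth(heavy_ties), 0)
})

test_that("kernel density and CDF match closed forms and quadrature", {
  m1 <- kde_model(0, bandwidth = 1)
  expect_equal(kde_pdf(m1, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)

  m2 <- kde_model(c(-1, 1), bandwidth = 1)
  expect_equal(kde_pdf(m2, 0), mean(dnorm(c(-1, 1))), tolerance = 1e-12)

  m3 <- kde_model(c(-1, 0, 1), bandwidth = 1)
  expect_equal(kde_cdf(m3, 1), mean(pnorm(c(2, 1, 0))), tolerance = 1e-12)
  # symmetry about the centre of mass
  expect_equal(kde_cdf(m3, 0), 0.5, tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:3) {
    e <- rnorm(50, sd = runif(1, 0.5, 3))
    model <- kde_model(e)
    grid <- seq(min(e) - 10 * model$bandwidth,
                max(e) + 10 * model$bandwidth, length.out = 2001)
    dens <- kde_pdf(model, grid)
    expect_true(all(dens >= 0))
    integral <- sum((dens[-1] + dens[-2001]) / 2 * diff(grid))
    expect_equal(integral, 1, tolerance = 1e-6)
    x <- runif(50, min(grid), max(grid))
    expect_equal(kde_cdf(model, x), oracle_kde_cdf(model, x),
                 tolerance = 1e-6)
    # CDF monotone with correct limits
    xs <- sort(x)
    expect_true(all(diff(kde_cdf(model, xs)) >= -1e-15))
    expect_lt(kde_cdf(model, min(grid)), 1e-6)
    expect_gt(kde_cdf(model, max(grid)), 1 - 1e-6)
  }
})

test_that("tail calling flags exactly the genes with extreme CDF values", {
  set.seed(41)
  e <- c(rnorm(99), 50)
  names(e) <- sprintf("G%d", seq_along(e))
  call <- call_biomarkers(e, alpha = 0.05)
  expect_true("G100" %in% call$entries$gene_id)
  expect_identical(call$entries$direction[call$entries$gene_id == "G100"],
                   "up")
  # brute force: the called set is exactly {j : Phi(e_j) outside tails}
  for (rep in 1:5) {
    e <- rnorm(200, sd = runif(1, 0.5, 5))
    names(e) <- sprintf("G%d", seq_along(e))
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    call <- call_biomarkers(e, alpha = alpha)
    model <- kde_model(e)
    phi <- kde_cdf(model, e)
    expected <- names(e)[phi < alpha / 2 | phi > 1 - alpha / 2]
    expect_setequal(call$entries$gene_id, expected)
    expect_true(all(call$entries$cdf_value < alpha / 2 |
                      call$entries$cdf_value > 1 - alpha / 2))
    expect_true(all(diff(abs(call$entries$residual)) <= 1e-12))
  }
})

test_that("degenerate and limiting alpha cases give empty calls", {
  zero <- stats::setNames(rep(0, 10), sprintf("G%d", 1:10))
  expect_warning(call <- call_biomarkers(zero), "degenerate")
  expect_identical(nrow(call$entries), 0L)

  set.seed(51)
  e <- stats::setNames(rnorm(100), sprintf("G%d", 1:100))
  expect_identical(nrow(call_biomarkers(e, alpha = 1e-12)$entries), 0L)
  expect_error(call_biomarkers(e, alpha = 0), "alpha")
  expect_error(call_biomarkers(e, alpha = 1.2), "alpha")
})

test_that("call sets are nested in alpha", {
  set.seed(61)
  e <- stats::setNames(rnorm(500), sprintf("G%d", 1:500))
  alphas <- c(0.01, 0.05, 0.1, 0.3)
  sets <- lapply(alphas, function(a)
    call_biomarkers(e, alpha = a)$entries$gene_id)
  for (k in seq_along(alphas)[-1])
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
})

test_that("calling is invariant under positive affine transforms", {
  set.seed(71)
  u <- rnorm(300, 10, 3)
  for (rep in 1:5) {
    y <- 1 + 0.8 * u + rnorm(300)
    base <- call_one_sample(y, u)
    a <- runif(1, 0.2, 5)
    b <- rnorm(1, sd = 10)
    trans <- call_one_sample(a * y + b, u)
    expect_identical(trans$entries$gene_id, base$entries$gene_id)
    expect_equal(trans$entries$cdf_value, base$entries$cdf_value,
                 tolerance = 1e-9)
    expect_equal(trans$entries$residual, a * base$entries$residual,
                 tolerance = 1e-9)
  }
})

test_that("run_ibi regresses each sample within its own group", {
  set.seed(81)
  q <- 200L
  vals <- matrix(rnorm(q * 8, 10), nrow = q)
  vals[, 5:8] <- vals[, 5:8] + 5  # the "-" group sits on its own level
  expr <- make_expr(vals, labels = rep(c("+", "-"), each = 4))
  res <- run_ibi(expr, alpha = 0.05)
  expect_named(res$calls, sample_ids(expr))
  expect_identical(res$fits$group, rep(c("+", "-"), each = 4))
  # permuting the sample columns leaves per-sample calls unchanged
  perm <- sample(8)
  expr_p <- grouped_expression(expr$values[, perm], labels = expr$labels)
  res_p <- run_ibi(expr_p, alpha = 0.05)
  for (sid in sample_ids(expr))
    expect_identical(res_p$calls[[sid]]$entries, res$calls[[sid]]$entries)
})

test_that("a group of identical samples yields empty calls, not failure", {
  col <- rnorm(50)
  expr <- make_expr(cbind(col, col, col), labels = c("+", "+", "+"),
                    samples = c("A", "B", "C"))
  res <- suppressWarnings(run_ibi(expr))
  expect_true(all(res$fits$n_called == 0L))
  expect_true(all(vapply(res$calls, function(cl) nrow(cl$entries),
                         integer(1)) == 0L))
})

test_that("a fixed bandwidth override is honoured", {
  set.seed(91)
  e <- stats::setNames(rnorm(100), sprintf("G%d", 1:100))
  call <- call_biomarkers(e, alpha = 0.05, bandwidth = 0.7)
  expect_equal(call$bandwidth, 0.7)
  model <- kde_model(e, bandwidth = 0.7)
  phi <- kde_cdf(model, e)
  expect_setequal(call$entries$gene_id,
                  names(e)[phi < 0.025 | phi > 0.975])
})
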