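# Independent oracles and fixture builders shared across the suite.

# Small labelled expression object built in code.
make_expr <- function(values, labels = NULL,
                      genes = sprintf("G%d", seq_len(nrow(values))),
                      samples = sprintf("S%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  if (!is.null(labels)) labels <- stats::setNames(labels, samples)
  grouped_expression(values, labels = labels)
}

# Brute-force simple-OLS oracle: solve the 2x2 normal equations directly.
oracle_ols <- function(u, y) {
  X <- cbind(1, u)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(beta0 = beta[1L], beta1 = beta[2L],
       residuals = as.numeric(y - X %*% beta))
}

# Textbook Welch two-sample t-test (unequal variances).
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Hand computation of the Silverman rule with independently computed
# spread statistics.
oracle_silverman <- function(e) {
  q <- length(e)
  s <- sqrt(sum((e - mean(e))^2) / (q - 1))
  qs <- stats::quantile(e, c(0.25, 0.75), names = FALSE)
  0.9 * min(s, (qs[2] - qs[1]) / 1.34) * q^(-1 / 5)
}

# Two-sample KS statistic computed from first principles.
oracle_ks_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(t) mean(x <= t), numeric(1))
  fy <- vapply(grid, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# Exact two-sample KS p-value by enumerating every assignment of the
# pooled sample into groups of sizes m and n (feasible for m, n <= 6).
oracle_ks_exact_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  d_obs <- oracle_ks_stat(x, y)
  combos <- utils::combn(m + n, m)
  d_all <- apply(combos, 2L, function(idx)
    oracle_ks_stat(pooled[idx], pooled[-idx]))
  mean(d_all >= d_obs - 1e-12)
}

# CDF oracle: trapezoidal integration of the kernel density on a dense
# grid, interpolated at the query points.
oracle_kde_cdf <- function(model, x, n_grid = 50001L) {
  e <- model$residuals
  h <- model$bandwidth
  grid <- seq(min(e) - 10 * h, max(e) + 10 * h, length.out = n_grid)
  dens <- kde_pdf(model, grid)
  dx <- diff(grid)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dx))
  stats::approx(grid, cum, xout = x, rule = 2)$y
}

# The per-sample calling path against a fixed average profile.
call_one_sample <- function(y, u, alpha = 0.05,
                            ids = sprintf("G%d", seq_along(y))) {
  names(y) <- ids
  fit <- fit_sample_regression(y, u, sample_id = "s")
  prof <- compute_residuals(y, fit, u)
  prof$gene_ids <- ids
  names(prof$residuals) <- ids
  call_biomarkers(prof, alpha = alpha)
}

# A synthetic biomarker_call with a fixed gene set, for evaluation tests.
make_call <- function(sample_id, genes, alpha = 0.05) {
  entries <- data.frame(gene_id = as.character(genes),
                        residual = rep(3, length(genes)),
                        cdf_value = rep(0.999, length(genes)),
                        direction = rep("up", length(genes)),
                        stringsAsFactors = FALSE)
  if (length(genes) == 0L)
    entries <- entries[0, , drop = FALSE]
  structure(list(sample_id = sample_id, alpha = alpha, bandwidth = 1,
                 entries = entries),
            class = "biomarker_call")
}
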