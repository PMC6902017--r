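# The biomarker-calling algorithm: group-average profile, per-sample OLS
# regression, residuals, Gaussian KDE of the residuals, and two-sided
# tail calling on the smoothed CDF.

#' Average expression profile of a group
#'
#' The per-gene arithmetic mean over the samples carrying one label; this
#' vector is the regressor every individual sample of the group is fitted
#' against.
#'
#' @param expr A labelled [grouped_expression()].
#' @param group `"+"` or `"-"`; must have at least one sample.
#' @return An object of class `average_sample`: list with `group`,
#'   `gene_ids`, and `u` (named numeric vector of per-gene means).
#' @export
compute_average_sample <- function(expr, group) {
  stopifnot(inherits(expr, "grouped_expression"))
  members <- group_samples(expr, group)
  if (length(members) == 0L)
    stop("group \"", group, "\" has no samples")
  u <- rowMeans(expr$values[, members, drop = FALSE])
  structure(list(group = normalize_labels(group),
                 gene_ids = gene_ids(expr), u = u),
            class = "average_sample")
}

#' Fit a single sample against its group average
#'
#' Simple ordinary least squares across the q genes: the sample's
#' expression values are regressed on the group-average profile,
#' `y_j = beta0 + beta1 * u_j + e_j`, using the closed-form solution of
#' the normal equations.
#'
#' @param sample_values Numeric vector of the sample's expression over
#'   the q genes, in the gene order of `avg`.
#' @param avg An [compute_average_sample()] result, or a plain numeric
#'   vector of per-gene means.
#' @param sample_id Optional sample id recorded in the fit.
#' @return An object of class `regression_fit`: list with `sample_id`,
#'   `beta0`, `beta1`, `r_squared`.
#' @export
fit_sample_regression <- function(sample_values, avg, sample_id = NA_character_) {
  u <- if (inherits(avg, "average_sample")) avg$u else as.numeric(avg)
  y <- as.numeric(sample_values)
  if (length(y) != length(u))
    stop("sample has ", length(y), " values but average has ", length(u))
  q <- length(u)
  if (q < 2L) stop("regression needs at least two genes")
  ubar <- mean(u)
  ybar <- mean(y)
  suu <- sum((u - ubar)^2)
  if (suu == 0) stop("degenerate regressor: average profile is constant")
  beta1 <- sum((u - ubar) * (y - ybar)) / suu
  beta0 <- ybar - beta1 * ubar
  e <- y - (beta0 + beta1 * u)
  sst <- sum((y - ybar)^2)
  r2 <- if (sst == 0) 1 else 1 - sum(e^2) / sst
  structure(list(sample_id = sample_id, beta0 = beta0, beta1 = beta1,
                 r_squared = r2),
            class = "regression_fit")
}

#' Per-gene regression residuals of a sample
#'
#' `e_j = y_j - (beta0 + beta1 * u_j)`. By the OLS normal equations the
#' residuals sum to zero and are orthogonal to the average profile.
#'
#' @param sample_values Numeric vector over the q genes.
#' @param fit A [fit_sample_regression()] result for this sample.
#' @param avg The same average profile the fit was produced from.
#' @return An object of class `residual_profile`: list with `sample_id`,
#'   `gene_ids`, `residuals` (named numeric vector).
#' @export
compute_residuals <- function(sample_values, fit, avg) {
  stopifnot(inherits(fit, "regression_fit"))
  u <- if (inherits(avg, "average_sample")) avg$u else as.numeric(avg)
  y <- as.numeric(sample_values)
  if (length(y) != length(u))
    stop("sample has ", length(y), " values but average has ", length(u))
  e <- y - (fit$beta0 + fit$beta1 * u)
  ids <- if (inherits(avg, "average_sample")) avg$gene_ids else names(u)
  if (!is.null(ids)) names(e) <- ids
  structure(list(sample_id = fit$sample_id, gene_ids = ids, residuals = e),
            class = "residual_profile")
}

#' Silverman rule-of-thumb bandwidth
#'
#' `h = 0.9 * min(sd, IQR/1.34) * q^(-1/5)` with `sd` the sample standard
#' deviation. When the IQR is zero but the residuals still have positive
#' spread (heavy ties), the rule falls back to the standard deviation
#' alone so the bandwidth stays positive.
#'
#' @param residuals Numeric vector, at least two values with positive
#'   spread.
#' @return Positive bandwidth in residual units.
#' @export
select_bandwidth <- function(residuals) {
  e <- as.numeric(residuals)
  if (length(e) < 2L) stop("bandwidth selection needs at least two residuals")
  s <- stats::sd(e)
  if (s == 0) stop("degenerate residuals: zero spread")
  spread <- min(s, stats::IQR(e) / 1.34)
  if (spread == 0) spread <- s
  0.9 * spread * length(e)^(-1 / 5)
}

#' Gaussian kernel density model of a residual vector
#'
#' @param residuals Numeric vector of kernel centres (the q residuals).
#' @param bandwidth Positive bandwidth `h`; by default chosen with
#'   [select_bandwidth()].
#' @return An object of class `kde_model`: list with `residuals`,
#'   `bandwidth`, `q`.
#' @export
kde_model <- function(residuals, bandwidth = NULL) {
  e <- as.numeric(residuals)
  if (length(e) < 1L || any(!is.finite(e)))
    stop("residuals must be a non-empty finite numeric vector")
  h <- if (is.null(bandwidth)) select_bandwidth(e) else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0) stop("bandwidth must be a positive number")
  structure(list(residuals = e, bandwidth = h, q = length(e)),
            class = "kde_model")
}

# Evaluate sum over kernel centres in memory-bounded chunks.
kde_eval <- function(model, x, fun) {
  e <- model$residuals
  h <- model$bandwidth
  q <- model$q
  x <- as.numeric(x)
  out <- numeric(length(x))
  chunk <- max(1L, floor(4e6 / q))
  for (start in seq(1L, length(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(x))
    z <- (rep(x[idx], each = q) - e) / h
    m <- matrix(fun(z), nrow = q)
    out[idx] <- colMeans(m)
  }
  out
}

#' Kernel density estimate of the residual distribution
#'
#' `f(x) = (1/(q h)) * sum_j K((x - e_j)/h)` with `K` the standard
#' Gaussian kernel.
#'
#' @param model A [kde_model()].
#' @param x Numeric vector of query points.
#' @return Non-negative densities, one per query point.
#' @export
kde_pdf <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  kde_eval(model, x, stats::dnorm) / model$bandwidth
}

#' Smoothed cumulative distribution of the residuals
#'
#' The closed-form integral of [kde_pdf()]:
#' `Phi(x) = (1/q) * sum_j pnorm((x - e_j)/h)`.
#'
#' @param model A [kde_model()].
#' @param x Numeric vector of query points.
#' @return Probabilities in `[0, 1]`, one per query point.
#' @export
kde_cdf <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  kde_eval(model, x, stats::pnorm)
}

# Last index k of the ascending vector `es` with Phi(es[k]) < alpha/2
# (lower tail), and first index with Phi(es[k]) > 1 - alpha/2 (upper
# tail). Phi(es[k]) is non-decreasing in k, so a binary search touching
# O(log q) points is exactly equivalent to evaluating the CDF at every
# residual; ties in `es` share a CDF value and therefore a call status.
tail_cut_indices <- function(model, es, alpha) {
  q <- length(es)
  phi1 <- function(k) kde_cdf(model, es[k])
  lo <- 0L
  hi <- q
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (phi1(mid) < alpha / 2) lo <- mid else hi <- mid - 1L
  }
  k_lo <- lo
  lo <- 1L
  hi <- q + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (phi1(mid) > 1 - alpha / 2) hi <- mid else lo <- mid + 1L
  }
  list(lower = k_lo, upper = lo)
}

#' Call the biomarker genes of one sample
#'
#' Builds a Gaussian KDE of the sample's residuals and flags every gene
#' whose residual falls in either tail of the smoothed CDF: gene j is
#' called when `Phi(e_j) < alpha/2` or `Phi(e_j) > 1 - alpha/2`. The two
#' tails form the credibility interval at confidence level `1 - alpha`;
#' direction is `"up"` for positive residuals (expression above the
#' sample's regression line) and `"down"` otherwise.
#'
#' A residual vector with zero spread (a perfect fit) admits no density
#' estimate and yields an empty call set with a warning rather than an
#' error.
#'
#' @param profile A [compute_residuals()] result, or a named numeric
#'   residual vector.
#' @param alpha Tail probability in (0, 1); default 0.05 (95% level).
#' @param bandwidth Optional fixed KDE bandwidth overriding Silverman's
#'   rule.
#' @return An object of class `biomarker_call`: list with `sample_id`,
#'   `alpha`, `bandwidth`, and `entries`, a data frame with columns
#'   `gene_id`, `residual`, `cdf_value`, `direction`, sorted by
#'   descending absolute residual.
#' @export
call_biomarkers <- function(profile, alpha = 0.05, bandwidth = NULL) {
  if (inherits(profile, "residual_profile")) {
    e <- profile$residuals
    ids <- profile$gene_ids
    sid <- profile$sample_id
  } else {
    e <- as.numeric(profile)
    ids <- names(profile)
    sid <- NA_character_
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  q <- length(e)
  if (q < 2L) stop("biomarker calling needs at least two genes")
  if (is.null(ids)) ids <- paste0("g", seq_len(q))
  empty <- data.frame(gene_id = character(), residual = numeric(),
                      cdf_value = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  model <- tryCatch(kde_model(e, bandwidth = bandwidth),
                    error = function(cond) {
                      if (grepl("degenerate residuals", conditionMessage(cond))) {
                        warning("degenerate residuals (zero spread): ",
                                "empty biomarker call", call. = FALSE)
                        NULL
                      } else stop(cond)
                    })
  if (is.null(model))
    return(structure(list(sample_id = sid, alpha = alpha,
                          bandwidth = NA_real_, entries = empty),
                     class = "biomarker_call"))
  ord <- order(e)
  cuts <- tail_cut_indices(model, e[ord], alpha)
  called_pos <- unique(c(if (cuts$lower >= 1L) ord[seq_len(cuts$lower)],
                         if (cuts$upper <= q) ord[cuts$upper:q]))
  if (length(called_pos) == 0L)
    return(structure(list(sample_id = sid, alpha = alpha,
                          bandwidth = model$bandwidth, entries = empty),
                     class = "biomarker_call"))
  entries <- data.frame(gene_id = ids[called_pos],
                        residual = unname(e[called_pos]),
                        cdf_value = kde_cdf(model, e[called_pos]),
                        direction = ifelse(e[called_pos] > 0, "up", "down"),
                        stringsAsFactors = FALSE)
  entries <- entries[order(-abs(entries$residual), entries$gene_id), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(list(sample_id = sid, alpha = alpha,
                 bandwidth = model$bandwidth, entries = entries),
            class = "biomarker_call")
}

#' @export
print.biomarker_call <- function(x, ...) {
  cat(sprintf("biomarker_call: sample %s, alpha %g, %d gene(s) called\n",
              x$sample_id, x$alpha, nrow(x$entries)))
  if (nrow(x$entries)) print(utils::head(x$entries, 10L))
  invisible(x)
}

#' Run the full biomarker-calling pipeline
#'
#' For every sample: regress it against the average profile of its own
#' labelled group, compute residuals, and call the genes in either CDF
#' tail. Samples whose residuals have zero spread (e.g. a group of
#' identical samples) receive an empty call with a warning rather than
#' failing the run.
#'
#' @param expr A labelled [grouped_expression()], usually already
#'   restricted to the DEG universe (see [select_degs()] and
#'   [apply_gene_filter()]).
#' @param alpha Tail probability in (0, 1); default 0.05.
#' @param bandwidth Optional fixed KDE bandwidth overriding Silverman's
#'   rule for every sample.
#' @return An object of class `ibi_result`: list with
#'   \describe{
#'     \item{`calls`}{named list, one [call_biomarkers()] result per
#'       sample (names are sample ids, input order).}
#'     \item{`fits`}{data frame with one row per sample: `sample_id`,
#'       `group`, `beta0`, `beta1`, `r_squared`, `bandwidth`,
#'       `n_called`.}
#'     \item{`alpha`}{the tail probability used.}
#'   }
#' @export
run_ibi <- function(expr, alpha = 0.05, bandwidth = NULL) {
  stopifnot(inherits(expr, "grouped_expression"))
  if (is.null(expr$labels)) stop("run_ibi requires group labels")
  groups <- unique(expr$labels)
  averages <- lapply(stats::setNames(groups, groups),
                     function(g) compute_average_sample(expr, g))
  sids <- sample_ids(expr)
  calls <- vector("list", length(sids))
  names(calls) <- sids
  fits <- vector("list", length(sids))
  for (i in seq_along(sids)) {
    sid <- sids[i]
    g <- expr$labels[[sid]]
    avg <- averages[[g]]
    fit <- fit_sample_regression(expr$values[, sid], avg, sample_id = sid)
    prof <- compute_residuals(expr$values[, sid], fit, avg)
    call <- call_biomarkers(prof, alpha = alpha, bandwidth = bandwidth)
    calls[[sid]] <- call
    fits[[i]] <- data.frame(sample_id = sid, group = g,
                            beta0 = fit$beta0, beta1 = fit$beta1,
                            r_squared = fit$r_squared,
                            bandwidth = call$bandwidth,
                            n_called = nrow(call$entries),
                            stringsAsFactors = FALSE)
  }
  structure(list(calls = calls, fits = do.call(rbind, fits), alpha = alpha),
            class = "ibi_result")
}

#' @export
print.ibi_result <- function(x, ...) {
  cat(sprintf("ibi_result: %d samples, alpha %g\n",
              length(x$calls), x$alpha))
  cat(sprintf("  genes called per sample: median %g (range %d-%d)\n",
              stats::median(x$fits$n_called), min(x$fits$n_called),
              max(x$fits$n_called)))
  invisible(x)
}

#' Flatten biomarker calls into one table
#'
#' @param calls An `ibi_result` or a named list of `biomarker_call`s.
#' @return Data frame with columns `sample_id`, `gene_id`, `residual`,
#'   `cdf_value`, `direction` (one row per called gene per sample).
#' @export
calls_table <- function(calls) {
  if (inherits(calls, "ibi_result")) calls <- calls$calls
  rows <- lapply(calls, function(cl) {
    if (nrow(cl$entries) == 0L) return(NULL)
    data.frame(sample_id = cl$sample_id, cl$entries,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), gene_id = character(),
                      residual = numeric(), cdf_value = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
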