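# Seeded simulator: baseline expression with optional latent-factor
# correlation, plus sample-specific perturbations of predefined gene
# groups with ground-truth emission.

#' Simulation configuration
#'
#' Parameters of the synthetic-expression experiment: an
#' `n_genes x n_samples` baseline with per-gene means drawn uniformly
#' from `baseline_mean_range`, an optional low-rank latent-factor
#' structure inducing gene-gene correlation, and i.i.d. Gaussian noise.
#' The genes are partitioned into `n_groups` contiguous equal blocks and
#' block i is perturbed in sample i by `multiplier` times the gene's
#' pre-perturbation mean, with a random up/down sign per gene.
#'
#' Defaults encode the reference design: 10 samples, 1000 genes in 10
#' groups of 100, means on \[5, 15\], unit noise, two latent factors
#' (loading sd 0.5), and a perturbation of twice the gene mean.
#'
#' @param n_samples Number of samples (default 10).
#' @param n_genes Number of genes (default 1000); must be a multiple of
#'   `n_groups`.
#' @param n_groups Number of gene groups (default 10); must not exceed
#'   `n_samples`.
#' @param baseline_mean_range Length-2 interval for per-gene baseline
#'   means (default `c(5, 15)`).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise
#'   (default 1).
#' @param n_latent_factors Number of shared latent factors (default 2);
#'   0 disables the correlation structure.
#' @param factor_loading_sd Standard deviation of the Gaussian factor
#'   loadings (default 0.5); factor scores are standard normal.
#' @param multiplier Perturbation magnitude as a multiple of the
#'   per-gene pre-perturbation mean (default 2; 0 disables
#'   perturbation).
#' @param seed Integer RNG seed (default 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 10L, n_genes = 1000L, n_groups = 10L,
                       baseline_mean_range = c(5, 15), noise_sd = 1,
                       n_latent_factors = 2L, factor_loading_sd = 0.5,
                       multiplier = 2, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_groups = as.integer(n_groups),
              baseline_mean_range = as.numeric(baseline_mean_range),
              noise_sd = as.numeric(noise_sd),
              n_latent_factors = as.integer(n_latent_factors),
              factor_loading_sd = as.numeric(factor_loading_sd),
              multiplier = as.numeric(multiplier),
              seed = as.integer(seed))
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$n_samples >= 1L, "n_samples must be >= 1")
  chk(cfg$n_genes >= 1L, "n_genes must be >= 1")
  chk(cfg$n_groups >= 1L, "n_groups must be >= 1")
  chk(cfg$n_genes %% cfg$n_groups == 0L,
      "n_genes must be a multiple of n_groups")
  chk(length(cfg$baseline_mean_range) == 2L &&
        all(is.finite(cfg$baseline_mean_range)) &&
        cfg$baseline_mean_range[1L] <= cfg$baseline_mean_range[2L],
      "baseline_mean_range must be a finite interval c(lo, hi)")
  chk(is.finite(cfg$noise_sd) && cfg$noise_sd > 0,
      "noise_sd must be > 0")
  chk(cfg$n_latent_factors >= 0L, "n_latent_factors must be >= 0")
  chk(is.finite(cfg$factor_loading_sd) && cfg$factor_loading_sd > 0,
      "factor_loading_sd must be > 0")
  chk(is.finite(cfg$multiplier) && cfg$multiplier >= 0,
      "multiplier must be >= 0")
  chk(!is.na(cfg$seed) && abs(cfg$seed) < 2^31 - 2,
      "seed must be an integer below 2^31 - 2 in magnitude")
  if (length(problems))
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("gene_%04d", seq_len(n))
sim_sample_ids <- function(n) sprintf("sample_%02d", seq_len(n))

#' Simulate a baseline expression matrix
#'
#' `value(g, s) = mu_g + sum_f load(g, f) * score(s, f) + eps(g, s)`
#' with `mu_g` uniform on `baseline_mean_range`, loadings
#' `N(0, factor_loading_sd^2)`, scores `N(0, 1)` and
#' `eps ~ N(0, noise_sd^2)`. Fully determined by `config$seed`. All
#' samples carry the `"+"` label (the simulation is a single-group
#' design).
#'
#' @param config A [sim_config()].
#' @return A labelled [grouped_expression()].
#' @export
simulate_baseline <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  qg <- config$n_genes
  ns <- config$n_samples
  mu <- stats::runif(qg, config$baseline_mean_range[1L],
                     config$baseline_mean_range[2L])
  values <- matrix(mu, nrow = qg, ncol = ns)
  if (config$n_latent_factors > 0L) {
    loadings <- matrix(stats::rnorm(qg * config$n_latent_factors,
                                    sd = config$factor_loading_sd),
                       nrow = qg)
    scores <- matrix(stats::rnorm(config$n_latent_factors * ns),
                     nrow = config$n_latent_factors)
    values <- values + loadings %*% scores
  }
  values <- values + matrix(stats::rnorm(qg * ns, sd = config$noise_sd),
                            nrow = qg)
  dimnames(values) <- list(sim_gene_ids(qg), sim_sample_ids(ns))
  labels <- stats::setNames(rep("+", ns), colnames(values))
  grouped_expression(values, labels = labels)
}

#' Gene-group block assignment
#'
#' Contiguous equal blocks by gene index: block i holds genes
#' `((i-1) * n_genes/n_groups + 1) .. (i * n_genes/n_groups)`.
#'
#' @param config A [sim_config()].
#' @return Named list mapping `"1" .. n_groups` to gene-id vectors.
#' @export
gene_groups <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per <- config$n_genes %/% config$n_groups
  ids <- sim_gene_ids(config$n_genes)
  stats::setNames(
    lapply(seq_len(config$n_groups),
           function(i) ids[((i - 1L) * per + 1L):(i * per)]),
    as.character(seq_len(config$n_groups)))
}

#' Construct a ground-truth object
#'
#' @param table Data frame with columns `sample_id`, `gene_id`, `sign`
#'   (+1/-1), `magnitude` (expression units).
#' @return List of class `ground_truth` with the `table` and `sets`, a
#'   named list mapping each sample id to its perturbed gene ids.
#' @export
ground_truth <- function(table) {
  stopifnot(all(c("sample_id", "gene_id", "sign", "magnitude") %in%
                  names(table)))
  sets <- split(table$gene_id, table$sample_id)
  structure(list(table = table, sets = sets), class = "ground_truth")
}

#' Inject sample-specific grouped perturbations
#'
#' For sample i (i = 1 .. `n_groups`), every gene g of block i is
#' shifted by `sign(g) * multiplier * mean_g`, where `mean_g` is the
#' gene's mean over all samples before any perturbation and the sign is
#' an even +1/-1 draw per gene (seeded from `config$seed`). Samples
#' beyond `n_groups` are left unperturbed. Unperturbed cells are
#' untouched to the last bit.
#'
#' @param expr The baseline [grouped_expression()] from
#'   [simulate_baseline()].
#' @param config The same [sim_config()].
#' @return List with `expr` (perturbed matrix) and `truth`
#'   (a [ground_truth()]).
#' @export
inject_perturbations <- function(expr, config) {
  stopifnot(inherits(expr, "grouped_expression"),
            inherits(config, "sim_config"))
  if (config$n_groups > n_samples(expr))
    stop("n_groups (", config$n_groups, ") exceeds number of samples (",
         n_samples(expr), ")")
  if (n_genes(expr) != config$n_genes)
    stop("matrix has ", n_genes(expr), " genes but config expects ",
         config$n_genes)
  # Offset the sign stream from the baseline stream so signs and
  # baseline means are independent draws.
  set.seed(config$seed + 1L)
  signs <- sample(c(-1, 1), n_genes(expr), replace = TRUE)
  names(signs) <- gene_ids(expr)
  pre_means <- rowMeans(expr$values)
  groups <- gene_groups(config)
  values <- expr$values
  sids <- sample_ids(expr)
  rows <- vector("list", config$n_groups)
  for (i in seq_len(config$n_groups)) {
    genes <- groups[[i]]
    shift <- signs[genes] * config$multiplier * pre_means[genes]
    values[genes, sids[i]] <- values[genes, sids[i]] + shift
    rows[[i]] <- data.frame(sample_id = sids[i], gene_id = genes,
                            sign = unname(signs[genes]),
                            magnitude = unname(abs(shift)),
                            stringsAsFactors = FALSE)
  }
  truth_tab <- do.call(rbind, rows)
  rownames(truth_tab) <- NULL
  list(expr = grouped_expression(values, labels = expr$labels),
       truth = ground_truth(truth_tab))
}

#' Simulate a complete perturbed dataset
#'
#' Convenience wrapper: [simulate_baseline()] followed by
#' [inject_perturbations()].
#'
#' @param config A [sim_config()].
#' @return List with `expr` and `truth` as in [inject_perturbations()].
#' @export
simulate_ibi_data <- function(config = sim_config()) {
  inject_perturbations(simulate_baseline(config), config)
}

#' Write / read ground truth as TSV
#'
#' The file lists one perturbed (sample, gene) pair per line:
#' `sample_id<TAB>gene_id<TAB>sign<TAB>magnitude` with a header row.
#'
#' @param truth A [ground_truth()].
#' @param path File path.
#' @return `path` (writer, invisibly) or a `ground_truth` (reader).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.table(truth$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "gene_id") %in% names(df)))
    stop("ground truth file needs sample_id and gene_id columns")
  if (is.null(df$sign)) df$sign <- NA_real_
  if (is.null(df$magnitude)) df$magnitude <- NA_real_
  ground_truth(df)
}
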