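# Evaluation machinery: rank-matrix KS specificity, biomarker frequency
# analysis across groups, and recovery scoring against simulation truth.

#' Rank matrix of one sample's biomarker genes
#'
#' For every gene called in the focal sample, the expression values of
#' that gene across all n samples are ranked (ascending, average ranks
#' for ties). Row i of the matrix holds sample i's ranks over the focal
#' sample's biomarker genes; comparing the focal row against any other
#' row shows whether the called genes are specific to the focal sample.
#'
#' @param expr A [grouped_expression()] containing every called gene.
#' @param call A [call_biomarkers()] result with a non-empty call set.
#' @return An object of class `rank_matrix`: list with `focal_sample`,
#'   `biomarker_genes`, and `ranks`, an n-samples x n-genes matrix.
#' @export
build_rank_matrix <- function(expr, call) {
  stopifnot(inherits(expr, "grouped_expression"),
            inherits(call, "biomarker_call"))
  genes <- call$entries$gene_id
  if (length(genes) == 0L) stop("no biomarkers to rank")
  if (n_samples(expr) < 2L) stop("ranking needs at least two samples")
  unknown <- setdiff(genes, gene_ids(expr))
  if (length(unknown))
    stop("called gene(s) absent from expression matrix: ",
         paste(unknown, collapse = ", "))
  sub <- expr$values[genes, , drop = FALSE]
  ranks <- t(apply(sub, 1L, rank, ties.method = "average"))
  ranks <- t(ranks)  # rows = samples, columns = genes
  dimnames(ranks) <- list(sample_ids(expr), genes)
  structure(list(focal_sample = call$sample_id, biomarker_genes = genes,
                 ranks = ranks),
            class = "rank_matrix")
}

#' Kolmogorov-Smirnov test between two rank-matrix rows
#'
#' Two-sample two-sided KS test comparing the rank vectors of samples
#' `i` and `j` over the focal sample's biomarker genes. The p-value
#' follows [stats::ks.test()] conventions: exact for small tie-free
#' samples, asymptotic otherwise (rank vectors usually contain ties, so
#' the asymptotic approximation is the common path; the tie warning is
#' suppressed).
#'
#' @param rm A [build_rank_matrix()] result.
#' @param i,j Distinct sample ids (rows of the rank matrix).
#' @return List with `statistic` (in `[0, 1]`) and `p_value`.
#' @export
ks_specificity_test <- function(rm, i, j) {
  stopifnot(inherits(rm, "rank_matrix"))
  if (identical(i, j)) stop("i and j must be distinct samples")
  for (s in c(i, j))
    if (!s %in% rownames(rm$ranks))
      stop("sample '", s, "' not in rank matrix")
  ri <- rm$ranks[i, ]
  rj <- rm$ranks[j, ]
  kt <- suppressWarnings(stats::ks.test(ri, rj, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Pairwise KS specificity summary
#'
#' For every ordered pair (i, j), i != j: build the rank matrix from
#' sample i's biomarker genes and KS-test row i against row j. Returns
#' the fraction of the n(n-1) p-values below `threshold`. Focal samples
#' with empty call sets contribute no pairs; the number of skipped pairs
#' is attached as an attribute.
#'
#' @param expr The [grouped_expression()] the calls were made on.
#' @param calls An `ibi_result` or named list of `biomarker_call`s.
#' @param threshold Significance threshold on the KS p-value
#'   (default 0.05).
#' @return Fraction of tested ordered pairs with p-value below
#'   `threshold`, with attributes `n_pairs` (tested) and `n_skipped`.
#' @export
ks_specificity_summary <- function(expr, calls, threshold = 0.05) {
  if (inherits(calls, "ibi_result")) calls <- calls$calls
  sids <- sample_ids(expr)
  n_sig <- 0L
  n_pairs <- 0L
  n_skipped <- 0L
  for (i in sids) {
    cl <- calls[[i]]
    if (is.null(cl) || nrow(cl$entries) == 0L) {
      n_skipped <- n_skipped + length(sids) - 1L
      next
    }
    rm_i <- build_rank_matrix(expr, cl)
    for (j in setdiff(sids, i)) {
      res <- ks_specificity_test(rm_i, i, j)
      n_pairs <- n_pairs + 1L
      if (res$p_value < threshold) n_sig <- n_sig + 1L
    }
  }
  frac <- if (n_pairs == 0L) 0 else n_sig / n_pairs
  structure(frac, n_pairs = n_pairs, n_skipped = n_skipped)
}

#' Per-group biomarker calling frequencies
#'
#' For every gene called in at least one sample: the proportion of each
#' group's samples in which the gene was called, and the difference
#' between the two proportions. A gene found in many samples of one
#' group but few of the other is a candidate group-level marker.
#'
#' @param calls An `ibi_result` or named list of `biomarker_call`s.
#' @param labels Named character vector mapping sample ids to
#'   `"+"`/`"-"`, or a labelled `grouped_expression`.
#' @return Data frame (class `frequency_table`) with columns `gene_id`,
#'   `freq_plus`, `freq_minus`, `diff`, ordered by gene id; empty when
#'   no gene was ever called.
#' @export
biomarker_frequency <- function(calls, labels) {
  if (inherits(calls, "ibi_result")) calls <- calls$calls
  if (inherits(labels, "grouped_expression")) labels <- labels$labels
  labels <- normalize_labels(labels)
  sids <- names(calls)
  missing <- setdiff(sids, names(labels))
  if (length(missing))
    stop("no label for sample(s): ", paste(missing, collapse = ", "))
  n_plus <- sum(labels[sids] == "+")
  n_minus <- sum(labels[sids] == "-")
  tab <- calls_table(calls)
  if (nrow(tab) == 0L)
    return(structure(data.frame(gene_id = character(),
                                freq_plus = numeric(),
                                freq_minus = numeric(), diff = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("frequency_table", "data.frame")))
  tab$group <- unname(labels[tab$sample_id])
  genes <- sort(unique(tab$gene_id))
  cnt <- function(g) {
    sub <- tab[tab$group == g, , drop = FALSE]
    v <- table(factor(sub$gene_id, levels = genes))
    as.numeric(v)
  }
  freq_plus <- if (n_plus > 0L) cnt("+") / n_plus else numeric(length(genes))
  freq_minus <- if (n_minus > 0L) cnt("-") / n_minus else numeric(length(genes))
  structure(data.frame(gene_id = genes, freq_plus = freq_plus,
                       freq_minus = freq_minus,
                       diff = freq_plus - freq_minus,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("frequency_table", "data.frame"))
}

#' Top genes by frequency difference
#'
#' Genes ranked by descending difference of calling frequency between
#' the two groups (ties broken by descending `freq_plus`, then by gene
#' id), truncated to the first `k`.
#'
#' @param table A [biomarker_frequency()] result.
#' @param k Positive number of genes to return; if larger than the
#'   table, the whole ranking is returned with a warning.
#' @return Character vector of gene ids.
#' @export
rank_frequency_difference <- function(table, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive integer")
  if (nrow(table) == 0L) stop("frequency table is empty")
  ord <- order(-table$diff, -table$freq_plus, table$gene_id)
  ranked <- table$gene_id[ord]
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds table size ", length(ranked),
            "; returning all genes")
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}

#' Score calls against simulation ground truth
#'
#' Per-sample and pooled precision/recall of the called gene sets
#' against each sample's predefined perturbed genes. Pooled precision is
#' `sum |called & truth| / sum |called|`, i.e. the call-count-weighted
#' mean of the per-sample precisions.
#'
#' @param calls An `ibi_result` or named list of `biomarker_call`s.
#' @param truth A [ground_truth()] (or a named list mapping sample ids
#'   to character vectors of perturbed gene ids) covering every sample
#'   in `calls`.
#' @return List (class `recovery_metrics`) with `per_sample` (data frame
#'   of `sample_id`, `n_called`, `n_truth`, `n_hit`, `precision`,
#'   `recall`; precision is `NA` for an empty call set) and `pooled`
#'   (list of `precision`, `recall`, `n_called`, `n_truth`, `n_hit`).
#' @export
evaluate_recovery <- function(calls, truth) {
  if (inherits(calls, "ibi_result")) calls <- calls$calls
  sets <- if (inherits(truth, "ground_truth")) truth$sets else truth
  missing <- setdiff(names(calls), names(sets))
  if (length(missing))
    stop("sample(s) absent from ground truth: ",
         paste(missing, collapse = ", "))
  rows <- lapply(names(calls), function(sid) {
    called <- calls[[sid]]$entries$gene_id
    tr <- sets[[sid]]
    hit <- length(intersect(called, tr))
    data.frame(sample_id = sid, n_called = length(called),
               n_truth = length(tr), n_hit = hit,
               precision = if (length(called)) hit / length(called)
                           else NA_real_,
               recall = if (length(tr)) hit / length(tr) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  tot_called <- sum(per_sample$n_called)
  tot_truth <- sum(per_sample$n_truth)
  tot_hit <- sum(per_sample$n_hit)
  pooled <- list(precision = if (tot_called) tot_hit / tot_called
                             else NA_real_,
                 recall = if (tot_truth) tot_hit / tot_truth else NA_real_,
                 n_called = tot_called, n_truth = tot_truth,
                 n_hit = tot_hit)
  structure(list(per_sample = per_sample, pooled = pooled),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("recovery: pooled precision %.4f, recall %.4f (%d called, %d truth)\n",
              x$pooled$precision, x$pooled$recall, x$pooled$n_called,
              x$pooled$n_truth))
  invisible(x)
}
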