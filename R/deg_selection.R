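# Differential-expression filtering: defines the q-gene universe on which
# the per-sample biomarker calling operates.

#' Select differentially expressed genes between the two groups
#'
#' A self-contained two-group test used to define the gene universe when
#' no external DEG list is supplied: per-gene Welch two-sample t-test
#' ("+" vs "-") with Benjamini-Hochberg adjustment across all genes.
#' The effect size is the difference of group means, reported as
#' `log2_fold_change` on the assumption that the input is already on a
#' log-like scale (the caller's responsibility); no shrinkage is applied.
#'
#' A gene is selected when `adjusted_p <= alpha_de` and
#' `|log2_fold_change| >= min_abs_log2fc`. Zero genes passing is a
#' warning, not an error. For single-group data (one label absent) no
#' DEG step is meaningful; use the full gene universe instead.
#'
#' @param expr A labelled [grouped_expression()] with at least two
#'   samples in each group.
#' @param alpha_de FDR threshold on the adjusted p-value (default 0.05,
#'   i.e. a 95% confidence level).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @return A data frame (class `deg_result`) with columns `gene_id`,
#'   `p_value`, `adjusted_p`, `log2_fold_change`, `selected`, ordered by
#'   ascending `adjusted_p` with ties broken by `gene_id`.
#' @export
select_degs <- function(expr, alpha_de = 0.05, min_abs_log2fc = 1) {
  stopifnot(inherits(expr, "grouped_expression"))
  if (is.null(expr$labels)) stop("select_degs requires group labels")
  plus <- group_samples(expr, "+")
  minus <- group_samples(expr, "-")
  if (length(plus) < 2L || length(minus) < 2L)
    stop("each group needs at least two samples (got ",
         length(plus), " \"+\", ", length(minus), " \"-\")")
  vp <- expr$values[, plus, drop = FALSE]
  vm <- expr$values[, minus, drop = FALSE]
  p_value <- vapply(seq_len(n_genes(expr)), function(j) {
    yp <- vp[j, ]
    ym <- vm[j, ]
    if (stats::sd(yp) == 0 && stats::sd(ym) == 0)
      return(if (mean(yp) == mean(ym)) 1 else 0)
    stats::t.test(yp, ym, var.equal = FALSE)$p.value
  }, numeric(1L))
  adjusted_p <- stats::p.adjust(p_value, method = "BH")
  lfc <- rowMeans(vp) - rowMeans(vm)
  selected <- adjusted_p <= alpha_de & abs(lfc) >= min_abs_log2fc
  out <- data.frame(gene_id = gene_ids(expr), p_value = p_value,
                    adjusted_p = adjusted_p, log2_fold_change = lfc,
                    selected = selected, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$adjusted_p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!any(selected))
    warning("no genes pass the DEG thresholds")
  structure(out, class = c("deg_result", "data.frame"))
}

#' Restrict an expression matrix to a gene list
#'
#' @param expr A [grouped_expression()].
#' @param genes Ordered character vector of gene ids to keep; every id
#'   must exist in `expr`.
#' @return The submatrix in the requested gene order, labels untouched.
#' @export
apply_gene_filter <- function(expr, genes) {
  stopifnot(inherits(expr, "grouped_expression"))
  genes <- as.character(genes)
  unknown <- setdiff(genes, gene_ids(expr))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  grouped_expression(expr$values[genes, , drop = FALSE],
                     labels = expr$labels)
}

#' Write a DEG result table as TSV
#'
#' @param deg A `deg_result` from [select_degs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_result <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
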