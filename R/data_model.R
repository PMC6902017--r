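# Domain types and file IO for expression matrices and sample annotations.

#' Construct a grouped expression object
#'
#' The central data container: a numeric genes x samples matrix together
#' with an optional binary group labelling of the samples. Labels use the
#' two-symbol alphabet `"+"` / `"-"`; a dataset where one of the two labels
#' is absent (e.g. a simulation where every sample carries `"+"`) is legal.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty rownames (gene ids) and colnames (sample ids). All
#'   entries must be finite.
#' @param labels Optional named character vector mapping every sample id to
#'   `"+"` or `"-"`. `NULL` means unlabelled (labels can be attached later
#'   with [attach_labels()]).
#' @return An object of class `grouped_expression`: a list with elements
#'   `values` (the matrix) and `labels` (named character vector or `NULL`).
#' @seealso [read_expression()], [attach_labels()], [zscore_by_gene()]
#' @export
grouped_expression <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix must have rownames (genes) and colnames (samples)")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  if (!is.null(labels)) {
    labels <- normalize_labels(labels)
    if (is.null(names(labels)) || anyNA(names(labels)))
      stop("'labels' must be a named vector (names are sample ids)")
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("no label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[sample_ids]  # drop extras, keep matrix order
    bad_lab <- unique(labels[!labels %in% c("+", "-")])
    if (length(bad_lab))
      stop("unknown label symbol(s): ", paste(bad_lab, collapse = ", "),
           " (expected \"+\" or \"-\")")
  }
  structure(list(values = values, labels = labels),
            class = "grouped_expression")
}

# Map the unicode minus sign to ASCII "-" so annotation files exported from
# manuscripts or spreadsheets parse cleanly.
normalize_labels <- function(x) {
  nm <- names(x)
  out <- gsub("−", "-", as.character(x))
  names(out) <- nm
  out
}

#' @export
print.grouped_expression <- function(x, ...) {
  cat(sprintf("grouped_expression: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (is.null(x$labels)) {
    cat("  labels: <none>\n")
  } else {
    cat(sprintf("  labels: %d \"+\", %d \"-\"\n",
                sum(x$labels == "+"), sum(x$labels == "-")))
  }
  invisible(x)
}

#' Gene and sample accessors
#'
#' @param expr A `grouped_expression`.
#' @return Character vector of ids, or an integer count.
#' @export
gene_ids <- function(expr) rownames(expr$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(expr) colnames(expr$values)

#' @rdname gene_ids
#' @export
n_genes <- function(expr) nrow(expr$values)

#' @rdname gene_ids
#' @export
n_samples <- function(expr) ncol(expr$values)

#' Samples belonging to one group
#'
#' @param expr A labelled `grouped_expression`.
#' @param group `"+"` or `"-"`.
#' @return Character vector of sample ids carrying the label.
#' @export
group_samples <- function(expr, group) {
  if (is.null(expr$labels)) stop("expression object has no labels")
  group <- normalize_labels(group)
  if (!group %in% c("+", "-")) stop("group must be \"+\" or \"-\"")
  names(expr$labels)[expr$labels == group]
}

#' Read an expression matrix from delimited text
#'
#' Parses a TSV or CSV file with one header row of ids and one id column
#' into a genes x samples [grouped_expression()] (without labels).
#'
#' @param path Path to the file. Files ending in `.csv` are read as
#'   comma-separated, anything else as tab-separated.
#' @param orientation Either `"genes_in_rows"` (default; the usual
#'   GEO/TCGA text-export convention) or `"samples_in_rows"`, in which
#'   case the parsed matrix is transposed.
#' @return A `grouped_expression` without labels.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows",
                                                  "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty expression matrix in ", path)
  row_ids <- df[[1L]]
  dup <- row_ids[duplicated(row_ids)]
  if (length(dup))
    stop("duplicate row id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  col_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]], path))
  dimnames(values) <- list(row_ids, col_ids)
  if (orientation == "samples_in_rows") values <- t(values)
  grouped_expression(values)
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, samples in columns, first column `gene_id`. Row and
#' column order follow the object (deterministic round trip).
#'
#' @param expr A `grouped_expression`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "grouped_expression"))
  df <- data.frame(gene_id = gene_ids(expr), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Two-column delimited text, `sample_id<TAB>label`, with an optional
#' header row. Labels may be any two-level alphabet; they are mapped onto
#' the internal `"+"` / `"-"` symbols, with the lexicographically first
#' observed level becoming `"+"` unless `positive` names the level that
#' should map to `"+"`.
#'
#' @param path Path to the annotation file.
#' @param positive Optional string: the label value to treat as `"+"`.
#' @return A data frame with columns `sample_id` and `label`
#'   (class `sample_annotation`), labels in `{"+","-"}`.
#' @export
read_sample_annotation <- function(path, positive = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation must have two columns in ", path)
  if (tolower(df[1L, 1L]) %in% c("sample_id", "sample") &&
      tolower(df[1L, 2L]) %in% c("label", "group"))
    df <- df[-1L, , drop = FALSE]
  sample_annotation(df[[1L]], df[[2L]], positive = positive)
}

#' Construct a sample annotation
#'
#' @param sample_id Character vector of unique sample ids.
#' @param label Character vector of group labels (two levels at most).
#' @param positive Optional label value to map to `"+"`; by default the
#'   lexicographically first level becomes `"+"`.
#' @return A `sample_annotation` data frame with labels in `{"+","-"}`.
#' @export
sample_annotation <- function(sample_id, label, positive = NULL) {
  sample_id <- as.character(sample_id)
  label <- normalize_labels(label)
  if (length(sample_id) != length(label))
    stop("sample_id and label lengths differ")
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup))
    stop("duplicate sample id(s) in annotation: ",
         paste(unique(dup), collapse = ", "))
  lev <- sort(unique(label))
  if (length(lev) > 2L)
    stop("more than two label levels: ", paste(lev, collapse = ", "))
  if (!all(lev %in% c("+", "-"))) {
    if (!is.null(positive)) {
      positive <- normalize_labels(positive)
      if (!positive %in% lev)
        stop("'positive' value '", positive, "' not among labels")
      label <- ifelse(label == positive, "+", "-")
    } else {
      label <- ifelse(label == lev[1L], "+", "-")
    }
  }
  structure(data.frame(sample_id = sample_id, label = label,
                       stringsAsFactors = FALSE),
            class = c("sample_annotation", "data.frame"))
}

#' Attach group labels to an expression matrix
#'
#' @param expr A `grouped_expression` without (or with stale) labels.
#' @param ann A [sample_annotation()]. Every sample of `expr` must appear;
#'   annotation rows for samples absent from the matrix are ignored.
#' @return `expr` with `labels` populated; sample order unchanged.
#' @export
attach_labels <- function(expr, ann) {
  stopifnot(inherits(expr, "grouped_expression"))
  if (!inherits(ann, "sample_annotation"))
    ann <- sample_annotation(ann$sample_id, ann$label)
  lab <- stats::setNames(ann$label, ann$sample_id)
  missing <- setdiff(sample_ids(expr), names(lab))
  if (length(missing))
    stop("sample(s) missing from annotation: ",
         paste(missing, collapse = ", "))
  grouped_expression(expr$values, labels = lab)
}

#' Per-gene z-score transform
#'
#' Centres and scales every gene row to mean 0 and unit sample standard
#' deviation (divisor n - 1). Genes with zero variance cannot be scaled
#' and are passed through as all-zero rows with a warning.
#'
#' @param expr A `grouped_expression` with at least two samples.
#' @return A `grouped_expression` of the same shape, labels preserved.
#' @export
zscore_by_gene <- function(expr) {
  stopifnot(inherits(expr, "grouped_expression"))
  if (n_samples(expr) < 2L)
    stop("z-score needs at least two samples")
  v <- expr$values
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  degenerate <- sd == 0
  sd[degenerate] <- 1  # centred row is already all zero
  out <- (v - mu) / sd
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance gene(s) left as all-zero rows")
  grouped_expression(out, labels = expr$labels)
}
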