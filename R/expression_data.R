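#' Construct an expression dataset
#'
#' Genes x samples matrix of (assumed log2-scale, already normalised)
#' expression values together with a two-group sample labelling. Rows with
#' missing values are dropped and duplicated gene identifiers collapsed by
#' their mean, both with a message, so downstream formulas always see
#' complete, uniquely-keyed vectors.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).
#' @param labels Character or factor vector of per-sample groups, values
#'   `"control"` or `"test"`; either named by sample ID or in column order.
#' @return Object of class `expression_dataset` with fields `genes`,
#'   `samples`, `values`, `labels` (factor with levels control, test).
#' @export
expression_dataset <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  storage.mode(values) <- "double"

  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("labels length does not match number of samples")
  }
  if (!all(labels %in% c("control", "test")))
    stop("labels must be 'control' or 'test'")
  labels <- factor(labels, levels = c("control", "test"))
  if (any(table(labels) < 2L))
    stop("need at least 2 samples per group (control and test)")

  keep <- stats::complete.cases(values)
  if (!all(keep)) {
    message(sprintf("dropping %d gene row(s) with missing values", sum(!keep)))
    values <- values[keep, , drop = FALSE]
  }
  if (!nrow(values)) stop("no complete gene rows left after filtering")

  if (anyDuplicated(rownames(values))) {
    ndup <- sum(duplicated(rownames(values)))
    message(sprintf("collapsing %d duplicate gene row(s) by mean", ndup))
    values <- rowsum(values, rownames(values), reorder = FALSE) /
      as.vector(table(factor(rownames(values), levels = unique(rownames(values)))))
  }

  structure(list(genes = rownames(values),
                 samples = colnames(values),
                 values = values,
                 labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d control, %d test)\n",
              length(x$genes), length(x$samples),
              sum(x$labels == "control"), sum(x$labels == "test")))
  invisible(x)
}

#' Load an expression matrix from a TSV file
#'
#' Expects a tab-separated file with a header row of sample IDs and gene
#' IDs in the first column.
#'
#' @param path Path to the TSV file.
#' @param labels Per-sample group assignment: either a named character
#'   vector (`sample -> "control"/"test"`) or a path to a two-column TSV
#'   `sample<TAB>group` without header.
#' @return An [expression_dataset()].
#' @export
load_expression <- function(path, labels) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expression TSV needs >= 2 sample columns")
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- genes

  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lt <- utils::read.delim(labels, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(lt[[2]]), as.character(lt[[1]]))
  }
  expression_dataset(values, labels)
}

#' Call differentially expressed genes
#'
#' Per-gene two-sided Welch two-sample t-test of test vs control samples.
#' The log fold-change is mean(test) - mean(control) on the (log-scale)
#' input values and serves directly as the signed expression change fed
#' into perturbation propagation. A gene is flagged differentially
#' expressed when its raw p-value falls below `alpha`.
#'
#' Degenerate rows (zero variance within both groups) get p = 1 when the
#' group means are equal and p = 0 otherwise, rather than erroring.
#'
#' @param data An [expression_dataset()].
#' @param alpha DEG threshold on the raw p-value (default 0.05).
#' @return Data frame (`deg_table`) with columns `gene`, `log_fc`,
#'   `p_value`, `is_de`.
#' @export
call_degs <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "expression_dataset"))
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1)
  ctrl <- data$values[, data$labels == "control", drop = FALSE]
  test <- data$values[, data$labels == "test", drop = FALSE]

  n <- nrow(data$values)
  p <- numeric(n)
  lfc <- rowMeans(test) - rowMeans(ctrl)
  for (i in seq_len(n)) {
    x <- test[i, ]; y <- ctrl[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p[i] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p[i] <- stats::t.test(x, y, var.equal = FALSE)$p.value
    }
  }
  out <- data.frame(gene = data$genes, log_fc = lfc, p_value = p,
                    is_de = p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Binarize expression for mutual-information weights
#'
#' Each gene is thresholded at its own location estimate across all
#' samples: values at or above the threshold become 1 (overexpression),
#' values below become 0 (underexpression). The default threshold is the
#' per-gene median, the label-free and scale-free choice; `center =
#' "mean"` switches to the per-gene mean.
#'
#' @param data An [expression_dataset()].
#' @param center `"median"` (default) or `"mean"`.
#' @return Integer 0/1 matrix with the same dimnames as `data$values`.
#' @export
binarize <- function(data, center = c("median", "mean")) {
  stopifnot(inherits(data, "expression_dataset"))
  center <- match.arg(center)
  ctr <- switch(center,
                median = apply(data$values, 1L, stats::median),
                mean = rowMeans(data$values))
  out <- (data$values >= ctr) * 1L
  storage.mode(out) <- "integer"
  out
}
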