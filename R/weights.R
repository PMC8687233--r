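#' Pearson interaction weight for one gene pair
#'
#' Sample Pearson correlation coefficient (n - 1 denominator) of two
#' expression vectors, the PSPIA interaction intensity. The signed value
#' is returned: multiplied into the edge sign beta it can flip the
#' effective direction of an anti-correlated interaction.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Correlation in [-1, 1], or `NA_real_` when either vector has
#'   zero standard deviation (the caller decides the fallback).
#' @export
pearson_weight <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("pearson_weight needs n >= 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

## plug-in entropy, base `base`, of a binary vector
.binary_entropy <- function(b, base = 2) {
  p <- mean(b == 1L)
  terms <- c(p, 1 - p)
  terms <- terms[terms > 0]
  -sum(terms * log(terms, base = base))
}

#' Mutual-information interaction weight for one gene pair
#'
#' Plug-in mutual information of two binarized expression vectors, the
#' MSPIA interaction intensity. Joint and marginal probabilities are the
#' empirical frequencies of the 2x2 table; cells with zero joint
#' probability contribute nothing. Logarithm base 2 by default (bits);
#' the base only rescales all weights by a common constant.
#'
#' @param bx,by Integer 0/1 vectors of equal length, n >= 2.
#' @param base Logarithm base (default 2).
#' @return Non-negative mutual information; 0 for degenerate (constant)
#'   marginals.
#' @export
mi_weight <- function(bx, by, base = 2) {
  stopifnot(length(bx) == length(by))
  if (length(bx) < 2L) stop("mi_weight needs n >= 2 samples")
  bx <- as.integer(bx); by <- as.integer(by)
  if (!all(bx %in% c(0L, 1L)) || !all(by %in% c(0L, 1L)))
    stop("mi_weight inputs must be binary (0/1)")
  n <- length(bx)
  mi <- 0
  for (vx in c(0L, 1L)) {
    px <- mean(bx == vx)
    if (px == 0) next
    for (vy in c(0L, 1L)) {
      py <- mean(by == vy)
      pxy <- sum(bx == vx & by == vy) / n
      if (pxy > 0)
        mi <- mi + pxy * log(pxy / (px * py), base = base)
    }
  }
  max(mi, 0)   # clip tiny negative rounding residue
}

#' Per-edge interaction weights for a pathway
#'
#' Computes one interaction-intensity weight per edge of `graph`:
#' * `unit` - every weight 1 (plain SPIA; expression data ignored),
#' * `pearson` - signed Pearson correlation of the two genes' expression,
#' * `mi` - mutual information of the two genes' binarized expression.
#'
#' Both measures are symmetric in the gene pair. Edges whose endpoint is
#' absent from the expression data, or whose correlation is undefined
#' because a gene has zero variance, fall back to weight 1 (plain SPIA
#' strength) rather than silently rewiring the topology; both events are
#' counted in the result's `report`.
#'
#' @param graph A [pathway_graph()].
#' @param data An [expression_dataset()]; may be NULL for `method = "unit"`.
#' @param method `"unit"`, `"pearson"` or `"mi"`.
#' @param abs_weights Use `|w|` instead of the signed Pearson value, for
#'   users who want the edge sign beta to carry all sign information
#'   (default FALSE: the weight enters the propagation exactly as
#'   computed).
#' @param mi_log_base Logarithm base for `method = "mi"` (default 2).
#' @param weight_samples Which samples enter the weight computation:
#'   `"all"` (default; both conditions pooled), `"control"` or `"test"`.
#' @return Object of class `weight_matrix`: list with `method`, `weights`
#'   (data.frame `source`, `target`, `weight` aligned with `graph$edges`)
#'   and `report` (counts of missing-gene and zero-variance fallbacks).
#' @export
edge_weights <- function(graph, data = NULL,
                         method = c("unit", "pearson", "mi"),
                         abs_weights = FALSE, mi_log_base = 2,
                         weight_samples = c("all", "control", "test")) {
  stopifnot(inherits(graph, "pathway_graph"))
  method <- match.arg(method)
  weight_samples <- match.arg(weight_samples)
  edges <- graph$edges
  report <- list(missing_gene_edges = 0L, zero_variance_edges = 0L)

  if (method == "unit" || nrow(edges) == 0L) {
    w <- rep(1, nrow(edges))
  } else {
    stopifnot(inherits(data, "expression_dataset"))
    keep <- if (weight_samples == "all") rep(TRUE, length(data$samples))
            else data$labels == weight_samples
    vals <- data$values[, keep, drop = FALSE]
    if (method == "mi") bvals <- binarize(data)[, keep, drop = FALSE]

    w <- numeric(nrow(edges))
    for (k in seq_len(nrow(edges))) {
      gi <- edges$source[k]; gj <- edges$target[k]
      if (!(gi %in% data$genes) || !(gj %in% data$genes)) {
        report$missing_gene_edges <- report$missing_gene_edges + 1L
        w[k] <- 1
        next
      }
      if (method == "pearson") {
        wk <- pearson_weight(vals[gi, ], vals[gj, ])
        if (is.na(wk)) {
          report$zero_variance_edges <- report$zero_variance_edges + 1L
          wk <- 1
        }
        w[k] <- wk
      } else {
        w[k] <- mi_weight(bvals[gi, ], bvals[gj, ], base = mi_log_base)
      }
    }
    if (abs_weights) w <- abs(w)
  }
  if (report$missing_gene_edges > 0L)
    message(sprintf("pathway '%s': %d edge(s) with gene(s) absent from data, weight 1 used",
                    graph$pathway_id, report$missing_gene_edges))
  if (report$zero_variance_edges > 0L)
    warning(sprintf("pathway '%s': %d edge(s) with zero-variance gene, weight 1 used",
                    graph$pathway_id, report$zero_variance_edges))

  structure(list(method = method,
                 weights = data.frame(source = edges$source,
                                      target = edges$target,
                                      weight = w,
                                      stringsAsFactors = FALSE),
                 report = report),
            class = "weight_matrix")
}

#' Write per-edge weights of one or more pathways to a TSV file
#'
#' Columns: `pathway_id`, `source`, `target`, `beta`, `weight`.
#'
#' @param graphs List of [pathway_graph()] objects.
#' @param weight_list List of `weight_matrix` objects, parallel to `graphs`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weight_tsv <- function(graphs, weight_list, path) {
  stopifnot(length(graphs) == length(weight_list))
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]; wm <- weight_list[[i]]
    if (!nrow(g$edges)) return(NULL)
    data.frame(pathway_id = g$pathway_id,
               source = g$edges$source, target = g$edges$target,
               beta = g$edges$beta, weight = wm$weights$weight,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(), source = character(),
                      target = character(), beta = integer(),
                      weight = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
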