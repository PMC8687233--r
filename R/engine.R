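## Build the propagation matrix M with M[i, j] = beta_ij * w_ij / nds(g_j)
## for each edge g_j -> g_i, 0 elsewhere. With unit weights this is the
## classical SPIA normalised signed adjacency.
.propagation_matrix <- function(graph, weights) {
  n <- length(graph$genes)
  M <- matrix(0, n, n, dimnames = list(graph$genes, graph$genes))
  edges <- graph$edges
  if (nrow(edges)) {
    i <- match(edges$target, graph$genes)   # row: downstream gene
    j <- match(edges$source, graph$genes)   # col: upstream gene
    M[cbind(i, j)] <- edges$beta * weights$weights$weight / graph$nds[j]
  }
  M
}

#' Per-gene perturbation factors for one pathway
#'
#' Solves the perturbation fixed point
#' \deqn{PF(g_i) = \Delta E(g_i) + \sum_j \beta_{ij} w_{ij} PF(g_j) / N_{ds}(g_j)}
#' i.e. a gene's perturbation is its own expression change plus the
#' weighted, sign-carrying contributions of its direct upstream genes,
#' each normalised by that upstream gene's number of downstream targets.
#' With all weights equal to 1 this is the plain SPIA perturbation
#' factor. The fixed point is obtained by a direct linear solve of
#' (I - M) pf = delta_e.
#'
#' The per-gene accumulation is Acc(g) = PF(g) - DeltaE(g), the
#' perturbation a gene receives from the topology beyond its own change;
#' the pathway statistic t_A is the sum of accumulations.
#'
#' @param graph A [pathway_graph()].
#' @param weights A `weight_matrix` from [edge_weights()] on the same
#'   graph.
#' @param delta_e Named numeric vector of signed expression changes (log
#'   fold-changes for DEGs, 0 otherwise); every pathway gene must be
#'   covered, extra names are ignored.
#' @return List of class `perturbation_result` with fields `pf`, `acc`
#'   (named numeric vectors), `t_a` (scalar) and `solver_status`
#'   (`"solved"` or `"singular"`; singular systems give NA results and are
#'   reported as skipped pathways upstream).
#' @export
perturbation_factors <- function(graph, weights, delta_e) {
  stopifnot(inherits(graph, "pathway_graph"))
  missing <- setdiff(graph$genes, names(delta_e))
  if (length(missing))
    stop("delta_e missing for pathway gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  d <- delta_e[graph$genes]
  n <- length(graph$genes)
  if (n == 0L)
    return(structure(list(pf = numeric(), acc = numeric(), t_a = 0,
                          solver_status = "solved"),
                     class = "perturbation_result"))

  A <- diag(n) - .propagation_matrix(graph, weights)
  if (rcond(A) < 1e-12) {
    return(structure(list(pf = stats::setNames(rep(NA_real_, n), graph$genes),
                          acc = stats::setNames(rep(NA_real_, n), graph$genes),
                          t_a = NA_real_, solver_status = "singular"),
                     class = "perturbation_result"))
  }
  pf <- stats::setNames(drop(solve(A, d)), graph$genes)
  acc <- pf - d
  structure(list(pf = pf, acc = acc, t_a = sum(acc), solver_status = "solved"),
            class = "perturbation_result")
}

## Accumulation as a linear functional of delta_e:
## t_A(d) = sum(solve(A, d)) - sum(d) = q . d  with q = colSums(A^-1) - 1.
## Returns NULL when (I - M) is numerically singular.
.accumulation_coefficients <- function(graph, weights) {
  n <- length(graph$genes)
  if (n == 0L) return(numeric())
  A <- diag(n) - .propagation_matrix(graph, weights)
  if (rcond(A) < 1e-12) return(NULL)
  stats::setNames(colSums(solve(A)) - 1, graph$genes)
}

#' Bootstrap p-value for the pathway perturbation statistic
#'
#' Builds the null distribution of the total accumulated perturbation t_A
#' by repeatedly assigning `n_de` fold-change values, sampled without
#' replacement from the genome-wide DEG fold-change pool, to `n_de`
#' uniformly chosen pathway genes (every other gene's change set to 0)
#' and recomputing t_A. The null is median-centred and compared
#' two-tailed; add-one smoothing keeps the p-value strictly positive so
#' the downstream combination with the over-representation p-value is
#' always defined. Ties between null and observed magnitudes count
#' against the pathway (conservative).
#'
#' @param graph A [pathway_graph()].
#' @param weights A `weight_matrix` on the same graph.
#' @param delta_e_observed Named numeric vector of observed signed
#'   expression changes over the pathway genes (0 for non-DEGs).
#' @param n_de Number of differentially expressed genes on the pathway
#'   (>= 1).
#' @param delta_e_pool Numeric vector of the fold-changes of all DEGs
#'   genome-wide.
#' @param iterations Bootstrap iterations (>= 1; default 2000).
#' @param seed Integer seed for this pathway's bootstrap stream.
#' @param placement_genes Optional subset of `graph$genes` eligible to
#'   receive a fold-change under the null (defaults to all pathway
#'   genes); used to restrict placement to genes actually measured.
#' @return List with `p_pert`, `t_a_observed`, `solver_status`.
#' @export
p_pert_bootstrap <- function(graph, weights, delta_e_observed, n_de,
                             delta_e_pool, iterations = 2000, seed = 1,
                             placement_genes = NULL) {
  stopifnot(iterations >= 1, n_de >= 1)
  if (is.null(placement_genes)) placement_genes <- graph$genes
  stopifnot(all(placement_genes %in% graph$genes))
  if (n_de > length(placement_genes))
    stop("n_de exceeds the number of eligible pathway genes")
  if (n_de > length(delta_e_pool))
    stop("n_de exceeds the genome-wide DEG pool size")

  q <- .accumulation_coefficients(graph, weights)
  if (is.null(q))
    return(list(p_pert = NA_real_, t_a_observed = NA_real_,
                solver_status = "singular"))

  d <- stats::setNames(rep(0, length(graph$genes)), graph$genes)
  d[names(delta_e_observed)] <- delta_e_observed
  t_obs <- sum(q * d)

  qp <- q[placement_genes]
  np <- length(qp)
  t_null <- numeric(iterations)
  set.seed(as.integer(seed))
  for (b in seq_len(iterations)) {
    idx <- sample.int(np, n_de)
    vals <- delta_e_pool[sample.int(length(delta_e_pool), n_de)]
    t_null[b] <- sum(qp[idx] * vals)
  }
  med <- stats::median(t_null)
  p <- (sum(abs(t_null - med) >= abs(t_obs - med)) + 1) / (iterations + 1)
  list(p_pert = p, t_a_observed = t_obs, solver_status = "solved")
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability that a pathway carries at least `r`
#' differentially expressed genes when `h` DEGs are drawn at random from
#' a reference set of `m` measured genes of which `t` lie on the pathway:
#' P(X >= r) = 1 - sum_{x=0}^{r-1} C(t, x) C(m-t, h-x) / C(m, h).
#'
#' @param m Genes in the reference set (all measured genes).
#' @param t Genes on the pathway (within the reference set).
#' @param h DEGs genome-wide.
#' @param r DEGs on the pathway.
#' @return Probability in [0, 1]; r = 0 gives 1 (empty sum).
#' @export
p_nde_hypergeometric <- function(m, t, h, r) {
  stopifnot(length(m) == 1L, length(t) == 1L, length(h) == 1L, length(r) == 1L)
  if (t > m || h > m || r > min(t, h) || r < 0 || t < 0 || h < 0)
    stop("invalid hypergeometric arguments: need 0 <= r <= min(t, h), t <= m, h <= m")
  if (r == 0) return(1)
  min(max(stats::phyper(r - 1, t, m - t, h, lower.tail = FALSE), 0), 1)
}

#' Combine over-representation and perturbation evidence
#'
#' The two independent p-values are combined through the tail probability
#' of the product of two independent uniforms: with c = p_nde * p_pert,
#' the combined value is p_g = c - c ln(c), itself uniform on (0, 1]
#' under the joint null.
#'
#' @param p_nde,p_pert Probabilities in (0, 1]. A zero input is an error:
#'   use the add-one-smoothed bootstrap p-value so the logarithm is
#'   defined.
#' @return Combined probability in (0, 1].
#' @export
combine_pg <- function(p_nde, p_pert) {
  stopifnot(length(p_nde) == length(p_pert))
  if (any(p_nde <= 0 | p_pert <= 0 | p_nde > 1 | p_pert > 1))
    stop("combine_pg inputs must lie in (0, 1]")
  cc <- p_nde * p_pert
  cc - cc * log(cc)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values across pathways; thin wrapper over
#' [stats::p.adjust()] so the multiple-testing estimator is configurable
#' in one place.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (NA passed through).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  stats::p.adjust(p_values, method = method)
}

## deterministic per-pathway seed: top-level seed + stable string hash of
## the pathway id, kept inside 32-bit integer range, so adding or removing
## one pathway never changes another pathway's bootstrap stream.
.pathway_seed <- function(seed, pathway_id) {
  h <- 0
  for (code in utf8ToInt(pathway_id)) h <- (h * 31 + code) %% 1048573
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Run the full pathway impact analysis
#'
#' For every pathway: counts its differentially expressed genes, computes
#' the hypergeometric over-representation p-value, propagates the DEG
#' fold-changes through the weighted signed topology to get the
#' accumulated perturbation t_A, derives a bootstrap p-value for t_A,
#' combines the two evidences, and finally adjusts the combined p-values
#' for multiple testing across all analysed pathways.
#'
#' The interaction weights are chosen by `method`: `"spia"` (all weights
#' 1), `"pspia"` (Pearson correlation) or `"mspia"` (mutual information
#' of binarized expression). Each pathway's bootstrap consumes a seed
#' derived from `seed` and the pathway id, so results per pathway do not
#' depend on which other pathways are analysed.
#'
#' @param data An [expression_dataset()] (holds values and group labels).
#' @param pathways A directory of pathway files (see [load_pathway_dir()])
#'   or a list of [pathway_graph()] objects.
#' @param method `"spia"`, `"pspia"` or `"mspia"`.
#' @param alpha Raw p-value threshold for DEG calling (default 0.05).
#' @param iterations Bootstrap iterations per pathway (default 2000).
#' @param seed Top-level integer seed (default 1).
#' @param fdr_method Multiple-testing estimator, `"BH"` or `"bonferroni"`.
#' @param abs_weights,mi_log_base,weight_samples Passed to [edge_weights()].
#' @param force_unit_weights Diagnostic switch: compute the analysis with
#'   every edge weight forced to 1 regardless of `method`; with this the
#'   weighted variants reduce exactly to plain SPIA.
#' @param deg_table Optional precomputed result of [call_degs()]; when
#'   supplied, `alpha` is ignored for DEG calling.
#' @return Data frame of class `pathway_result`, one row per pathway,
#'   columns `pathway_id`, `pathway_name`, `pathway_size`, `n_de`, `t_a`,
#'   `p_nde`, `p_pert`, `p_g`, `p_g_fdr`, `status`, sorted ascending by
#'   `p_g` (skipped pathways, with NA probabilities, last). `status` is
#'   `"ok"`, `"skipped_no_de"` (no DEG on the pathway) or
#'   `"skipped_singular"` (perturbation system not solvable).
#' @export
run_analysis <- function(data, pathways,
                         method = c("spia", "pspia", "mspia"),
                         alpha = 0.05, iterations = 2000, seed = 1,
                         fdr_method = c("BH", "bonferroni"),
                         abs_weights = FALSE, mi_log_base = 2,
                         weight_samples = "all",
                         force_unit_weights = FALSE,
                         deg_table = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  method <- match.arg(method)
  fdr_method <- match.arg(fdr_method)
  if (is.character(pathways)) pathways <- load_pathway_dir(pathways)
  stopifnot(length(pathways) >= 1L,
            all(vapply(pathways, inherits, TRUE, "pathway_graph")))

  if (is.null(deg_table)) deg_table <- call_degs(data, alpha = alpha)
  m <- nrow(deg_table)                     # reference set = measured genes
  de <- deg_table[deg_table$is_de, , drop = FALSE]
  h <- nrow(de)
  pool <- de$log_fc
  de_lfc <- stats::setNames(de$log_fc, de$gene)

  wmethod <- if (force_unit_weights) "unit" else
    switch(method, spia = "unit", pspia = "pearson", mspia = "mi")

  rows <- lapply(pathways, function(g) {
    present <- intersect(g$genes, deg_table$gene)
    t_path <- length(present)
    de_on <- intersect(present, de$gene)
    r <- length(de_on)

    row <- data.frame(pathway_id = g$pathway_id,
                      pathway_name = g$pathway_name,
                      pathway_size = t_path, n_de = r,
                      t_a = NA_real_, p_nde = NA_real_, p_pert = NA_real_,
                      p_g = NA_real_, p_g_fdr = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    if (r == 0L || t_path == 0L) {
      row$status <- "skipped_no_de"
      return(row)
    }

    wm <- edge_weights(g, data, method = wmethod,
                       abs_weights = abs_weights, mi_log_base = mi_log_base,
                       weight_samples = weight_samples)
    delta_obs <- de_lfc[de_on]
    boot <- p_pert_bootstrap(g, wm, delta_obs, n_de = r,
                             delta_e_pool = pool,
                             iterations = iterations,
                             seed = .pathway_seed(seed, g$pathway_id),
                             placement_genes = present)
    if (boot$solver_status == "singular") {
      row$status <- "skipped_singular"
      return(row)
    }
    row$t_a <- boot$t_a_observed
    row$p_nde <- p_nde_hypergeometric(m, t_path, h, r)
    row$p_pert <- boot$p_pert
    row$p_g <- combine_pg(row$p_nde, row$p_pert)
    row
  })

  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- !is.na(res$p_g)                    # adjust across analysed pathways only
  res$p_g_fdr[ok] <- fdr_adjust(res$p_g[ok], method = fdr_method)
  res <- res[order(res$p_g, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("pathway_result", "data.frame")
  res
}

#' Write pathway results to a TSV file
#'
#' Rows are written in ascending `p_g` order with `NA` fields for skipped
#' pathways.
#'
#' @param results A `pathway_result` data frame from [run_analysis()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
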