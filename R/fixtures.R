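#' Specification for a synthetic two-condition expression fixture
#'
#' Bundles every dial of the seeded toy generator: pathway topology
#' (number, size, edge density, inhibition fraction), study layout
#' (control/test sample counts), differential-expression structure
#' (fraction of background DE genes and their mean log fold-change) and
#' the co-expression structure along pathway edges (target pairwise
#' correlation, noise level). The defaults emulate a small two-group
#' microarray study: 10 control vs 12 test samples, log2-scale values, a
#' DE shift of 2 log2 units over noise with standard deviation 0.5, and
#' edge-adjacent genes correlated at 0.7.
#'
#' Generation is a pure function of the spec: identical specs reproduce
#' byte-identical fixtures.
#'
#' @param n_genes Genes in the measured universe.
#' @param n_pathways Number of pathways to simulate.
#' @param genes_per_pathway Genes per pathway (>= 2).
#' @param edge_density Probability of each ordered gene pair (no
#'   self-loops) carrying an edge, in (0, 1].
#' @param inhibition_fraction Probability an edge is inhibitory (beta = -1).
#' @param n_control,n_test Samples per group (>= 2 each).
#' @param de_fraction Fraction of off-pathway genes shifted as background
#'   DE genes.
#' @param effect_size Mean log fold-change applied to DE genes.
#' @param edge_correlation Target Pearson correlation of edge-adjacent
#'   gene pairs, in (-1, 1) when `noise_sd > 0`.
#' @param noise_sd Standard deviation of a gene's expression around its
#'   group mean.
#' @param seed Integer seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 300, n_pathways = 5, genes_per_pathway = 15,
                         edge_density = 0.15, inhibition_fraction = 0.2,
                         n_control = 10, n_test = 12,
                         de_fraction = 0.1, effect_size = 2,
                         edge_correlation = 0.7, noise_sd = 0.5, seed = 1) {
  spec <- list(n_genes = n_genes, n_pathways = n_pathways,
               genes_per_pathway = genes_per_pathway,
               edge_density = edge_density,
               inhibition_fraction = inhibition_fraction,
               n_control = n_control, n_test = n_test,
               de_fraction = de_fraction, effect_size = effect_size,
               edge_correlation = edge_correlation, noise_sd = noise_sd,
               seed = seed)
  stopifnot(spec$genes_per_pathway >= 2,
            spec$edge_density > 0, spec$edge_density <= 1,
            spec$inhibition_fraction >= 0, spec$inhibition_fraction <= 1,
            spec$de_fraction >= 0, spec$de_fraction <= 1,
            spec$n_control >= 2, spec$n_test >= 2,
            abs(spec$edge_correlation) <= 1, spec$noise_sd >= 0)
  class(spec) <- "fixture_spec"
  spec
}

## one random signed digraph over `genes`; NULL when it came out edgeless
.random_pathway <- function(id, genes, density, inhibition_fraction) {
  pairs <- expand.grid(source = genes, target = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < density
  if (!any(keep)) return(NULL)
  pairs <- pairs[keep, , drop = FALSE]
  beta <- ifelse(stats::runif(nrow(pairs)) < inhibition_fraction, -1L, 1L)
  pathway_graph(id, paste("synthetic pathway", id), genes = genes,
                edges = data.frame(source = pairs$source,
                                   target = pairs$target,
                                   beta = beta, stringsAsFactors = FALSE))
}

#' Generate seeded random pathway topologies
#'
#' Each pathway draws `genes_per_pathway` genes from the universe
#' (disjoint sets while the universe allows it, then reuse) and connects
#' each ordered pair with probability `edge_density`; edges are
#' inhibitory with probability `inhibition_fraction`. A pathway that
#' comes out edgeless is regenerated once; a second failure is an error
#' (raise the density).
#'
#' @param spec A [fixture_spec()].
#' @return Named list of [pathway_graph()] objects (`pw01`, `pw02`, ...).
#' @export
make_pathways <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(as.integer(spec$seed))
  universe <- sprintf("g%04d", seq_len(spec$n_genes))
  avail <- universe
  graphs <- vector("list", spec$n_pathways)
  for (p in seq_len(spec$n_pathways)) {
    if (length(avail) >= spec$genes_per_pathway) {
      genes <- sample(avail, spec$genes_per_pathway)
      avail <- setdiff(avail, genes)
    } else {
      genes <- sample(universe, spec$genes_per_pathway)
    }
    id <- sprintf("pw%02d", p)
    g <- .random_pathway(id, genes, spec$edge_density, spec$inhibition_fraction)
    if (is.null(g))
      g <- .random_pathway(id, genes, spec$edge_density, spec$inhibition_fraction)
    if (is.null(g))
      stop("pathway ", id, " has zero edges after one regeneration; ",
           "increase edge_density")
    graphs[[p]] <- g
  }
  names(graphs) <- vapply(graphs, `[[`, "", "pathway_id")
  graphs
}

## undirected connected components of a pathway's edge set
.edge_components <- function(graph) {
  comp <- stats::setNames(seq_along(graph$genes), graph$genes)
  for (k in seq_len(nrow(graph$edges))) {
    a <- comp[graph$edges$source[k]]; b <- comp[graph$edges$target[k]]
    if (a != b) comp[comp == b] <- a
  }
  comp
}

## BFS sign assignment: s[target] = s[source] * rel_sign(edge); first
## assignment wins on conflicts (odd cycles cannot all be satisfied)
.propagate_signs <- function(graph, rel_sign) {
  s <- stats::setNames(rep(NA_integer_, length(graph$genes)), graph$genes)
  edges <- graph$edges
  repeat {
    seedg <- names(s)[is.na(s)][1]
    if (is.na(seedg) || is.null(seedg)) break
    s[seedg] <- 1L
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(edges))) {
        u <- edges$source[k]; v <- edges$target[k]
        rs <- rel_sign[k]
        if (!is.na(s[u]) && is.na(s[v])) { s[v] <- s[u] * rs; changed <- TRUE }
        else if (!is.na(s[v]) && is.na(s[u])) { s[u] <- s[v] * rs; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  s
}

#' Generate a seeded two-condition expression matrix for a pathway set
#'
#' Baseline expression is Gaussian around a common log2-scale intercept
#' with standard deviation `noise_sd`. Correlation along pathway edges is
#' induced by one shared latent factor per connected component: each
#' member gene loads sqrt(|edge_correlation|) on the factor (sign-flipped
#' on one endpoint for negative targets) plus sqrt(1 - |edge_correlation|)
#' idiosyncratic noise, so edge-adjacent pairs realise approximately the
#' target correlation. When `perturbed_pathway_index` is set, that
#' pathway's genes receive a coherent `effect_size` shift in the test
#' samples only, with the sign propagated along the topology (flipped
#' across inhibitory edges) so that the perturbation accumulates rather
#' than cancels; additionally a `de_fraction` share of off-pathway genes
#' is shifted with random sign as incoherent background DE.
#'
#' @param spec A [fixture_spec()].
#' @param pathways Pathway list from [make_pathways()].
#' @param perturbed_pathway_index Index into `pathways` of the pathway to
#'   perturb, or NULL for no coherent perturbation.
#' @return List with `data` (an [expression_dataset()]) and `truth`
#'   (data.frame `gene`, `is_de`, `true_lfc`, `on_perturbed_pathway`).
#' @export
make_expression <- function(spec, pathways, perturbed_pathway_index = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (abs(spec$edge_correlation) == 1 && spec$noise_sd > 0)
    stop("|edge_correlation| = 1 with noise_sd > 0 is unachievable")
  set.seed(as.integer(spec$seed) %% 2100000000L + 31L)

  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  n_samples <- spec$n_control + spec$n_test
  samples <- c(sprintf("ctrl_%02d", seq_len(spec$n_control)),
               sprintf("test_%02d", seq_len(spec$n_test)))
  labels <- stats::setNames(rep(c("control", "test"),
                                c(spec$n_control, spec$n_test)), samples)
  is_test <- labels == "test"

  rho <- spec$edge_correlation
  load_shared <- sqrt(abs(rho))
  load_own <- sqrt(1 - abs(rho))

  ## standardised signal: latent factor per connected pathway component
  z <- matrix(stats::rnorm(spec$n_genes * n_samples), spec$n_genes, n_samples,
              dimnames = list(genes, samples))
  signal <- load_own * z
  pure_noise <- rep(TRUE, spec$n_genes)
  names(pure_noise) <- genes
  for (g in pathways) {
    comp <- .edge_components(g)
    corr_sign <- .propagate_signs(g, rep(if (rho < 0) -1L else 1L,
                                         nrow(g$edges)))
    for (cid in unique(comp)) {
      members <- names(comp)[comp == cid]
      members <- members[members %in% genes & pure_noise[members]]
      if (length(members) < 2L) next
      f <- stats::rnorm(n_samples)
      for (gene in members)
        signal[gene, ] <- corr_sign[gene] * load_shared * f +
          load_own * z[gene, ]
      pure_noise[members] <- FALSE
    }
  }
  values <- 8 + spec$noise_sd * signal

  ## differential expression: coherent on the perturbed pathway,
  ## incoherent background elsewhere
  true_lfc <- stats::setNames(rep(0, spec$n_genes), genes)
  on_perturbed <- stats::setNames(rep(FALSE, spec$n_genes), genes)
  if (!is.null(perturbed_pathway_index)) {
    g <- pathways[[perturbed_pathway_index]]
    dir <- .propagate_signs(g, g$edges$beta)
    pg <- intersect(g$genes, genes)
    true_lfc[pg] <- dir[pg] * spec$effect_size
    on_perturbed[pg] <- TRUE
  }
  background <- setdiff(genes, names(on_perturbed)[on_perturbed])
  n_bg <- round(spec$de_fraction * length(background))
  if (n_bg > 0) {
    bg <- sample(background, n_bg)
    true_lfc[bg] <- sample(c(-1, 1), n_bg, replace = TRUE) * spec$effect_size
  }
  values[, is_test] <- values[, is_test] + true_lfc

  truth <- data.frame(gene = genes,
                      is_de = true_lfc != 0,
                      true_lfc = unname(true_lfc),
                      on_perturbed_pathway = unname(on_perturbed),
                      stringsAsFactors = FALSE)
  list(data = expression_dataset(values, labels), truth = truth)
}

#' Write a complete fixture to disk
#'
#' Emits one edge-list file per pathway (`<id>.tsv`), the expression
#' matrix (`expression.tsv`), the sample labels (`labels.tsv`) and the
#' DE truth table (`truth.tsv`) under `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @param perturbed_pathway_index Passed to [make_expression()].
#' @return Invisibly, the list returned by [make_expression()] plus
#'   `pathways`.
#' @export
write_fixture <- function(spec, dir, perturbed_pathway_index = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pw_dir <- file.path(dir, "pathways")
  dir.create(pw_dir, showWarnings = FALSE)
  pathways <- make_pathways(spec)
  for (g in pathways)
    write_edge_list(g, file.path(pw_dir, paste0(g$pathway_id, ".tsv")))
  fx <- make_expression(spec, pathways, perturbed_pathway_index)
  tab <- data.frame(gene = fx$data$genes, fx$data$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = fx$data$samples,
                                group = as.character(fx$data$labels)),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(fx$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fx, list(pathways = pathways)))
}
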