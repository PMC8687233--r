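## Independent oracles and small constructors shared across the suite.
## Every oracle recomputes its quantity by brute force or direct
## propagation, never through the code path it checks.

## chain pathway g1 -> g2 -> ... with given edge signs
chain_graph <- function(n, betas = rep(1L, n - 1L), id = "chain") {
  genes <- paste0("g", seq_len(n))
  pathway_graph(id, id, genes = genes,
                edges = data.frame(source = genes[-n], target = genes[-1],
                                   beta = betas, stringsAsFactors = FALSE))
}

## weight_matrix with prescribed per-edge weights (aligned to graph$edges)
manual_weights <- function(graph, w) {
  wm <- edge_weights(graph, method = "unit")
  wm$weights$weight <- w
  wm
}

## forward propagation of perturbation factors in topological order;
## valid for DAGs only
pf_forward_oracle <- function(graph, weights, delta_e) {
  genes <- graph$genes
  pf <- delta_e[genes]
  edges <- graph$edges
  w <- weights$weights$weight
  ## Kahn topological order
  indeg <- table(factor(edges$target, levels = genes))
  order_out <- character(0)
  queue <- genes[indeg == 0]
  indeg <- as.vector(indeg); names(indeg) <- genes
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, u)
    hits <- which(edges$source == u)
    for (k in hits) {
      v <- edges$target[k]
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  stopifnot(length(order_out) == length(genes))  # acyclic
  for (u in order_out) {
    hits <- which(edges$source == u)
    for (k in hits)
      pf[edges$target[k]] <- pf[edges$target[k]] +
        edges$beta[k] * w[k] * pf[u] / graph$nds[u]
  }
  pf
}

## random DAG over n genes: edges only from lower to higher index
random_dag <- function(n, p_edge = 0.4, p_inhib = 0.3) {
  genes <- paste0("g", seq_len(n))
  src <- character(); tgt <- character(); beta <- integer()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p_edge) {
      src <- c(src, genes[i]); tgt <- c(tgt, genes[j])
      beta <- c(beta, if (stats::runif(1) < p_inhib) -1L else 1L)
    }
  }
  if (!length(src)) { src <- genes[1]; tgt <- genes[2]; beta <- 1L }
  pathway_graph("dag", "dag", genes = genes,
                edges = data.frame(source = src, target = tgt, beta = beta,
                                   stringsAsFactors = FALSE))
}

## exhaustive-enumeration upper-tail hypergeometric: draw h of m genes,
## first t genes are "on the pathway", P(overlap >= r)
hyper_enum_oracle <- function(m, t, h, r) {
  if (r == 0) return(1)
  combos <- utils::combn(m, h)
  mean(colSums(combos <= t) >= r)
}

## plug-in entropy (base 2) of a binary vector
entropy_oracle <- function(b) {
  p <- mean(b == 1)
  pr <- c(p, 1 - p); pr <- pr[pr > 0]
  -sum(pr * log2(pr))
}

## tiny expression dataset from a matrix sketch
tiny_dataset <- function(values, n_control, n_test) {
  colnames(values) <- c(sprintf("c%d", seq_len(n_control)),
                        sprintf("t%d", seq_len(n_test)))
  expression_dataset(values, rep(c("control", "test"), c(n_control, n_test)))
}

## minimal KGML document text from entry/relation tables
kgml_text <- function(entries, relations, title = "toy") {
  ent <- vapply(seq_len(nrow(entries)), function(i)
    sprintf('  <entry id="%s" name="%s" type="%s"/>',
            entries$id[i], entries$name[i], entries$type[i]), "")
  rel <- vapply(seq_len(nrow(relations)), function(i)
    sprintf('  <relation entry1="%s" entry2="%s" type="PPrel">\n    <subtype name="%s" value="x"/>\n  </relation>',
            relations$entry1[i], relations$entry2[i], relations$subtype[i]), "")
  paste0('<?xml version="1.0"?>\n<pathway name="path:toy" title="', title,
         '">\n', paste(c(ent, rel), collapse = "\n"), "\n</pathway>\n")
}

write_kgml <- function(entries, relations, path = tempfile(fileext = ".xml")) {
  writeLines(kgml_text(entries, relations), path)
  path
}
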