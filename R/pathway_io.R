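#' Construct a pathway graph
#'
#' A `pathway_graph` is a directed, signed gene network: nodes are gene
#' identifiers and each edge carries an interaction sign `beta` (+1 for
#' activation/expression, -1 for inhibition/repression). The object also
#' stores the signed adjacency in matrix form (`beta_matrix`, entry (i, j)
#' is the signed effect of gene j on gene i) and the per-gene downstream
#' count `nds` (out-degree), which normalises perturbation propagation.
#'
#' Duplicate (source, target) pairs are resolved last-wins with a warning;
#' self-loops are kept but flagged in the parse report.
#'
#' @param pathway_id Single string identifying the pathway.
#' @param pathway_name Human-readable pathway name.
#' @param genes Character vector of gene identifiers (nodes). Genes named
#'   only in `edges` are appended automatically.
#' @param edges A data.frame with columns `source`, `target`, `beta`
#'   (beta must be +1 or -1), or NULL for an edgeless pathway.
#' @param report Optional list of parser bookkeeping (dropped relation
#'   counts etc.); stored as the `report` field.
#' @return An object of class `pathway_graph` with fields `pathway_id`,
#'   `pathway_name`, `genes`, `edges`, `beta_matrix`, `nds`, `report`.
#' @examples
#' g <- pathway_graph("p1", "toy", c("A", "B", "C"),
#'                    data.frame(source = c("A", "B"), target = c("B", "C"),
#'                               beta = c(1, -1)))
#' g$nds
#' @export
pathway_graph <- function(pathway_id, pathway_name = pathway_id,
                          genes = character(), edges = NULL,
                          report = list()) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        beta = integer(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "beta") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$beta <- as.integer(edges$beta)
  if (nrow(edges) && !all(edges$beta %in% c(-1L, 1L)))
    stop("edge beta values must be +1 or -1")

  genes <- unique(c(as.character(genes), edges$source, edges$target))

  ## last parsed occurrence of a duplicated (source, target) pair wins
  if (nrow(edges)) {
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      ndup <- sum(duplicated(key))
      warning(sprintf("pathway '%s': %d duplicate edge(s), keeping last occurrence",
                      pathway_id, ndup))
      edges <- edges[!duplicated(key, fromLast = TRUE), , drop = FALSE]
      report$duplicate_edges <- ndup
    }
    nself <- sum(edges$source == edges$target)
    if (nself > 0) {
      message(sprintf("pathway '%s': %d self-loop(s) retained", pathway_id, nself))
      report$self_loops <- nself
    }
  }
  rownames(edges) <- NULL

  n <- length(genes)
  beta_matrix <- matrix(0L, n, n, dimnames = list(genes, genes))
  if (nrow(edges))
    beta_matrix[cbind(match(edges$target, genes), match(edges$source, genes))] <-
      edges$beta

  nds <- colSums(beta_matrix != 0L)
  storage.mode(nds) <- "integer"

  structure(list(pathway_id = pathway_id,
                 pathway_name = pathway_name,
                 genes = genes,
                 edges = edges,
                 beta_matrix = beta_matrix,
                 nds = nds,
                 report = report),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s' (%s): %d genes, %d edges\n",
              x$pathway_id, x$pathway_name, length(x$genes), nrow(x$edges)))
  if (length(x$report))
    cat("  parse report:",
        paste(names(x$report), unlist(x$report), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

## relation subtype -> edge sign mapping; anything not matched is dropped.
## inhibition/repression are tested first so that "repression" never matches
## an activation pattern by accident.
.kgml_subtype_sign <- function(subtype_names) {
  s <- tolower(paste(subtype_names, collapse = " "))
  if (grepl("inhibition|repression", s)) return(-1L)
  if (grepl("activation|expression", s)) return(1L)
  NA_integer_
}

#' Parse a KGML (KEGG XML) pathway file
#'
#' Reads the KEGG Markup Language dialect: `entry` elements of type
#' `"gene"` become nodes (an entry naming several genes is expanded to
#' every member, each inheriting the entry's relations) and `relation`
#' elements are mapped to signed edges. Relation subtypes containing
#' "activation" or "expression" yield beta = +1, subtypes containing
#' "inhibition" or "repression" yield beta = -1; every other relation
#' (binding/association, compound-mediated, indirect effects, ...) is
#' dropped and counted in the returned graph's `report$dropped_relations`.
#' Compound nodes are ignored: perturbation propagation here is defined on
#' genes only, so no edges are routed through compounds.
#'
#' @param path Path to a KGML file.
#' @return A [pathway_graph()]; `report` records kept/dropped relation
#'   counts.
#' @examples
#' kgml <- system.file("extdata", "synthetic_toy_pathway.xml", package = "wspia")
#' g <- parse_kgml(kgml)
#' g$edges
#' @export
parse_kgml <- function(path) {
  if (!file.exists(path)) stop("KGML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed XML in KGML file '", path, "': ",
                         conditionMessage(e)))
  root <- xml2::xml_attrs(doc)
  pathway_id <- if (!is.na(root["name"])) unname(root["name"]) else
    tools::file_path_sans_ext(basename(path))
  pathway_name <- if (!is.na(root["title"])) unname(root["title"]) else pathway_id

  entries <- xml2::xml_find_all(doc, ".//entry")
  entry_genes <- list()
  for (e in entries) {
    if (!identical(xml2::xml_attr(e, "type"), "gene")) next
    id <- xml2::xml_attr(e, "id")
    nm <- xml2::xml_attr(e, "name")
    genes <- strsplit(trimws(nm), "\\s+")[[1]]
    genes <- genes[nzchar(genes)]
    if (length(genes)) entry_genes[[id]] <- genes
  }
  if (!length(entry_genes))
    stop("KGML file '", path, "' contains no gene entries")

  relations <- xml2::xml_find_all(doc, ".//relation")
  src <- character(); tgt <- character(); beta <- integer()
  dropped <- 0L; kept <- 0L
  for (r in relations) {
    e1 <- xml2::xml_attr(r, "entry1")
    e2 <- xml2::xml_attr(r, "entry2")
    subtypes <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
    sign <- .kgml_subtype_sign(subtypes)
    g1 <- entry_genes[[e1]]; g2 <- entry_genes[[e2]]
    if (is.na(sign) || is.null(g1) || is.null(g2)) {
      dropped <- dropped + 1L
      next
    }
    kept <- kept + 1L
    ## multi-gene entries expand to all member pairs
    pairs <- expand.grid(source = g1, target = g2,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    src <- c(src, pairs$source)
    tgt <- c(tgt, pairs$target)
    beta <- c(beta, rep(sign, nrow(pairs)))
  }

  pathway_graph(pathway_id, pathway_name,
                genes = unique(unlist(entry_genes, use.names = FALSE)),
                edges = data.frame(source = src, target = tgt, beta = beta,
                                   stringsAsFactors = FALSE),
                report = list(relations_total = length(relations),
                              relations_kept = kept,
                              dropped_relations = dropped))
}

#' Parse a signed edge-list pathway file
#'
#' The edge-list format is one edge per line, `source<TAB>target<TAB>sign`
#' with sign one of `+1`, `-1`, `1`. Comment lines starting with `#` may
#' carry metadata of the form `# pathway_id: xxx` or `# pathway_name: xxx`.
#'
#' @param path Path to an edge-list file.
#' @return A [pathway_graph()].
#' @seealso [write_edge_list()] for the inverse operation.
#' @export
parse_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pathway_id <- tools::file_path_sans_ext(basename(path))
  pathway_name <- pathway_id
  src <- character(); tgt <- character(); beta <- integer()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*(pathway_id|pathway_name)\\s*:\\s*(.+?)\\s*$", line))[[1]]
      if (length(m) == 3L) {
        if (m[2] == "pathway_id") pathway_id <- m[3] else pathway_name <- m[3]
      }
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop(sprintf("edge-list '%s' line %d: expected 3 tab-separated fields", path, i))
    if (!parts[3] %in% c("+1", "-1", "1"))
      stop(sprintf("edge-list '%s' line %d: sign '%s' not in {+1,-1,1}",
                   path, i, parts[3]))
    src <- c(src, parts[1]); tgt <- c(tgt, parts[2])
    beta <- c(beta, as.integer(parts[3]))
  }
  pathway_graph(pathway_id, pathway_name,
                edges = data.frame(source = src, target = tgt, beta = beta,
                                   stringsAsFactors = FALSE))
}

#' Write a pathway graph to the signed edge-list format
#'
#' @param graph A [pathway_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pathway_id: %s", graph$pathway_id),
               sprintf("# pathway_name: %s", graph$pathway_name)), con)
  if (nrow(graph$edges))
    writeLines(sprintf("%s\t%s\t%+d", graph$edges$source, graph$edges$target,
                       graph$edges$beta), con)
  invisible(path)
}

#' Downstream-gene counts
#'
#' Number of distinct downstream targets (out-degree) per gene; the
#' denominator that normalises each upstream gene's contribution during
#' perturbation propagation.
#'
#' @param graph A [pathway_graph()].
#' @return Named integer vector, one entry per gene (0 for sink genes).
#' @export
downstream_counts <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  graph$nds
}

#' Load every pathway file in a directory
#'
#' Files ending in `.xml` are parsed as KGML, files ending in `.tsv` or
#' `.txt` as signed edge-lists. One pathway per file.
#'
#' @param dir Directory of pathway files.
#' @return Named list of [pathway_graph()] objects (names = pathway ids).
#' @export
load_pathway_dir <- function(dir) {
  if (!dir.exists(dir)) stop("pathway directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.(xml|tsv|txt)$", full.names = TRUE)
  if (!length(files)) stop("no pathway files (*.xml, *.tsv, *.txt) in: ", dir)
  graphs <- lapply(files, function(f) {
    if (grepl("\\.xml$", f)) parse_kgml(f) else parse_edge_list(f)
  })
  names(graphs) <- vapply(graphs, `[[`, "", "pathway_id")
  graphs
}
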