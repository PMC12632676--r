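#' Classify a protein's druggability
#'
#' `direct` if any drug targets the protein itself; otherwise `secondary` if
#' any first-shell interactor at interaction score `>= score_min` is a drug
#' target; otherwise `none`. Proteins absent from the PPI table are treated
#' as having no interactors.
#'
#' @param protein Protein (gene) symbol.
#' @param drug_targets Tibble `drug`, `target`.
#' @param ppi Tibble `protein_a`, `protein_b`, `score` (undirected).
#' @param score_min Interaction confidence threshold (default 0.9; 0.8 is
#'   the documented alternative).
#' @return `"direct"`, `"secondary"` or `"none"`.
#' @export
classify_druggability <- function(protein, drug_targets, ppi,
                                  score_min = 0.9) {
  if (protein %in% drug_targets$target) return("direct")
  nb <- c(ppi$protein_b[ppi$protein_a == protein & ppi$score >= score_min],
          ppi$protein_a[ppi$protein_b == protein & ppi$score >= score_min])
  if (any(nb %in% drug_targets$target)) "secondary" else "none"
}

#' Assemble the drug-protein-phenotype evidence network
#'
#' Builds one typed graph component per prioritized protein: the protein
#' node, an `mr_association` edge (signed by MR beta) to the kidney-outcome
#' node, `targets` edges from its drugs, `interacts` edges to first-shell
#' interactors at or above `score_min` (and `targets` edges from drugs
#' hitting those interactors), and `phewas_association` edges to its
#' significant phecodes. Summary counts (unique drugs, unique targets,
#' unique drug-target pairs) are attached as graph attributes.
#'
#' @param verdicts Verdict table ([protein_verdicts()]) or any tibble with
#'   `protein_id`; rows define the prioritized proteins.
#' @param mr_betas Named numeric vector of MR betas per protein (sign of the
#'   kidney association); missing proteins get NA.
#' @param phewas_hits Tibble `protein_id`, `phecode`, `beta` of significant
#'   hits (optional).
#' @param drug_targets,ppi Fixture tables as in [classify_druggability()].
#' @param score_min Interaction threshold (default 0.9).
#' @return An `igraph` object with vertex attribute `type` in
#'   `{drug, protein, kidney_outcome, phecode}` and edge attributes `type`,
#'   `score`, `sign`.
#' @export
build_network <- function(verdicts, mr_betas = NULL, phewas_hits = NULL,
                          drug_targets, ppi, score_min = 0.9) {
  proteins <- unique(verdicts$protein_id)
  nodes <- tibble::tibble(name = "kidney_outcome", type = "kidney_outcome")
  edges <- tibble::tibble(from = character(), to = character(),
                          type = character(), score = numeric(),
                          sign = numeric())
  add_node <- function(nodes, name, type) {
    if (name %in% nodes$name) nodes
    else dplyr::bind_rows(nodes, tibble::tibble(name = name, type = type))
  }
  for (p in proteins) {
    nodes <- add_node(nodes, p, "protein")
    b <- if (!is.null(mr_betas) && p %in% names(mr_betas)) mr_betas[[p]] else NA_real_
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = p, to = "kidney_outcome", type = "mr_association",
      score = NA_real_, sign = sign(b %||% NA_real_)))
    for (d in drug_targets$drug[drug_targets$target == p]) {
      nodes <- add_node(nodes, d, "drug")
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        from = d, to = p, type = "targets", score = NA_real_, sign = NA_real_))
    }
    ints <- ppi[(ppi$protein_a == p | ppi$protein_b == p) &
                  ppi$score >= score_min, , drop = FALSE]
    if (nrow(ints) > 0) {
      other <- ifelse(ints$protein_a == p, ints$protein_b, ints$protein_a)
      for (k in seq_along(other)) {
        if (other[k] == p) next
        nodes <- add_node(nodes, other[k], "protein")
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          from = p, to = other[k], type = "interacts",
          score = ints$score[k], sign = NA_real_))
        for (d in drug_targets$drug[drug_targets$target == other[k]]) {
          nodes <- add_node(nodes, d, "drug")
          edges <- dplyr::bind_rows(edges, tibble::tibble(
            from = d, to = other[k], type = "targets", score = NA_real_,
            sign = NA_real_))
        }
      }
    }
    if (!is.null(phewas_hits)) {
      ph <- phewas_hits[phewas_hits$protein_id == p, , drop = FALSE]
      for (k in seq_len(nrow(ph))) {
        pc <- paste0("phecode:", ph$phecode[k])
        nodes <- add_node(nodes, pc, "phecode")
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          from = p, to = pc, type = "phewas_association", score = NA_real_,
          sign = sign(ph$beta[k] %||% NA_real_)))
      }
    }
  }
  edges <- dplyr::distinct(edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = as.data.frame(nodes))
  tgt_edges <- edges[edges$type == "targets", ]
  igraph::graph_attr(g, "n_drugs") <- dplyr::n_distinct(tgt_edges$from)
  igraph::graph_attr(g, "n_targets") <- dplyr::n_distinct(tgt_edges$to)
  igraph::graph_attr(g, "n_pairs") <- nrow(dplyr::distinct(
    tgt_edges[, c("from", "to")]))
  g
}

#' Export / import an evidence network as text
#'
#' Writes a node table, an edge table (tab-delimited) and a GraphML file;
#' `read_network` reconstructs the graph from the node/edge tables so the
#' round trip preserves the node and edge multisets.
#'
#' @param graph From [build_network()].
#' @param dir Output directory.
#' @return `write_network`: `dir` invisibly; `read_network`: an `igraph`.
#' @export
write_network <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  edges <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  igraph::write_graph(graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  nodes <- utils::read.table(file.path(dir, "nodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  edges <- utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
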