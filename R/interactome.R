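# cross-set protein-interaction bridge analysis on scored edge tables

#' Combine per-channel interaction scores into one probability
#'
#' Prior-corrected noisy-OR integration of evidence channels, the standard
#' way interaction databases combine independent evidence types:
#' each channel score is first stripped of the prior,
#' `s_i' = max(0, (s_i - prior) / (1 - prior))`, the corrected scores are
#' combined as `S' = 1 - prod(1 - s_i')`, and the prior is added back,
#' `S = S' + prior * (1 - S')`.
#'
#' @param channel_scores Numeric vector of per-channel probabilities in
#'   `[0, 1]`.
#' @param prior Baseline interaction probability in `[0, 1)` (default
#'   0.041, the convention of the major interaction database).
#' @return Combined probability in `[prior, 1]` (or `prior` itself when no
#'   channel exceeds it).
#' @export
combined_score <- function(channel_scores, prior = 0.041) {
  if (!is.numeric(prior) || length(prior) != 1L || prior < 0 || prior >= 1)
    stop_invalid("prior must lie in [0, 1)")
  if (!length(channel_scores)) return(prior)
  if (any(!is.finite(channel_scores)) ||
      any(channel_scores < 0 | channel_scores > 1))
    stop(errorCondition("channel scores must lie in [0, 1]",
                        class = c("picramp_invalid_score", "picramp_error")))
  s <- pmax(0, (channel_scores - prior) / (1 - prior))
  s_comb <- 1 - prod(1 - s)
  s_comb + prior * (1 - s_comb)
}

.canonical_edges <- function(edges) {
  edges <- as.data.frame(edges)
  if (!all(c("gene_a", "gene_b") %in% names(edges)))
    stop_invalid("edge table needs gene_a and gene_b columns")
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges
}

#' Edges bridging two gene sets
#'
#' Undirected edges with one endpoint in `set_a` and the other in `set_b`,
#' filtered at `min_score` on the combined score and sorted by descending
#' score. Genes present in both sets are flagged with a warning and removed
#' from both before matching.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param edges Data frame with columns `gene_a`, `gene_b`, `combined`
#'   (plus any channel columns, carried through).
#' @param min_score Minimum combined score retained (default 0.4, the usual
#'   medium-confidence cutoff).
#' @return The filtered, sorted edge data frame with an added `a_member`
#'   column naming the `set_a` endpoint.
#' @export
cross_set_edges <- function(set_a, set_b, edges, min_score = 0.4) {
  edges <- .canonical_edges(edges)
  if (!"combined" %in% names(edges))
    stop_invalid("edge table needs a 'combined' score column")
  shared <- intersect(set_a, set_b)
  if (length(shared)) {
    warning(sprintf("genes in both sets removed from the bridge: %s",
                    paste(shared, collapse = ", ")))
    set_a <- setdiff(set_a, shared)
    set_b <- setdiff(set_b, shared)
  }
  ab <- (edges$gene_a %in% set_a & edges$gene_b %in% set_b) |
        (edges$gene_a %in% set_b & edges$gene_b %in% set_a)
  out <- edges[ab & edges$combined >= min_score, , drop = FALSE]
  out <- out[order(-out$combined, out$gene_a, out$gene_b), , drop = FALSE]
  out$a_member <- ifelse(out$gene_a %in% set_a, out$gene_a, out$gene_b)
  rownames(out) <- NULL
  out
}

#' Flag genes against a membership annotation
#'
#' Pure set membership against a user-supplied annotation list (e.g. a GO
#' term's gene list); no live database queries.
#'
#' @param genes Character vector of gene symbols.
#' @param annotation Character vector of annotated symbols.
#' @return Named logical vector.
#' @export
annotate_genes <- function(genes, annotation) {
  stats::setNames(genes %in% annotation, genes)
}

#' Read / write a scored edge TSV
#'
#' Columns: `gene_a`, `gene_b`, optional `channel_*` columns, `combined`.
#'
#' @param path TSV file path.
#' @param edges Edge data frame (for writing).
#' @return `read_edge_tsv`: the edge data frame; `write_edge_tsv`: `path`
#'   invisibly.
#' @export
read_edge_tsv <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("missing edge table: %s", path))
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_edge_tsv
#' @export
write_edge_tsv <- function(edges, path) {
  data.table::fwrite(as.data.frame(edges), path, sep = "\t")
  invisible(path)
}

#' Export the bipartite bridge subgraph as GraphML
#'
#' @param bridge_edges Output of [cross_set_edges()].
#' @param set_a,set_b The gene sets (stored as a vertex `side` attribute).
#' @param path GraphML output path.
#' @return `path`, invisibly.
#' @export
write_bridge_graphml <- function(bridge_edges, set_a, set_b, path) {
  genes <- unique(c(bridge_edges$gene_a, bridge_edges$gene_b))
  g <- igraph::graph_from_data_frame(
    bridge_edges[, c("gene_a", "gene_b", "combined")],
    directed = FALSE,
    vertices = data.frame(name = genes,
                          side = ifelse(genes %in% set_a, "set_a", "set_b")))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
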