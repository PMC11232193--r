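#' Decompose triplets into the two edges through the shared miRNA
#'
#' Each lncRNA-miRNA-mRNA triplet is rendered as two network edges,
#' lncRNA-miRNA and miRNA-mRNA, carrying the triplet's differential partial
#' correlation as weight.
#'
#' @param triplets data frame with columns `lncRNA`, `miRNA`, `mRNA` and
#'   optionally `delta_rho`.
#' @return data frame with columns `source`, `interaction`, `target`,
#'   `delta_rho`.
#' @export
triplet_edges <- function(triplets) {
  triplets <- as.data.frame(triplets, stringsAsFactors = FALSE)
  d <- triplets$delta_rho %||% rep(NA_real_, nrow(triplets))
  rbind(
    data.frame(source = triplets$lncRNA, interaction = "lncRNA-miRNA",
               target = triplets$miRNA, delta_rho = d,
               stringsAsFactors = FALSE),
    data.frame(source = triplets$miRNA, interaction = "miRNA-mRNA",
               target = triplets$mRNA, delta_rho = d,
               stringsAsFactors = FALSE))
}

edge_input <- function(x) {
  if (inherits(x, "patient_network")) x$edges
  else as.data.frame(x, stringsAsFactors = FALSE)
}

#' Export a network in SIF format
#'
#' Writes Cytoscape-loadable SIF (`source<TAB>interaction<TAB>target`) with
#' edge types `lncRNA-miRNA` and `miRNA-mRNA`.
#'
#' @param x a [patient_network()] or a triplet data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(x, path) {
  edges <- triplet_edges(edge_input(x))
  if (nrow(edges) == 0L)
    psnet_warn("exporting an empty network")
  write.table(unique(edges[c("source", "interaction", "target")]), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert triplets to an igraph object
#'
#' Nodes carry the attribute `rna_type` (`lncRNA`, `miRNA` or `mRNA`) and
#' edges carry `interaction` and `delta_rho`, matching the shapes/attributes
#' used for Cytoscape visualization.
#'
#' @param x a [patient_network()] or triplet data frame.
#' @return an [igraph::igraph] object.
#' @export
as_cerna_graph <- function(x) {
  tri <- edge_input(x)
  edges <- triplet_edges(tri)
  nodes <- unique(rbind(
    data.frame(name = tri$lncRNA, rna_type = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(name = tri$miRNA, rna_type = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(name = tri$mRNA, rna_type = "mRNA",
               stringsAsFactors = FALSE)))
  if (anyDuplicated(nodes$name))
    psnet_error("a node appears with more than one RNA type",
                "psnet_validate_error")
  edges$delta_rho[is.na(edges$delta_rho)] <- 0
  agg <- stats::aggregate(delta_rho ~ source + interaction + target,
                          data = edges, FUN = mean)
  igraph::graph_from_data_frame(agg[c("source", "target", "interaction",
                                      "delta_rho")],
                                directed = FALSE, vertices = nodes)
}

#' Export a network in GraphML format
#'
#' GraphML with node attribute `rna_type` and edge attributes `interaction`
#' and `delta_rho`, loadable by Cytoscape.
#'
#' @inheritParams export_sif
#' @return `path`, invisibly.
#' @export
export_graphml <- function(x, path) {
  g <- as_cerna_graph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Pool patient networks into one cohort network
#'
#' Merges the triplet edges of several patient-specific networks (or the
#' selected-triplet table) into one network, recording for every triplet how
#' many patients support it and the mean differential partial correlation
#' across supporting patients.
#'
#' @param networks list of [patient_network()] objects.
#' @return data frame with triplet columns plus `support` and
#'   `mean_delta_rho`, sorted by decreasing support.
#' @export
pooled_network <- function(networks) {
  stopifnot(is.list(networks))
  edges <- do.call(rbind, lapply(networks, function(nw) edge_input(nw)))
  if (is.null(edges) || nrow(edges) == 0L) {
    psnet_warn("pooling empty networks")
    return(data.frame(lncRNA = character(), miRNA = character(),
                      mRNA = character(), support = integer(),
                      mean_delta_rho = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(edges$lncRNA, edges$miRNA, edges$mRNA, sep = "\r")
  agg <- data.frame(edges[!duplicated(key), c("lncRNA", "miRNA", "mRNA")],
                    support = as.vector(table(key)[unique(key)]),
                    mean_delta_rho = as.vector(tapply(edges$delta_rho, key,
                                                      mean)[unique(key)]),
                    stringsAsFactors = FALSE)
  agg <- agg[order(-agg$support, agg$lncRNA), ]
  rownames(agg) <- NULL
  agg
}
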