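# Multi-layer interaction networks: first-order construction from seeds,
# greedy minimization, merging, and hub detection.
#
# Edge direction (TF -> gene, miRNA -> gene) is metadata only: connectivity
# is always computed on the undirected graph.

as_edge_table <- function(interactions) {
  edges <- if (inherits(interactions, "interaction_set")) interactions$edges
           else interactions
  stopifnot(all(c("source", "target", "layer") %in% names(edges)))
  edges
}

as_node_types <- function(interactions) {
  if (inherits(interactions, "interaction_set")) interactions$node_types
  else NULL
}

#' Build a first-order interaction network around seed genes
#'
#' Collects the seeds plus every node adjacent to a seed on the requested
#' layers, with all edges among the collected nodes (the induced first-order
#' subgraph). Seeds missing from the interaction universe are kept as
#' isolated seed nodes with a warning.
#'
#' @param seeds character vector of seed genes.
#' @param interactions an `interaction_set` or an edge tibble
#'   `(source, target, layer)`.
#' @param layers which layers to use.
#' @param node_types optional tibble `(node, biotype)` for node annotation.
#' @return An object of class `omic_network`: list with `graph` (igraph,
#'   undirected), `nodes` (tibble: node, role, biotype), `seeds`, `layers`.
#' @export
build_network <- function(seeds, interactions,
                          layers = c("ppi", "tf_gene", "mirna_gene"),
                          node_types = NULL) {
  if (length(seeds) == 0) abort("seeds must be non-empty", class = "personet_error")
  edges <- as_edge_table(interactions) |> filter(.data$layer %in% layers)
  node_types <- node_types %||% as_node_types(interactions)

  touch <- edges$source %in% seeds | edges$target %in% seeds
  neighbors <- setdiff(unique(c(edges$source[touch], edges$target[touch])),
                       seeds)
  nodes <- c(seeds, neighbors)
  keep <- edges$source %in% nodes & edges$target %in% nodes
  sub <- edges[keep, , drop = FALSE]

  isolated <- setdiff(seeds, unique(c(sub$source, sub$target)))
  if (length(isolated) > 0)
    warn(sprintf("%d seed(s) have no interactions and stay isolated: %s",
                 length(isolated), paste(head(isolated, 5), collapse = ", ")))

  g <- igraph::graph_from_data_frame(
    sub[, c("source", "target", "layer")], directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- igraph::simplify(g, edge.attr.comb = "first")
  new_omic_network(g, seeds, layers, node_types)
}

new_omic_network <- function(g, seeds, layers, node_types = NULL) {
  nm <- igraph::V(g)$name
  nodes <- tibble(node = nm,
                  role = ifelse(nm %in% seeds, "seed", "connector"))
  if (!is.null(node_types)) {
    nodes <- left_join(nodes, node_types[, c("node", "biotype")], by = "node")
  } else nodes$biotype <- NA_character_
  structure(list(graph = g, nodes = nodes,
                 seeds = intersect(seeds, nm), layers = layers),
            class = "omic_network")
}

#' @export
print.omic_network <- function(x, ...) {
  cat(sprintf("<omic_network> %d nodes (%d seeds), %d edges [%s]\n",
              igraph::vcount(x$graph), length(x$seeds),
              igraph::ecount(x$graph), paste(x$layers, collapse = ",")))
  invisible(x)
}

#' Network edge table
#' @param net an `omic_network`.
#' @return Tibble `(source, target, layer)`.
#' @export
network_edges <- function(net) {
  df <- igraph::as_data_frame(net$graph, what = "edges")
  tibble(source = df$from, target = df$to,
         layer = df$layer %||% NA_character_)
}

# number of connected components that contain at least one seed
seed_component_count <- function(g, seeds) {
  comp <- igraph::components(g)
  length(unique(comp$membership[intersect(seeds, igraph::V(g)$name)]))
}

#' Greedy minimum network retaining seed connectivity
#'
#' Removes non-seed nodes greedily while preserving the number of connected
#' components that contain at least one seed: candidates are visited in
#' ascending degree, ties broken by ascending betweenness and then node
#' identifier, and a node is removed if and only if its removal does not
#' split (or merge) any seed-bearing component. Removal repeats to a fixed
#' point, so the retained connectors form a minimal essential set: dropping
#' any one of them would disconnect seeds.
#'
#' @param net an `omic_network` (typically from [build_network()]).
#' @param seeds seed genes; defaults to the network's own seed set.
#' @return The minimized `omic_network`; all seeds are retained.
#' @export
minimum_network <- function(net, seeds = NULL) {
  stopifnot(inherits(net, "omic_network"))
  seeds <- seeds %||% net$seeds
  g <- net$graph
  target_comp <- seed_component_count(g, seeds)
  repeat {
    cand <- setdiff(igraph::V(g)$name, seeds)
    if (length(cand) == 0) break
    deg <- igraph::degree(g)[cand]
    btw <- igraph::betweenness(g)[cand]
    ord <- cand[order(deg, btw, cand)]
    removed <- FALSE
    for (v in ord) {
      g2 <- igraph::delete_vertices(g, v)
      if (seed_component_count(g2, seeds) == target_comp) {
        g <- g2
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  new_omic_network(g, seeds, net$layers, net$nodes[, c("node", "biotype")])
}

#' Merge networks by node and edge union
#'
#' A node is a seed in the merged network if it is a seed in any input;
#' biotypes must agree where both are annotated. Per-node provenance (which
#' inputs contributed it) is kept in the node table.
#'
#' @param nets list of `omic_network` objects (or several passed via `...`).
#' @param ... networks, if `nets` is a single network.
#' @return The merged `omic_network` with a `provenance` list-column.
#' @export
merge_networks <- function(nets, ...) {
  if (inherits(nets, "omic_network")) nets <- c(list(nets), list(...))
  stopifnot(length(nets) >= 2)
  labels <- names(nets) %||% paste0("net", seq_along(nets))
  labels[labels == ""] <- paste0("net", which(labels == ""))

  all_nodes <- bind_rows(lapply(seq_along(nets), function(i)
    mutate(nets[[i]]$nodes, .net = labels[i])))
  conflicts <- all_nodes |>
    filter(!is.na(.data$biotype)) |>
    distinct(.data$node, .data$biotype) |>
    count(.data$node) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0)
    abort(sprintf("conflicting biotypes for node(s): %s",
                  paste(head(conflicts$node, 5), collapse = ", ")),
          class = "personet_error")

  edges <- bind_rows(lapply(nets, network_edges)) |>
    distinct(.data$source, .data$target, .data$layer)
  seeds <- unique(unlist(lapply(nets, `[[`, "seeds")))
  nodes <- unique(all_nodes$node)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::simplify(g, edge.attr.comb = "first")
  layers <- unique(unlist(lapply(nets, `[[`, "layers")))
  out <- new_omic_network(g, seeds, layers,
                          distinct(all_nodes[!is.na(all_nodes$biotype),
                                             c("node", "biotype")]))
  prov <- all_nodes |> group_by(.data$node) |>
    summarise(provenance = list(unique(.data$.net)), .groups = "drop")
  out$nodes <- left_join(out$nodes, prov, by = "node")
  out
}

#' Nodes shared between two networks, partitioned by biotype
#'
#' @param net_a,net_b `omic_network` objects on the same identifier
#'   universe.
#' @return Tibble `(node, biotype)` of the shared nodes, with the biotype
#'   partition available via `table()`; empty when the networks are
#'   disjoint.
#' @export
shared_hub <- function(net_a, net_b) {
  shared <- intersect(net_a$nodes$node, net_b$nodes$node)
  bio <- bind_rows(net_a$nodes, net_b$nodes) |>
    filter(!is.na(.data$biotype)) |>
    distinct(.data$node, .data$biotype)
  out <- tibble(node = sort(shared))
  left_join(out, bio, by = "node")
}

#' Connector genes linking several GET gene sets
#'
#' Builds the first-order network on the union of the GET genes, minimizes
#' it, and returns the non-seed connectors that remain. When no path links
#' the GET sets the connector list is empty and a warning reports the
#' disconnection.
#'
#' @param get_gene_sets list (>= 2) of character gene sets.
#' @param interactions interaction table or `interaction_set`.
#' @param layers layers to use.
#' @return Character vector of connector genes.
#' @export
connect_gets <- function(get_gene_sets, interactions,
                         layers = c("ppi", "tf_gene", "mirna_gene")) {
  stopifnot(length(get_gene_sets) >= 2)
  seeds <- unique(unlist(get_gene_sets))
  net <- suppressWarnings(build_network(seeds, interactions, layers))
  mn <- minimum_network(net)
  if (seed_component_count(mn$graph, mn$seeds) > 1)
    warn("GET sets are not fully connected by the interaction universe")
  setdiff(mn$nodes$node, seeds)
}
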