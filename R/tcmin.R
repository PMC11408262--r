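# Hub expansion into the multi-modular regulatory network, regulator
# signature modules, and network analytics.

#' Expand a control hub into its direct-interactor network
#'
#' Collects every direct interactor of any hub member on the miRNA-gene and
#' protein-protein layers and keeps only hub-incident edges (hub-hub and
#' hub-interactor): the expanded network is hub-centric by construction.
#' Each non-hub node records its regulator signature — the exact subset of
#' hub miRNAs targeting it — and the hub proteins it touches.
#'
#' @param hub character vector of hub members, or a list with elements
#'   `mirnas` and `proteins`. A warning is raised when the composition is
#'   not the standard 3 miRNAs + 3 protein-coding genes.
#' @param interactions an `interaction_set` or edge tibble.
#' @param layers layers queried for direct interactors.
#' @param node_types tibble `(node, biotype)`; taken from the
#'   `interaction_set` when available.
#' @return An object of class `tcmin`: list with `hub` (tibble node,
#'   biotype), `nodes` (tibble: node, biotype, signature (list of hub
#'   miRNAs), hub_proteins (list)), `edges`, and `graph` (undirected
#'   igraph over hub and interactors).
#' @export
expand_hub <- function(hub, interactions,
                       layers = c("mirna_gene", "ppi"),
                       node_types = NULL) {
  node_types <- node_types %||% as_node_types(interactions)
  if (is.list(hub) && !is.data.frame(hub)) {
    hub_mirnas <- hub$mirnas
    hub_proteins <- hub$proteins
    hub <- c(hub_mirnas, hub_proteins)
  } else {
    stopifnot(!is.null(node_types))
    bt <- node_types$biotype[match(hub, node_types$node)]
    hub_mirnas <- hub[!is.na(bt) & bt == "mirna"]
    hub_proteins <- setdiff(hub, hub_mirnas)
  }
  if (length(hub_mirnas) != 3 || length(hub_proteins) != 3)
    warn(sprintf("nonstandard hub composition: %d miRNAs + %d others",
                 length(hub_mirnas), length(hub_proteins)))

  edges <- as_edge_table(interactions) |> filter(.data$layer %in% layers)
  universe <- unique(c(edges$source, edges$target))
  absent <- setdiff(hub, universe)
  if (length(absent) > 0)
    abort(sprintf("hub member(s) missing from the interaction universe: %s",
                  paste(absent, collapse = ", ")), class = "personet_error")

  inc <- edges$source %in% hub | edges$target %in% hub
  hub_edges <- edges[inc, , drop = FALSE]
  other <- ifelse(hub_edges$source %in% hub & !(hub_edges$target %in% hub),
                  hub_edges$target,
                  ifelse(hub_edges$target %in% hub &
                           !(hub_edges$source %in% hub),
                         hub_edges$source, NA_character_))
  partner_hub <- ifelse(is.na(other), NA_character_,
                        ifelse(hub_edges$source %in% hub,
                               hub_edges$source, hub_edges$target))
  interactors <- sort(unique(other[!is.na(other)]))

  pairs <- tibble(node = other, hub_member = partner_hub) |>
    filter(!is.na(.data$node)) |> distinct()
  sig <- pairs |> filter(.data$hub_member %in% hub_mirnas) |>
    group_by(.data$node) |>
    summarise(signature = list(sort(unique(.data$hub_member))),
              .groups = "drop")
  prot <- pairs |> filter(.data$hub_member %in% hub_proteins) |>
    group_by(.data$node) |>
    summarise(hub_proteins = list(sort(unique(.data$hub_member))),
              .groups = "drop")

  nodes <- tibble(node = interactors) |>
    left_join(sig, by = "node") |>
    left_join(prot, by = "node") |>
    mutate(signature = purrr::map(.data$signature, ~ .x %||% character(0)),
           hub_proteins = purrr::map(.data$hub_proteins,
                                     ~ .x %||% character(0)))
  if (!is.null(node_types))
    nodes <- left_join(nodes, node_types[, c("node", "biotype")], by = "node")
  else nodes$biotype <- NA_character_

  hub_tbl <- tibble(node = hub,
                    biotype = ifelse(hub %in% hub_mirnas, "mirna",
                                     "protein_coding"))
  g <- igraph::graph_from_data_frame(
    hub_edges[, c("source", "target", "layer")], directed = FALSE,
    vertices = data.frame(name = c(hub, interactors)))
  g <- igraph::simplify(g, edge.attr.comb = "first")

  structure(list(hub = hub_tbl, hub_mirnas = hub_mirnas,
                 hub_proteins = hub_proteins,
                 nodes = nodes,
                 edges = as_tibble(hub_edges), graph = g),
            class = "tcmin")
}

#' @export
print.tcmin <- function(x, ...) {
  cat(sprintf("<tcmin> hub of %d (%d miRNA + %d protein), %d direct interactors, %d edges\n",
              nrow(x$hub), length(x$hub_mirnas), length(x$hub_proteins),
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Partition network genes into regulator-signature modules
#'
#' Modules M1-M7 are the seven non-empty subsets of the three hub miRNAs:
#' every non-hub gene with at least one hub-miRNA edge belongs to the
#' module matching exactly its regulator signature. Canonically, M1-M3 are
#' the two-miRNA signatures in descending member count, M4 the
#' all-three-miRNAs signature, and M5-M7 the single-miRNA signatures in
#' descending member count. Modules M8-M10 collect the miRNAs attached to
#' each hub protein (in hub-protein order); a miRNA touching several hub
#' proteins is assigned to each, flagged `multi_assigned`. Genes with
#' neither a hub-miRNA edge nor (for miRNAs) a hub-protein edge are
#' reported in the `unassigned` attribute.
#'
#' @param tc a [expand_hub()] result.
#' @return An object of class `module_assignment`: tibble
#'   `(module, signature, member, biotype, multi_assigned)` with attribute
#'   `unassigned`.
#' @export
regulator_signature_modules <- function(tc) {
  stopifnot(inherits(tc, "tcmin"))
  nodes <- tc$nodes
  sig_chr <- vapply(nodes$signature, paste, "", collapse = "+")
  has_sig <- sig_chr != ""

  sig_tab <- tibble(node = nodes$node[has_sig],
                    biotype = nodes$biotype[has_sig],
                    signature = sig_chr[has_sig],
                    size = lengths(nodes$signature[has_sig]))
  sigs <- sig_tab |> count(.data$signature, .data$size) |>
    arrange(.data$size, dplyr::desc(.data$n), .data$signature)
  pairs2 <- sigs |> filter(.data$size == 2) |> arrange(dplyr::desc(.data$n))
  singles <- sigs |> filter(.data$size == 1) |> arrange(dplyr::desc(.data$n))
  triple <- sigs |> filter(.data$size == 3)
  module_of <- c(setNames(paste0("M", seq_len(nrow(pairs2))), pairs2$signature),
                 if (nrow(triple) > 0) setNames("M4", triple$signature),
                 setNames(paste0("M", 4 + seq_len(nrow(singles))),
                          singles$signature))

  gene_modules <- sig_tab |>
    mutate(module = unname(module_of[.data$signature]),
           multi_assigned = FALSE) |>
    select("module", "signature", member = "node", "biotype",
           "multi_assigned")

  # M8-M10: miRNA clusters of the hub proteins
  prot_rows <- list()
  for (i in seq_along(tc$hub_proteins)) {
    p <- tc$hub_proteins[i]
    members <- nodes |>
      filter(.data$biotype == "mirna",
             purrr::map_lgl(.data$hub_proteins, ~ p %in% .x))
    if (nrow(members) > 0)
      prot_rows[[p]] <- tibble(
        module = paste0("M", 7 + i), signature = p,
        member = members$node, biotype = members$biotype,
        multi_assigned = lengths(members$hub_proteins) > 1)
  }
  out <- bind_rows(gene_modules, bind_rows(prot_rows)) |>
    arrange(.data$module, .data$member)

  assigned <- unique(out$member)
  unassigned <- setdiff(nodes$node, assigned)
  if (length(unassigned) > 0)
    attr(out, "unassigned") <- unassigned
  class(out) <- c("module_assignment", class(out))
  out
}

#' Module sizes
#' @param modules a `module_assignment`.
#' @return Tibble `(module, signature, n)`.
#' @export
module_sizes <- function(modules) {
  as_tibble(modules) |> group_by(.data$module, .data$signature) |>
    summarise(n = n(), .groups = "drop") |> arrange(.data$module)
}

#' Per-node degree, clustering coefficient and eigenvector centrality
#'
#' Eigenvector centrality is computed by power iteration on the adjacency
#' of the largest connected component (with a unit diagonal shift so that
#' bipartite-like graphs converge), normalized to a maximum of 1; nodes
#' outside the largest component receive 0. The clustering coefficient is
#' the per-node triangle density (isolated and degree-1 nodes get 0).
#'
#' @param net an `omic_network`, `tcmin`, or igraph object.
#' @param tol power-iteration convergence tolerance (max absolute change).
#' @param max_iter iteration cap; exceeding it raises an error reporting
#'   the residual.
#' @return Tibble `(node, degree, clustering, eigenvector)`.
#' @export
node_metrics <- function(net, tol = 1e-10, max_iter = 10000) {
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  cc <- unname(igraph::transitivity(g, type = "localundirected",
                                    isolates = "zero"))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- comp$membership == main
  ev <- numeric(length(nm))
  sub <- igraph::induced_subgraph(g, which(in_main))
  A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
  x <- rep(1, nrow(A))
  it <- 0L
  repeat {
    it <- it + 1L
    xn <- as.numeric(A %*% x) + x   # unit shift keeps the iteration stable
    xn <- xn / max(xn)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
    if (it >= max_iter)
      abort(sprintf("eigenvector centrality did not converge: residual %.3g after %d iterations",
                    delta, it), class = "personet_error")
  }
  ev[in_main] <- x[match(nm[in_main], igraph::V(sub)$name)]
  if (any(!in_main) && sum(!in_main) > 0)
    warn(sprintf("%d node(s) outside the largest component get eigenvector 0",
                 sum(!in_main)))
  tibble(node = nm, degree = unname(deg), clustering = cc, eigenvector = ev)
}

as_igraph <- function(net) {
  if (inherits(net, "igraph")) net
  else if (inherits(net, "omic_network") || inherits(net, "tcmin")) net$graph
  else abort("cannot interpret network object", class = "personet_error")
}

#' Community detection by modularity maximization
#'
#' Louvain-style greedy modularity optimization (multi-level algorithm),
#' deterministic given the seed. A network without edges yields one
#' community per node and Q = 0.
#'
#' @param net network object or igraph.
#' @param resolution resolution parameter of the modularity objective.
#' @param seed integer seed.
#' @return List with `membership` (tibble node, community) and
#'   `modularity` (Q of the returned partition).
#' @export
community_detection <- function(net, resolution = 1, seed = 1) {
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  if (igraph::ecount(g) == 0) {
    return(list(membership = tibble(node = nm,
                                    community = seq_along(nm)),
                modularity = 0))
  }
  cl <- with_seed(as.integer(seed),
                  igraph::cluster_louvain(g, resolution = resolution))
  list(membership = tibble(node = nm,
                           community = as.integer(igraph::membership(cl))),
       modularity = igraph::modularity(g, igraph::membership(cl)))
}

#' Extend a hub network with personality lncRNA interactions
#'
#' Adds, for every interaction involving a personality-associated lncRNA,
#' the non-lncRNA partner gene to the network (if not already present).
#' The lncRNAs themselves are tracked as linkers rather than counted among
#' the network genes, mirroring how the extension is reported: the
#' extended gene count covers regulated genes only.
#'
#' @param tc a `tcmin` object.
#' @param lnc_interactions tibble `(source, target, layer)` of lncRNA
#'   interactions.
#' @param personality_lncrnas the lncRNA identifiers driving the extension.
#' @param node_types tibble `(node, biotype)` for the added genes.
#' @return The extended `tcmin`, with extra fields `n_lnc_interactions`,
#'   `lncrna_linkers`, and `added_genes`.
#' @export
extend_with_lncrna <- function(tc, lnc_interactions, personality_lncrnas,
                               node_types = NULL) {
  stopifnot(inherits(tc, "tcmin"))
  e <- lnc_interactions
  rel <- e[e$source %in% personality_lncrnas |
             e$target %in% personality_lncrnas, , drop = FALSE]
  partner <- ifelse(rel$source %in% personality_lncrnas, rel$target,
                    rel$source)
  linkers <- unique(c(rel$source, rel$target))
  linkers <- intersect(linkers, personality_lncrnas)
  existing <- c(tc$hub$node, tc$nodes$node)
  added <- setdiff(unique(partner), c(existing, personality_lncrnas))

  out <- tc
  if (length(added) > 0) {
    add_tbl <- tibble(node = added,
                      signature = list(character(0)),
                      hub_proteins = list(character(0)))
    if (!is.null(node_types))
      add_tbl <- left_join(add_tbl, node_types[, c("node", "biotype")],
                           by = "node")
    else add_tbl$biotype <- NA_character_
    out$nodes <- bind_rows(tc$nodes, add_tbl)
  }
  out$edges <- bind_rows(tc$edges, as_tibble(rel))
  out$n_lnc_interactions <- nrow(rel)
  out$lncrna_linkers <- sort(linkers)
  out$added_genes <- added
  out
}
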