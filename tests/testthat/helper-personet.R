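# Shared helpers: tiny configurations, an adjusted-Rand-index oracle, and a
# brute-force minimal-connector enumerator used to check greedy network
# minimization.

tiny_cfg <- function(seed = 1, ...) {
  defaults <- list(
    rng_seed = seed, n_subjects = 24, n_genes = 60,
    profile_sizes = c(creative = 8, organized = 10, unregulated = 6),
    n_biclusters = 3, bicluster_genes = 8, n_regions = 6,
    signature_counts = c(A = 6, B = 7, C = 5, AB = 3, AC = 3, BC = 3,
                         ABC = 2),
    ppi_only_pc = 12, mirna_cluster_sizes = c(3, 3, 3),
    n_pseudogenes = 2, n_other_ncrna = 2, n_decoys = 4,
    n_lnc_mirnas = 4, n_lnc_ncrnas = 2, n_personality_lncrnas = 3,
    n_lnc_link_edges = 5)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# pair-counting adjusted Rand index (independent of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# gene -> planted bicluster labels from an expression_set truth
planted_gene_labels <- function(es) {
  sets <- lapply(es$truth$biclusters, `[[`, "genes")
  setNames(rep(seq_along(sets), times = lengths(sets)), unlist(sets))
}

# hard gene assignment from an fnmf fit (factor with largest loading)
fnmf_gene_assignment <- function(fit) {
  setNames(apply(fit$H, 2, which.max), colnames(fit$H))
}

# All minimal connector subsets of a network: enumerate every subset of
# non-seed nodes, keep those whose induced graph (seeds + subset) preserves
# the seed-component count, and reduce to the inclusion-minimal ones.
minimal_connector_sets <- function(graph, seeds) {
  nodes <- igraph::V(graph)$name
  connectors <- setdiff(nodes, seeds)
  target <- length(unique(
    igraph::components(graph)$membership[intersect(seeds, nodes)]))
  count_for <- function(keep) {
    sub <- igraph::induced_subgraph(graph, c(seeds, keep))
    length(unique(igraph::components(sub)$membership[seeds]))
  }
  valid <- list()
  for (size in 0:length(connectors)) {
    for (keep in utils::combn(connectors, size, simplify = FALSE)) {
      if (count_for(keep) == target) valid[[length(valid) + 1L]] <- keep
    }
  }
  is_minimal <- vapply(valid, function(s) {
    !any(vapply(valid, function(t)
      length(t) < length(s) && all(t %in% s), logical(1)))
  }, logical(1))
  valid[is_minimal]
}

random_edge_table <- function(n_nodes, p, seed) {
  g <- withr::with_seed(seed,
    igraph::sample_gnp(n_nodes, p))
  igraph::V(g)$name <- LETTERS[seq_len(n_nodes)]
  df <- igraph::as_data_frame(g, what = "edges")
  tibble::tibble(source = df$from, target = df$to, layer = "ppi")
}
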