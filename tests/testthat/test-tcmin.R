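small_interactions <- function(seed = 1) gen_interactions(tiny_cfg(seed = seed))

test_that("hub expansion collects exactly the direct interactors with signatures", {
  it <- small_interactions()
  cfg <- tiny_cfg()
  tc <- expand_hub(list(mirnas = cfg$hub_mirnas, proteins = cfg$hub_proteins),
                   it)
  expect_setequal(tc$nodes$node, it$truth$tcmin_members)
  # a gene targeted by two hub miRNAs appears once, with signature size 2
  ab_gene <- it$truth$pools$AB[1]
  row <- tc$nodes[tc$nodes$node == ab_gene, ]
  expect_equal(nrow(row), 1)
  expect_setequal(row$signature[[1]], cfg$hub_mirnas[1:2])

  expect_error(suppressWarnings(
    expand_hub(c("nope", cfg$hub_mirnas[1:2], cfg$hub_proteins), it)),
    "nope", class = "personet_error")
  expect_warning(expand_hub(list(mirnas = cfg$hub_mirnas[1:2],
                                 proteins = cfg$hub_proteins), it),
                 "nonstandard")
})

test_that("a hub with only internal edges expands to just the hub", {
  types <- tibble::tibble(node = c("m1", "m2", "m3", "p1", "p2", "p3"),
                          biotype = c(rep("mirna", 3),
                                      rep("protein_coding", 3)))
  edges <- tibble::tibble(
    source = c("p1", "p2", "p3", "m1", "m2", "m3"),
    target = c("p2", "p3", "p1", "p1", "p2", "p3"),
    layer = c(rep("ppi", 3), rep("mirna_gene", 3)))
  tc <- expand_hub(list(mirnas = c("m1", "m2", "m3"),
                        proteins = c("p1", "p2", "p3")),
                   edges, node_types = types)
  expect_equal(nrow(tc$nodes), 0)
  expect_equal(nrow(tc$hub), 6)
})

test_that("regulator-signature modules partition hub-miRNA targets exactly", {
  it <- small_interactions(seed = 2)
  cfg <- tiny_cfg(seed = 2)
  tc <- expand_hub(list(mirnas = cfg$hub_mirnas, proteins = cfg$hub_proteins),
                   it)
  mods <- regulator_signature_modules(tc)
  sizes <- module_sizes(mods)

  # M1-M7 partition the genes with >= 1 hub-miRNA edge
  m17 <- as_tibble(mods)[as_tibble(mods)$module %in% paste0("M", 1:7), ]
  expect_equal(anyDuplicated(m17$member), 0L)
  with_sig <- tc$nodes$node[lengths(tc$nodes$signature) > 0]
  expect_setequal(m17$member, with_sig)

  # canonical ordering: pairs by descending size, triple = M4, singletons
  # by descending size
  pools <- it$truth$pools
  expect_equal(sizes$n[sizes$module == "M4"],
               length(pools$ABC))
  pair_sizes <- sort(c(length(pools$AB), length(pools$AC), length(pools$BC)),
                     decreasing = TRUE)
  expect_equal(sizes$n[sizes$module %in% c("M1", "M2", "M3")][
    order(sizes$module[sizes$module %in% c("M1", "M2", "M3")])],
    pair_sizes)

  # M8-M10 are the miRNA clusters of the hub proteins
  m8 <- as_tibble(mods)[as_tibble(mods)$module == "M8", ]
  expect_true(all(m8$biotype == "mirna"))
  expect_setequal(m8$member, pools$clusters[[cfg$hub_proteins[1]]])

  # ppi-only protein partners carry no signature -> reported unassigned
  expect_true(all(unlist(pools$ppi) %in% attr(mods, "unassigned")))
})

test_that("node metrics match closed-form values on canonical graphs", {
  star <- igraph::make_star(11, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:11)
  ms <- node_metrics(star)
  expect_equal(ms$eigenvector[1], 1)  # center dominates
  expect_true(all(ms$eigenvector[-1] < 1))

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  mt <- node_metrics(tri)
  expect_equal(mt$clustering, rep(1, 3))
  expect_equal(mt$eigenvector, rep(1, 3), tolerance = 1e-8)
})

test_that("eigenvector centrality matches a dense eigen-decomposition oracle", {
  g <- withr::with_seed(50, igraph::sample_gnp(50, 0.12))
  igraph::V(g)$name <- sprintf("n%02d", 1:50)
  comp <- igraph::components(g)
  main <- igraph::induced_subgraph(g, which(comp$membership ==
                                              which.max(comp$csize)))
  A <- as.matrix(igraph::as_adjacency_matrix(main))
  eg <- eigen(A, symmetric = TRUE)
  oracle <- abs(eg$vectors[, 1])
  oracle <- oracle / max(oracle)
  ms <- suppressWarnings(node_metrics(g, tol = 1e-12))
  got <- ms$eigenvector[match(igraph::V(main)$name, ms$node)]
  expect_equal(got, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # relabeling invariance
  perm <- withr::with_seed(51, sample(50))
  g2 <- igraph::permute(g, perm)
  ms2 <- suppressWarnings(node_metrics(g2, tol = 1e-12))
  expect_equal(ms2$eigenvector[match(ms$node, ms2$node)], ms$eigenvector,
               tolerance = 1e-9)
})

test_that("community detection separates cliques and is seed-deterministic", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  igraph::V(g)$name <- paste0("v", 1:12)
  cd <- community_detection(g, seed = 3)
  expect_equal(length(unique(cd$membership$community)), 2)
  expect_gt(cd$modularity, 0.3)
  # direct Q computation from the partition formula
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  part <- cd$membership$community
  q_oracle <- 0
  for (cmm in unique(part)) {
    inside <- igraph::V(g)$name[part == cmm]
    sub <- igraph::induced_subgraph(g, inside)
    e_c <- igraph::ecount(sub)
    d_c <- sum(deg[part == cmm])
    q_oracle <- q_oracle + e_c / m - (d_c / (2 * m))^2
  }
  expect_equal(cd$modularity, q_oracle, tolerance = 1e-12)

  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("f", 1:5)
  expect_equal(length(unique(community_detection(full)$membership$community)),
               1)

  empty <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(empty)$name <- paste0("e", 1:4)
  cd0 <- community_detection(empty)
  expect_equal(cd0$modularity, 0)
  expect_equal(length(unique(cd0$membership$community)), 4)

  cd_a <- community_detection(g, seed = 9)
  cd_b <- community_detection(g, seed = 9)
  expect_identical(cd_a$membership, cd_b$membership)
})

test_that("lncRNA extension adds partner genes and counts interactions", {
  it <- small_interactions(seed = 3)
  cfg <- tiny_cfg(seed = 3)
  tc <- expand_hub(list(mirnas = cfg$hub_mirnas, proteins = cfg$hub_proteins),
                   it)
  base_n <- nrow(tc$nodes)
  ext <- extend_with_lncrna(tc, it$lnc_expansion, it$truth$lncrnas,
                            it$node_types)
  expect_equal(nrow(ext$nodes), base_n + length(it$truth$lnc_new_genes))
  expect_setequal(ext$added_genes, it$truth$lnc_new_genes)
  # biotype conservation: composition sums to the node count
  comp <- biotype_composition(ext$nodes$node, it$node_types |>
                                dplyr::rename(gene = node))
  expect_equal(sum(comp$n), nrow(ext$nodes))

  links <- extend_with_lncrna(tc, it$lnc_links, it$truth$lncrnas,
                              it$node_types)
  expect_equal(links$n_lnc_interactions, nrow(it$lnc_links))
  expect_length(links$added_genes, 0)

  same <- extend_with_lncrna(tc, it$lnc_expansion[0, ], it$truth$lncrnas)
  expect_equal(nrow(same$nodes), base_n)
})
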