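# Fixture bundles: everything the pipeline consumes, generated in one call.

#' Generate a complete synthetic input bundle
#'
#' Builds every pipeline input (expression + labels, brain atlas, gene sets,
#' typed interaction tables, lncRNA tables, annotations, personality and
#' switch gene lists) with consistent planted structure. Two profiles are
#' provided:
#'
#' * `"small"` — a minutes-scale bundle for tests and examples;
#' * `"paper_scale"` — the replication profile: 459 subjects
#'   (creative 125 / organized 241 / unregulated 93), a 34,602-gene array
#'   with 7 planted biclusters of 104 genes (728 bicluster genes in all),
#'   972 personality genes of which 129 sit inside the hub-expanded
#'   network, seed networks minimizing to 45 and 43 nodes sharing the
#'   6-gene hub, a hub interactor set of 4190 genes
#'   (3919 / 198 / 38 / 35 by biotype) extending to 4376, and exact
#'   LLPS-RNA annotation counts (1699 of the extended network members,
#'   9571 of a 61,035-gene universe high-throughput; 72 reviewed).
#'
#' Four bicluster/GE-set pairs are planted to share brain regions
#' (9 distinct regions in all), so the colocalization stage recovers four
#' genomic-environmental-transcriptomic subsets.
#'
#' @param profile `"small"` or `"paper_scale"`.
#' @param seed integer root seed.
#' @param n_universe size of the annotation gene universe (defaults to
#'   61,035 for `paper_scale`, 3,000 for `small`).
#' @return An object of class `personet_fixtures`; see Details.
#' @details The returned list carries `cfg`, `expression`, `t_sets`,
#'   `ge_sets`, `atlas`, `interactions`, `annotations`,
#'   `personality_genes`, `switch_genes`, `personality_lncrnas`,
#'   `universe`, and the planted `truth`.
#' @examples
#' fx <- make_fixtures("small", seed = 7)
#' dim(fx$expression$values)
#' @export
make_fixtures <- function(profile = c("small", "paper_scale"), seed = 1,
                          n_universe = NULL) {
  profile <- match.arg(profile)
  enrich_map <- list(T1 = c("R01", "R02", "R03"), SAER = c("R01", "R02", "R03"),
                     T2 = c("R04", "R05", "R06"), SASC = c("R04", "R05", "R06"),
                     T3 = c("R07", "R08"), SC = c("R07", "R08"),
                     T4 = "R09", ER = "R09")
  if (profile == "paper_scale") {
    cfg <- synth_config(rng_seed = seed, bicluster_genes = 104,
                        region_enrichment = enrich_map)
    n_universe <- n_universe %||% 61035L
    n_personality <- 972L; n_in_network <- 129L
    ge_sizes <- c(SA = 200, SC = 200, ER = 200,
                  SASC = 124, SAER = 124, SCER = 124)
  } else {
    cfg <- synth_config(
      rng_seed = seed, n_subjects = 90L, n_genes = 800L,
      profile_sizes = c(creative = 25, organized = 40, unregulated = 25),
      bicluster_genes = 40L, n_regions = 12L,
      region_enrichment = enrich_map,
      signature_counts = c(A = 30, B = 35, C = 20, AB = 12, AC = 8,
                           BC = 10, ABC = 8),
      ppi_only_pc = 12L, mirna_cluster_sizes = c(8L, 8L, 8L),
      n_pseudogenes = 4L, n_other_ncrna = 4L, n_decoys = 6L,
      n_lnc_mirnas = 10L, n_lnc_ncrnas = 4L,
      n_personality_lncrnas = 6L, n_lnc_link_edges = 12L)
    n_universe <- n_universe %||% 3000L
    n_personality <- 180L; n_in_network <- 20L
    ge_sizes <- c(SA = 30, SC = 30, ER = 30, SASC = 30, SAER = 30, SCER = 30)
  }
  stopifnot(sum(ge_sizes) == n_personality)

  expr <- gen_expression(cfg)
  inter <- gen_interactions(cfg)
  t_sets <- setNames(lapply(expr$truth$biclusters, `[[`, "genes"),
                     vapply(expr$truth$biclusters, `[[`, "", "id"))

  with_seed(substream_seed(seed, "fixtures"), {
    pools <- inter$truth$pools
    # personality genes inside the hub-expanded network: 5 switch genes in
    # the largest singleton-signature pool (module M5), one in the next
    switch_in_b <- sample(setdiff(pools$B, unlist(pools$ppi)), 5)
    switch_in_a <- sample(setdiff(pools$A, unlist(pools$ppi)), 1)
    switch_genes <- c(switch_in_b, switch_in_a)
    other_pool <- setdiff(unlist(pools[c("A", "B", "C", "AB", "AC", "BC", "ABC")]),
                          switch_genes)
    in_network <- c(switch_genes,
                    sample(other_pool, n_in_network - length(switch_genes)))
    expr_genes <- colnames(expr$values)
    non_t <- setdiff(expr_genes, unlist(t_sets))
    outside <- sample(non_t, n_personality - n_in_network)
    personality_genes <- sample(c(in_network, outside))  # shuffled
    ge_sets <- split(personality_genes,
                     rep(names(ge_sizes), times = ge_sizes))[names(ge_sizes)]

    atlas_genes <- c(expr_genes, in_network)
    atlas <- gen_atlas(cfg, gene_sets = c(t_sets, ge_sets), genes = atlas_genes)

    # annotation universe with planted LLPS counts
    nodes <- inter$node_types$node
    universe <- unique(c(expr_genes, nodes))
    n_fill <- n_universe - length(universe)
    if (n_fill < 0)
      abort("annotation universe smaller than the generated gene pool",
            class = "personet_error")
    filler <- make_ids("U", n_fill, width = 5)
    universe <- c(universe, filler)

    members_ext <- c(inter$truth$tcmin_members, inter$truth$lnc_new_genes)
    if (profile == "paper_scale") {
      llps_counts <- list(AB = 72, BC = 46, AC = 35, ABC = 5,
                          A = 651, B = 489, C = 277,
                          clusters = 70, ppi = 30, expansion = 24)
    } else {
      sizes <- c(lengths(pools[c("AB", "BC", "AC", "ABC", "A", "B", "C")]),
                 clusters = length(unlist(pools$clusters)),
                 ppi = length(unlist(pools$ppi)),
                 expansion = length(inter$truth$lnc_new_genes))
      llps_counts <- as.list(round(0.4 * sizes))
    }
    flat_pools <- c(pools[c("AB", "BC", "AC", "ABC", "A", "B", "C")],
                    list(clusters = unlist(pools$clusters, use.names = FALSE),
                         ppi = unlist(pools$ppi, use.names = FALSE),
                         expansion = inter$truth$lnc_new_genes))
    llps_members <- plant_flags(flat_pools, llps_counts)
    outside_pool <- setdiff(universe, c(members_ext, cfg$hub_mirnas,
                                        cfg$hub_proteins, inter$truth$lncrnas))
    n_ht_total <- if (profile == "paper_scale") 9571L
                  else round(cfg$llps_fraction * n_universe) + length(llps_members)
    llps_outside <- sample(outside_pool,
                           max(0L, n_ht_total - length(llps_members)))
    llps_ht <- c(llps_members, llps_outside)
    n_rev_total <- if (profile == "paper_scale") 72L else 20L
    n_rev_in <- if (profile == "paper_scale") 23L else 6L
    llps_reviewed <- c(sample(members_ext, n_rev_in),
                       sample(outside_pool, n_rev_total - n_rev_in))

    known <- inter$node_types[, c("node", "biotype")]
    idx <- match(universe, known$node)
    biotype <- ifelse(is.na(idx),
                      sample(c("protein_coding", "lncrna", "pseudogene",
                               "other_ncrna"),
                             length(universe), replace = TRUE,
                             prob = c(0.8, 0.12, 0.05, 0.03)),
                      known$biotype[idx])
    annotations <- tibble(gene = universe, biotype = biotype,
                          llps_reviewed = universe %in% llps_reviewed,
                          llps_ht = universe %in% llps_ht)
  })

  structure(
    list(profile = profile, cfg = cfg, expression = expr,
         t_sets = t_sets, ge_sets = ge_sets, atlas = atlas,
         interactions = inter, annotations = annotations,
         personality_genes = personality_genes, switch_genes = switch_genes,
         personality_lncrnas = inter$truth$lncrnas,
         universe = universe,
         truth = c(expr$truth["responsive_genes"], inter$truth,
                   list(llps_ht = llps_ht, llps_reviewed = llps_reviewed,
                        in_network_personality = in_network))),
    class = "personet_fixtures")
}

#' @export
print.personet_fixtures <- function(x, ...) {
  cat(sprintf("<personet_fixtures> profile '%s': %d subjects, %d genes, %d-gene universe\n",
              x$profile, nrow(x$expression$values), ncol(x$expression$values),
              length(x$universe)))
  invisible(x)
}
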