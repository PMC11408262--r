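# End-to-end orchestration of the seven analysis stages over a fixture
# bundle (or equivalently structured inputs). The package's functions are
# the interface; this driver chains them with one root seed and returns a
# report object carrying every stage artifact plus provenance.

#' Run the full integration pipeline
#'
#' Executes, in order: quantile normalization and variable-gene selection;
#' fuzzy NMF biclustering; brain-region colocalization of bicluster and
#' genomic-environmental gene sets (GET subsets); construction and
#' minimization of the seed interaction networks; network merging and hub
#' detection; hub expansion with regulator-signature modules, node metrics
#' and communities; lncRNA extension; and LLPS enrichment statistics.
#'
#' Seed gene sets for the network stage are taken from
#' `fixtures$truth$seed_sets` when present (replication use: the seed lists
#' are inputs), otherwise from the GET subset gene payloads.
#'
#' @param fixtures a [make_fixtures()] bundle (or a list with the same
#'   elements).
#' @param n_top_genes number of most-variable genes carried forward.
#' @param k factorization rank.
#' @param membership_threshold bicluster membership cutoff (default `1/k`).
#' @param n_perm permutations per colocalization test.
#' @param alpha significance level for region links.
#' @param correction multiple-testing correction across regions.
#' @param layers interaction layers used for network construction.
#' @param n_boot bootstrap replicates for the profile ANOVA.
#' @param seed root seed; every stage derives a substream.
#' @return An object of class `personet_report`: list of stage results
#'   (`preprocess`, `bicluster`, `colocalize`, `networks`, `tcmin`,
#'   `enrichment`) plus `provenance`.
#' @export
run_pipeline <- function(fixtures,
                         n_top_genes = NULL, k = 7,
                         membership_threshold = NULL,
                         n_perm = 1999, alpha = 0.05,
                         correction = "bonferroni",
                         layers = c("ppi", "tf_gene", "mirna_gene"),
                         n_boot = 50, seed = 1) {
  fx <- fixtures
  expr <- fx$expression
  n_top_genes <- n_top_genes %||% min(1500L, ncol(expr$values))

  ## stage 1: preprocessing + group statistics
  norm <- quantile_normalize(expr$values)
  top <- select_variable_genes(norm, n_top_genes)
  boot <- bootstrap_profile_anova(norm, expr$labels, genes = top,
                                  n_boot = n_boot,
                                  seed = substream_seed(seed, "bootstrap"))

  ## stage 2: biclustering
  fit <- fnmf(norm[, top, drop = FALSE], k = k,
              seed = substream_seed(seed, "fnmf"))
  bics <- extract_biclusters(fit, membership_threshold)
  overlap <- bicluster_overlap(bics)

  ## stage 3: colocalization -> GET subsets
  t_sets <- setNames(lapply(bics, `[[`, "genes"),
                     vapply(bics, `[[`, "", "id"))
  coloc_seed <- substream_seed(seed, "colocalize")
  t_links <- bind_rows(imap(t_sets, function(gs, id)
    suppressWarnings(region_significance(gs, fx$atlas, n_perm = n_perm,
                                         seed = coloc_seed, alpha = alpha,
                                         correction = correction,
                                         set_id = id))))
  ge_links <- bind_rows(imap(fx$ge_sets, function(gs, id)
    region_significance(gs, fx$atlas, n_perm = n_perm, seed = coloc_seed,
                        alpha = alpha, correction = correction,
                        set_id = id)))
  gets <- find_get_subsets(t_links, ge_links, t_sets, fx$ge_sets)

  ## stage 4-5: seed networks, minimization, merge, hub
  seed_sets <- fx$truth$seed_sets %||%
    setNames(lapply(seq_len(nrow(gets)), function(i)
      union(gets$t_genes[[i]], gets$ge_genes[[i]])), gets$id)
  nets <- lapply(seed_sets, function(s)
    suppressWarnings(build_network(s, fx$interactions, layers)))
  min_nets <- lapply(nets, minimum_network)
  merged <- merge_networks(min_nets)
  hub <- shared_hub(min_nets[[1]], min_nets[[2]])

  ## stage 6: hub expansion, modules, analytics, extension
  tc <- expand_hub(hub$node, fx$interactions)
  modules <- regulator_signature_modules(tc)
  metrics <- node_metrics(tc)
  comms <- community_detection(tc, seed = substream_seed(seed, "community"))
  ext <- extend_with_lncrna(tc, fx$interactions$lnc_expansion,
                            fx$personality_lncrnas,
                            fx$interactions$node_types)

  ## stage 7: enrichment overlays
  ann <- fx$annotations
  ext_genes <- ext$nodes$node
  llps_ht <- ann$gene[ann$llps_ht]
  llps_rev <- ann$gene[ann$llps_reviewed]
  enr_ht <- set_enrichment(ext_genes, llps_ht, ann$gene)
  enr_rev <- set_enrichment(ext_genes, llps_rev, ann$gene)
  composition <- biotype_composition(tc$nodes$node, ann)
  composition_ext <- biotype_composition(ext_genes, ann)
  pers <- gene_list_overlap(tc$nodes$node, fx$personality_genes, modules)
  sw <- gene_list_overlap(tc$nodes$node, fx$switch_genes, modules)
  mod_llps <- module_llps_fractions(modules, llps_ht)

  structure(list(
    preprocess = list(n_genes = ncol(norm), top_genes = top, bootstrap = boot),
    bicluster = list(fit = fit, biclusters = bics, overlap = overlap),
    colocalize = list(t_links = t_links, ge_links = ge_links, gets = gets),
    networks = list(minimum = min_nets, merged = merged, hub = hub),
    tcmin = list(network = tc, modules = modules, metrics = metrics,
                 communities = comms, extended = ext),
    enrichment = list(llps_ht = enr_ht, llps_reviewed = enr_rev,
                      composition = composition,
                      composition_extended = composition_ext,
                      personality_overlap = pers, switch_overlap = sw,
                      module_llps = mod_llps),
    provenance = list(
      seed = as.integer(seed),
      package_version = as.character(utils::packageVersion("personet")),
      parameters = list(n_top_genes = n_top_genes, k = k,
                        membership_threshold = membership_threshold %||% 1 / k,
                        n_perm = n_perm, alpha = alpha,
                        correction = correction, layers = layers,
                        n_boot = n_boot),
      config_hash = rlang::hash(fx$cfg))),
    class = "personet_report")
}

#' @export
print.personet_report <- function(x, ...) {
  cat("<personet_report>\n")
  cat(sprintf("  variable genes: %d; biclusters: %d (shared genes: %d)\n",
              length(x$preprocess$top_genes), length(x$bicluster$biclusters),
              length(x$bicluster$overlap$shared_genes)))
  cat(sprintf("  GET subsets: %d over %d shared regions\n",
              nrow(x$colocalize$gets),
              length(unique(unlist(x$colocalize$gets$shared_regions)))))
  cat(sprintf("  merged network: %d nodes; hub: %d\n",
              nrow(x$networks$merged$nodes), nrow(x$networks$hub)))
  cat(sprintf("  hub interactors: %d (extended: %d)\n",
              nrow(x$tcmin$network$nodes), nrow(x$tcmin$extended$nodes)))
  cat(sprintf("  LLPS (high-throughput): %.1f%% members vs %.1f%% background\n",
              100 * x$enrichment$llps_ht$member_fraction,
              100 * x$enrichment$llps_ht$background_fraction))
  invisible(x)
}

#' Write a pipeline report to JSON (plus a short Markdown summary)
#'
#' @param report a `personet_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- report_summary(report)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Pipeline report", "",
          sprintf("- seed: %d", report$provenance$seed),
          sprintf("- variable genes: %d", summary$n_top_genes),
          sprintf("- biclusters: %d", summary$n_biclusters),
          sprintf("- GET subsets: %d (%d shared regions)",
                  summary$n_get_subsets, summary$n_shared_regions),
          sprintf("- merged network: %d nodes; hub: %d",
                  summary$merged_network_size, summary$hub_size),
          sprintf("- hub interactors: %d (extended %d)",
                  summary$n_hub_interactors, summary$n_extended),
          sprintf("- LLPS: %.1f%% vs %.1f%% background",
                  summary$llps_member_pct, summary$llps_background_pct))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

report_summary <- function(report) {
  list(
    seed = report$provenance$seed,
    config_hash = report$provenance$config_hash,
    package_version = report$provenance$package_version,
    n_top_genes = length(report$preprocess$top_genes),
    n_biclusters = length(report$bicluster$biclusters),
    n_shared_bicluster_genes = length(report$bicluster$overlap$shared_genes),
    n_get_subsets = nrow(report$colocalize$gets),
    n_shared_regions =
      length(unique(unlist(report$colocalize$gets$shared_regions))),
    minimum_network_sizes =
      unname(vapply(report$networks$minimum,
                    function(n) nrow(n$nodes), integer(1))),
    merged_network_size = nrow(report$networks$merged$nodes),
    hub_size = nrow(report$networks$hub),
    n_hub_interactors = nrow(report$tcmin$network$nodes),
    n_extended = nrow(report$tcmin$extended$nodes),
    modularity = report$tcmin$communities$modularity,
    llps_member_pct = 100 * report$enrichment$llps_ht$member_fraction,
    llps_background_pct = 100 * report$enrichment$llps_ht$background_fraction)
}
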