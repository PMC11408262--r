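#' Configuration for the synthetic multi-omic data generator
#'
#' Bundles every knob of the synthetic-data generators into a single
#' validated object. The defaults encode the replication study conditions:
#' 459 subjects split into three personality-profile groups (creative 125,
#' organized 241, unregulated 93), a 34,602-gene expression array, seven
#' planted subject-by-gene biclusters, a genes-by-regions brain atlas, and a
#' multi-layer interaction universe whose regulator hub is 3 miRNAs plus
#' 3 protein-coding genes shared between two seed networks.
#'
#' @param n_subjects number of subjects (rows of the expression matrix).
#' @param n_genes number of genes on the expression array.
#' @param profile_sizes named integer vector of subjects per personality
#'   profile; must sum to `n_subjects`.
#' @param n_biclusters number of planted subject-by-gene biclusters (the
#'   factorization rank `k` used downstream).
#' @param bicluster_genes genes per planted bicluster (blocks are disjoint in
#'   genes); `NULL` picks `floor(n_genes / (3 * n_biclusters))`.
#' @param bicluster_subject_range range of the fraction of subjects drawn
#'   into each bicluster; subject sets may overlap across biclusters.
#' @param bicluster_effect log2-units expression shift inside a planted
#'   bicluster. Zero is allowed (planted structure becomes unrecoverable).
#' @param profile_effect named per-profile mean shifts (log2 units) applied
#'   to the responsive gene subset; defaults encode the ordered effect
#'   creative > organized > unregulated.
#' @param responsive_frac fraction of genes responding to the profile effect.
#' @param noise_sd standard deviation of i.i.d. Gaussian noise (log2 units).
#' @param baseline_mean,baseline_sd per-gene baseline expression parameters
#'   (log2 intensity scale, post-normalization).
#' @param n_regions number of brain regions in the synthetic atlas.
#' @param region_enrichment named list mapping gene-set id to the regions in
#'   which that set's genes are over-expressed.
#' @param atlas_effect additive atlas expression boost in enriched regions.
#' @param hub_mirnas,hub_proteins identifiers of the planted control hub
#'   (3 miRNAs and 3 protein-coding genes).
#' @param signature_counts named counts of protein-coding genes per hub
#'   miRNA regulator signature. Names use the letters A, B, C for the three
#'   hub miRNAs in order, so `"AB"` is the set targeted by exactly the first
#'   and second hub miRNA. All 7 non-empty signatures must be present.
#' @param ppi_only_pc protein-coding genes interacting with hub proteins
#'   only (protein-protein layer, no hub-miRNA edge).
#' @param mirna_cluster_sizes miRNAs attached to each hub protein.
#' @param n_pseudogenes,n_other_ncrna pseudogenes and other ncRNAs targeted
#'   by single hub miRNAs.
#' @param n_decoys prunable leaf nodes attached to seed genes per network.
#' @param n_lnc_mirnas,n_lnc_ncrnas new miRNAs / other ncRNAs reachable only
#'   through personality lncRNA interactions (the network extension).
#' @param n_personality_lncrnas number of personality-associated lncRNAs.
#' @param n_lnc_link_edges lncRNA interaction edges landing on genes already
#'   in the hub-expanded network.
#' @param llps_fraction background probability that a gene carries a
#'   high-throughput LLPS-RNA annotation.
#' @param llps_reviewed_fraction background probability of a reviewed
#'   LLPS-RNA annotation.
#' @param rng_seed integer root seed; every generator derives its own
#'   substream from it (see [substream_seed()]).
#'
#' @return An object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(n_subjects = 20, n_genes = 50,
#'                     profile_sizes = c(creative = 6, organized = 9,
#'                                       unregulated = 5))
#' cfg$n_subjects
#' @export
synth_config <- function(n_subjects = 459,
                         n_genes = 34602,
                         profile_sizes = c(creative = 125, organized = 241,
                                           unregulated = 93),
                         n_biclusters = 7,
                         bicluster_genes = NULL,
                         bicluster_subject_range = c(0.25, 0.45),
                         bicluster_effect = 2,
                         profile_effect = c(creative = 1, organized = 0.5,
                                            unregulated = 0),
                         responsive_frac = 0.05,
                         noise_sd = 0.5,
                         baseline_mean = 7,
                         baseline_sd = 0.8,
                         n_regions = 20,
                         region_enrichment = list(),
                         atlas_effect = 3,
                         hub_mirnas = c("mir-A", "mir-B", "mir-C"),
                         hub_proteins = c("HUBP1", "HUBP2", "HUBP3"),
                         signature_counts = c(A = 1300, B = 1400, C = 800,
                                              AB = 122, AC = 67, BC = 80,
                                              ABC = 8),
                         ppi_only_pc = 142,
                         mirna_cluster_sizes = c(66, 66, 66),
                         n_pseudogenes = 38,
                         n_other_ncrna = 35,
                         n_decoys = 10,
                         n_lnc_mirnas = 173,
                         n_lnc_ncrnas = 13,
                         n_personality_lncrnas = 20,
                         n_lnc_link_edges = 102,
                         llps_fraction = 0.157,
                         llps_reviewed_fraction = 72 / 61035,
                         rng_seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    profile_sizes = profile_sizes, n_biclusters = as.integer(n_biclusters),
    bicluster_genes = bicluster_genes,
    bicluster_subject_range = bicluster_subject_range,
    bicluster_effect = bicluster_effect, profile_effect = profile_effect,
    responsive_frac = responsive_frac, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    n_regions = as.integer(n_regions), region_enrichment = region_enrichment,
    atlas_effect = atlas_effect,
    hub_mirnas = hub_mirnas, hub_proteins = hub_proteins,
    signature_counts = signature_counts, ppi_only_pc = as.integer(ppi_only_pc),
    mirna_cluster_sizes = as.integer(mirna_cluster_sizes),
    n_pseudogenes = as.integer(n_pseudogenes),
    n_other_ncrna = as.integer(n_other_ncrna),
    n_decoys = as.integer(n_decoys),
    n_lnc_mirnas = as.integer(n_lnc_mirnas),
    n_lnc_ncrnas = as.integer(n_lnc_ncrnas),
    n_personality_lncrnas = as.integer(n_personality_lncrnas),
    n_lnc_link_edges = as.integer(n_lnc_link_edges),
    llps_fraction = llps_fraction,
    llps_reviewed_fraction = llps_reviewed_fraction,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  if (is.null(cfg$bicluster_genes)) {
    cfg$bicluster_genes <- max(2L, cfg$n_genes %/% (3L * cfg$n_biclusters))
  }
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_subjects < 2) config_error("n_subjects", "need at least 2 subjects")
  if (cfg$n_genes < 1) config_error("n_genes", "need at least 1 gene")
  if (is.null(names(cfg$profile_sizes)) || any(names(cfg$profile_sizes) == ""))
    config_error("profile_sizes", "must be a named vector of group sizes")
  if (sum(cfg$profile_sizes) != cfg$n_subjects)
    config_error("profile_sizes",
                 sprintf("sizes sum to %d but n_subjects is %d",
                         sum(cfg$profile_sizes), cfg$n_subjects))
  if (cfg$n_biclusters < 1) config_error("n_biclusters", "must be >= 1")
  if (!is.null(cfg$bicluster_genes) &&
      cfg$bicluster_genes * cfg$n_biclusters > cfg$n_genes)
    config_error("bicluster_genes",
                 "disjoint gene blocks exceed the number of genes")
  if (!(cfg$noise_sd > 0)) config_error("noise_sd", "must be > 0")
  if (cfg$llps_fraction < 0 || cfg$llps_fraction > 1)
    config_error("llps_fraction", "must lie in [0, 1]")
  if (!all(sort(names(cfg$profile_effect)) == sort(names(cfg$profile_sizes))))
    config_error("profile_effect",
                 "must name the same profiles as profile_sizes")
  if (length(cfg$hub_mirnas) != 3 || length(cfg$hub_proteins) != 3)
    config_error("hub_mirnas", "the planted hub uses 3 miRNAs and 3 proteins")
  needed <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  if (!all(needed %in% names(cfg$signature_counts)))
    config_error("signature_counts",
                 paste("must name all 7 non-empty signatures:",
                       paste(needed, collapse = ", ")))
  if (any(cfg$signature_counts < 1))
    config_error("signature_counts", "every signature must be populated")
  if (length(cfg$mirna_cluster_sizes) != 3)
    config_error("mirna_cluster_sizes", "one cluster per hub protein")
  if (cfg$ppi_only_pc < 12)
    config_error("ppi_only_pc",
                 "need at least 4 protein partners per hub protein to wire the seed networks")
  if (anyDuplicated(c(cfg$hub_mirnas, cfg$hub_proteins)))
    config_error("hub_mirnas", "hub identifiers must be distinct")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  subjects: %d (%s)\n", x$n_subjects,
              paste(sprintf("%s=%d", names(x$profile_sizes), x$profile_sizes),
                    collapse = ", ")))
  cat(sprintf("  genes: %d; planted biclusters: %d x %d genes (effect %.2g, noise sd %.2g)\n",
              x$n_genes, x$n_biclusters, x$bicluster_genes %||% NA_integer_,
              x$bicluster_effect, x$noise_sd))
  cat(sprintf("  atlas: %d regions; hub: %s + %s\n", x$n_regions,
              paste(x$hub_mirnas, collapse = ","),
              paste(x$hub_proteins, collapse = ",")))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}
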