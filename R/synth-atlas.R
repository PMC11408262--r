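#' Generate a genes-by-regions brain expression atlas
#'
#' Simulates the normalized mean-expression summary that the colocalization
#' stage scores gene sets against. Baseline expression is gamma-distributed
#' (nonnegative, right-skewed, mean 5 atlas units); for each entry of
#' `cfg$region_enrichment`, the named gene set's rows gain
#' `cfg$atlas_effect` in the listed regions.
#'
#' @param cfg a [synth_config()] object; `cfg$region_enrichment` is a named
#'   list `set id -> character vector of regions`.
#' @param gene_sets named list of character vectors; every gene must appear
#'   among the atlas genes.
#' @param genes atlas gene universe (row order of the result). Defaults to
#'   the union of `gene_sets`.
#' @return Numeric matrix `length(genes) x cfg$n_regions` with dimnames,
#'   rows in input gene order, all entries nonnegative.
#' @examples
#' cfg <- synth_config(n_subjects = 4, n_genes = 10, n_regions = 3,
#'                     profile_sizes = c(creative = 1, organized = 2,
#'                                       unregulated = 1),
#'                     region_enrichment = list(setA = "R01"))
#' atlas <- gen_atlas(cfg, list(setA = c("g1", "g2")),
#'                    genes = paste0("g", 1:6))
#' mean(atlas[c("g1", "g2"), "R01"]) > mean(atlas[3:6, "R01"])
#' @export
gen_atlas <- function(cfg, gene_sets, genes = NULL) {
  stopifnot(inherits(cfg, "synth_config"), is.list(gene_sets))
  if (is.null(genes)) genes <- unique(unlist(gene_sets))
  missing <- setdiff(unique(unlist(gene_sets)), genes)
  if (length(missing) > 0)
    abort(sprintf("gene set genes absent from the atlas universe: %s",
                  paste(head(missing, 10), collapse = ", ")),
          class = "personet_error")
  unknown_sets <- setdiff(names(cfg$region_enrichment), names(gene_sets))
  if (length(unknown_sets) > 0)
    abort(sprintf("region_enrichment names gene sets not supplied: %s",
                  paste(unknown_sets, collapse = ", ")),
          class = "personet_error")

  regions <- make_ids("R", cfg$n_regions, width = 2)
  with_seed(substream_seed(cfg$rng_seed, "atlas"), {
    atlas <- matrix(stats::rgamma(length(genes) * cfg$n_regions,
                                  shape = 4, rate = 0.8),
                    nrow = length(genes),
                    dimnames = list(genes, regions))
    for (set in names(cfg$region_enrichment)) {
      regs <- intersect(cfg$region_enrichment[[set]], regions)
      if (length(regs) < length(cfg$region_enrichment[[set]]))
        warn(sprintf("region_enrichment for '%s' names regions outside the atlas", set))
      atlas[gene_sets[[set]], regs] <- atlas[gene_sets[[set]], regs] +
        cfg$atlas_effect
    }
  })
  atlas
}
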