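#' Generate per-gene annotations (biotype and LLPS membership)
#'
#' Draws a biotype for every gene and Bernoulli LLPS-RNA membership at the
#' configured background rates; genes inside `designated_set` are annotated
#' at the elevated `designated_rate` instead. Known biotypes (for example
#' from an [gen_interactions()] node table) can be supplied and are kept.
#'
#' @param cfg a [synth_config()] object; `cfg$llps_fraction` and
#'   `cfg$llps_reviewed_fraction` set the background annotation rates.
#' @param genes character vector of gene identifiers.
#' @param designated_set optional subset of `genes` annotated at an elevated
#'   high-throughput LLPS rate.
#' @param designated_rate elevated rate for `designated_set`.
#' @param known_biotypes optional tibble `(node, biotype)` fixing biotypes.
#' @return Tibble `(gene, biotype, llps_reviewed, llps_ht)`.
#' @examples
#' cfg <- synth_config(llps_fraction = 0.2)
#' ann <- gen_annotations(cfg, paste0("g", 1:50))
#' mean(ann$llps_ht)  # near 0.2
#' @export
gen_annotations <- function(cfg, genes, designated_set = NULL,
                            designated_rate = 0.39,
                            known_biotypes = NULL) {
  stopifnot(inherits(cfg, "synth_config"), is.character(genes))
  with_seed(substream_seed(cfg$rng_seed, "annotations"), {
    biotype <- sample(
      c("protein_coding", "mirna", "lncrna", "pseudogene", "other_ncrna"),
      length(genes), replace = TRUE,
      prob = c(0.72, 0.06, 0.12, 0.06, 0.04))
    if (!is.null(known_biotypes)) {
      idx <- match(genes, known_biotypes$node)
      hit <- !is.na(idx)
      biotype[hit] <- known_biotypes$biotype[idx[hit]]
    }
    rate <- rep(cfg$llps_fraction, length(genes))
    if (!is.null(designated_set)) rate[genes %in% designated_set] <- designated_rate
    llps_ht <- runif(length(genes)) < rate
    llps_reviewed <- runif(length(genes)) < cfg$llps_reviewed_fraction
  })
  tibble(gene = genes, biotype = biotype,
         llps_reviewed = llps_reviewed, llps_ht = llps_ht)
}

# Plant exact annotation counts: pick `counts[[pool]]` genes from each pool
# (without replacement) and flag them. Used by the replication fixtures,
# where the enrichment arithmetic must land on fixed counts rather than
# binomial draws around them.
plant_flags <- function(pools, counts) {
  flagged <- character(0)
  for (nm in names(counts)) {
    pool <- pools[[nm]]
    n <- counts[[nm]]
    if (n > length(pool))
      abort(sprintf("cannot plant %d flags in pool '%s' of size %d",
                    n, nm, length(pool)), class = "personet_error")
    if (n > 0) flagged <- c(flagged, sample(pool, n))
  }
  flagged
}
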