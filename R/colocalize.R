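# Brain-region colocalization of gene sets against an expression atlas.

#' Mean atlas expression of a gene set per brain region
#'
#' @param gene_set character vector of genes.
#' @param atlas numeric genes-by-regions matrix with gene rownames.
#' @param set_id label used in messages.
#' @return Tibble `(region, mean_expression)` in atlas column order.
#' @export
region_scores <- function(gene_set, atlas, set_id = "gene set") {
  stopifnot(is.matrix(atlas), !is.null(rownames(atlas)))
  present <- intersect(gene_set, rownames(atlas))
  if (length(present) == 0)
    abort(sprintf("no genes of '%s' found in the atlas", set_id),
          class = "personet_error")
  missing <- setdiff(gene_set, present)
  if (length(missing) > 0)
    warn(sprintf("%d/%d genes of '%s' absent from the atlas",
                 length(missing), length(gene_set), set_id))
  means <- colMeans(atlas[present, , drop = FALSE])
  tibble(region = colnames(atlas), mean_expression = unname(means))
}

#' Permutation test for per-region over-expression of a gene set
#'
#' Tests, one region at a time, whether the gene set's mean atlas
#' expression exceeds what same-sized random gene sets achieve. The null is
#' built by drawing `n_perm` gene sets of identical size from the atlas
#' without replacement; the one-sided empirical p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, then corrected across
#' regions.
#'
#' @param gene_set character vector of genes.
#' @param atlas genes-by-regions matrix.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param alpha significance level applied to the adjusted p-values.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param set_id label recorded in the output.
#' @return Tibble `(gene_set_id, region, mean_expression, empirical_p,
#'   adjusted_p, significant)`.
#' @export
region_significance <- function(gene_set, atlas, n_perm = 1999, seed = 1,
                                alpha = 0.05,
                                correction = c("bonferroni", "bh"),
                                set_id = "set") {
  correction <- match.arg(correction)
  if (n_perm < 100) abort("n_perm must be >= 100", class = "personet_error")
  present <- intersect(gene_set, rownames(atlas))
  if (length(present) > nrow(atlas))
    abort("gene set larger than the atlas", class = "personet_error")
  obs <- region_scores(present, atlas, set_id = set_id)
  m <- length(present)
  n_regions <- ncol(atlas)

  exceed <- integer(n_regions)
  with_seed(as.integer(seed), {
    for (i in seq_len(n_perm)) {
      null_means <- colMeans(atlas[sample.int(nrow(atlas), m), , drop = FALSE])
      exceed <- exceed + (null_means >= obs$mean_expression)
    }
  })
  p <- unname((1 + exceed) / (1 + n_perm))
  adj <- if (correction == "bonferroni") pmin(1, p * n_regions)
         else p.adjust(p, method = "BH")
  tibble(gene_set_id = set_id, region = obs$region,
         mean_expression = obs$mean_expression,
         empirical_p = p, adjusted_p = adj,
         significant = adj <= alpha)
}

#' Intersect significant regions of transcriptomic and genomic gene sets
#'
#' Pairs every transcriptomic bicluster with every genomic-environmental
#' gene set and emits a genomic-environmental-transcriptomic (GET) subset
#' whenever the two flag at least one brain region in common. The gene
#' payload of a GET subset is the union of the pair's genes with provenance
#' retained; the two gene sets need not overlap.
#'
#' @param t_links tibble of region links for the transcriptomic sets
#'   (rows from [region_significance()], possibly several `gene_set_id`s).
#' @param ge_links same for the genomic-environmental sets.
#' @param t_sets,ge_sets optional named gene-set lists supplying payloads.
#' @return Tibble `(id, t_set, ge_set, n_shared, shared_regions, t_genes,
#'   ge_genes)`; the last three are list-columns. Zero rows when nothing is
#'   shared.
#' @export
find_get_subsets <- function(t_links, ge_links, t_sets = NULL, ge_sets = NULL) {
  sig_regions <- function(links, id)
    links$region[links$gene_set_id == id & links$significant]
  t_ids <- unique(t_links$gene_set_id)
  ge_ids <- unique(ge_links$gene_set_id)
  out <- list()
  for (ti in t_ids) {
    for (gi in ge_ids) {
      shared <- intersect(sig_regions(t_links, ti), sig_regions(ge_links, gi))
      if (length(shared) > 0) {
        out[[length(out) + 1L]] <- tibble(
          id = paste(ti, gi, sep = "-"), t_set = ti, ge_set = gi,
          n_shared = length(shared), shared_regions = list(shared),
          t_genes = list(t_sets[[ti]] %||% character(0)),
          ge_genes = list(ge_sets[[gi]] %||% character(0)))
      }
    }
  }
  if (length(out) == 0)
    return(tibble(id = character(0), t_set = character(0),
                  ge_set = character(0), n_shared = integer(0),
                  shared_regions = list(), t_genes = list(),
                  ge_genes = list()))
  bind_rows(out)
}
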