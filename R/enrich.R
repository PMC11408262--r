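# Annotation overlays: contingency-table enrichment, biotype composition,
# reference-list overlap, per-module LLPS fractions.

#' Annotation enrichment of a gene set against a background universe
#'
#' Pearson chi-square (2 x 2, no continuity correction) plus a two-sided
#' Fisher exact test for enrichment of an annotation inside a member set
#' relative to the full background universe. Fractions are reported as
#' member_count / member_total and background_count / background_total,
#' i.e. the annotation rate inside the set versus in the whole universe.
#'
#' @param member_genes the gene set of interest (must be a subset of
#'   `background_genes`).
#' @param annotation_set annotated genes (subset of the background).
#' @param background_genes the gene universe.
#' @return Object of class `enrichment_result`: list with counts, totals,
#'   fractions, `chi2`, `p` (chi-square), `fisher_p`, and the 2 x 2
#'   `table`.
#' @examples
#' bg <- paste0("g", 1:100)
#' set_enrichment(bg[1:20], bg[c(1:10, 50:59)], bg)
#' @export
set_enrichment <- function(member_genes, annotation_set, background_genes) {
  background_genes <- unique(background_genes)
  member_genes <- unique(member_genes)
  annotation_set <- unique(annotation_set)
  if (length(background_genes) == 0)
    abort("background universe is empty", class = "personet_error")
  out_m <- setdiff(member_genes, background_genes)
  if (length(out_m) > 0)
    abort(sprintf("%d member gene(s) missing from the background universe",
                  length(out_m)), class = "personet_error")
  out_a <- setdiff(annotation_set, background_genes)
  if (length(out_a) > 0)
    abort(sprintf("%d annotated gene(s) missing from the background universe",
                  length(out_a)), class = "personet_error")

  a <- length(intersect(member_genes, annotation_set))
  b <- length(member_genes) - a
  c_ <- length(annotation_set) - a
  d <- length(background_genes) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(c("annotated", "not"),
                                c("member", "background")))
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  fis <- fisher.test(tab)
  structure(
    list(member_count = a,
         member_total = length(member_genes),
         background_count = length(annotation_set),
         background_total = length(background_genes),
         member_fraction = a / length(member_genes),
         background_fraction = length(annotation_set) /
           length(background_genes),
         chi2 = unname(chi$statistic),
         p = unname(chi$p.value),
         fisher_p = unname(fis$p.value),
         table = tab),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d/%d members annotated (%.1f%%, ~%.0f%%) vs %d/%d background (%.1f%%)\n",
              x$member_count, x$member_total, 100 * x$member_fraction,
              100 * x$member_fraction,
              x$background_count, x$background_total,
              100 * x$background_fraction))
  cat(sprintf("  chi2 = %.4g, p = %.3g; Fisher p = %.3g\n",
              x$chi2, x$p, x$fisher_p))
  invisible(x)
}

#' Biotype composition of a node set
#'
#' @param nodes character vector of gene/node identifiers.
#' @param annotations tibble with columns `gene` (or `node`) and `biotype`.
#' @return Tibble `(biotype, n)`; counts sum to `length(unique(nodes))`.
#'   Unannotated nodes are counted as `"other"` with a warning.
#' @export
biotype_composition <- function(nodes, annotations) {
  key <- if ("gene" %in% names(annotations)) "gene" else "node"
  nodes <- unique(nodes)
  if (length(nodes) == 0) {
    out <- tibble(biotype = character(0), n = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  bt <- annotations$biotype[match(nodes, annotations[[key]])]
  if (anyNA(bt)) {
    warn(sprintf("%d node(s) without biotype annotation counted as 'other'",
                 sum(is.na(bt))))
    bt[is.na(bt)] <- "other"
  }
  out <- as_tibble(table(biotype = bt)) |> rename(n = "n") |>
    arrange(dplyr::desc(.data$n))
  attr(out, "total") <- length(nodes)
  out
}

#' Overlap between network nodes and a reference gene list
#'
#' @param nodes network node identifiers.
#' @param reference reference gene list (same namespace).
#' @param modules optional `module_assignment` for a per-module breakdown
#'   of the overlapping genes.
#' @return List with `genes` (the intersection), `n`, and `by_module`
#'   (tibble module, n; `NULL` without module input).
#' @export
gene_list_overlap <- function(nodes, reference, modules = NULL) {
  genes <- sort(intersect(unique(nodes), unique(reference)))
  by_module <- NULL
  if (!is.null(modules)) {
    by_module <- as_tibble(modules) |>
      filter(.data$member %in% genes) |>
      count(.data$module, name = "n")
  }
  list(genes = genes, n = length(genes), by_module = by_module)
}

#' Per-module LLPS-RNA percentages
#'
#' @param modules a `module_assignment` (or tibble with `module`,
#'   `member`).
#' @param llps_set character vector of LLPS-annotated genes.
#' @return Tibble `(module, n, n_llps, pct, pct_1dp)` where `pct` is the
#'   raw percentage and `pct_1dp` its one-decimal rounding; empty modules
#'   do not appear.
#' @export
module_llps_fractions <- function(modules, llps_set) {
  as_tibble(modules) |>
    group_by(.data$module) |>
    summarise(n = n(), n_llps = sum(.data$member %in% llps_set),
              .groups = "drop") |>
    mutate(pct = 100 * .data$n_llps / .data$n,
           pct_1dp = round(.data$pct, 1)) |>
    arrange(.data$module)
}
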