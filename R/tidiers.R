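# broom-style tidiers for the fitted objects.

#' Tidy an FNMF fit into a long loading table
#'
#' @param x an `fnmf_fit`.
#' @param matrix `"W"` (subject loadings) or `"H"` (gene loadings).
#' @param ... unused.
#' @return Tibble `(element, factor, loading, membership)` where
#'   `membership` is the row-normalized fuzzy membership.
#' @export
tidy.fnmf_fit <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  m <- if (matrix == "W") x$W else t(x$H)
  mn <- normalize_rows(m)
  as_tibble(m, rownames = "element") |>
    tidyr::pivot_longer(-"element", names_to = "factor",
                        values_to = "loading") |>
    mutate(membership = tidyr::pivot_longer(
      as_tibble(mn, rownames = "element"), -"element",
      names_to = "factor", values_to = "m")$m)
}

#' @export
glance.fnmf_fit <- function(x, ...) {
  tibble(k = x$k, iterations = x$iterations, converged = x$converged,
         final_error = tail(x$objective, 1), max_shift = max(x$shift))
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(F = x$F, p = x$p, bonferroni_alpha = x$bonferroni_alpha,
         degenerate = x$degenerate)
}

#' @export
tidy.bicluster_set <- function(x, ...) {
  bind_rows(lapply(x, function(b) {
    bind_rows(
      tibble(bicluster = b$id, type = "subject",
             element = names(b$subject_memberships),
             membership = unname(b$subject_memberships)),
      tibble(bicluster = b$id, type = "gene",
             element = names(b$gene_memberships),
             membership = unname(b$gene_memberships)))
  }))
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(member_count = x$member_count, member_total = x$member_total,
         background_count = x$background_count,
         background_total = x$background_total,
         member_pct = 100 * x$member_fraction,
         background_pct = 100 * x$background_fraction,
         chi2 = x$chi2, p = x$p, fisher_p = x$fisher_p)
}
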