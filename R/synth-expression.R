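#' Generate a labeled expression matrix with planted structure
#'
#' Simulates a subjects-by-genes matrix of normalized log2 intensities with
#' three planted layers on top of per-gene Gaussian baselines:
#' disjoint gene blocks elevated in (possibly overlapping) subject subsets
#' (the planted biclusters), an ordered per-profile mean shift on a
#' "responsive" gene subset, and i.i.d. Gaussian noise. The generator is a
#' pure function of the configuration: the same `rng_seed` reproduces the
#' matrix bit for bit.
#'
#' @param cfg a [synth_config()] object.
#' @return An object of class `expression_set`: a list with
#'   \describe{
#'     \item{values}{numeric `n_subjects x n_genes` matrix with subject and
#'       gene dimnames (log2 scale).}
#'     \item{labels}{tibble with columns `subject_id`, `profile`.}
#'     \item{truth}{planted structure: `biclusters` (id, genes, subjects),
#'       `responsive_genes`, and the effect sizes used.}
#'   }
#' @examples
#' cfg <- synth_config(n_subjects = 12, n_genes = 30, n_biclusters = 2,
#'                     profile_sizes = c(creative = 4, organized = 5,
#'                                       unregulated = 3))
#' es <- gen_expression(cfg)
#' dim(es$values)
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_synth_config(cfg)
  n <- cfg$n_subjects
  m <- cfg$n_genes
  k <- cfg$n_biclusters
  bg <- cfg$bicluster_genes
  if (bg * k > m)
    config_error("bicluster_genes", "disjoint gene blocks exceed the number of genes")

  subjects <- make_ids("S", n, width = 5)
  genes <- make_ids("G", m, width = 6)
  labels <- tibble(
    subject_id = subjects,
    profile = rep(names(cfg$profile_sizes), times = cfg$profile_sizes))

  with_seed(substream_seed(cfg$rng_seed, "expression"), {
    baseline <- rnorm(m, cfg$baseline_mean, cfg$baseline_sd)
    values <- matrix(rnorm(n * m, 0, cfg$noise_sd), nrow = n) +
      matrix(baseline, nrow = n, ncol = m, byrow = TRUE)

    # planted biclusters: disjoint gene blocks, overlapping subject subsets
    perm <- sample.int(m)
    blocks <- split(perm[seq_len(bg * k)], rep(seq_len(k), each = bg))
    bic <- vector("list", k)
    for (j in seq_len(k)) {
      frac <- runif(1, cfg$bicluster_subject_range[1],
                    cfg$bicluster_subject_range[2])
      subs <- sort(sample.int(n, max(2L, round(frac * n))))
      values[subs, blocks[[j]]] <- values[subs, blocks[[j]]] +
        cfg$bicluster_effect
      bic[[j]] <- list(id = paste0("T", j),
                       genes = sort(genes[blocks[[j]]]),
                       subjects = subjects[subs])
    }

    # ordered profile effect on a responsive gene subset outside the blocks
    pool <- setdiff(seq_len(m), unlist(blocks))
    n_resp <- min(length(pool), max(1L, round(cfg$responsive_frac * m)))
    resp <- sort(sample(pool, n_resp))
    shift <- cfg$profile_effect[labels$profile]
    values[, resp] <- values[, resp] + shift
  })

  dimnames(values) <- list(subjects, genes)
  structure(
    list(values = values,
         labels = labels,
         truth = list(biclusters = bic,
                      responsive_genes = genes[resp],
                      bicluster_effect = cfg$bicluster_effect,
                      profile_effect = cfg$profile_effect,
                      noise_sd = cfg$noise_sd)),
    class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d subjects x %d genes, %d planted biclusters\n",
              nrow(x$values), ncol(x$values), length(x$truth$biclusters)))
  invisible(x)
}
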