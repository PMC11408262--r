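# Expression preprocessing and group-difference statistics.

#' Quantile-normalize a subjects-by-genes expression matrix
#'
#' Forces every subject's expression distribution onto the common
#' across-subject mean quantile profile (ties averaged). After
#' normalization the sorted value vector of every subject is identical.
#'
#' @param x numeric matrix, subjects in rows, genes in columns; all values
#'   finite.
#' @return A matrix of the same shape and dimnames.
#' @examples
#' m <- matrix(c(1, 2, 3, 8), nrow = 2)  # rows (1,3) and (2,8)
#' quantile_normalize(m)                 # both rows become (1.5, 5.5)
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x)))
    abort("expression matrix contains non-finite values", class = "personet_error")
  if (nrow(x) < 2)
    abort("quantile normalization needs at least 2 subjects", class = "personet_error")
  # limma's normalizeQuantiles works on columns-as-samples
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}

#' Select the most variable genes
#'
#' Ranks genes by expression variance and returns the `n` largest, in
#' descending variance order with ties broken by ascending gene identifier.
#' The default pools all subjects; `method = "between_profile"` instead
#' ranks by the variance of per-profile means, emphasising genes whose mean
#' differs across personality profiles.
#'
#' @param x numeric subjects-by-genes matrix with gene column names.
#' @param n number of genes to keep.
#' @param method variance definition, `"pooled"` (default) or
#'   `"between_profile"`.
#' @param labels required for `"between_profile"`: a vector of per-subject
#'   profile labels, or a tibble with columns `subject_id` and `profile`.
#' @return Character vector of `n` gene identifiers.
#' @export
select_variable_genes <- function(x, n, method = c("pooled", "between_profile"),
                                  labels = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (n <= 0) abort("n must be positive", class = "personet_error")
  if (n > ncol(x))
    abort(sprintf("requested %d genes but the matrix has %d", n, ncol(x)),
          class = "personet_error")
  if (method == "pooled") {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- v * nrow(x) / (nrow(x) - 1)
  } else {
    if (is.null(labels)) abort("labels required for between_profile variance",
                               class = "personet_error")
    lab <- extract_labels(labels, rownames(x))
    grand <- rowsum(x, lab) / as.vector(table(lab)[sort(unique(lab))])
    v <- apply(grand, 2, var)
  }
  ord <- order(-v, colnames(x))
  colnames(x)[ord][seq_len(n)]
}

extract_labels <- function(labels, subjects = NULL) {
  if (is.data.frame(labels)) {
    if (!is.null(subjects)) {
      labels$profile[match(subjects, labels$subject_id)]
    } else labels$profile
  } else as.character(labels)
}

#' One-way ANOVA across personality profiles with Tukey HSD follow-up
#'
#' Classical one-way ANOVA of a per-subject quantity across the profile
#' groups, with all pairwise Tukey honestly-significant-difference tests,
#' point-biserial (Pearson) effect sizes per pair, and the
#' Bonferroni-adjusted significance threshold for the pairwise family.
#'
#' @param values numeric vector, one value per subject.
#' @param labels per-subject group labels (vector, or tibble with columns
#'   `subject_id`, `profile`).
#' @param alpha family-wise significance level used for the reported
#'   Bonferroni threshold.
#' @return An object of class `group_comparison`: list with `F`, `p`,
#'   `pairwise` (tibble: pair, diff, tukey_p, r), `bonferroni_alpha`, and a
#'   `degenerate` flag (zero within-group variance).
#' @examples
#' profile_anova(c(1, 2, 5, 6, 9, 10),
#'               c("a", "a", "b", "b", "c", "c"))
#' @export
profile_anova <- function(values, labels, alpha = 0.05) {
  g <- factor(extract_labels(labels))
  stopifnot(length(values) == length(g))
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least two groups", class = "personet_error")
  if (any(sizes < 2))
    abort(sprintf("every group needs n >= 2 (got %s)",
                  paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")),
          class = "personet_error")
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  n_pairs <- length(pairs)

  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  if (ssw == 0) {
    pairwise <- purrr::map(pairs, function(pr) {
      keep <- g %in% pr
      tibble(pair = paste(pr, collapse = "-"),
             diff = mean(values[g == pr[2]]) - mean(values[g == pr[1]]),
             tukey_p = 0,
             r = pairwise_effect_size(values[keep], droplevels(g[keep])))
    }) |> bind_rows()
    return(structure(list(F = Inf, p = 0, pairwise = pairwise,
                          bonferroni_alpha = alpha / n_pairs,
                          degenerate = TRUE),
                     class = "group_comparison"))
  }

  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$g
  pairwise <- purrr::map(pairs, function(pr) {
    keep <- g %in% pr
    key <- paste(pr[2], pr[1], sep = "-")  # TukeyHSD row naming
    tibble(pair = paste(pr, collapse = "-"),
           diff = unname(tuk[key, "diff"]),
           tukey_p = unname(tuk[key, "p adj"]),
           r = pairwise_effect_size(values[keep], droplevels(g[keep])))
  }) |> bind_rows()

  structure(list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
                 pairwise = pairwise, bonferroni_alpha = alpha / n_pairs,
                 degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F = %.4g, p = %.3g%s\n", x$F, x$p,
              if (x$degenerate) " (degenerate: zero within-group variance)" else ""))
  print(x$pairwise)
  invisible(x)
}

#' Point-biserial effect size between two groups
#'
#' Pearson product-moment correlation between the 0/1 group indicator and
#' the values, the standard-scale effect size in which magnitudes of about
#' 0.2, 0.5 and 0.8 read as small, medium and large. The first group (first
#' factor level, or first label encountered) is coded 0.
#'
#' @param values numeric vector.
#' @param groups two-level group labels.
#' @return The correlation `r`; 0 with a warning when the values are
#'   constant (correlation undefined).
#' @export
pairwise_effect_size <- function(values, groups) {
  g <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  if (nlevels(g) != 2)
    abort("exactly two groups required", class = "personet_error")
  ind <- as.numeric(g == levels(g)[2])
  if (stats::sd(values) == 0 || stats::sd(ind) == 0) {
    warn("effect size undefined for constant input; returning 0")
    return(0)
  }
  cor(ind, values)
}

#' Bootstrap ANOVA of profile differences in mean gene expression
#'
#' For each bootstrap replicate, subjects are resampled with replacement
#' within each profile; each gene's expression is then averaged within each
#' profile, the per-gene grand mean is removed (genes differ hugely in
#' baseline expression, which would otherwise swamp the profile contrast),
#' and a one-way ANOVA is run with the centered gene-level means as
#' observations and profiles as groups. Replicate F statistics and pairwise
#' point-biserial effect sizes (computed on pair-centered means) are
#' aggregated.
#'
#' @param x subjects-by-genes matrix (typically restricted to the selected
#'   variable genes).
#' @param labels per-subject profile labels.
#' @param genes optional gene subset (column names).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @return List with `mean_F`, `ci` (2.5/97.5 percentiles of F), `F`
#'   (per-replicate), and `pairwise` (tibble of mean effect size r per
#'   profile pair).
#' @export
bootstrap_profile_anova <- function(x, labels, genes = NULL, n_boot = 100,
                                    seed = 1) {
  stopifnot(n_boot >= 1)
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  lab <- extract_labels(labels, rownames(x))
  groups <- sort(unique(lab))
  idx_by_group <- lapply(groups, function(gr) which(lab == gr))
  names(idx_by_group) <- groups
  if (any(lengths(idx_by_group) == 0))
    abort("a profile has no subjects after restriction", class = "personet_error")
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  res <- with_seed(as.integer(seed), {
    purrr::map(seq_len(n_boot), function(b) {
      means <- vapply(groups, function(gr) {
        take <- sample(idx_by_group[[gr]], length(idx_by_group[[gr]]),
                       replace = TRUE)
        colMeans(x[take, , drop = FALSE])
      }, numeric(ncol(x)))  # genes x groups
      centered <- means - rowMeans(means)
      vals <- as.vector(centered)
      grp <- factor(rep(groups, each = ncol(x)))
      fit <- aov(vals ~ grp)
      Fb <- summary(fit)[[1]]$`F value`[1]
      rs <- vapply(pairs, function(pr) {
        pairm <- means[, pr, drop = FALSE] - rowMeans(means[, pr, drop = FALSE])
        pairwise_effect_size(as.vector(pairm), rep(pr, each = ncol(x)))
      }, numeric(1))
      list(F = Fb, r = rs)
    })
  })
  Fs <- vapply(res, `[[`, numeric(1), "F")
  rmat <- do.call(rbind, lapply(res, `[[`, "r"))
  list(mean_F = mean(Fs),
       ci = unname(quantile(Fs, c(0.025, 0.975))),
       F = Fs,
       pairwise = tibble(pair = vapply(pairs, paste, "", collapse = "-"),
                         mean_r = colMeans(rmat)),
       n_boot = n_boot)
}
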