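# Fuzzy non-negative matrix factorization biclustering.
#
# The factorization itself is plain Frobenius NMF with multiplicative
# updates; the "fuzzy" reading comes afterwards, when the subject and gene
# loadings are row-normalized into memberships over the k factors and
# thresholded into (possibly overlapping) biclusters.

#' Fuzzy NMF of an expression matrix
#'
#' Factorizes a nonnegative subjects-by-genes matrix `X ~ W H` with
#' `W >= 0` (subjects x k) and `H >= 0` (k x genes) by multiplicative
#' updates minimizing the Frobenius reconstruction error. If the input has
#' negative entries it is shifted by its global minimum first (the shift is
#' recorded in the result). Initialization is uniform random given `seed`,
#' so a fixed seed reproduces the factors exactly.
#'
#' Expression input is mapped to the nonnegative orthant before
#' factorization. The default `shift = "gene_min"` subtracts each gene's
#' minimum, which removes the per-gene baseline: the baseline is close to a
#' rank-1 component that would otherwise compete with the planted block
#' structure for factors. `"global_min"` subtracts the single global
#' minimum instead, and `"none"` requires an already nonnegative matrix.
#' The applied shift is recorded in the fit.
#'
#' @param x numeric matrix (subjects x genes).
#' @param k factorization rank (number of biclusters).
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-change stopping tolerance.
#' @param shift nonnegativity transform: `"gene_min"` (default),
#'   `"global_min"`, or `"none"`.
#' @param n_runs number of seeded runs; with `n_runs > 1` the run with the
#'   lowest final reconstruction error is kept (a light-weight consensus
#'   alternative; the default single run is fully auditable).
#' @return An object of class `fnmf_fit`: list with `W`, `H`, `k`,
#'   `objective` (per-iteration Frobenius error, non-increasing), `shift`
#'   (the subtracted offset: per-gene vector or scalar), `iterations`,
#'   `converged`, `seed`.
#' @examples
#' x <- outer(rep(1:2, each = 4), rep(c(1, 3), each = 5))
#' fit <- fnmf(x, k = 1, seed = 1, shift = "none")
#' tail(fit$objective, 1) < 1e-4
#' @export
fnmf <- function(x, k, seed = 1, max_iter = 500, tol = 1e-6,
                 shift = c("gene_min", "global_min", "none"), n_runs = 1) {
  stopifnot(is.matrix(x), is.numeric(x))
  shift <- match.arg(shift)
  if (k < 1) abort("k must be >= 1", class = "personet_error")
  if (k > min(dim(x)))
    abort(sprintf("k = %d exceeds min(dim) = %d", k, min(dim(x))),
          class = "personet_error")
  offset <- switch(shift,
    gene_min = apply(x, 2, min),
    global_min = if (min(x) < 0) -min(x) else 0,
    none = 0)
  if (shift == "gene_min") {
    x <- sweep(x, 2, offset)
  } else if (shift == "global_min") {
    x <- x + offset
  } else if (min(x) < 0) {
    abort("matrix has negative entries; use shift = 'gene_min' or 'global_min'",
          class = "personet_error")
  }
  if (all(x == 0)) abort("all-zero matrix cannot be factorized",
                         class = "personet_error")

  runs <- lapply(seq_len(n_runs), function(r) {
    fnmf_single(x, k, seed = as.integer(seed) + (r - 1L),
                max_iter = max_iter, tol = tol)
  })
  best <- which.min(vapply(runs, function(f) tail(f$objective, 1), numeric(1)))
  fit <- runs[[best]]
  fit$shift <- offset
  fit$seed <- as.integer(seed)
  dimnames(fit$W) <- list(rownames(x), paste0("F", seq_len(k)))
  dimnames(fit$H) <- list(paste0("F", seq_len(k)), colnames(x))
  structure(fit, class = "fnmf_fit")
}

fnmf_single <- function(x, k, seed, max_iter, tol) {
  n <- nrow(x); m <- ncol(x)
  eps <- 1e-10
  with_seed(seed, {
    W <- matrix(runif(n * k), n, k)
    H <- matrix(runif(k * m), k, m)
  })
  obj <- numeric(max_iter)
  prev <- Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    W <- W * (x %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    H <- H * (t(W) %*% x) / ((t(W) %*% W) %*% H + eps)
    obj[it] <- sqrt(sum((x - W %*% H)^2))
    if (is.finite(prev) && prev > 0 &&
        (prev - obj[it]) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- obj[it]
  }
  list(W = W, H = H, k = k, objective = obj[seq_len(it)],
       iterations = it, converged = converged)
}

#' @export
print.fnmf_fit <- function(x, ...) {
  cat(sprintf("<fnmf_fit> k = %d, %d x %d, %d iterations (%s), final error %.4g\n",
              x$k, nrow(x$W), ncol(x$H), x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              tail(x$objective, 1)))
  invisible(x)
}

#' Threshold fuzzy memberships into biclusters
#'
#' Row-normalizes the factor loadings into fuzzy memberships (each subject's
#' and each gene's memberships sum to 1 over the k factors) and collects,
#' per factor, the subjects and genes whose membership reaches the
#' threshold. Subjects and genes may appear in several biclusters.
#'
#' @param fit an [fnmf()] result.
#' @param membership_threshold membership cutoff in (0, 1]; the default
#'   `1/k` keeps members exceeding a uniform spread over factors.
#' @return An object of class `bicluster_set`: list of biclusters
#'   (`id`, `subjects`, `genes`, `subject_memberships`,
#'   `gene_memberships`), with the threshold as an attribute.
#' @export
extract_biclusters <- function(fit, membership_threshold = NULL) {
  stopifnot(inherits(fit, "fnmf_fit"))
  thr <- membership_threshold %||% (1 / fit$k)
  if (thr <= 0 || thr > 1)
    abort("membership_threshold must lie in (0, 1]", class = "personet_error")
  Wn <- normalize_rows(fit$W)
  Hn <- t(normalize_rows(t(fit$H)))
  subjects <- rownames(fit$W) %||% make_ids("S", nrow(fit$W), 5)
  genes <- colnames(fit$H) %||% make_ids("G", ncol(fit$H), 6)
  bics <- lapply(seq_len(fit$k), function(j) {
    si <- which(Wn[, j] >= thr)
    gi <- which(Hn[j, ] >= thr)
    list(id = paste0("T", j),
         subjects = subjects[si],
         genes = genes[gi],
         subject_memberships = setNames(Wn[si, j], subjects[si]),
         gene_memberships = setNames(Hn[j, gi], genes[gi]))
  })
  structure(bics, class = "bicluster_set", threshold = thr)
}

normalize_rows <- function(m) {
  s <- rowSums(m)
  s[s == 0] <- 1
  m / s
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("<bicluster_set> %d biclusters (threshold %.3g)\n",
              length(x), attr(x, "threshold")))
  for (b in x)
    cat(sprintf("  %s: %d subjects, %d genes\n", b$id,
                length(b$subjects), length(b$genes)))
  invisible(x)
}

#' Gene overlap between biclusters
#'
#' @param biclusters a `bicluster_set` (or plain named list of gene sets).
#' @return List with `pairwise` (tibble: bicluster_a, bicluster_b,
#'   n_shared) and `shared_genes` (genes occurring in two or more
#'   biclusters).
#' @export
bicluster_overlap <- function(biclusters) {
  sets <- if (inherits(biclusters, "bicluster_set")) {
    setNames(lapply(biclusters, `[[`, "genes"),
             vapply(biclusters, `[[`, "", "id"))
  } else biclusters
  if (length(sets) < 2)
    abort("need at least two biclusters", class = "personet_error")
  ids <- names(sets)
  prs <- utils::combn(ids, 2, simplify = FALSE)
  pairwise <- purrr::map(prs, function(pr) {
    shared <- intersect(sets[[pr[1]]], sets[[pr[2]]])
    tibble(bicluster_a = pr[1], bicluster_b = pr[2], n_shared = length(shared))
  }) |> bind_rows()
  tab <- table(unlist(sets))
  list(pairwise = pairwise,
       shared_genes = sort(names(tab)[tab >= 2]))
}
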