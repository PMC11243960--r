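#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation between two sample vectors with the
#' two-sided p-value from `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite, each with
#'   nonzero variance.
#' @return data.frame with columns `r`, `p`, `n`.
#' @export
pearson_with_pvalue <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Top-k correlation network from transcription factors to genes
#'
#' Correlates each transcription-factor row with every candidate gene row
#' across the shared sample columns and keeps, per TF, the `k` genes with
#' the largest absolute Pearson r (ties broken by lexicographic gene id).
#' Edges carry the signed correlation, its t-based p-value and the rank
#' within the TF.  When fewer than `k` candidates exist, all are returned
#' with a warning.  Selection is invariant under any uniform affine
#' transform of the expression values.
#'
#' @param tf_mat numeric matrix, TFs x samples (rownames = TF ids).
#' @param gene_mat numeric matrix, candidate genes x samples, same sample
#'   columns as `tf_mat`.
#' @param k edges kept per TF (default 50).
#' @return data.frame with columns `source`, `target`, `r`, `p`, `n`,
#'   `rank`.
#' @export
tf_correlation_network <- function(tf_mat, gene_mat, k = 50) {
  stopifnot(is.matrix(tf_mat), is.matrix(gene_mat),
            ncol(tf_mat) == ncol(gene_mat), k >= 1)
  if (is.null(rownames(tf_mat)) || is.null(rownames(gene_mat))) {
    stop("both matrices need feature rownames", call. = FALSE)
  }
  n <- ncol(tf_mat)
  if (n < 3L) stop("need at least 3 shared samples", call. = FALSE)
  cc <- stats::cor(t(tf_mat), t(gene_mat))   # TFs x genes
  tstat <- cc * sqrt(n - 2) / sqrt(pmax(1 - cc^2, 0))
  pmat <- 2 * stats::pt(-abs(tstat), n - 2)
  pmat[cc^2 >= 1] <- 0
  edges <- vector("list", nrow(tf_mat))
  for (i in seq_len(nrow(tf_mat))) {
    tf <- rownames(tf_mat)[i]
    cand <- setdiff(colnames(cc), tf)
    if (length(cand) < k) {
      warning(sprintf("TF %s: only %d candidate genes for top-%d selection",
                      tf, length(cand), k), call. = FALSE)
    }
    r <- cc[i, cand]
    ord <- order(-abs(r), cand)
    sel <- ord[seq_len(min(k, length(cand)))]
    edges[[i]] <- data.frame(source = tf, target = cand[sel],
                             r = unname(r[sel]),
                             p = unname(pmat[i, cand][sel]),
                             n = n, rank = seq_along(sel),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, edges)
}

#' Mantel test between two feature-by-sample matrices
#'
#' Computes Euclidean (by default) distance matrices over the shared
#' samples of the two inputs and correlates their vectorised upper
#' triangles (the Mantel statistic r_M).  Significance is assessed by
#' permuting the sample labels of the second matrix: with `B` random
#' permutations the one-sided p-value is
#' `(1 + #\{r_perm >= r_obs\}) / (1 + B)`; with `exact = TRUE` all `n!`
#' permutations (including the identity) are enumerated and
#' `p = #\{r_perm >= r_obs\} / n!`.  A two-sided option compares absolute
#' statistics instead.
#'
#' @param x,y numeric matrices, features x samples, with the same samples
#'   in the same order (`n >= 4`); or `dist` objects over the same
#'   samples.
#' @param permutations number of random permutations (>= 99).
#' @param seed integer seed for the permutation draw, or `NULL`.
#' @param method distance metric passed to [stats::dist()].
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @param exact enumerate all permutations instead of sampling (requires
#'   `n <= 7`).
#' @return an object of class `mantel_result`: list with `statistic`,
#'   `p.value`, `permutations`, `exact`, `alternative`, `seed`, `n`.
#' @export
mantel_test <- function(x, y, permutations = 999, seed = NULL,
                        method = "euclidean",
                        alternative = c("greater", "two.sided"),
                        exact = FALSE) {
  alternative <- match.arg(alternative)
  as_dist <- function(m) {
    if (inherits(m, "dist")) return(m)
    stopifnot(is.matrix(m), is.numeric(m))
    stats::dist(t(m), method = method)
  }
  dx <- as_dist(x)
  dy <- as_dist(y)
  n <- attr(dx, "Size")
  if (attr(dy, "Size") != n) {
    stop("x and y must share the same sample set", call. = FALSE)
  }
  if (n < 4L) {
    stop("Mantel test needs at least 4 samples (too few distinct permutations)",
         call. = FALSE)
  }
  ux <- as.vector(dx)
  Dy <- as.matrix(dy)
  # lower.tri in column-major order matches the pair ordering of a dist
  # vector, keeping ux and the permuted y distances aligned pairwise
  il <- lower.tri(Dy)
  r_obs <- stats::cor(ux, Dy[il])
  stat_of <- function(perm) stats::cor(ux, Dy[perm, perm][il])
  bigger <- function(rp) {
    if (alternative == "greater") rp >= r_obs else abs(rp) >= abs(r_obs)
  }
  if (exact) {
    if (n > 7L) stop("exact enumeration limited to n <= 7 samples",
                     call. = FALSE)
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, stat_of)
    p <- mean(bigger(r_perm))
    nperm <- nrow(perms)
  } else {
    if (permutations < 99L) {
      stop("at least 99 permutations are required", call. = FALSE)
    }
    r_perm <- with_seed(seed, replicate(permutations, stat_of(sample.int(n))))
    p <- (1 + sum(bigger(r_perm))) / (1 + permutations)
    nperm <- permutations
  }
  structure(list(statistic = r_obs, p.value = p, permutations = nperm,
                 exact = exact, alternative = alternative,
                 seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "<mantel_result> r_M = %.4f, p = %.4g (%s%d permutations, %s, n = %d)\n",
    x$statistic, x$p.value, if (x$exact) "exact, " else "",
    x$permutations, x$alternative, x$n))
  invisible(x)
}

#' Mantel summary over enzyme gene groups and single metabolites
#'
#' Runs one Mantel test per (enzyme group, metabolite) pair: genes sharing
#' an enzyme annotation (EC number) form the first matrix, the single
#' metabolite row the second.  This mirrors the integration display that
#' links enzyme-number gene groups to named Calvin-cycle metabolites.
#' Each pair receives a deterministic seed derived from `seed` so the
#' whole table is reproducible.
#'
#' @param gene_mat numeric matrix, genes x samples.
#' @param gene_groups named character vector mapping gene id to its
#'   enzyme (EC) group; genes absent from it are ignored.
#' @param metab_mat numeric matrix, metabolites x samples (same samples).
#' @param permutations permutations per test.
#' @param seed base seed.
#' @param ... further arguments passed to [mantel_test()].
#' @return data.frame with columns `enzyme`, `metabolite`, `r_m`, `p`,
#'   `n_genes`, `permutations`.
#' @export
mantel_pairs <- function(gene_mat, gene_groups, metab_mat,
                         permutations = 999, seed = 1, ...) {
  stopifnot(is.matrix(gene_mat), is.matrix(metab_mat),
            ncol(gene_mat) == ncol(metab_mat))
  gene_groups <- gene_groups[names(gene_groups) %in% rownames(gene_mat)]
  if (!length(gene_groups)) {
    stop("no annotated genes present in gene_mat", call. = FALSE)
  }
  enzymes <- sort(unique(gene_groups))
  mets <- rownames(metab_mat)
  rows <- list()
  idx <- 0L
  for (enz in enzymes) {
    genes <- names(gene_groups)[gene_groups == enz]
    for (met in mets) {
      idx <- idx + 1L
      res <- mantel_test(gene_mat[genes, , drop = FALSE],
                         metab_mat[met, , drop = FALSE],
                         permutations = permutations,
                         seed = if (is.null(seed)) NULL else seed + idx, ...)
      rows[[idx]] <- data.frame(enzyme = enz, metabolite = met,
                                r_m = res$statistic, p = res$p.value,
                                n_genes = length(genes),
                                permutations = res$permutations,
                                row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
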