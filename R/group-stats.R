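#' Group means with standard errors and LSD letters
#'
#' One-way ANOVA followed by pairwise least-significant-difference (LSD)
#' comparisons at level `alpha`, summarised as compact letters: groups
#' sharing a letter are not significantly different.  This is the usual
#' presentation for small-n phenotyping experiments (means +/- SE with
#' lettered bars, n = 3 replicates per treatment).
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @param alpha significance level of the pairwise LSD tests.
#' @return a data.frame with columns `group`, `n`, `mean`, `se`, `letter`.
#' @export
group_summary <- function(values, groups, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) == length(groups),
            alpha > 0, alpha < 1)
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  lev <- sort(unique(groups))
  n <- vapply(lev, function(g) sum(groups == g), integer(1))
  if (any(n < 2L)) stop("each group needs at least 2 replicates", call. = FALSE)
  m <- vapply(lev, function(g) mean(values[groups == g]), numeric(1))
  fit <- stats::aov(values ~ factor(groups))
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  se <- sqrt(mse / n)
  k <- length(lev)
  if (k == 1L) {
    letter <- "a"
  } else {
    nsd <- matrix(TRUE, k, k, dimnames = list(lev, lev))
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        tstat <- (m[i] - m[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
        p <- 2 * stats::pt(-abs(tstat), stats::df.residual(fit))
        nsd[i, j] <- nsd[j, i] <- p >= alpha
      }
    }
    g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                             diag = FALSE)
    cliques <- igraph::max_cliques(g)
    # order letter groups by descending best mean so 'a' marks the top
    cliques <- cliques[order(-vapply(cliques,
                                     function(cl) max(m[as.integer(cl)]),
                                     numeric(1)))]
    letter <- character(k)
    for (ci in seq_along(cliques)) {
      idx <- as.integer(cliques[[ci]])
      letter[idx] <- paste0(letter[idx], letters[ci])
    }
    letter <- vapply(strsplit(letter, ""),
                     function(ch) paste(sort(ch), collapse = ""),
                     character(1))
  }
  data.frame(group = lev, n = as.integer(n), mean = unname(m),
             se = unname(se), letter = letter,
             row.names = NULL, stringsAsFactors = FALSE)
}
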