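# Shared fixture builders and independent oracles.

# Two-group omics table from a features x 6 matrix (A_1..A_3, B_1..B_3).
two_group_table <- function(mat, layer = "protein") {
  colnames(mat) <- paste(rep(c("A", "B"), each = 3), 1:3, sep = "_")
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("%s_%03d", layer, seq_len(nrow(mat)))
  }
  omics_table(mat, data.frame(sample = colnames(mat),
                              group = rep(c("A", "B"), each = 3)),
              layer)
}

# Independent permutation enumerator: filter the full n^n tuple grid.
perms_oracle <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
}

# Hand-rolled Euclidean distance matrix over columns.
dist_oracle <- function(m) {
  n <- ncol(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((m[, i] - m[, j])^2))
    }
  }
  D
}

# Exact one-sided Mantel p by full enumeration, from scratch.
mantel_exact_oracle <- function(x, y) {
  Dx <- dist_oracle(x)
  Dy <- dist_oracle(y)
  vec <- function(D) D[lower.tri(D)]
  r_obs <- cor(vec(Dx), vec(Dy))
  perms <- perms_oracle(ncol(x))
  r_perm <- apply(perms, 1L, function(p) cor(vec(Dx), vec(Dy[p, p])))
  list(statistic = r_obs, p = mean(r_perm >= r_obs))
}
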