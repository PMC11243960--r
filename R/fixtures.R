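# Packaged worked-example tables (published differential-expression and
# correlation summaries for the UV-B / ABA four-group experiment).

fixture_path <- function(name) {
  system.file("extdata", name, package = "fluoromics", mustWork = TRUE)
}

#' Calvin-cycle differentially expressed genes (A vs B), worked example
#'
#' Seven Calvin-cycle genes from the UV-B comparison (A control vs B
#' UV-B): transcript-level Q-value, log2 fold change (B/A), raw p-value
#' and KEGG enzyme annotation.  With `tidy = TRUE` the table is reshaped
#' into the record format expected by [screen_differential()] (columns
#' `feature`, `comparison`, `fc`, `log2fc`, `p`, `q`, `ec`).
#'
#' @param tidy return screening-ready records instead of the raw table.
#' @return a data.frame.
#' @export
calvin_cycle_degs <- function(tidy = FALSE) {
  tab <- utils::read.table(fixture_path("calvin_cycle_degs.tsv"),
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!tidy) return(tab)
  data.frame(feature = tab$gene_id, comparison = "AvsB",
             fc = 2^tab$log2fc_AvsB, log2fc = tab$log2fc_AvsB,
             p = tab$p_AvsB, q = tab$q_AvsB, ec = tab$ec,
             stringsAsFactors = FALSE)
}

#' G2-like transcription-factor family members, worked example
#'
#' The G2-like (GLK) family members reported as significantly altered in
#' at least one comparison of the four-group UV-B / ABA experiment, with
#' log2 fold change and Q-value per comparison (`AvsB`, `DvsC`, `AvsC`;
#' missing entries are `NA`).  One gene id appears in two rows of the
#' published table; the rows are preserved verbatim, and the tidy form
#' de-duplicates by (gene, comparison).
#'
#' @param tidy return one record per (gene, comparison) with columns
#'   `feature`, `comparison`, `fc`, `log2fc`, `q`.
#' @return a data.frame.
#' @export
g2like_members <- function(tidy = FALSE) {
  tab <- utils::read.table(fixture_path("g2like_members.tsv"),
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!tidy) return(tab)
  comps <- c("AvsB", "DvsC", "AvsC")
  long <- do.call(rbind, lapply(comps, function(cmp) {
    lfc <- tab[[paste0("log2fc_", cmp)]]
    q <- tab[[paste0("q_", cmp)]]
    keep <- !is.na(lfc) & !is.na(q)
    data.frame(feature = tab$gene_id[keep], comparison = cmp,
               fc = 2^lfc[keep], log2fc = lfc[keep], q = q[keep],
               stringsAsFactors = FALSE)
  }))
  long[!duplicated(long[, c("feature", "comparison")]), , drop = FALSE]
}

#' G2-like TF vs Calvin-cycle gene correlations, worked example
#'
#' Published Pearson correlations (with p-values) between the two
#' significant G2-like family members and five Calvin-cycle
#' differentially expressed genes.  These printed values serve as a
#' fixture for the "strongly correlated" (`|r| > 0.9`) filter, not as a
#' recomputation target.
#'
#' @return a data.frame with columns `tf_id`, `gene_id`, `pcc`, `p_value`.
#' @export
tf_calvin_correlations <- function() {
  utils::read.table(fixture_path("tf_calvin_pcc.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}
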