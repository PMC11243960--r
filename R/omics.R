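#' Feature-by-sample omics table with a group design
#'
#' Container for one omics layer: a positive abundance matrix (FPKM for
#' transcripts, reporter intensity for proteins, peak intensity for
#' metabolites) with features in rows and samples in columns, a design
#' table mapping each sample to its treatment group, and optional feature
#' annotations (EC number, transcription-factor family).
#'
#' @param abundance numeric matrix, features x samples, no negative
#'   values; rownames are feature ids, colnames are sample ids.
#' @param design data.frame with columns `sample`, `group`; every sample
#'   column must appear.
#' @param layer one of `"transcript"`, `"protein"`, `"metabolite"`.
#' @param annotations optional data.frame with a `feature` column plus
#'   annotation columns (e.g. `ec`, `tf_family`).
#' @param meta free-form metadata list.
#' @return an object of class `omics_table`.
#' @export
omics_table <- function(abundance, design, layer,
                        annotations = NULL, meta = list()) {
  layer <- match.arg(layer, c("transcript", "protein", "metabolite"))
  stopifnot(is.matrix(abundance), is.numeric(abundance),
            is.data.frame(design))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance matrix needs feature rownames and sample colnames",
         call. = FALSE)
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and nonnegative", call. = FALSE)
  }
  if (!all(c("sample", "group") %in% names(design))) {
    stop("design must have columns sample and group", call. = FALSE)
  }
  missing <- setdiff(colnames(abundance), design$sample)
  if (length(missing)) {
    stop(sprintf("samples without a group in the design: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  design <- design[match(colnames(abundance), design$sample), , drop = FALSE]
  if (!is.null(annotations) && !"feature" %in% names(annotations)) {
    stop("annotations must have a 'feature' column", call. = FALSE)
  }
  structure(list(abundance = abundance, design = design, layer = layer,
                 annotations = annotations, meta = meta),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<omics_table> %s layer: %d features x %d samples (groups %s)\n",
              x$layer, nrow(x$abundance), ncol(x$abundance),
              paste(sort(unique(x$design$group)), collapse = "/")))
  invisible(x)
}

group_columns <- function(tab, group) {
  idx <- which(tab$design$group == group)
  if (length(idx) < 2L) {
    stop(sprintf("group '%s' needs at least 2 replicates (found %d)",
                 group, length(idx)), call. = FALSE)
  }
  idx
}

#' Per-feature fold change between two groups
#'
#' `FC = mean(treatment) / mean(control)` on the linear abundance scale,
#' with group roles taken from a paper-style comparison label (`"AvsB"`
#' means control A, treatment B).  Zero control means are handled by a
#' configurable small offset added to both group means; the offset used is
#' recorded as an attribute.
#'
#' @param tab an [omics_table()].
#' @param comparison comparison label, e.g. `"AvsB"`.
#' @param offset nonnegative pseudo-abundance added to both means.
#' @return data.frame with columns `feature`, `mean_control`,
#'   `mean_treatment`, `fc`, `log2fc`.
#' @export
fold_change <- function(tab, comparison, offset = 0) {
  stopifnot(inherits(tab, "omics_table"), offset >= 0)
  cmp <- parse_comparison(comparison)
  ic <- group_columns(tab, cmp$control)
  it <- group_columns(tab, cmp$treatment)
  mc <- rowMeans(tab$abundance[, ic, drop = FALSE])
  mt <- rowMeans(tab$abundance[, it, drop = FALSE])
  if (offset == 0 && any(mc == 0)) {
    stop("control group mean is zero for some features; set a positive offset",
         call. = FALSE)
  }
  fc <- (mt + offset) / (mc + offset)
  out <- data.frame(feature = rownames(tab$abundance),
                    mean_control = unname(mc), mean_treatment = unname(mt),
                    fc = unname(fc), log2fc = unname(log2(fc)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "offset") <- offset
  attr(out, "comparison") <- comparison
  out
}

#' Per-feature Welch t-test between two groups
#'
#' Two-sided Welch (unequal-variance) t-test on log2 abundances, the
#' robust default for n = 3 replicate designs.  Features where both groups
#' are constant get `p = 1` when the constants agree and `p = 0` when they
#' differ; such features are flagged in the `zero_variance` column.
#'
#' @param tab an [omics_table()].
#' @param comparison comparison label, e.g. `"AvsB"`.
#' @param log_transform test on `log2(abundance + offset)` (default) or on
#'   the linear scale.
#' @param offset pseudo-abundance added before the log transform.
#' @return data.frame with columns `feature`, `t`, `df`, `p`,
#'   `zero_variance`.
#' @export
welch_test <- function(tab, comparison, log_transform = TRUE, offset = 0) {
  stopifnot(inherits(tab, "omics_table"))
  cmp <- parse_comparison(comparison)
  ic <- group_columns(tab, cmp$control)
  it <- group_columns(tab, cmp$treatment)
  x <- tab$abundance
  if (log_transform) {
    if (any(x[, c(ic, it)] + offset <= 0)) {
      stop("zero abundances under log transform; set a positive offset",
           call. = FALSE)
    }
    x <- log2(x + offset)
  }
  n <- nrow(x)
  tt <- df <- p <- rep(NA_real_, n)
  zv <- logical(n)
  for (i in seq_len(n)) {
    a <- x[i, it]; b <- x[i, ic]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      zv[i] <- TRUE
      p[i] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      next
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    tt[i] <- unname(ht$statistic)
    df[i] <- unname(ht$parameter)
    p[i] <- ht$p.value
  }
  data.frame(feature = rownames(x), t = tt, df = df, p = p,
             zero_variance = zv, row.names = NULL, stringsAsFactors = FALSE)
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a two-class partial-least-squares model (NIPALS, class-coded
#' response, features autoscaled to unit variance) on log2 abundances and
#' returns the VIP score of every retained feature,
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{aj}/\|w_a\|)^2 / \sum_a SS_a},}
#' where `SS_a` is the response variance explained by component `a`.  By
#' construction the mean squared VIP over retained features is 1, so
#' `VIP > 1` marks features with above-average discriminating weight.
#' Constant features cannot be autoscaled and are dropped with a warning.
#'
#' @param tab an [omics_table()].
#' @param comparison comparison label, e.g. `"AvsB"`.
#' @param ncomp number of PLS components (default 1).
#' @param log_transform model log2 abundances (default) or linear values.
#' @param offset pseudo-abundance added before the log transform.
#' @return data.frame with columns `feature`, `vip`.
#' @export
pls_vip <- function(tab, comparison, ncomp = 1, log_transform = TRUE,
                    offset = 0) {
  stopifnot(inherits(tab, "omics_table"), ncomp >= 1)
  cmp <- parse_comparison(comparison)
  ic <- group_columns(tab, cmp$control)
  it <- group_columns(tab, cmp$treatment)
  x <- tab$abundance[, c(ic, it), drop = FALSE]
  if (log_transform) {
    if (any(x + offset <= 0)) {
      stop("zero abundances under log transform; set a positive offset",
           call. = FALSE)
    }
    x <- log2(x + offset)
  }
  X <- t(x)                                   # samples x features
  y <- c(rep(-1, length(ic)), rep(1, length(it)))
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant feature(s) before PLS scaling",
                    sum(!keep)), call. = FALSE)
  }
  X <- scale(X[, keep, drop = FALSE])
  y <- y - mean(y)
  p <- ncol(X)
  if (p < 2L) stop("at least 2 non-constant features are required",
                   call. = FALSE)
  ncomp <- min(ncomp, nrow(X) - 1L, p)
  W <- matrix(0, p, ncomp)
  ss <- numeric(ncomp)
  Xa <- X; ya <- y
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) {
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    tsc <- drop(Xa %*% w)
    tt <- sum(tsc^2)
    pl <- drop(crossprod(Xa, tsc)) / tt
    q <- sum(ya * tsc) / tt
    W[, a] <- w
    ss[a] <- q^2 * tt                         # response SS explained
    Xa <- Xa - tcrossprod(tsc, pl)
    ya <- ya - tsc * q
  }
  if (ncomp < 1L) stop("PLS found no discriminating direction", call. = FALSE)
  W <- W[, seq_len(ncomp), drop = FALSE]
  ss <- ss[seq_len(ncomp)]
  vip <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  data.frame(feature = rownames(x)[keep], vip = unname(vip),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default screening thresholds per omics layer
#'
#' The standard rule set for this kind of UV-B stress screen:
#' metabolites are called with `VIP > 1` and `FC >= 1.5` (up) or
#' `FC <= 0.67` (down); proteins with `p < 0.05` and `FC >= 1.2` (up) or
#' `FC <= 0.83` (down); transcripts with `Q < 0.05` and any `FC > 1` (up)
#' or `FC < 1` (down).  The transcript fold bounds are exposed so a
#' stricter fold threshold can be configured.
#'
#' @return a named list of per-layer threshold lists.
#' @export
screening_thresholds <- function() {
  list(metabolite = list(vip = 1, fc_up = 1.5, fc_down = 0.67),
       protein = list(p = 0.05, fc_up = 1.2, fc_down = 0.83),
       transcript = list(q = 0.05, fc_up = 1, fc_down = 1))
}

#' Call differential features under a layer's screening rule
#'
#' Applies the layer rule to a record table and appends a `call` column
#' (`"up"`, `"down"` or `"ns"`).  Required record columns: `feature` and
#' `fc` always; `vip` for metabolites; `p` for proteins; `q` for
#' transcripts.
#'
#' @param records data.frame of per-feature statistics.
#' @param layer `"transcript"`, `"protein"` or `"metabolite"`.
#' @param thresholds per-layer threshold list; defaults to
#'   [screening_thresholds()] for the layer.
#' @return `records` with a `call` column; thresholds echoed as an
#'   attribute.
#' @export
screen_differential <- function(records, layer, thresholds = NULL) {
  layer <- match.arg(layer, c("transcript", "protein", "metabolite"))
  th <- thresholds %||% screening_thresholds()[[layer]]
  stopifnot(is.data.frame(records), "fc" %in% names(records))
  need <- switch(layer, metabolite = "vip", protein = "p", transcript = "q")
  if (!need %in% names(records)) {
    stop(sprintf("%s screening requires a '%s' column", layer, need),
         call. = FALSE)
  }
  fc <- records$fc
  call <- rep("ns", nrow(records))
  if (layer == "metabolite") {
    sig <- !is.na(records$vip) & records$vip > th$vip
    call[sig & fc >= th$fc_up] <- "up"
    call[sig & fc <= th$fc_down] <- "down"
  } else if (layer == "protein") {
    sig <- !is.na(records$p) & records$p < th$p
    call[sig & fc >= th$fc_up] <- "up"
    call[sig & fc <= th$fc_down] <- "down"
  } else {
    sig <- !is.na(records$q) & records$q < th$q
    call[sig & fc > th$fc_up] <- "up"
    call[sig & fc < th$fc_down] <- "down"
  }
  records$call <- call
  attr(records, "thresholds") <- th
  attr(records, "layer") <- layer
  records
}

#' Run the full screening stage for one layer and comparison
#'
#' Convenience wrapper chaining [fold_change()], the layer's test
#' ([welch_test()] for proteins and transcripts, with Benjamini-Hochberg
#' Q-values for transcripts; [pls_vip()] for metabolites, which also get a
#' Welch p for reference) and [screen_differential()].
#'
#' @param tab an [omics_table()].
#' @param comparison comparison label, e.g. `"AvsB"`.
#' @param thresholds optional per-layer threshold list.
#' @param offset pseudo-abundance for zero handling.
#' @param ncomp PLS components for the metabolite VIP.
#' @return tidy call table (one row per feature).
#' @export
screen_layer <- function(tab, comparison, thresholds = NULL, offset = 0,
                         ncomp = 1) {
  stopifnot(inherits(tab, "omics_table"))
  rec <- fold_change(tab, comparison, offset = offset)
  wt <- welch_test(tab, comparison, offset = offset)
  rec$p <- wt$p[match(rec$feature, wt$feature)]
  rec$q <- NA_real_
  rec$vip <- NA_real_
  if (tab$layer == "transcript") {
    rec$q <- stats::p.adjust(rec$p, method = "BH")
  } else if (tab$layer == "metabolite") {
    v <- pls_vip(tab, comparison, ncomp = ncomp, offset = offset)
    rec$vip <- v$vip[match(rec$feature, v$feature)]
  }
  out <- screen_differential(rec, tab$layer, thresholds)
  out$layer <- tab$layer
  out$comparison <- comparison
  out
}

#' Per-feature z-score standardisation for heat maps
#'
#' Standardises each feature (row) to mean 0 and standard deviation 1
#' across samples, the usual preprocessing for expression heat maps.
#' Constant features cannot be scaled; their rows are set to 0 and their
#' ids recorded in the `constant_features` attribute.
#'
#' @param tab an [omics_table()] or a numeric matrix (features x samples).
#' @param features optional subset of feature ids to keep.
#' @return standardised matrix with a `constant_features` attribute.
#' @export
zscore_matrix <- function(tab, features = NULL) {
  x <- if (inherits(tab, "omics_table")) tab$abundance else tab
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(x))
    if (length(missing)) {
      stop(sprintf("unknown features: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    x <- x[features, , drop = FALSE]
  }
  if (ncol(x) < 2L) {
    stop("z-scores need at least 2 samples", call. = FALSE)
  }
  mu <- rowMeans(x)
  sdev <- apply(x, 1L, stats::sd)
  constant <- sdev == 0
  sdev[constant] <- 1
  z <- (x - mu) / sdev
  z[constant, ] <- 0
  attr(z, "constant_features") <- rownames(x)[constant]
  z
}
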