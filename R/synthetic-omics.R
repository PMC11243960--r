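#' Design of a planted multi-omics dataset
#'
#' Describes the ground truth for [gen_omics_dataset()]: feature counts
#' per layer, the four-group design (A control, B UV-B, C UV-B + ABA,
#' D ABA) with a fixed number of biological replicates, planted log2 fold
#' changes (applied to group B, i.e. B vs A effects), latent-factor
#' loadings tying transcription-factor features to their targets (so
#' TF-target pairs have an across-sample Pearson correlation of known
#' sign), and a shared latent factor coupling a gene block to a metabolite
#' block (so the coupling is detectable by a Mantel test).  Noise is
#' log-normal: Gaussian with standard deviation `sigma` on the log2 scale.
#'
#' Default feature ids are `<layer>_001` ... ; every planted, TF, target
#' or coupled feature must exist in its layer.
#'
#' @param n_features named integer vector with entries `transcript`,
#'   `protein`, `metabolite`.
#' @param groups treatment group labels.
#' @param reps_per_group biological replicates per group (>= 2).
#' @param planted_log2fc named list per layer of named numeric vectors
#'   mapping feature id to its planted log2 fold change (B vs A).
#' @param tf_target_map named list: TF feature id -> list with `targets`
#'   (feature ids) and `loadings` (same length, signs give the expected
#'   correlation sign).
#' @param coupled_genes,coupled_metabolites feature ids sharing the
#'   gene-metabolite latent factor.
#' @param gene_metabolite_coupling loading of that shared factor.
#' @param sigma log2-scale noise standard deviation.
#' @param seed integer seed.
#' @return an object of class `planted_omics_design`.
#' @export
planted_omics_design <- function(
    n_features = c(transcript = 120, protein = 80, metabolite = 40),
    groups = c("A", "B", "C", "D"),
    reps_per_group = 3,
    planted_log2fc = list(
      transcript = stats::setNames(c(2, -2, 1.5, -1.5),
                                   sprintf("transcript_%03d", 1:4)),
      protein = stats::setNames(c(2, -2, 1.5, -1.5),
                                sprintf("protein_%03d", 1:4)),
      metabolite = stats::setNames(c(2, -2, 1, -1),
                                   sprintf("metabolite_%03d", 1:4))),
    tf_target_map = list(
      transcript_101 = list(targets = sprintf("transcript_%03d", 102:107),
                            loadings = c(1, 1, 1, -1, -1, 1))),
    coupled_genes = sprintf("transcript_%03d", 111:115),
    coupled_metabolites = sprintf("metabolite_%03d", 31:35),
    gene_metabolite_coupling = 1,
    sigma = 0.25, seed = 1) {
  layers <- c("transcript", "protein", "metabolite")
  stopifnot(all(layers %in% names(n_features)),
            all(n_features[layers] >= 1),
            length(groups) >= 2, !anyDuplicated(groups),
            reps_per_group >= 2, sigma >= 0,
            gene_metabolite_coupling >= 0)
  if (!all(c("A", "B") %in% groups)) {
    stop("groups must include 'A' (control) and 'B' (treatment)",
         call. = FALSE)
  }
  feature_ids <- lapply(stats::setNames(layers, layers), function(l) {
    sprintf("%s_%03d", l, seq_len(n_features[[l]]))
  })
  for (l in names(planted_log2fc)) {
    bad <- setdiff(names(planted_log2fc[[l]]), feature_ids[[l]])
    if (length(bad)) {
      stop(sprintf("planted features not in the %s layer: %s", l,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  for (tf in names(tf_target_map)) {
    spec <- tf_target_map[[tf]]
    bad <- setdiff(c(tf, spec$targets), feature_ids$transcript)
    if (length(bad)) {
      stop(sprintf("TF map refers to unknown transcript feature(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (length(spec$targets) != length(spec$loadings)) {
      stop("tf_target_map targets and loadings must have equal length",
           call. = FALSE)
    }
  }
  if (length(setdiff(coupled_genes, feature_ids$transcript)) ||
      length(setdiff(coupled_metabolites, feature_ids$metabolite))) {
    stop("coupled gene/metabolite ids must exist in their layers",
         call. = FALSE)
  }
  structure(list(n_features = n_features, groups = groups,
                 reps_per_group = reps_per_group,
                 feature_ids = feature_ids,
                 planted_log2fc = planted_log2fc,
                 tf_target_map = tf_target_map,
                 coupled_genes = coupled_genes,
                 coupled_metabolites = coupled_metabolites,
                 gene_metabolite_coupling = gene_metabolite_coupling,
                 sigma = sigma, seed = seed),
            class = "planted_omics_design")
}

#' Generate transcript, protein and metabolite tables with known truth
#'
#' Simulates the three omics layers of a four-group, replicated UV-B
#' experiment on the log2 scale: per-feature baselines drawn uniformly in
#' `[3, 10]` log2 units, planted B-vs-A effects added to group B samples,
#' latent factors (one per transcription factor, one shared gene-
#' metabolite factor) added with their loadings, and Gaussian noise of
#' standard deviation `sigma`; values are returned on the linear positive
#' scale (`2^log2`).  Transcript annotations mark TF features as
#' `G2-like` family members and assign EC numbers to the coupled gene
#' block so the integration stage can group genes by enzyme.
#'
#' Under a fixed seed the output is bit-identical across calls.
#'
#' @param design a [planted_omics_design()].
#' @return named list of three [omics_table()]s (`transcript`, `protein`,
#'   `metabolite`), each carrying the design in `meta$design`.
#' @export
gen_omics_dataset <- function(design) {
  stopifnot(inherits(design, "planted_omics_design"))
  groups <- design$groups
  reps <- design$reps_per_group
  samples <- as.vector(t(outer(groups, seq_len(reps), paste, sep = "_")))
  grp <- rep(groups, each = reps)
  ns <- length(samples)
  des_df <- data.frame(sample = samples, group = grp,
                       stringsAsFactors = FALSE)
  with_seed(design$seed, {
    z_tf <- lapply(design$tf_target_map, function(...) stats::rnorm(ns))
    z_couple <- stats::rnorm(ns)
    out <- list()
    for (layer in c("transcript", "protein", "metabolite")) {
      ids <- design$feature_ids[[layer]]
      nf <- length(ids)
      base <- stats::runif(nf, 3, 10)
      logm <- matrix(base, nf, ns) +
        matrix(stats::rnorm(nf * ns, 0, design$sigma), nf, ns)
      dimnames(logm) <- list(ids, samples)
      planted <- design$planted_log2fc[[layer]]
      if (length(planted)) {
        logm[names(planted), grp == "B"] <-
          logm[names(planted), grp == "B"] + planted
      }
      if (layer == "transcript") {
        for (tf in names(design$tf_target_map)) {
          spec <- design$tf_target_map[[tf]]
          z <- z_tf[[tf]]
          logm[tf, ] <- logm[tf, ] + z
          logm[spec$targets, ] <- logm[spec$targets, ] +
            outer(spec$loadings, z)
        }
        if (length(design$coupled_genes)) {
          logm[design$coupled_genes, ] <-
            logm[design$coupled_genes, ] +
            design$gene_metabolite_coupling *
            matrix(z_couple, length(design$coupled_genes), ns, byrow = TRUE)
        }
      }
      if (layer == "metabolite" && length(design$coupled_metabolites)) {
        logm[design$coupled_metabolites, ] <-
          logm[design$coupled_metabolites, ] +
          design$gene_metabolite_coupling *
          matrix(z_couple, length(design$coupled_metabolites), ns,
                 byrow = TRUE)
      }
      ann <- NULL
      if (layer == "transcript") {
        ann <- data.frame(feature = ids,
                          tf_family = ifelse(
                            ids %in% names(design$tf_target_map),
                            "G2-like", NA_character_),
                          ec = NA_character_,
                          stringsAsFactors = FALSE)
        ecs <- c("EC:4.1.1.39", "EC:4.1.2.13", "EC:3.1.3.11", "EC:5.3.1.6")
        ann$ec[match(design$coupled_genes, ids)] <-
          rep_len(ecs, length(design$coupled_genes))
      }
      out[[layer]] <- omics_table(2^logm, des_df, layer,
                                  annotations = ann,
                                  meta = list(design = design,
                                              seed = design$seed))
    }
    out
  })
}
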