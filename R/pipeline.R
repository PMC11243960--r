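#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline: stage toggles, the
#' per-layer screening thresholds, permutation count and seed for the
#' Mantel stage, the top-k size of the TF correlation network (default
#' 50), the `|r| > strong_r` "strongly correlated" filter (default 0.9),
#' the control group for difference curves, and the rETR convention
#' factors.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param stages subset of `c("ojip", "pam", "screen", "integrate")`.
#' @param comparisons comparison labels to screen, e.g. `c("AvsB")`.
#' @param control_group group serving as control for difference curves.
#' @param thresholds per-layer screening thresholds; defaults to
#'   [screening_thresholds()].
#' @param permutations Mantel permutations (>= 99).
#' @param top_k genes kept per transcription factor in the network.
#' @param strong_r absolute-correlation cutoff for the "strong" flag.
#' @param offset pseudo-abundance used when omics tables contain zeros.
#' @param absorptance,psii_fraction rETR convention factors.
#' @param lsd_alpha significance level for the ANOVA + LSD letters.
#' @return an object of class `fluoromics_config`.
#' @export
fluoromics_config <- function(seed = 1,
                              stages = c("ojip", "pam", "screen", "integrate"),
                              comparisons = "AvsB",
                              control_group = "A",
                              thresholds = screening_thresholds(),
                              permutations = 999,
                              top_k = 50,
                              strong_r = 0.9,
                              offset = 0,
                              absorptance = 0.84,
                              psii_fraction = 0.5,
                              lsd_alpha = 0.05) {
  stages <- match.arg(stages, c("ojip", "pam", "screen", "integrate"),
                      several.ok = TRUE)
  if (!is.numeric(permutations) || permutations < 99) {
    stop("permutations must be at least 99", call. = FALSE)
  }
  if (!is.numeric(top_k) || top_k < 1) {
    stop("top_k must be at least 1", call. = FALSE)
  }
  if (!is.numeric(strong_r) || strong_r <= 0 || strong_r > 1) {
    stop("strong_r must lie in (0, 1]", call. = FALSE)
  }
  for (layer in names(thresholds)) {
    if (any(unlist(thresholds[[layer]]) <= 0)) {
      stop(sprintf("%s thresholds must be positive", layer), call. = FALSE)
    }
  }
  stopifnot(offset >= 0, absorptance > 0, psii_fraction > 0,
            lsd_alpha > 0, lsd_alpha < 1)
  vapply(comparisons, function(x) {
    parse_comparison(x)
    TRUE
  }, logical(1))
  structure(list(seed = as.integer(seed), stages = stages,
                 comparisons = comparisons, control_group = control_group,
                 thresholds = thresholds,
                 permutations = as.integer(permutations),
                 top_k = as.integer(top_k), strong_r = strong_r,
                 offset = offset, absorptance = absorptance,
                 psii_fraction = psii_fraction, lsd_alpha = lsd_alpha),
            class = "fluoromics_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [read_config()] returns a validated `fluoromics_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(fluoromics_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(fluoromics_config, vals)
}

#' @rdname read_config
#' @param config a [fluoromics_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fluoromics_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Average normalised curves of one treatment group onto the grid of its
# first member; returns a minimal normalized_curves object.
mean_group_curves <- function(curves, label) {
  grid <- curves[[1L]]$time
  lo <- max(vapply(curves, function(cv) cv$time[1L], numeric(1)))
  hi <- min(vapply(curves, function(cv) cv$time[length(cv$time)], numeric(1)))
  grid <- grid[grid >= lo & grid <= hi]
  vt <- rowMeans(vapply(curves,
                        function(cv) interp_logtime(cv$time, cv$vt, grid),
                        numeric(length(grid))))
  wt <- rowMeans(vapply(curves,
                        function(cv) interp_logtime(cv$time, cv$wt, grid),
                        numeric(length(grid))))
  structure(list(time = grid, vt = vt, wt = wt, label = label),
            class = "normalized_curves")
}

safe_group_summary <- function(values, groups, alpha) {
  tryCatch(group_summary(values, groups, alpha), error = function(e) NULL)
}

#' Run the analysis pipeline and write tidy result tables
#'
#' Executes the enabled stages on in-memory inputs and writes one tidy
#' delimited table per result kind into `out_dir`, plus a `run_log.txt`
#' recording the applied thresholds and seed.  Given the same
#' configuration, inputs and seed, the run directory contents are
#' byte-identical across runs.  Missing inputs for an enabled stage are
#' reported before any computation starts.
#'
#' Stages and outputs:
#' \describe{
#'   \item{ojip}{`jip_parameters.tsv` (one row per transient and
#'     parameter), `jip_group_summary.tsv` (mean, SE, LSD letters),
#'     `difference_curves.tsv` and `delta_wk.tsv` (group-mean
#'     treatment-vs-control differences and the K-band statistic).}
#'   \item{pam}{`quenching.tsv` (per step), `light_curve_fits.tsv`
#'     (alpha, ETRmax, Ek per sample), `pam_group_summary.tsv`.}
#'   \item{screen}{`screening.tsv` (per layer, comparison and feature).}
#'   \item{integrate}{`network_edges.tsv` (top-k TF-gene edges with the
#'     strong-correlation flag) and, when enzyme groups and a metabolite
#'     layer are available, `mantel.tsv`.}
#' }
#'
#' @param config a [fluoromics_config()].
#' @param inputs list with (depending on enabled stages) `transients`
#'   (named list of [fluorescence_transient()]), `light_curves` (named
#'   list of [light_curve_dataset()]), `omics` (named list of
#'   [omics_table()]s), `tf_features` (character), `gene_groups` (named
#'   character: gene id -> enzyme), `mantel_metabolites` (optional
#'   character subset).
#' @param out_dir output directory (created if needed).
#' @return the normalised output path, invisibly.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(inherits(config, "fluoromics_config"), is.list(inputs))
  need <- list(
    ojip = function() length(inputs$transients) > 0,
    pam = function() length(inputs$light_curves) > 0,
    screen = function() length(inputs$omics) > 0,
    integrate = function() !is.null(inputs$omics$transcript) &&
      length(inputs$tf_features) > 0)
  for (st in config$stages) {
    if (!need[[st]]()) {
      stop(sprintf("stage '%s' is enabled but its inputs are missing", st),
           call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("fluoromics pipeline run",
                 sprintf("seed: %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ", ")))
  screen_results <- NULL
  with_seed(config$seed, {
    if ("ojip" %in% config$stages) {
      trs <- inputs$transients
      ids <- names(trs) %||% sprintf("transient_%02d", seq_along(trs))
      jp <- do.call(rbind, lapply(seq_along(trs), function(i) {
        df <- as.data.frame(jip_parameters(trs[[i]]))
        data.frame(sample = ids[i], group = trs[[i]]$label, df,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(jp, file.path(out_dir, "jip_parameters.tsv"))
      gs <- do.call(rbind, lapply(split(jp, jp$parameter), function(d) {
        s <- safe_group_summary(d$value, d$group, config$lsd_alpha)
        if (is.null(s)) return(NULL)
        data.frame(parameter = d$parameter[1L], s, stringsAsFactors = FALSE)
      }))
      if (!is.null(gs)) {
        write_tsv(gs, file.path(out_dir, "jip_group_summary.tsv"))
      }
      curves <- lapply(trs, normalize_transient)
      labels <- vapply(trs, function(x) x$label, character(1))
      if (config$control_group %in% labels) {
        ctrl <- mean_group_curves(curves[labels == config$control_group],
                                  config$control_group)
        diffs <- lapply(setdiff(unique(labels), config$control_group),
                        function(g) {
          difference_curves(mean_group_curves(curves[labels == g], g), ctrl)
        })
        dtab <- do.call(rbind, lapply(diffs, function(d) {
          data.frame(treatment = d$treatment_label,
                     control = d$control_label,
                     time = d$time, dvt = d$dvt, dwt = d$dwt,
                     stringsAsFactors = FALSE)
        }))
        write_tsv(dtab, file.path(out_dir, "difference_curves.tsv"))
        write_tsv(do.call(rbind, lapply(diffs, function(d) {
          data.frame(treatment = d$treatment_label,
                     control = d$control_label, dwk = d$dwk,
                     stringsAsFactors = FALSE)
        })), file.path(out_dir, "delta_wk.tsv"))
      }
    }
    if ("pam" %in% config$stages) {
      lcs <- inputs$light_curves
      ids <- names(lcs) %||% sprintf("curve_%02d", seq_along(lcs))
      qtab <- do.call(rbind, lapply(seq_along(lcs), function(i) {
        q <- quenching_parameters(lcs[[i]],
                                  absorptance = config$absorptance,
                                  psii_fraction = config$psii_fraction)
        data.frame(sample = ids[i], group = lcs[[i]]$label,
                   fv_fm = attr(q, "fv_fm"), q, stringsAsFactors = FALSE)
      }))
      write_tsv(qtab, file.path(out_dir, "quenching.tsv"))
      ftab <- do.call(rbind, lapply(seq_along(lcs), function(i) {
        q <- quenching_parameters(lcs[[i]],
                                  absorptance = config$absorptance,
                                  psii_fraction = config$psii_fraction)
        fit <- fit_light_curve(q$par, q$retr)
        data.frame(sample = ids[i], group = lcs[[i]]$label,
                   fv_fm = attr(q, "fv_fm"), alpha = fit$alpha,
                   etrmax = fit$etrmax, ek = fit$ek, rss = fit$rss,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(ftab, file.path(out_dir, "light_curve_fits.tsv"))
      ps <- do.call(rbind, lapply(c("fv_fm", "alpha", "etrmax", "ek"),
                                  function(parm) {
        s <- safe_group_summary(ftab[[parm]], ftab$group, config$lsd_alpha)
        if (is.null(s)) return(NULL)
        data.frame(parameter = parm, s, stringsAsFactors = FALSE)
      }))
      if (!is.null(ps)) {
        write_tsv(ps, file.path(out_dir, "pam_group_summary.tsv"))
      }
    }
    if (any(c("screen", "integrate") %in% config$stages) &&
        length(inputs$omics)) {
      screen_results <- do.call(rbind, unlist(recursive = FALSE,
        lapply(names(inputs$omics), function(layer) {
          lapply(config$comparisons, function(cmp) {
            res <- screen_layer(inputs$omics[[layer]], cmp,
                                thresholds = config$thresholds[[layer]],
                                offset = config$offset)
            log_lines <<- c(log_lines, sprintf(
              "screen %s %s: thresholds %s", layer, cmp,
              paste(names(config$thresholds[[layer]]),
                    unlist(config$thresholds[[layer]]),
                    sep = "=", collapse = ", ")))
            res
          })
        })))
    }
    if ("screen" %in% config$stages) {
      write_tsv(screen_results, file.path(out_dir, "screening.tsv"))
    }
    if ("integrate" %in% config$stages) {
      ttab <- inputs$omics$transcript
      x <- ttab$abundance
      off <- if (any(x == 0)) max(config$offset, 1e-6) else config$offset
      logm <- log2(x + off)
      tfs <- intersect(inputs$tf_features, rownames(logm))
      if (!length(tfs)) {
        stop("none of the requested TF features are in the transcript table",
             call. = FALSE)
      }
      tcalls <- screen_results[screen_results$layer == "transcript" &
                                 screen_results$comparison ==
                                 config$comparisons[1L], ]
      cand <- setdiff(tcalls$feature[tcalls$call != "ns"], tfs)
      if (!length(cand)) cand <- setdiff(rownames(logm), tfs)
      edges <- suppressWarnings(
        tf_correlation_network(logm[tfs, , drop = FALSE],
                               logm[cand, , drop = FALSE],
                               k = config$top_k))
      edges$strong <- abs(edges$r) > config$strong_r
      write_tsv(edges, file.path(out_dir, "network_edges.tsv"))
      log_lines <- c(log_lines,
                     sprintf("network: top_k=%d over %d candidates, strong |r|>%g",
                             config$top_k, length(cand), config$strong_r))
      if (!is.null(inputs$omics$metabolite) &&
          length(inputs$gene_groups)) {
        mtab <- inputs$omics$metabolite
        mx <- mtab$abundance
        moff <- if (any(mx == 0)) max(config$offset, 1e-6) else config$offset
        mlog <- log2(mx + moff)
        if (length(inputs$mantel_metabolites)) {
          mlog <- mlog[intersect(inputs$mantel_metabolites, rownames(mlog)),
                       , drop = FALSE]
        }
        mt <- mantel_pairs(logm, inputs$gene_groups, mlog,
                           permutations = config$permutations,
                           seed = config$seed)
        write_tsv(mt, file.path(out_dir, "mantel.tsv"))
        log_lines <- c(log_lines,
                       sprintf("mantel: %d permutations per pair",
                               config$permutations))
      }
    }
  })
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(normalizePath(out_dir))
}

#' Load a pipeline input directory
#'
#' Reads the on-disk layout produced by the `simulate` CLI subcommand
#' (subdirectories `transients/`, `light_curves/`, `omics/`, plus
#' `tf_features.txt`, `gene_groups.tsv`, `mantel_metabolites.txt`) into
#' the in-memory `inputs` list expected by [run_pipeline()].  Transient
#' group labels are taken from the `<group>_<replicate>.tsv` filename
#' convention; light-curve labels come from their headers.
#'
#' @param dir input directory.
#' @return an inputs list.
#' @export
read_pipeline_inputs <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: %s", dir),
                             call. = FALSE)
  inputs <- list()
  tdir <- file.path(dir, "transients")
  if (dir.exists(tdir)) {
    files <- sort(list.files(tdir, pattern = "\\.tsv$", full.names = TRUE))
    inputs$transients <- stats::setNames(lapply(files, function(f) {
      read_transient_table(f, label = sub("_.*$", "", basename(f)))
    }), sub("\\.tsv$", "", basename(files)))
  }
  ldir <- file.path(dir, "light_curves")
  if (dir.exists(ldir)) {
    files <- sort(list.files(ldir, pattern = "\\.tsv$", full.names = TRUE))
    inputs$light_curves <- stats::setNames(
      lapply(files, read_light_curve_table),
      sub("\\.tsv$", "", basename(files)))
  }
  odir <- file.path(dir, "omics")
  if (dir.exists(odir)) {
    design <- file.path(odir, "design.tsv")
    ann <- file.path(odir, "annotations.tsv")
    inputs$omics <- list()
    for (layer in c("transcript", "protein", "metabolite")) {
      f <- file.path(odir, paste0(layer, ".tsv"))
      if (file.exists(f)) {
        inputs$omics[[layer]] <- read_omics_table(
          f, design, layer,
          annotations = if (layer == "transcript" && file.exists(ann)) ann)
      }
    }
  }
  tf_file <- file.path(dir, "tf_features.txt")
  if (file.exists(tf_file)) inputs$tf_features <- readLines(tf_file)
  gg_file <- file.path(dir, "gene_groups.tsv")
  if (file.exists(gg_file)) {
    gg <- utils::read.table(gg_file, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    inputs$gene_groups <- stats::setNames(gg$enzyme, gg$feature)
  }
  mm_file <- file.path(dir, "mantel_metabolites.txt")
  if (file.exists(mm_file)) inputs$mantel_metabolites <- readLines(mm_file)
  inputs
}
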