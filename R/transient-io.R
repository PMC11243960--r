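#' Fast fluorescence transient
#'
#' Container for one fast chlorophyll fluorescence induction record: a
#' strictly increasing time axis in seconds and the fluorescence signal in
#' arbitrary units.  The record must hold at least 50 samples and must
#' cover the K-J-I window (300 µs to 30 ms), otherwise the cardinal points
#' that every downstream normalisation relies on are undefined.
#'
#' @param time times in seconds, strictly increasing, all > 0.
#' @param fluorescence fluorescence values, finite and >= 0.
#' @param label treatment group label (e.g. `"A"` control, `"B"` UV-B).
#' @param meta free-form metadata list (the synthetic generator stores its
#'   model and seed here).
#' @return an object of class `fluorescence_transient`.
#' @export
fluorescence_transient <- function(time, fluorescence, label = NA_character_,
                                   meta = list()) {
  if (!is.numeric(time) || !is.numeric(fluorescence)) {
    stop("time and fluorescence must be numeric", call. = FALSE)
  }
  if (length(time) != length(fluorescence)) {
    stop("time and fluorescence must have equal length", call. = FALSE)
  }
  if (length(time) < 50L) {
    stop(sprintf("transient has %d samples; at least 50 are required",
                 length(time)), call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and > 0", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0)) {
    stop("fluorescence values must be finite and >= 0", call. = FALSE)
  }
  cardinal <- c(K = 3e-4, J = 2e-3, I = 3e-2)
  missing <- cardinal[cardinal < time[1L] | cardinal > time[length(time)]]
  if (length(missing)) {
    stop(sprintf(
      "record covers [%.3g, %.3g] s but must include the cardinal time(s) %s",
      time[1L], time[length(time)],
      paste(sprintf("%s (%g s)", names(missing), missing), collapse = ", ")),
      call. = FALSE)
  }
  structure(list(time = time, fluorescence = fluorescence,
                 label = label, meta = meta),
            class = "fluorescence_transient")
}

#' @export
print.fluorescence_transient <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_transient> %d samples, %.3g-%.3g s, group %s\n",
    length(x$time), x$time[1L], x$time[length(x$time)], x$label))
  invisible(x)
}

#' Table dialect for instrument-style exports
#'
#' Instrument exports are not standardised, so a small dialect descriptor
#' is passed instead of guessing: field separator, time unit and comment
#' prefix.  When `time_unit` is `NULL` the unit is parsed from the time
#' column header (`time_s`, `time_ms`, `time_us` and common variants).
#'
#' @param sep field separator.
#' @param time_unit one of `"s"`, `"ms"`, `"us"`, or `NULL` to read it from
#'   the header.
#' @param comment comment prefix for header metadata lines.
#' @return a list of class `transient_dialect`.
#' @export
transient_dialect <- function(sep = "\t", time_unit = NULL, comment = "#") {
  if (!is.null(time_unit)) {
    time_unit <- match.arg(time_unit, c("s", "ms", "us"))
  }
  structure(list(sep = sep, time_unit = time_unit, comment = comment),
            class = "transient_dialect")
}

time_unit_scale <- function(unit) {
  switch(unit, s = 1, ms = 1e-3, us = 1e-6,
         stop(sprintf("unknown time unit '%s'", unit), call. = FALSE))
}

unit_from_header <- function(name) {
  m <- regmatches(name, regexpr("(?i)(?<=[_ (])(s|ms|us|µs)\\)?$",
                                name, perl = TRUE))
  if (!length(m)) return(NULL)
  unit <- sub(")", "", tolower(m), fixed = TRUE)
  if (unit == "µs") unit <- "us"
  unit
}

#' Read a two-column time/fluorescence table
#'
#' Reads an instrument-style export (two numeric columns: time and
#' fluorescence), converts times to seconds, sorts rows by time and
#' collapses duplicated timestamps by averaging their fluorescence.
#' Non-numeric cells are rejected with their row numbers, short or
#' truncated records are rejected with the missing cardinal coverage
#' named.
#'
#' @param path file to read.
#' @param dialect a [transient_dialect()].
#' @param label group label attached to the returned transient.
#' @return a [fluorescence_transient()].
#' @export
read_transient_table <- function(path, dialect = transient_dialect(),
                                 label = NA_character_) {
  stopifnot(inherits(dialect, "transient_dialect"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.table(path, sep = dialect$sep, header = TRUE,
                           comment.char = dialect$comment,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 2L) {
    stop(sprintf("%s: expected 2 columns (time, fluorescence), found %d",
                 path, ncol(raw)), call. = FALSE)
  }
  unit <- dialect$time_unit %||% unit_from_header(names(raw)[1L])
  if (is.null(unit)) {
    stop(sprintf(
      "%s: time unit not declared; name the column e.g. 'time_ms' or set it in the dialect",
      path), call. = FALSE)
  }
  vals <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (j in 1:2) {
    bad <- which(is.na(vals[[j]]) & nzchar(trimws(raw[[j]])))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' in column %d, data row %d",
                   path, raw[[j]][bad[1L]], j, bad[1L]), call. = FALSE)
    }
    if (anyNA(vals[[j]])) {
      stop(sprintf("%s: empty cell in column %d, data row %d",
                   path, j, which(is.na(vals[[j]]))[1L]), call. = FALSE)
    }
  }
  time <- vals[[1L]] * time_unit_scale(unit)
  f <- vals[[2L]]
  ord <- order(time)
  time <- time[ord]; f <- f[ord]
  if (anyDuplicated(time)) {
    agg <- tapply(f, time, mean)
    time <- as.numeric(names(agg))
    f <- as.numeric(agg)
  }
  fluorescence_transient(time, f, label = label,
                         meta = list(source = path, time_unit = unit))
}

#' Write a transient as a two-column delimited table
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the transient to full double precision.  With
#' `sidecar = TRUE` a small YAML metadata file (`<path>.meta.yml`)
#' recording the group label and, for synthetic transients, the generator
#' seed is written next to the table.
#'
#' @param x a [fluorescence_transient()].
#' @param path output file.
#' @param time_unit unit for the written time column.
#' @param sep field separator.
#' @param sidecar also write `<path>.meta.yml`.
#' @return `path`, invisibly.
#' @export
write_transient_table <- function(x, path, time_unit = "s", sep = "\t",
                                  sidecar = FALSE) {
  stopifnot(inherits(x, "fluorescence_transient"))
  time_unit <- match.arg(time_unit, c("s", "ms", "us"))
  lines <- c(paste(paste0("time_", time_unit), "fluorescence", sep = sep),
             paste(sprintf("%.17g", x$time / time_unit_scale(time_unit)),
                   sprintf("%.17g", x$fluorescence), sep = sep))
  writeLines(lines, path)
  if (sidecar) {
    meta <- list(label = x$label, n = length(x$time),
                 time_unit = time_unit,
                 seed = x$meta$seed %||% NA)
    yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  }
  invisible(path)
}

#' Read a rapid-light-curve table
#'
#' Expects `#`-prefixed header lines declaring the dark-adapted reference
#' (`# F0 <value>` and `# Fm <value>`, optionally `# label <group>`)
#' followed by a delimited table with columns `par`, `f`, `fm_prime`.
#'
#' @param path file to read.
#' @param sep field separator.
#' @return a [light_curve_dataset()].
#' @export
read_light_curve_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    parts <- strsplit(trimws(sub("^#\\s*", "", h)), "\\s+")[[1L]]
    if (length(parts) >= 2L) kv[[parts[1L]]] <- parts[2L]
  }
  for (need in c("F0", "Fm")) {
    if (is.null(kv[[need]])) {
      stop(sprintf("%s: missing '# %s <value>' header line", path, need),
           call. = FALSE)
    }
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], sep = sep,
                           header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("par", "f", "fm_prime") %in% names(tab))) {
    stop(sprintf("%s: columns par, f, fm_prime are required", path),
         call. = FALSE)
  }
  light_curve_dataset(F0 = as.numeric(kv$F0), Fm = as.numeric(kv$Fm),
                      steps = tab[, c("par", "f", "fm_prime")],
                      label = kv$label %||% NA_character_,
                      meta = list(source = path,
                                  seed = as.numeric(kv$seed %||% NA)))
}

#' Write a rapid-light-curve table
#'
#' @param ds a [light_curve_dataset()].
#' @param path output file.
#' @param sep field separator.
#' @param sidecar also write `<path>.meta.yml` with label and seed.
#' @return `path`, invisibly.
#' @export
write_light_curve_table <- function(ds, path, sep = "\t", sidecar = FALSE) {
  stopifnot(inherits(ds, "light_curve_dataset"))
  hdr <- c(sprintf("# F0 %.17g", ds$F0), sprintf("# Fm %.17g", ds$Fm))
  if (!is.na(ds$label)) hdr <- c(hdr, paste("# label", ds$label))
  body <- c(paste(c("par", "f", "fm_prime"), collapse = sep),
            paste(sprintf("%.17g", ds$steps$par),
                  sprintf("%.17g", ds$steps$f),
                  sprintf("%.17g", ds$steps$fm_prime), sep = sep))
  writeLines(c(hdr, body), path)
  if (sidecar) {
    yaml::write_yaml(list(label = ds$label, seed = ds$meta$seed %||% NA),
                     paste0(path, ".meta.yml"))
  }
  invisible(path)
}
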