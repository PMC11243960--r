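# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  `seed = NULL` means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Interpolation linear in log(time): OJIP grids are log-spaced, so this is
# the natural scheme for evaluating a trace at the cardinal times.
interp_logtime <- function(time, values, t_out) {
  if (any(t_out < time[1L]) || any(t_out > time[length(time)])) {
    stop(sprintf(
      "time(s) %s s outside the recorded range [%.3g, %.3g] s",
      paste(signif(t_out[t_out < time[1L] | t_out > time[length(time)]], 3),
            collapse = ", "),
      time[1L], time[length(time)]), call. = FALSE)
  }
  stats::approx(log(time), values, xout = log(t_out), ties = mean)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "AvsB" -> control "A", treatment "B" (paper-style comparison labels:
# the first group is the control, FC = treatment / control).
parse_comparison <- function(comparison) {
  stopifnot(is.character(comparison), length(comparison) == 1L)
  parts <- strsplit(comparison, "vs", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(!nzchar(parts))) {
    stop("comparison must look like 'AvsB' (control vs treatment)",
         call. = FALSE)
  }
  list(control = parts[1L], treatment = parts[2L])
}

# All n! permutations of 1..n as an (n! x n) integer matrix.  Used for the
# exhaustive Mantel mode; guarded to small n.
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- p + (p >= k)  # relabel 1..n-1 onto 1..n skipping k
    out[[k]] <- cbind(rep.int(k, nrow(m)), m)
  }
  do.call(rbind, out)
}
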