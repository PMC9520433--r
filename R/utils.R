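#' @keywords internal
"_PACKAGE"

# Shared input checks used across modules. All stop() with the offending
# value so pipeline-level error summaries are informative.

check_proportion <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside the admissible range", name, x),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d (got %s)", name, min,
                 format(x)), call. = FALSE)
  invisible(as.integer(x))
}

check_symmetric <- function(m, name, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("'%s' is not symmetric (max asymmetry > %g)", name, tol),
         call. = FALSE)
  invisible(m)
}

# Scale a vector to an exact sample variance (denominator n-1); returns
# zeros if target is 0. Used by the generator so realized variance
# fractions match their targets by construction.
scale_to_var <- function(x, target_var) {
  if (target_var == 0) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (s == 0) stop("cannot scale a constant vector to positive variance")
  (x - mean(x)) / s * sqrt(target_var)
}

# Deterministic child seed derivation: keeps every stage's stream distinct
# while staying reproducible from one user-facing seed (and < 2^31).
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
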