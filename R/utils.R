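# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Harmonic-number constant a_n = sum_{i=1}^{n-1} 1/i
#'
#' Appears in Watterson's estimator and Tajima's D normalisation.
#' @param n number of sequences (>= 2)
#' @return sum of reciprocals 1..(n-1)
#' @keywords internal
harmonic_a <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

# guard for a single positive integer-ish scalar
check_count <- function(x, name, zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < if (zero_ok) 0 else 1) {
    stop(sprintf("'%s' must be a single %s integer", name,
                 if (zero_ok) "non-negative" else "positive"), call. = FALSE)
  }
  as.integer(x)
}
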