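# Internal numerical helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# two-sided normal p-value from a z-score, kept on log-safe path for large |z|
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# |z| implied by a two-sided p-value
p_to_z <- function(p) stats::qnorm(p / 2, lower.tail = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
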