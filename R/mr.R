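#' Single-instrument Wald-ratio Mendelian randomisation
#'
#' The Wald ratio is the effect of the genetic instrument on the outcome
#' divided by its effect on the exposure, `ratio = beta_out / beta_exp`,
#' estimating the causal effect of a 1 s.d. increase in the exposure (on the
#' log-odds scale for a binary outcome). The standard error is first order,
#' `se = |se_out / beta_exp|`, ignoring exposure-side uncertainty; the odds
#' ratio and its 95% Wald confidence interval follow by exponentiation and
#' the p-value from the normal approximation. Instruments with exposure
#' `|z| < weak_z` are flagged (not dropped) as weak.
#'
#' @param beta_exp,se_exp instrument effect and SE on the exposure
#'   (`beta_exp != 0`, `se_exp > 0`).
#' @param beta_out,se_out instrument effect and SE on the outcome.
#' @param weak_z weak-instrument flag threshold on `|beta_exp/se_exp|`
#'   (default 4).
#' @return A `wald_estimate`: list with `ratio`, `se`, `or_`, `ci_low`,
#'   `ci_high`, `p`, `weak_instrument`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, weak_z = 4) {
  if (beta_exp == 0) stopf("beta_exp must be non-zero")
  stopifnot(se_exp > 0, se_out > 0)
  ratio <- beta_out / beta_exp
  se <- abs(se_out / beta_exp)
  z_exp <- abs(beta_exp / se_exp)
  weak <- z_exp < weak_z
  if (weak)
    warnf("weak instrument: exposure |z| = %.2f < %g", z_exp, weak_z)
  structure(list(ratio = ratio,
                 se = se,
                 or_ = exp(ratio),
                 ci_low = exp(ratio - 1.96 * se),
                 ci_high = exp(ratio + 1.96 * se),
                 p = z_to_p(ratio / se),
                 weak_instrument = weak),
            class = "wald_estimate")
}

#' @export
print.wald_estimate <- function(x, ...) {
  cat(sprintf("Wald ratio %.3f (SE %.3f); OR %.2f [%.2f, %.2f]; p = %.3g%s\n",
              x$ratio, x$se, x$or_, x$ci_low, x$ci_high, x$p,
              if (isTRUE(x$weak_instrument)) " [weak instrument]" else ""))
  invisible(x)
}

#' Per-allele odds ratio with 95% confidence interval
#'
#' Exponentiates a log-odds effect and its Wald interval
#' `exp(beta +/- 1.96 se)`; values are additionally returned rounded to two
#' decimals for display, the convention for reporting per-allele ORs.
#'
#' @param beta per-allele log-odds effect.
#' @param se its standard error (> 0).
#' @return List with `or_`, `ci_low`, `ci_high` (exact) and `display`
#'   (two-decimal rounded `c(or, low, high)`).
#' @export
per_allele_or <- function(beta, se) {
  stopifnot(se > 0)
  or_ <- exp(beta)
  lo <- exp(beta - 1.96 * se)
  hi <- exp(beta + 1.96 * se)
  list(or_ = or_, ci_low = lo, ci_high = hi,
       display = round(c(or = or_, low = lo, high = hi), 2))
}
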