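#' Single-signal fine-mapping posteriors
#'
#' Posterior inclusion probabilities (PIPs) under the assumption of exactly
#' one causal variant in the region:
#' \deqn{PIP_j = \frac{\pi_j \, BF_j}{\sum_k \pi_k \, BF_k}}
#' with per-variant priors `pi` (normalised internally) and Wakefield Bayes
#' factors `BF`. Computed in the log domain.
#'
#' @param abf an [abf_vector()].
#' @param prior non-negative per-variant prior weights (default uniform);
#'   normalised internally.
#' @return A `pip_vector`: list with `ids`, `pip` (sums to 1), `prior`
#'   (normalised prior used).
#' @export
single_signal_pips <- function(abf, prior = NULL) {
  q <- length(abf$ids)
  if (is.null(prior)) prior <- rep(1 / q, q)
  if (length(prior) != q) stopf("prior length (%d) != number of variants (%d)", length(prior), q)
  if (any(prior < 0)) stopf("prior must be non-negative")
  if (sum(prior) <= 0) stopf("prior has no mass")
  prior <- prior / sum(prior)

  lw <- ifelse(prior > 0, log(prior) + abf$log_abf, -Inf)
  lz <- logsumexp(lw)
  if (!is.finite(lz)) stopf("all prior x BF weights are zero")
  pip <- exp(lw - lz)
  structure(list(ids = abf$ids, pip = stats::setNames(pip, abf$ids),
                 prior = stats::setNames(prior, abf$ids)),
            class = "pip_vector")
}

#' @export
print.pip_vector <- function(x, ...) {
  cat(sprintf("pip_vector: %d variants; top:\n", length(x$ids)))
  print(utils::head(sort(x$pip, decreasing = TRUE), 5L))
  invisible(x)
}

#' Turn stage-one PIPs into stage-two priors
#'
#' Transfers posterior inclusion probabilities from one analysis into the
#' prior of a subsequent analysis (e.g. from the best-powered ancestry into
#' a second ancestry), flooring every variant so none is irreversibly zeroed
#' by stage one:
#' \deqn{\pi_j \propto PIP_j + f}
#' with floor `f` defaulting to `1 / (10 Q)` for `Q` variants.
#'
#' @param pips a `pip_vector` from [single_signal_pips()], or a named
#'   numeric PIP vector.
#' @param floor non-negative additive floor; default `1/(10 * Q)`.
#' @return Named, normalised prior vector.
#' @export
transfer_priors <- function(pips, floor = NULL) {
  p <- if (inherits(pips, "pip_vector")) pips$pip else pips
  q <- length(p)
  floor <- floor %||% (1 / (10 * q))
  stopifnot(floor >= 0)
  pr <- p + floor
  pr / sum(pr)
}

#' Stepwise two-ancestry fine-mapping with PIP-prior transfer
#'
#' Stage 1 fine-maps the better-powered ancestry under equal per-variant
#' priors; stage 2 fine-maps the second ancestry using the stage-1 PIPs
#' (floored and renormalised via [transfer_priors()]) as priors. The two
#' ancestries may carry different variant sets: the transferred prior acts
#' on the intersection, while variants present only in ancestry 2 receive
#' the floor weight.
#'
#' @param abf_anc1,abf_anc2 [abf_vector()] objects for the two ancestries.
#' @param floor prior floor for the transfer; default `1/(10 * Q1)` with
#'   `Q1` the ancestry-1 region size.
#' @return List with `stage1` and `stage2` `pip_vector`s.
#' @export
stepwise_multiancestry <- function(abf_anc1, abf_anc2, floor = NULL) {
  if (!length(intersect(abf_anc1$ids, abf_anc2$ids)))
    stopf("no variants shared between ancestries")
  stage1 <- single_signal_pips(abf_anc1)
  floor <- floor %||% (1 / (10 * length(abf_anc1$ids)))
  transferred <- transfer_priors(stage1, floor = floor)
  prior2 <- transferred[abf_anc2$ids]
  prior2[is.na(prior2)] <- floor   # ancestry-2-only variants get the floor
  prior2 <- prior2 / sum(prior2)
  stage2 <- single_signal_pips(abf_anc2, prior = unname(prior2))
  list(stage1 = stage1, stage2 = stage2)
}
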