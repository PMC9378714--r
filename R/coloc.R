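#' Wakefield approximate Bayes factor for one association record
#'
#' With observed effect `beta`, standard error `se` (variance `V = se^2`),
#' normal effect prior with standard deviation `prior_sd` (`W = prior_sd^2`)
#' and `z = beta/se`, the asymptotic Bayes factor against the null is
#' \deqn{\log \mathrm{ABF} = \tfrac12 \log(1 - r) + \tfrac{z^2 r}{2}, \quad
#'       r = W / (V + W),}
#' i.e. the marginal-likelihood ratio N(beta; 0, V+W) / N(beta; 0, V).
#'
#' The default effect-size priors follow the conventions of the
#' colocalisation method family: `prior_sd = 0.15` on the standardised scale
#' for quantitative traits and `0.2` on the log-odds scale for binary traits.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param prior_sd prior standard deviation of the true effect (>= 0);
#'   `0` encodes a point-mass-at-zero prior and yields log ABF = 0.
#' @return Natural-log ABF, vectorised over records.
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  stopifnot(all(se > 0), prior_sd >= 0)
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log1p(-r) + z^2 * r / 2
}

#' Default effect-size prior standard deviation by trait type
#'
#' @param trait_type `"quantitative"` (0.15, standardised scale) or
#'   `"binary"` (0.2, log-odds scale).
#' @return Numeric scalar.
#' @export
default_prior_sd <- function(trait_type = c("quantitative", "binary")) {
  switch(match.arg(trait_type), quantitative = 0.15, binary = 0.2)
}

#' Per-variant ABF vector for a summary-statistics table
#'
#' @param table a [sumstats_table()].
#' @param prior_sd effect-size prior sd; default chosen by trait type via
#'   [default_prior_sd()].
#' @return An `abf_vector`: list with `ids`, `pos`, `log_abf`, `prior_sd`,
#'   and per-variant `p` (used for sentinel identification).
#' @export
abf_vector <- function(table, prior_sd = NULL) {
  prior_sd <- prior_sd %||% default_prior_sd(attr(table, "trait_type"))
  la <- log_abf(table$beta, table$se, prior_sd)
  if (any(!is.finite(la))) stopf("non-finite log ABF encountered")
  structure(list(ids = table$id, pos = table$pos, log_abf = la,
                 prior_sd = prior_sd, p = table$p,
                 z = table$beta / table$se,
                 trait_label = attr(table, "trait_label")),
            class = "abf_vector")
}

#' Colocalisation priors
#'
#' Per-variant prior probabilities that a variant is causal for trait 1 only
#' (`p1`), trait 2 only (`p2`), or both (`p12`). Defaults are the method
#' family's standard settings `p1 = p2 = 1e-4`, `p12 = 1e-5`.
#'
#' @param p1,p2,p12 priors in `(0, 1)` with `p12 <= min(p1, p2)`.
#' @param q optional region size; when `q * (p1 + p2 + p12) >= 1` a warning
#'   is emitted (priors implausibly large for the region).
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, q = NULL) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1)
  if (p12 > min(p1, p2))
    stopf("p12 (%g) must not exceed min(p1, p2) = %g", p12, min(p1, p2))
  if (!is.null(q) && q * (p1 + p2 + p12) >= 1)
    warnf("q * (p1 + p2 + p12) >= 1: priors implausibly large for region of %d variants", q)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

# identify the sentinel (regional lead) of an abf_vector:
# smallest p, ties by larger |z|, then by lower position
sentinel_of <- function(abf) {
  ord <- order(abf$p, -abs(abf$z), abf$pos)
  abf$ids[ord[1]]
}

#' Pairwise five-hypothesis Bayesian colocalisation
#'
#' Computes posterior probabilities for the five regional hypotheses —
#' H0: no signal for either trait; H1/H2: signal for one trait only;
#' H3: distinct causal variants; H4: one shared causal variant — from
#' per-variant approximate Bayes factors of two traits on an identical,
#' harmonised variant set. All arithmetic is performed in the log domain via
#' log-sum-exp; the H3 term `S1*S2 - S12` is guarded against catastrophic
#' cancellation (a negative remainder is clamped to zero with a warning).
#'
#' @param abf1,abf2 [abf_vector()] objects over the same ordered variant ids.
#' @param priors a [coloc_priors()].
#' @return A `coloc_result`: list with `pp` (named PP.H0..PP.H4, summing to
#'   1), `per_snp_h4` (posterior of each variant being the shared causal one
#'   given H4, summing to 1), `sentinel1`, `sentinel2`, `n_snps`, and
#'   `filter_flags` (filled by the guard functions, `NA` until then).
#' @export
coloc <- function(abf1, abf2, priors = coloc_priors()) {
  if (!identical(abf1$ids, abf2$ids))
    stopf("ABF vectors must be on the identical ordered variant set (harmonise first)")
  q <- length(abf1$ids)
  if (q < 2L) stopf("fewer than 2 shared variants")

  lb1 <- abf1$log_abf
  lb2 <- abf2$log_abf
  lS1 <- logsumexp(lb1)
  lS2 <- logsumexp(lb2)
  lS12 <- logsumexp(lb1 + lb2)

  lL0 <- 0
  lL1 <- log(priors$p1) + lS1
  lL2 <- log(priors$p2) + lS2
  # H3: p1*p2*(S1*S2 - S12), computed as a guarded difference of exponentials
  ldiff <- lS1 + lS2
  if (lS12 >= ldiff) {
    if (lS12 > ldiff + 1e-9)
      warnf("S12 exceeds S1*S2; H3 weight clamped to 0")
    lL3 <- -Inf
  } else {
    lL3 <- log(priors$p1) + log(priors$p2) + ldiff + log1p(-exp(lS12 - ldiff))
  }
  lL4 <- log(priors$p12) + lS12

  lL <- c(lL0, lL1, lL2, lL3, lL4)
  lZ <- logsumexp(lL)
  pp <- exp(lL - lZ)
  names(pp) <- paste0("PP.H", 0:4)

  lps <- lb1 + lb2
  per_snp <- exp(lps - logsumexp(lps))
  names(per_snp) <- abf1$ids

  structure(list(pp = pp,
                 per_snp_h4 = per_snp,
                 sentinel1 = sentinel_of(abf1),
                 sentinel2 = sentinel_of(abf2),
                 n_snps = q,
                 priors = priors,
                 filter_flags = list(instrument_represented = NA,
                                     sentinel_ld_pass = NA)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d SNPs\n", x$n_snps))
  print(round(x$pp, 4))
  cat(sprintf("  sentinels: %s / %s\n", x$sentinel1, x$sentinel2))
  invisible(x)
}

#' Default prior-sensitivity grid
#'
#' The standard robustness grid: `p1` and `p2` over `c(1e-4, 1e-5, 1e-6)`
#' and `p12` over `c(1e-5, 5e-6, 1e-6)` — 27 candidate combinations before
#' removing those violating `p12 <= min(p1, p2)`.
#'
#' @return data.frame with columns `p1`, `p2`, `p12`.
#' @export
default_prior_grid <- function() {
  expand.grid(p1 = c(1e-4, 1e-5, 1e-6),
              p2 = c(1e-4, 1e-5, 1e-6),
              p12 = c(1e-5, 5e-6, 1e-6),
              KEEP.OUT.ATTRS = FALSE)
}

#' Prior-sensitivity analysis over a grid
#'
#' Re-runs [coloc()] at every admissible grid point; combinations with
#' `p12 > min(p1, p2)` are skipped (reported in `n_skipped`). The result is
#' flagged `robust` when PP(H4) exceeds `pp_min` at every retained point.
#'
#' @param abf1,abf2 [abf_vector()] objects on the shared variant set.
#' @param grid data.frame with columns `p1`, `p2`, `p12`
#'   (default [default_prior_grid()]).
#' @param pp_min robustness threshold on PP(H4) (default 0.8).
#' @return List with `results` (data.frame: priors + PP.H0..PP.H4), `robust`,
#'   `n_retained`, `n_skipped`.
#' @export
prior_sensitivity <- function(abf1, abf2, grid = default_prior_grid(), pp_min = 0.8) {
  ok <- grid$p12 <= pmin(grid$p1, grid$p2)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(sprintf("prior_sensitivity: skipped %d combination(s) with p12 > min(p1, p2)", n_skipped))
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0L) stopf("no admissible prior combinations in grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- coloc(abf1, abf2,
                 coloc_priors(grid$p1[i], grid$p2[i], grid$p12[i]))
    cbind(grid[i, , drop = FALSE], as.data.frame(as.list(res$pp)))
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results,
       robust = all(results$PP.H4 > pp_min),
       n_retained = nrow(results),
       n_skipped = n_skipped)
}

#' Is the lead instrument represented in the shared variant set?
#'
#' TRUE iff the lead variant itself, or any proxy with `r^2` strictly above
#' `r2_min`, appears among the shared (overlapping) variant ids. A lead
#' absent from the LD panel returns FALSE with a warning (conservative).
#'
#' @param lead_id lead variant (e.g. lead cis-pQTL) id.
#' @param shared_ids variant ids in the harmonised overlap.
#' @param ld an [ld_matrix()].
#' @param r2_min strict `r^2` threshold (default 0.8).
#' @return Logical scalar.
#' @export
instrument_represented <- function(lead_id, shared_ids, ld, r2_min = 0.8) {
  if (lead_id %in% shared_ids) return(TRUE)
  if (!lead_id %in% ld$ids) {
    warnf("lead variant '%s' absent from LD panel; treating as unrepresented", lead_id)
    return(FALSE)
  }
  proxies <- find_proxies(ld, lead_id, r2_min)
  any(proxies$id %in% shared_ids)
}

#' Are the two regional sentinels in strong LD?
#'
#' A high PP(H4) with discordant sentinels (regional lead variants for the
#' two traits not in strong LD) violates the single-causal-variant assumption
#' and flags a likely false positive; this guard requires
#' `r^2(sentinel1, sentinel2) > r2_min` (strict).
#'
#' @param result a [coloc()] result.
#' @param ld an [ld_matrix()] containing both sentinels.
#' @param r2_min strict `r^2` threshold (default 0.8).
#' @return Logical scalar; FALSE with a warning if a sentinel is absent from
#'   the panel.
#' @export
sentinel_concordance <- function(result, ld, r2_min = 0.8) {
  s1 <- result$sentinel1
  s2 <- result$sentinel2
  if (!s1 %in% ld$ids || !s2 %in% ld$ids) {
    warnf("sentinel(s) absent from LD panel; concordance treated as failed")
    return(FALSE)
  }
  r2(ld, s1, s2) > r2_min
}
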