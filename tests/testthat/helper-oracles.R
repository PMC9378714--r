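# Shared fixtures and independent oracles, built in code at test time.

# quick sumstats_table from parallel vectors
make_table <- function(ids, beta, se, pos = seq_along(ids),
                       ea = "A", nea = "G", eaf = 0.3, n = 10000,
                       p = NULL, coverage = NA_real_,
                       trait_label = "t", trait_type = "quantitative") {
  q <- length(ids)
  p <- p %||% (2 * pnorm(-abs(beta / se)))
  sumstats_table(data.frame(
    id = ids, chrom = "1", pos = pos,
    ea = rep_len(ea, q), nea = rep_len(nea, q), eaf = rep_len(eaf, q),
    beta = beta, se = rep_len(se, q), p = p, n = rep_len(n, q),
    coverage = rep_len(coverage, q), stringsAsFactors = FALSE),
    trait_label = trait_label, trait_type = trait_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# abf_vector straight from a log-ABF vector (bypasses summary statistics)
make_abf <- function(lb, ids = sprintf("v%d", seq_along(lb)),
                     pos = seq_along(lb), label = "t") {
  structure(list(ids = ids, pos = pos, log_abf = lb, prior_sd = 0.15,
                 p = rep(0.5, length(lb)), z = rep(0, length(lb)),
                 trait_label = label),
            class = "abf_vector")
}

# brute-force five-hypothesis oracle: enumerate all (Q+1)^2 causal
# configuration pairs (0 = no causal variant) with the stated priors
coloc_oracle <- function(lb1, lb2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  q <- length(lb1)
  b1 <- exp(lb1); b2 <- exp(lb2)
  w <- matrix(0, q + 1L, q + 1L)
  w[1, 1] <- 1
  w[-1, 1] <- p1 * b1
  w[1, -1] <- p2 * b2
  for (i in seq_len(q)) for (j in seq_len(q))
    w[i + 1L, j + 1L] <- if (i == j) p12 * b1[i] * b2[i] else p1 * p2 * b1[i] * b2[j]
  inner <- w[-1, -1, drop = FALSE]
  h4 <- sum(diag(inner))
  pp <- c(w[1, 1], sum(w[-1, 1]), sum(w[1, -1]), sum(inner) - h4, h4)
  pp / sum(pp)
}

# marginal-likelihood-ratio oracle for the Wakefield ABF via quadrature;
# integrand is evaluated on a log scale around the posterior mode so the
# oracle stays accurate for large |z| where the peak is extremely narrow
log_abf_quadrature <- function(beta, se, prior_sd) {
  V <- se^2; W <- prior_sd^2
  mode <- beta * W / (V + W)
  sd_post <- sqrt(V * W / (V + W) + .Machine$double.eps)
  lpeak <- dnorm(beta, mode, se, log = TRUE) + dnorm(mode, 0, prior_sd, log = TRUE)
  marg <- integrate(function(b)
    exp(dnorm(beta, b, se, log = TRUE) + dnorm(b, 0, prior_sd, log = TRUE) - lpeak),
    lower = mode - 12 * sd_post, upper = mode + 12 * sd_post,
    rel.tol = 1e-12)$value
  (log(marg) + lpeak) - dnorm(beta, 0, se, log = TRUE)
}

# individual-level design matrix with EXACT sample correlation R
# (whiten empirical covariance, then colour with chol(R))
design_with_correlation <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- nrow(R)
  X <- scale(matrix(rnorm(n * p), n, p))
  X <- X %*% solve(chol(cov(X)))
  X %*% chol(R)
}

# draw per-trait regional z-score tables on a fixed panel (shared LD), one
# causal variant per trait; lighter than simulate_sumstats for reuse in loops
sim_tables_on_panel <- function(panel, causals, ve = 0.01, n = 10000, seed = 1) {
  ids <- panel$variant_ids
  map <- attr(panel, "map")
  R <- colocscreen:::nearest_psd(compute_ld(panel)$r[ids, ids])
  cholR <- chol(R)
  set.seed(seed)
  lapply(seq_along(causals), function(t) {
    lam <- numeric(length(ids))
    if (!is.null(causals[[t]])) lam[match(causals[[t]], ids)] <- sqrt(ve)
    z <- colocscreen:::draw_z(cholR, R, lam, n)
    se <- rep(1 / sqrt(n), length(ids))
    sumstats_table(data.frame(
      id = ids, chrom = map$chrom, pos = map$pos, ea = map$ea, nea = map$nea,
      eaf = 0.3, beta = z * se, se = se, p = 2 * pnorm(-abs(z)), n = n,
      stringsAsFactors = FALSE),
      trait_label = paste0("trait", t), trait_type = "quantitative")
  })
}
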