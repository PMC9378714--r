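test_that("log_abf matches the quadrature marginal-likelihood oracle", {
  cases <- expand.grid(beta = c(-0.3, 0, 0.02, 0.1, 0.5),
                       se = c(0.02, 0.1), prior_sd = c(0.05, 0.15, 0.2))
  for (k in seq_len(nrow(cases))) {
    with(cases[k, ], expect_equal(
      log_abf(beta, se, prior_sd),
      log_abf_quadrature(beta, se, prior_sd),
      tolerance = 1e-8))
  }
})

test_that("log_abf limiting behaviour: point-mass prior and null penalty", {
  expect_equal(log_abf(0.7, 0.01, prior_sd = 0), 0)
  expect_equal(log_abf(-3, 2, prior_sd = 0), 0)
  # beta = 0 with V = W: pure Occam penalty 0.5 * log(0.5)
  expect_equal(log_abf(0, 0.1, prior_sd = 0.1), 0.5 * log(0.5))
})

test_that("coloc posteriors and per-SNP H4 each sum to one", {
  set.seed(1)
  a1 <- make_abf(rnorm(40, 0, 3))
  a2 <- make_abf(rnorm(40, 0, 3))
  res <- coloc(a1, a2)
  expect_equal(sum(res$pp), 1, tolerance = 1e-10)
  expect_equal(sum(res$per_snp_h4), 1, tolerance = 1e-10)
})

test_that("coloc equals the brute-force configuration-pair oracle", {
  set.seed(99)
  for (rep in 1:10) {
    q <- sample(3:50, 1)
    lb1 <- rnorm(q, 0, 4); lb2 <- rnorm(q, 0, 4)
    if (rep %% 2 == 0) {        # plant a shared strong signal half the time
      j <- sample(q, 1); lb1[j] <- lb1[j] + 40; lb2[j] <- lb2[j] + 40
    }
    res <- coloc(make_abf(lb1), make_abf(lb2))
    expect_equal(unname(res$pp), coloc_oracle(lb1, lb2), tolerance = 1e-10)
  }
})

test_that("trait-swap relabels H1/H2 and preserves H0/H3/H4", {
  set.seed(2)
  a1 <- make_abf(rnorm(30, 0, 3) + c(rep(0, 29), 10))
  a2 <- make_abf(rnorm(30, 0, 2))
  f <- coloc(a1, a2)$pp
  b <- coloc(a2, a1)$pp
  expect_equal(unname(f[c("PP.H1", "PP.H2")]), unname(b[c("PP.H2", "PP.H1")]),
               tolerance = 1e-12)
  expect_equal(unname(f[c("PP.H0", "PP.H3", "PP.H4")]),
               unname(b[c("PP.H0", "PP.H3", "PP.H4")]), tolerance = 1e-12)
})

test_that("flat traits give PP(H0) > 0.97 at default priors, Q = 100", {
  a <- make_abf(rep(0, 100))
  res <- coloc(a, a)
  expect_gt(res$pp["PP.H0"], 0.97)
  # closed form: L0 = 1, L1 = L2 = Q 1e-4, L3 = Q(Q-1) 1e-8, L4 = Q 1e-5
  q <- 100
  L <- c(1, q * 1e-4, q * 1e-4, q * (q - 1) * 1e-8, q * 1e-5)
  expect_equal(unname(res$pp), L / sum(L), tolerance = 1e-10)
})

test_that("inflating one trait's evidence drains PP(H0)", {
  set.seed(5)
  lb1 <- rnorm(50, 0, 1); lb2 <- rnorm(50, 0, 1)
  pp0 <- sapply(c(0, 5, 10, 20), function(cc)
    coloc(make_abf(lb1 + cc), make_abf(lb2))$pp["PP.H0"])
  expect_true(all(diff(pp0) < 0))
})

test_that("prior_sensitivity: grid size, skip rule, degenerate identity", {
  grid <- default_prior_grid()
  expect_equal(nrow(grid), 27L)
  a1 <- make_abf(c(rep(0, 19), 12))
  a2 <- make_abf(c(rep(0, 19), 11))
  ps <- prior_sensitivity(a1, a2, grid)
  ok <- grid$p12 <= pmin(grid$p1, grid$p2)
  expect_equal(ps$n_retained, sum(ok))
  expect_equal(ps$n_skipped, sum(!ok))
  # one-point grid = plain coloc
  one <- prior_sensitivity(a1, a2, data.frame(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5))
  plain <- coloc(a1, a2)
  expect_equal(unlist(one$results[1, paste0("PP.H", 0:4)]),
               plain$pp, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PP(H4) is non-decreasing in p12 at fixed p1, p2", {
  set.seed(6)
  a1 <- make_abf(rnorm(30) + c(rep(0, 29), 8))
  a2 <- make_abf(rnorm(30) + c(rep(0, 29), 6))
  ps <- prior_sensitivity(a1, a2)$results
  for (grp in split(ps, list(ps$p1, ps$p2), drop = TRUE)) {
    grp <- grp[order(grp$p12), ]
    expect_true(all(diff(grp$PP.H4) >= -1e-12))
  }
})

test_that("instrument_represented: lead, strict proxy threshold, oracle scan", {
  ids <- c("lead", "proxy95", "proxy80", "far")
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- sqrt(0.95)
  r[1, 3] <- r[3, 1] <- sqrt(0.8)
  r[1, 4] <- r[4, 1] <- 0.1
  dimnames(r) <- list(ids, ids)
  ld <- ld_matrix(r)
  expect_true(instrument_represented("lead", c("lead", "far"), ld))
  expect_true(instrument_represented("lead", c("proxy95", "far"), ld))
  expect_false(instrument_represented("lead", c("proxy80", "far"), ld))  # r2 = 0.8 strict
  expect_warning(ok <- instrument_represented("ghost", "lead", ld), "absent")
  expect_false(ok)

  panel <- simulate_panel(n_hap = 800, n_var = 12, block_len = 12, rho = 0.95,
                          seed = 31)
  pld <- compute_ld(panel)
  shared <- setdiff(pld$ids, "snp6")
  want <- any(sapply(shared, function(v) pld$r["snp6", v]^2 > 0.8))
  expect_identical(instrument_represented("snp6", shared, pld), want)
})

test_that("sentinel_concordance applies the strict r2 rule", {
  set.seed(44)
  lb1 <- c(rep(0, 3), 30); lb2 <- c(30, rep(0, 3))
  a1 <- make_abf(lb1); a1$p <- c(0.5, 0.5, 0.5, 1e-12)
  a2 <- make_abf(lb2); a2$p <- c(1e-12, 0.5, 0.5, 0.5)
  res <- coloc(a1, a2)
  expect_identical(res$sentinel1, "v4")
  expect_identical(res$sentinel2, "v1")
  make_ld <- function(rho) {
    r <- diag(4); r[1, 4] <- r[4, 1] <- rho
    dimnames(r) <- list(sprintf("v%d", 1:4), sprintf("v%d", 1:4))
    ld_matrix(r)
  }
  expect_false(sentinel_concordance(res, make_ld(sqrt(0.12))))
  expect_false(sentinel_concordance(res, make_ld(sqrt(0.79))))
  expect_true(sentinel_concordance(res, make_ld(sqrt(0.85))))
  # identical sentinels always pass
  res2 <- coloc(a1, a1)
  expect_true(sentinel_concordance(res2, make_ld(0)))
})

test_that("sentinel ties break by |z| then position", {
  a <- make_abf(c(5, 5, 5))
  a$p <- c(0.01, 0.001, 0.001)
  a$z <- c(2, 3, 4)
  expect_identical(colocscreen:::sentinel_of(a), "v3")
  a$z <- c(2, 3, 3)
  expect_identical(colocscreen:::sentinel_of(a), "v2")
})

test_that("coloc distinguishes shared and distinct causal variants with power", {
  panel <- simulate_panel(n_hap = 1000, n_var = 60, block_len = 10, rho = 0.9,
                          seed = 13)
  pp4 <- pp3 <- numeric(30)
  for (s in 1:30) {
    d4 <- simulate_sumstats(panel, scenario("H4", causal1 = "snp30", seed = 1000 + s))
    h <- harmonise_pair(d4$t1, d4$t2)
    pp4[s] <- coloc(abf_vector(h$t1), abf_vector(h$t2))$pp["PP.H4"]
    d3 <- simulate_sumstats(panel, scenario("H3", causal1 = "snp30",
                                            causal2 = "snp5", seed = 2000 + s))
    h3 <- harmonise_pair(d3$t1, d3$t2)
    pp3[s] <- coloc(abf_vector(h3$t1), abf_vector(h3$t2))$pp["PP.H3"]
  }
  expect_gt(mean(pp4 > 0.8), 0.85)
  expect_gt(median(pp3), 0.8)
})
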