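test_that("read_sumstats validates, uppercases alleles, drops bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsid\tchr\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs766826\t11\t34507397\tt\tc\t0.36\t-0.07\t0.01\t5.38e-6\t10708",
    "rs_bad_allele\t11\t34507500\tN\tc\t0.10\t0.05\t0.01\t0.5\t10708",
    "rs_zero_se\t11\t34507600\ta\tg\t0.10\t0.05\t0\t0.5\t10708"),
    path)
  # the published row's p comes from a meta-analysis model, so it disagrees
  # with the normal approximation from beta/se: the consistency warning fires
  expect_warning(
    expect_message(
      tab <- read_sumstats(path, "ELF5", "quantitative", column_preset("pgwas")),
      "dropped 2"),
    "inconsistent")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$ea, "T")
  expect_equal(tab$nea, "C")
  expect_equal(tab$eaf, 0.36)
  expect_equal(tab$beta, -0.07)
})

test_that("read_sumstats fails on header-only files and missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsid\tchr\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
             path)
  expect_error(read_sumstats(path, "x", column_map = column_preset("pgwas")),
               "zero valid rows")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchr\tpos", "rs1\t1\t100"), path2)
  expect_error(read_sumstats(path2, "x", column_map = column_preset("pgwas")),
               "missing required column|absent")
})

test_that("read_sumstats warns when p disagrees with beta/se by > 10x", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsid\tchr\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\t1\t100\ta\tg\t0.3\t0.5\t0.1\t0.9\t1000"),  # |z| = 5, p should be ~6e-7
    path)
  expect_warning(read_sumstats(path, "x", column_map = column_preset("pgwas")),
                 "inconsistent")
})

test_that("extract_region keeps inclusive boundaries", {
  tab <- make_table(c("a", "b", "c"), beta = c(0, 0, 0), se = 0.1,
                    pos = c(499999, 500000, 1500000))
  out <- extract_region(tab, anchor = 1000000, flank = 500000)
  expect_setequal(out$id, c("b", "c"))
  # flank 0: only variants inside the anchor interval
  out0 <- extract_region(tab, anchor = c(499999, 500000), flank = 0)
  expect_setequal(out0$id, c("a", "b"))
  # empty result is an empty table, not an error
  expect_equal(nrow(extract_region(tab, anchor = 5e7, flank = 0)), 0L)
})

test_that("harmonise_pair flips swapped alleles and drops incompatible pairs", {
  t1 <- make_table(c("v1", "v2", "v3"), beta = c(0.1, 0.2, 0.3), se = 0.05,
                   ea = c("A", "A", "A"), nea = c("G", "G", "G"), eaf = 0.2)
  t2 <- make_table(c("v1", "v2", "v3"), beta = c(0.1, 0.2, 0.3), se = 0.05,
                   ea = c("G", "A", "C"), nea = c("A", "G", "T"), eaf = 0.8)
  h <- harmonise_pair(t1, t2)
  expect_setequal(h$t1$id, c("v1", "v2"))          # v3 incompatible: dropped
  i <- match("v1", h$t2$id)
  expect_equal(h$t2$beta[i], -0.1)                  # swapped: sign flipped
  expect_equal(h$t2$eaf[i], 1 - 0.8)
  expect_equal(h$t2$beta[match("v2", h$t2$id)], 0.2) # exact: untouched
  expect_identical(h$t1$id, h$t2$id)
})

test_that("palindromic variants in the MAF band are dropped", {
  t1 <- make_table(c("p1", "p2"), beta = c(0.1, 0.1), se = 0.05,
                   ea = c("A", "A"), nea = c("T", "T"), eaf = c(0.45, 0.10))
  t2 <- make_table(c("p1", "p2"), beta = c(0.1, 0.1), se = 0.05,
                   ea = c("A", "A"), nea = c("T", "T"), eaf = c(0.45, 0.10))
  h <- harmonise_pair(t1, t2)
  expect_identical(h$t1$id, "p2")   # MAF 0.45 inside [0.40, 0.50] band
  h2 <- harmonise_pair(t1, t2, drop_palindromic_maf_band = NULL)
  expect_setequal(h2$t1$id, c("p1", "p2"))
})

test_that("harmonise_pair is idempotent and self-harmonisation is identity", {
  set.seed(42)
  t1 <- make_table(sprintf("v%d", 1:20), beta = rnorm(20, 0, 0.05), se = 0.02,
                   ea = sample(c("A", "C"), 20, TRUE), nea = "G",
                   eaf = runif(20, 0.05, 0.35))
  t2 <- make_table(sprintf("v%d", 1:20), beta = rnorm(20, 0, 0.05), se = 0.02,
                   ea = "G", nea = sample(c("A", "C"), 20, TRUE),
                   eaf = runif(20, 0.05, 0.35))
  h1 <- harmonise_pair(t1, t2)
  h2 <- harmonise_pair(h1$t1, h1$t2)
  expect_equal(as.data.frame(h2$t1), as.data.frame(h1$t1))
  expect_equal(as.data.frame(h2$t2), as.data.frame(h1$t2))

  hs <- harmonise_pair(t1, t1)
  expect_equal(hs$t2$beta, t1$beta[match(hs$t2$id, t1$id)])
})

test_that("harmonisation commutes with region extraction", {
  set.seed(7)
  ids <- sprintf("v%d", 1:30)
  t1 <- make_table(ids, beta = rnorm(30, 0, 0.05), se = 0.02,
                   pos = seq(1e6, by = 1e4, length.out = 30))
  t2 <- make_table(ids, beta = rnorm(30, 0, 0.05), se = 0.02,
                   pos = seq(1e6, by = 1e4, length.out = 30))
  anchor <- 1.1e6; flank <- 5e4
  a <- harmonise_pair(extract_region(t1, anchor, flank),
                      extract_region(t2, anchor, flank))
  b0 <- harmonise_pair(t1, t2)
  b <- list(t1 = extract_region(b0$t1, anchor, flank),
            t2 = extract_region(b0$t2, anchor, flank))
  expect_equal(as.data.frame(a$t1), as.data.frame(b$t1), ignore_attr = TRUE)
  expect_equal(as.data.frame(a$t2), as.data.frame(b$t2), ignore_attr = TRUE)
})

test_that("study_coverage_filter uses a strict threshold and keeps missing", {
  tab <- make_table(c("a", "b", "c"), beta = 0, se = 0.1,
                    coverage = c(0.79, NA, 1))
  out <- study_coverage_filter(tab, 0.8)
  expect_setequal(out$id, c("b", "c"))
  all1 <- make_table(c("a", "b"), beta = 0, se = 0.1, coverage = c(1, 1))
  expect_equal(nrow(study_coverage_filter(all1, 0.8)), 2L)
})

test_that("conditional_adjust zeroes leads, is identity for empty leads and identity LD", {
  ids <- sprintf("v%d", 1:5)
  tab <- make_table(ids, beta = c(0.5, 0.2, -0.1, 0.3, 0), se = 0.1)
  R <- diag(5); dimnames(R) <- list(ids, ids)
  ld <- ld_matrix(R)
  expect_identical(conditional_adjust(tab, ld, character()), tab)
  adj <- conditional_adjust(tab, ld, "v1")
  expect_equal(adj$beta[adj$id == "v1"], 0)
  expect_equal(adj$beta[adj$id != "v1"], tab$beta[tab$id != "v1"])
})

test_that("conditional_adjust matches an OLS residualisation oracle", {
  ids <- sprintf("v%d", 1:5)
  R <- outer(1:5, 1:5, function(i, j) 0.6^abs(i - j))
  dimnames(R) <- list(ids, ids)
  n <- 400
  X <- design_with_correlation(n, R, seed = 11)
  set.seed(12)
  y <- X %*% c(0.4, 0, 0, 0.2, 0) + rnorm(n)
  leads <- c("v1", "v4")
  S <- match(leads, ids)
  scale_c <- sqrt(n - 1)              # X_j' X_j = n - 1 exactly
  z_marg <- drop(crossprod(X, y)) / scale_c
  # oracle: cross-product of each variant with y residualised on the leads
  Xs <- X[, S, drop = FALSE]
  My <- y - Xs %*% solve(crossprod(Xs), crossprod(Xs, y))
  z_oracle <- drop(crossprod(X, My)) / scale_c
  se <- 0.05
  tab <- make_table(ids, beta = z_marg * se, se = se)
  adj <- conditional_adjust(tab, ld_matrix(R), leads)
  z_adj <- adj$beta / adj$se
  expect_equal(unname(z_adj[-S]), unname(z_oracle[-S]), tolerance = 1e-8)
  expect_equal(unname(z_adj[S]), c(0, 0))
})

test_that("conditional_adjust refuses collinear leads", {
  ids <- c("a", "b", "c")
  R <- matrix(c(1, 1, 0.2, 1, 1, 0.2, 0.2, 0.2, 1), 3, 3,
              dimnames = list(ids, ids))
  tab <- make_table(ids, beta = c(0.5, 0.5, 0.1), se = 0.1)
  expect_error(conditional_adjust(tab, ld_matrix(R), c("a", "b")),
               "singular|collinear")
})

test_that("synthetic records keep p consistent with |beta/se|", {
  panel <- simulate_panel(n_hap = 600, n_var = 40, seed = 5)
  d <- simulate_sumstats(panel, scenario("H4", causal1 = "snp20", seed = 5))
  for (tab in list(d$t1, d$t2)) {
    z_stored <- abs(tab$beta / tab$se)
    z_from_p <- qnorm(tab$p / 2, lower.tail = FALSE)
    keep <- is.finite(z_from_p) & z_stored > 0.1
    expect_lt(max(abs(z_from_p[keep] / z_stored[keep] - 1)), 0.1)
  }
})

test_that("write_sumstats round-trips through the fixed column order", {
  tab <- make_table(c("a", "b"), beta = c(0.123456, -0.2), se = 0.01)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- data.table::fread(path, data.table = FALSE)
  expect_identical(names(back),
                   c("ID", "CHR", "POS", "EA", "NEA", "EAF", "BETA", "SE",
                     "P", "N", "COVERAGE"))
  expect_equal(back$BETA, tab$beta)
})
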