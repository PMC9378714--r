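#' Simulate a reference genotype panel with block LD structure
#'
#' Haplotypes are generated blockwise by a first-order Markov copying
#' process: within a block, each haplotype copies its allele at the previous
#' variant with probability `rho` and otherwise draws a fresh allele at that
#' variant's frequency; blocks are independent. Diploid dosages are formed
#' by pairing consecutive haplotypes. Larger `rho` and longer blocks yield
#' stronger and longer-ranged LD, mimicking, at the two extremes, the long
#' LD blocks of European-ancestry panels and the shorter blocks of
#' African-ancestry panels.
#'
#' @param n_hap number of haplotypes (must be even; samples = `n_hap / 2`).
#' @param n_var number of variants.
#' @param block_len variants per LD block.
#' @param rho within-block copying probability in `[0, 1)`.
#' @param maf_range length-2 range in `(0, 0.5]` from which variant allele
#'   frequencies are drawn uniformly.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param chrom,start,spacing variant coordinates: ids are `snp<i>` placed
#'   at `start + (i-1) * spacing` on `chrom`.
#' @return A [genotype_panel()] whose `variants` data.frame (attribute
#'   `map`) holds `id`, `chrom`, `pos`, `ea`, `nea`.
#' @export
simulate_panel <- function(n_hap = 2000, n_var = 100, block_len = 20,
                           rho = 0.9, maf_range = c(0.05, 0.5), seed = 1,
                           chrom = "1", start = 1e6, spacing = 1000) {
  stopifnot(rho >= 0, rho < 1, n_hap %% 2 == 0)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("infeasible maf_range: must lie within (0, 0.5]")
  set.seed(seed)

  f <- stats::runif(n_var, maf_range[1], maf_range[2])
  block <- ((seq_len(n_var) - 1L) %/% block_len) + 1L
  H <- matrix(0L, nrow = n_hap, ncol = n_var)
  H[, 1] <- stats::rbinom(n_hap, 1L, f[1])
  for (j in 2:n_var) {
    fresh <- stats::rbinom(n_hap, 1L, f[j])
    if (block[j] == block[j - 1L]) {
      copy <- stats::runif(n_hap) < rho
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    } else {
      H[, j] <- fresh
    }
  }
  dos <- H[seq(1, n_hap, by = 2), ] + H[seq(2, n_hap, by = 2), ]

  ids <- sprintf("snp%d", seq_len(n_var))
  colnames(dos) <- ids
  panel <- genotype_panel(dos, variant_ids = ids)
  attr(panel, "map") <- data.frame(
    id = ids, chrom = chrom, pos = start + (seq_len(n_var) - 1L) * spacing,
    ea = "A", nea = "G", stringsAsFactors = FALSE)
  attr(panel, "seed") <- seed
  panel
}

#' Describe a causal-variant scenario
#'
#' Encodes one of the five regional hypotheses for a pair of traits:
#' H0 (neither trait has a signal), H1/H2 (one trait only), H3 (distinct
#' causal variants) and H4 (one shared causal variant).
#'
#' @param hypothesis `"H0"`, `"H1"`, `"H2"`, `"H3"` or `"H4"`.
#' @param causal1,causal2 causal variant id per trait (`NULL` for none;
#'   under H4 they must be identical, under H3 distinct).
#' @param ve1,ve2 per-variant variance explained by the causal variant for
#'   each trait (default 0.01).
#' @param n1,n2 sample size per trait (defaults 10000).
#' @param trait_type1,trait_type2 `"quantitative"` or `"binary"`.
#' @param case_fraction2 case fraction for a binary trait 2 (default 0.5).
#' @param seed integer seed.
#' @return A `coloc_scenario` list.
#' @export
scenario <- function(hypothesis = c("H4", "H0", "H1", "H2", "H3"),
                     causal1 = NULL, causal2 = NULL,
                     ve1 = 0.01, ve2 = 0.01, n1 = 10000, n2 = 10000,
                     trait_type1 = "quantitative", trait_type2 = "quantitative",
                     case_fraction2 = 0.5, seed = 1) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "H4") {
    if (is.null(causal1) && !is.null(causal2)) causal1 <- causal2
    if (is.null(causal2) && !is.null(causal1)) causal2 <- causal1
    if (!identical(causal1, causal2))
      stopf("H4 requires the identical causal variant for both traits")
  }
  if (hypothesis == "H3" && (is.null(causal1) || is.null(causal2) ||
                             identical(causal1, causal2)))
    stopf("H3 requires distinct causal variants for the two traits")
  if (hypothesis == "H0") causal1 <- causal2 <- NULL
  if (hypothesis == "H1") causal2 <- NULL
  if (hypothesis == "H2") causal1 <- NULL
  structure(list(hypothesis = hypothesis, causal1 = causal1, causal2 = causal2,
                 ve1 = ve1, ve2 = ve2, n1 = n1, n2 = n2,
                 trait_type1 = trait_type1, trait_type2 = trait_type2,
                 case_fraction2 = case_fraction2, seed = seed),
            class = "coloc_scenario")
}

# repair a correlation matrix to PSD by eigenvalue clipping
nearest_psd <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  message(sprintf("nearest_psd: clipping %d eigenvalue(s) below %g",
                  sum(e$values < eps), eps))
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  (R2 + t(R2)) / 2
}

# draw one marginal z vector: z ~ MVN(sqrt(n_eff) * R %*% lambda, R)
draw_z <- function(cholR, R, lambda, n_eff) {
  mu <- if (all(lambda == 0)) numeric(nrow(R)) else sqrt(n_eff) * drop(R %*% lambda)
  mu + drop(crossprod(cholR, stats::rnorm(nrow(R))))
}

# standardised joint-effect vector for one causal variant
lambda_for <- function(ids, causal, ve) {
  lam <- numeric(length(ids))
  if (!is.null(causal)) {
    if (!causal %in% ids) stopf("causal variant '%s' not in panel", causal)
    if (ve > 0.5) stopf("per-variant variance explained must be <= 0.5")
    lam[match(causal, ids)] <- sqrt(ve)
  }
  lam
}

#' Simulate regional GWAS summary statistics under a scenario
#'
#' Marginal z-scores are drawn jointly as `z ~ MVN(sqrt(n) R lambda, R)`
#' where `lambda` is the standardised joint-effect vector (so the causal
#' variant's expected `|z|` is `sqrt(n * ve)`) and `R` the panel LD matrix
#' (repaired to positive semi-definite by eigenvalue clipping when needed).
#' On the standardised quantitative scale `se = 1/sqrt(n)` exactly and
#' `beta = z * se`; binary traits use the effective sample size
#' `n * phi * (1 - phi)` with case fraction `phi`. P-values are two-sided
#' normal. The RNG stream is split per trait from the scenario seed and the
#' generator is bit-reproducible.
#'
#' @param panel a [simulate_panel()] result (or any [genotype_panel()] with
#'   a `map` attribute).
#' @param scen a [scenario()].
#' @return List with `t1`, `t2` ([sumstats_table()]s) and `truth` (manifest
#'   list: hypothesis, causal ids, seed, true Wald ratio where defined).
#' @export
simulate_sumstats <- function(panel, scen) {
  map <- attr(panel, "map")
  if (is.null(map)) stopf("panel carries no variant map")
  ids <- panel$variant_ids
  R <- compute_ld(panel)$r[ids, ids]
  R <- nearest_psd(R)
  cholR <- chol(R)

  eaf <- colMeans(panel$dosages, na.rm = TRUE) / 2

  one_trait <- function(label, causal, ve, n, trait_type, case_fraction, subseed) {
    set.seed(subseed)
    lam <- lambda_for(ids, causal, ve)
    n_eff <- if (trait_type == "binary") n * case_fraction * (1 - case_fraction) else n
    z <- draw_z(cholR, R, lam, n_eff)
    se <- rep(1 / sqrt(n_eff), length(ids))
    sumstats_table(data.frame(
      id = ids, chrom = map$chrom, pos = map$pos, ea = map$ea, nea = map$nea,
      eaf = eaf, beta = z * se, se = se, p = z_to_p(z), n = n,
      stringsAsFactors = FALSE),
      trait_label = label, trait_type = trait_type)
  }

  t1 <- one_trait("trait1", scen$causal1, scen$ve1, scen$n1, scen$trait_type1,
                  0.5, scen$seed * 2L + 11L)
  t2 <- one_trait("trait2", scen$causal2, scen$ve2, scen$n2, scen$trait_type2,
                  scen$case_fraction2, scen$seed * 2L + 12L)

  truth <- list(hypothesis = scen$hypothesis,
                causal1 = scen$causal1, causal2 = scen$causal2,
                ve1 = scen$ve1, ve2 = scen$ve2, n1 = scen$n1, n2 = scen$n2,
                seed = scen$seed,
                wald_ratio = if (scen$hypothesis == "H4" && scen$ve1 > 0)
                  sqrt(scen$ve2 / scen$ve1) else NA_real_)
  list(t1 = t1, t2 = t2, truth = truth)
}

#' Simulate the same locus in two ancestries with different LD
#'
#' Generates two independent panels over a shared variant catalogue — the
#' second with shorter LD blocks — and, for each ancestry, regional summary
#' statistics with the same causal variant. Emulates the situation where a
#' second ancestry with faster LD decay sharpens fine-mapping resolution.
#'
#' @param causal causal variant id (e.g. `"snp50"`).
#' @param n1,n2 GWAS sample size per ancestry (defaults 10000 and 2000).
#' @param ve variance explained by the causal variant (both ancestries).
#' @param n_var number of variants.
#' @param block_len1,block_len2 LD block lengths (ancestry 2 shorter).
#' @param rho1,rho2 copying probabilities.
#' @param n_hap1,n_hap2 haplotypes per panel.
#' @param seed integer seed.
#' @return List with `panel1`, `panel2`, `t1`, `t2` (one table per
#'   ancestry) and `truth`.
#' @export
simulate_two_ancestry <- function(causal = "snp50", n1 = 10000, n2 = 2000,
                                  ve = 0.01, n_var = 100,
                                  block_len1 = 20, block_len2 = 5,
                                  rho1 = 0.95, rho2 = 0.95,
                                  n_hap1 = 2000, n_hap2 = 2000, seed = 1) {
  panel1 <- simulate_panel(n_hap1, n_var, block_len1, rho1, seed = seed * 3L + 1L)
  panel2 <- simulate_panel(n_hap2, n_var, block_len2, rho2, seed = seed * 3L + 2L)
  s1 <- scenario("H1", causal1 = causal, ve1 = ve, n1 = n1, seed = seed * 3L + 3L)
  s2 <- scenario("H1", causal1 = causal, ve1 = ve, n1 = n2, seed = seed * 3L + 4L)
  d1 <- simulate_sumstats(panel1, s1)
  d2 <- simulate_sumstats(panel2, s2)
  list(panel1 = panel1, panel2 = panel2,
       t1 = d1$t1, t2 = d2$t1,
       truth = list(causal = causal, n1 = n1, n2 = n2, ve = ve, seed = seed))
}

#' Simulate a full protein-by-outcome screening data set
#'
#' Builds a multi-region catalogue (one region per protein, block-diagonal
#' LD) in which every protein has a strong cis signal, selected
#' protein-outcome pairs share that causal variant with the outcome (planted
#' H4), one pair may carry a distinct outcome signal in the same region
#' (planted H3), and all remaining regions are null for the outcomes. Used
#' to validate end-to-end screen behaviour against a known truth manifest.
#'
#' @param n_proteins number of protein regions (default 10).
#' @param n_outcomes number of outcome traits (default 2).
#' @param h4_pairs data.frame with columns `protein`, `outcome` (indices)
#'   naming planted shared-signal pairs.
#' @param h3_pairs same shape, planted distinct-signal pairs.
#' @param n_var,n,n_outcome,ve,block_len,rho,n_hap region and panel
#'   parameters: variants per region, protein GWAS sample size, outcome GWAS
#'   sample size (defaults to four times the protein study, reflecting that
#'   disease meta-analyses are far larger than proteomic GWAS), variance
#'   explained of planted signals, LD block length, copying probability,
#'   haplotypes.
#' @param seed integer seed.
#' @return List with `proteins` (list of tables), `outcomes` (list of
#'   tables), `panel`, `truth` (data.frame of planted pairs with causal
#'   ids).
#' @export
simulate_screen_dataset <- function(n_proteins = 10, n_outcomes = 2,
                                    h4_pairs = data.frame(protein = c(1, 2), outcome = c(1, 2)),
                                    h3_pairs = data.frame(protein = 3, outcome = 1),
                                    n_var = 80, n = 10000, n_outcome = 4 * n,
                                    ve = 0.01,
                                    block_len = 10, rho = 0.9, n_hap = 1000,
                                    seed = 1) {
  set.seed(seed)
  panels <- lapply(seq_len(n_proteins), function(i)
    simulate_panel(n_hap, n_var, block_len, rho, seed = seed * 101L + i,
                   chrom = "1", start = 1e6 + (i - 1) * 5e6))
  # region-unique ids
  for (i in seq_len(n_proteins)) {
    ids <- sprintf("r%d_%s", i, panels[[i]]$variant_ids)
    colnames(panels[[i]]$dosages) <- ids
    panels[[i]]$variant_ids <- ids
    m <- attr(panels[[i]], "map"); m$id <- ids; attr(panels[[i]], "map") <- m
  }
  # block-diagonal combined panel (independent regions)
  dos <- do.call(cbind, lapply(panels, function(p) p$dosages))
  panel <- genotype_panel(dos)
  attr(panel, "map") <- do.call(rbind, lapply(panels, function(p) attr(p, "map")))

  # choose causal variants: mid-region for the protein; for H3 the outcome
  # causal sits in a different LD block
  mid <- n_var %/% 2
  protein_causal <- sprintf("r%d_snp%d", seq_len(n_proteins), mid)

  key <- function(df) if (nrow(df)) paste(df$protein, df$outcome) else character()
  h4_key <- key(h4_pairs); h3_key <- key(h3_pairs)

  proteins <- vector("list", n_proteins)
  outcomes <- lapply(seq_len(n_outcomes), function(j) NULL)
  truth <- NULL
  outcome_parts <- rep(list(list()), n_outcomes)

  for (i in seq_len(n_proteins)) {
    ids <- panels[[i]]$variant_ids
    sc_seed <- seed * 977L + i * 13L
    # protein trait: always a cis signal at its causal variant
    for (j in seq_len(n_outcomes)) {
      pk <- paste(i, j)
      if (pk %in% h4_key) {
        sc <- scenario("H4", causal1 = protein_causal[i], ve1 = ve, ve2 = ve,
                       n1 = n, n2 = n_outcome, trait_type2 = "binary",
                       seed = sc_seed + j)
      } else if (pk %in% h3_key) {
        distinct <- sprintf("r%d_snp%d", i, min(n_var, mid + 3L * block_len))
        sc <- scenario("H3", causal1 = protein_causal[i], causal2 = distinct,
                       ve1 = ve, ve2 = ve, n1 = n, n2 = n_outcome,
                       trait_type2 = "binary", seed = sc_seed + j)
      } else {
        sc <- scenario("H1", causal1 = protein_causal[i], ve1 = ve,
                       n1 = n, n2 = n_outcome, trait_type2 = "binary",
                       seed = sc_seed + j)
      }
      d <- simulate_sumstats(panels[[i]], sc)
      if (j == 1L) {
        p_tab <- d$t1
        attr(p_tab, "trait_label") <- sprintf("protein%d", i)
        proteins[[i]] <- p_tab
      }
      o_tab <- d$t2
      outcome_parts[[j]][[i]] <- as.data.frame(o_tab)
      truth <- rbind(truth, data.frame(
        protein = i, outcome = j, hypothesis = sc$hypothesis,
        causal1 = sc$causal1 %||% NA_character_,
        causal2 = sc$causal2 %||% NA_character_))
    }
  }
  outcomes <- lapply(seq_len(n_outcomes), function(j)
    sumstats_table(do.call(rbind, outcome_parts[[j]]),
                   trait_label = sprintf("outcome%d", j), trait_type = "binary"))
  names(proteins) <- sprintf("protein%d", seq_len(n_proteins))
  names(outcomes) <- sprintf("outcome%d", seq_len(n_outcomes))
  list(proteins = proteins, outcomes = outcomes, panel = panel,
       truth = truth, protein_causal = protein_causal,
       anchors = stats::setNames(
         lapply(seq_len(n_proteins), function(i) {
           m <- attr(panels[[i]], "map")
           list(start = min(m$pos), end = max(m$pos))
         }), names(proteins)))
}
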