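#' Default configuration of the colocalisation-first screen
#'
#' All thresholds used by [run_screen()]: the cis window flank, the
#' suggestive-evidence prefilter, the colocalisation priors, the PP(H4)
#' candidate threshold, the LD guard threshold, the study-coverage filter
#' and the tier significance bounds.
#'
#' @param window cis flank in bp around the protein-coding gene (5e5).
#' @param p_sug suggestive-evidence prefilter (1e-5, strict `<`).
#' @param priors a [coloc_priors()].
#' @param pp_min candidate threshold on PP(H4) (0.8, strict `>`).
#' @param r2_min LD guard threshold (0.8, strict `>`).
#' @param coverage minimum study-coverage fraction (0.8).
#' @param gw genome-wide significance bound (5e-8, strict `<`).
#' @param sug suggestive tier bound (1e-4, strict `<`).
#' @param weak_z weak-instrument flag threshold.
#' @return Named list of settings.
#' @export
screen_config <- function(window = 5e5, p_sug = 1e-5, priors = coloc_priors(),
                          pp_min = 0.8, r2_min = 0.8, coverage = 0.8,
                          gw = 5e-8, sug = 1e-4, weak_z = 4) {
  list(window = window, p_sug = p_sug, priors = priors, pp_min = pp_min,
       r2_min = r2_min, coverage = coverage, gw = gw, sug = sug,
       weak_z = weak_z)
}

#' Suggestive-evidence prefilter for a trait pair
#'
#' A region is tested only when at least one of the two traits shows
#' suggestive evidence, i.e. its regional minimum p-value is strictly below
#' `p_sug`.
#'
#' @param t1,t2 harmonised [sumstats_table()]s.
#' @param p_sug threshold (default 1e-5).
#' @return Logical scalar.
#' @export
prefilter <- function(t1, t2, p_sug = 1e-5) {
  min(t1$p, na.rm = TRUE) < p_sug || min(t2$p, na.rm = TRUE) < p_sug
}

#' Three-tier candidate significance classification
#'
#' Tier 1: genome-wide significant (`p < gw`) in both the protein and the
#' outcome statistics. Tier 2: genome-wide significant in exactly one of the
#' two. Tier 3: suggestive, with both p-values strictly between `gw` and
#' `sug`. All inequalities strict; a pair fitting none of the three rules
#' (e.g. one p in `[sug, 1]` without genome-wide significance on the other
#' side) returns `NA` and is flagged by the caller.
#'
#' @param p_protein,p_outcome regional p-values for the two traits.
#' @param gw genome-wide threshold (default 5e-8).
#' @param sug suggestive bound (default 1e-4).
#' @return Integer tier 1, 2, 3, or `NA_integer_`.
#' @export
classify_tier <- function(p_protein, p_outcome, gw = 5e-8, sug = 1e-4) {
  stopifnot(length(p_protein) == 1L, length(p_outcome) == 1L)
  gw1 <- p_protein < gw
  gw2 <- p_outcome < gw
  if (gw1 && gw2) return(1L)
  if (xor(gw1, gw2)) return(2L)
  sub1 <- p_protein > gw & p_protein < sug
  sub2 <- p_outcome > gw & p_outcome < sug
  if (sub1 && sub2) return(3L)
  NA_integer_
}

#' Run the proteome-wide colocalisation-first screen
#'
#' For every protein-outcome pair: extract the cis window around the
#' protein's gene anchor, harmonise the two tables, apply the
#' study-coverage filter to the outcome statistics, apply the
#' suggestive-evidence prefilter, colocalise, and apply the two robustness
#' guards (lead cis-pQTL representation and sentinel LD concordance). Pairs
#' with `PP(H4) > pp_min` and both guards passing are classified into tiers
#' and receive a Wald-ratio Mendelian-randomisation estimate using the lead
#' cis-pQTL (the variant most strongly associated with the protein among
#' shared variants) as instrument. Per-pair failures are logged and
#' skipped, never fatal to the whole screen.
#'
#' @param protein_tables named list of protein [sumstats_table()]s.
#' @param outcome_tables named list of outcome [sumstats_table()]s.
#' @param panel a [genotype_panel()] covering the regional variants (used
#'   for the LD guards).
#' @param config a [screen_config()].
#' @param anchors named list (by protein) of gene anchors for
#'   [extract_region()]; `NULL` uses each protein table's full span.
#' @return List with `candidates` (data.frame, one row per emitted
#'   candidate, ordered by decreasing `|ratio|`), `log` (data.frame of
#'   per-pair dispositions) and `results` (full `coloc_result`s for
#'   candidates).
#' @export
run_screen <- function(protein_tables, outcome_tables, panel,
                       config = screen_config(), anchors = NULL) {
  stopifnot(length(protein_tables) > 0, length(outcome_tables) > 0)
  if (is.null(names(protein_tables)))
    names(protein_tables) <- paste0("protein", seq_along(protein_tables))
  if (is.null(names(outcome_tables)))
    names(outcome_tables) <- paste0("outcome", seq_along(outcome_tables))

  log_rows <- list()
  cand_rows <- list()
  results <- list()

  for (pn in names(protein_tables)) {
    pt_full <- protein_tables[[pn]]
    anchor <- if (!is.null(anchors)) anchors[[pn]] else
      list(start = min(pt_full$pos), end = max(pt_full$pos))
    pt <- extract_region(pt_full, anchor, flank = config$window)
    for (on in names(outcome_tables)) {
      disposition <- tryCatch({
        ot_full <- outcome_tables[[on]]
        if (nrow(ot_full) == 0L) stop("empty outcome table")
        ot <- extract_region(ot_full, anchor, flank = config$window)
        if (nrow(pt) == 0L || nrow(ot) == 0L) stop("empty regional table")
        ot <- study_coverage_filter(ot, config$coverage)
        h <- harmonise_pair(pt, ot)
        if (!prefilter(h$t1, h$t2, config$p_sug)) {
          "prefilter"
        } else {
          ab1 <- abf_vector(h$t1)
          ab2 <- abf_vector(h$t2)
          res <- coloc(ab1, ab2, config$priors)
          ld <- suppressWarnings(compute_ld(panel, intersect(panel$variant_ids, pt$id)))
          lead <- sentinel_of(ab1)  # lead cis-pQTL among shared variants
          rep_ok <- instrument_represented(lead, h$t1$id, ld, config$r2_min)
          sen_ok <- sentinel_concordance(res, ld, config$r2_min)
          res$filter_flags <- list(instrument_represented = rep_ok,
                                   sentinel_ld_pass = sen_ok)
          if (res$pp["PP.H4"] <= config$pp_min) {
            "pp_below_threshold"
          } else if (!rep_ok) {
            "instrument_not_represented"
          } else if (!sen_ok) {
            "sentinel_discordant"
          } else {
            i1 <- match(lead, h$t1$id)
            tier <- classify_tier(min(h$t1$p), min(h$t2$p), config$gw, config$sug)
            if (is.na(tier)) {
              "tier_undefined"
            } else {
              wl <- withCallingHandlers(
                wald_ratio(h$t1$beta[i1], h$t1$se[i1],
                           h$t2$beta[i1], h$t2$se[i1], weak_z = config$weak_z),
                warning = function(w) invokeRestart("muffleWarning"))
              sen_r2 <- r2(ld, res$sentinel1, res$sentinel2)
              cand_rows[[length(cand_rows) + 1L]] <- data.frame(
                protein = pn, outcome = on, tier = tier,
                pp_h3 = unname(res$pp["PP.H3"]), pp_h4 = unname(res$pp["PP.H4"]),
                sentinel_protein = res$sentinel1, sentinel_outcome = res$sentinel2,
                sentinel_r2 = sen_r2,
                rsid = lead, ea = h$t1$ea[i1], nea = h$t1$nea[i1],
                eaf = h$t1$eaf[i1],
                beta_protein = h$t1$beta[i1], se_protein = h$t1$se[i1],
                p_protein = h$t1$p[i1],
                beta_outcome = h$t2$beta[i1], se_outcome = h$t2$se[i1],
                p_outcome = h$t2$p[i1],
                wald_ratio = wl$ratio, wald_se = wl$se, or_ = wl$or_,
                ci_low = wl$ci_low, ci_high = wl$ci_high, wald_p = wl$p,
                weak_instrument = wl$weak_instrument,
                stringsAsFactors = FALSE)
              results[[paste(pn, on, sep = ":")]] <- res
              "candidate"
            }
          }
        }
      }, error = function(e) paste0("error: ", conditionMessage(e)))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        protein = pn, outcome = on, disposition = disposition,
        stringsAsFactors = FALSE)
    }
  }

  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(protein = character(), outcome = character(), tier = integer(),
               pp_h3 = numeric(), pp_h4 = numeric(),
               sentinel_protein = character(), sentinel_outcome = character(),
               sentinel_r2 = numeric(), rsid = character(), ea = character(),
               nea = character(), eaf = numeric(), beta_protein = numeric(),
               se_protein = numeric(), p_protein = numeric(),
               beta_outcome = numeric(), se_outcome = numeric(),
               p_outcome = numeric(), wald_ratio = numeric(),
               wald_se = numeric(), or_ = numeric(), ci_low = numeric(),
               ci_high = numeric(), wald_p = numeric(),
               weak_instrument = logical(), stringsAsFactors = FALSE)
  if (nrow(candidates)) {
    candidates <- candidates[order(-abs(candidates$wald_ratio),
                                   candidates$protein, candidates$outcome), ]
    rownames(candidates) <- NULL
    stopifnot(all(candidates$pp_h4 > config$pp_min),
              !anyNA(candidates$tier))
  }
  list(candidates = candidates,
       log = do.call(rbind, log_rows),
       results = results)
}

#' Write screen results to TSV and JSON
#'
#' The TSV mirrors the candidate-table logic of a published prioritisation
#' summary (tier, PP(H3)/PP(H4), sentinel LD, instrument rsid, alleles, EAF,
#' per-trait effects/SEs/p-values, MR estimate); the JSON carries the full
#' colocalisation results. Ordering is deterministic (as returned by
#' [run_screen()]).
#'
#' @param screen result of [run_screen()].
#' @param tsv_path,json_path output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_report <- function(screen, tsv_path, json_path) {
  for (p in c(tsv_path, json_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) stopf("output directory does not exist: %s", d)
  }
  data.table::fwrite(screen$candidates, tsv_path, sep = "\t", quote = FALSE,
                     na = "NA")
  full <- lapply(names(screen$results), function(k) {
    r <- screen$results[[k]]
    list(pair = k, pp = as.list(r$pp),
         sentinel1 = r$sentinel1, sentinel2 = r$sentinel2,
         n_snps = r$n_snps, filter_flags = r$filter_flags,
         per_snp_h4 = as.list(r$per_snp_h4))
  })
  jsonlite::write_json(full, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(tsv = tsv_path, json = json_path))
}
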