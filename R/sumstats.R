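#' Regional GWAS summary statistics
#'
#' A `sumstats_table` is a `data.frame` of per-variant association records for
#' one trait in one genomic region, with columns `id`, `chrom`, `pos`, `ea`,
#' `nea`, `eaf`, `beta`, `se`, `p`, `n`, `coverage`, sorted by position, plus
#' attributes `trait_label`, `trait_type` (`"quantitative"` or `"binary"`) and
#' an optional `region` (list with `chrom`, `start`, `end`, `anchor`).
#'
#' Coordinates are 1-based and inclusive at both ends. Effects (`beta`) are on
#' the standardised scale for quantitative traits and on the log-odds scale
#' for binary traits. `coverage` is the fraction of contributing studies in a
#' meta-analysis that report the variant; `NA` means no meta-analysis
#' structure and is treated as full coverage downstream.
#'
#' @param df data.frame holding the columns above (`coverage` optional).
#' @param trait_label character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param region optional list with `chrom`, `start`, `end` and optionally
#'   `anchor` (gene label or centre position).
#' @return A validated `sumstats_table`.
#' @export
sumstats_table <- function(df, trait_label, trait_type = c("quantitative", "binary"),
                           region = NULL) {
  trait_type <- match.arg(trait_type)
  required <- c("id", "chrom", "pos", "ea", "nea", "eaf", "beta", "se", "p", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  if (!"coverage" %in% names(df)) df$coverage <- NA_real_
  df <- as.data.frame(df)[, c(required, "coverage")]
  df$ea <- toupper(as.character(df$ea))
  df$nea <- toupper(as.character(df$nea))
  if (anyDuplicated(df$id))
    stopf("duplicate variant ids: %s",
          paste(utils::head(unique(df$id[duplicated(df$id)]), 3L), collapse = ", "))
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            trait_label = trait_label,
            trait_type = trait_type,
            region = region,
            class = c("sumstats_table", "data.frame"))
}

#' @export
print.sumstats_table <- function(x, ...) {
  cat(sprintf("sumstats_table: %s (%s), %d variants\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  r <- attr(x, "region")
  if (!is.null(r))
    cat(sprintf("  region %s:%d-%d\n", r$chrom, r$start, r$end))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# rebuild a table from a subset of rows, keeping metadata
rebuild_sumstats <- function(df, template, region = attr(template, "region")) {
  sumstats_table(df,
                 trait_label = attr(template, "trait_label"),
                 trait_type = attr(template, "trait_type"),
                 region = region)
}

#' Column-map presets for common summary-statistics dialects
#'
#' Returns a named list mapping the standard internal field names to the
#' column headers of a known source file format. `"covid_hgi_r6"` covers the
#' COVID-19 Host Genetics Initiative release-6 meta-analysis files;
#' `"pgwas"` covers plasma-proteome GWAS regional files.
#'
#' @param preset `"covid_hgi_r6"` or `"pgwas"`.
#' @return Named character vector usable as `column_map` in [read_sumstats()].
#' @export
column_preset <- function(preset = c("covid_hgi_r6", "pgwas")) {
  preset <- match.arg(preset)
  switch(preset,
    covid_hgi_r6 = c(
      id = "rsid", chrom = "#CHR", pos = "POS", ea = "ALT", nea = "REF",
      eaf = "all_meta_AF", beta = "all_inv_var_meta_beta",
      se = "all_inv_var_meta_sebeta", p = "all_inv_var_meta_p",
      n = "all_inv_var_meta_effective", coverage = "study_coverage"),
    pgwas = c(
      id = "rsid", chrom = "chr", pos = "pos", ea = "effect_allele",
      nea = "other_allele", eaf = "eaf", beta = "beta", se = "se",
      p = "pval", n = "n"))
}

#' Read and validate GWAS summary statistics
#'
#' Reads a delimited (optionally gzip-compressed) summary-statistics file,
#' renames columns through `column_map`, uppercases alleles, and drops rows
#' with non-ACGT alleles or non-positive standard errors (the number dropped
#' is reported). A consistency check compares each row's p-value with the
#' two-sided normal p implied by `beta/se`; disagreement beyond a factor of
#' ten raises a warning (not an error), as meta-analysis p-values may come
#' from heterogeneity-adjusted tests.
#'
#' @param path file path (TSV/whitespace-delimited; `.gz` allowed).
#' @param trait_label trait name stored on the result.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param column_map named character vector mapping internal field names
#'   (`id`, `chrom`, `pos`, `ea`, `nea`, `eaf`, `beta`, `se`, `p`, `n`,
#'   optionally `coverage`) to the file's column headers; see
#'   [column_preset()]. Fields already matching internal names may be omitted.
#' @return A [sumstats_table()].
#' @export
read_sumstats <- function(path, trait_label, trait_type = "quantitative",
                          column_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  required <- c("id", "chrom", "pos", "ea", "nea", "eaf", "beta", "se", "p", "n")
  if (!is.null(column_map)) {
    for (field in names(column_map)) {
      src <- column_map[[field]]
      if (!src %in% names(dt)) {
        if (field == "coverage") next  # optional
        stopf("column '%s' (mapped to field '%s') absent from %s", src, field, path)
      }
      names(dt)[names(dt) == src] <- field
    }
  }
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))

  dt$ea <- toupper(as.character(dt$ea))
  dt$nea <- toupper(as.character(dt$nea))
  ok <- dt$ea %in% c("A", "C", "G", "T") & dt$nea %in% c("A", "C", "G", "T") &
    dt$ea != dt$nea & is.finite(dt$se) & dt$se > 0
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("read_sumstats: dropped %d row(s) with invalid alleles or se <= 0", n_drop))
  dt <- dt[ok, , drop = FALSE]
  if (nrow(dt) == 0L) stopf("zero valid rows in %s", path)

  # p vs z consistency: warn when off by more than a factor of 10
  z_implied <- abs(dt$beta / dt$se)
  p_implied <- z_to_p(z_implied)
  bad <- is.finite(dt$p) & dt$p > 0 & p_implied > 0 &
    abs(log10(dt$p) - log10(p_implied)) > 1
  if (any(bad))
    warnf("%d row(s) have p-values inconsistent with beta/se beyond a factor of 10",
          sum(bad))
  sumstats_table(dt, trait_label = trait_label, trait_type = trait_type)
}

#' Extract a flanked region around an anchor
#'
#' Keeps records with `anchor_start - flank <= pos <= anchor_end + flank`,
#' boundaries inclusive (the convention used for cis windows around a
#' protein-coding gene; default flank 500 kb).
#'
#' @param table a [sumstats_table()].
#' @param anchor either a single position, a length-2 numeric
#'   `c(start, end)` interval, or a list with `start`, `end` and optionally
#'   `chrom`/`label`.
#' @param flank non-negative flank in base pairs (default `5e5`).
#' @return A `sumstats_table` restricted to the window (possibly empty).
#' @export
extract_region <- function(table, anchor, flank = 5e5) {
  stopifnot(flank >= 0)
  if (is.list(anchor)) {
    a_start <- anchor$start; a_end <- anchor$end
  } else if (length(anchor) == 2L) {
    a_start <- anchor[1]; a_end <- anchor[2]
  } else {
    a_start <- a_end <- anchor
  }
  if (a_start > a_end) stopf("anchor start > end")
  lo <- a_start - flank
  hi <- a_end + flank
  keep <- table$pos >= lo & table$pos <= hi
  region <- list(chrom = if (nrow(table)) table$chrom[1] else NA,
                 start = lo, end = hi, anchor = anchor)
  rebuild_sumstats(as.data.frame(table)[keep, , drop = FALSE], table, region = region)
}

#' Harmonise two summary-statistics tables onto a shared variant set
#'
#' Intersects both tables on variant id; where the second table's effect and
#' other alleles are swapped relative to the first, its `beta` changes sign
#' and `eaf` becomes `1 - eaf`. Variants whose allele pairs are incompatible
#' are dropped. Strand-ambiguous (palindromic) A/T and C/G variants are
#' dropped when both tables carry an allele frequency and the minor-allele
#' frequency lies inside `drop_palindromic_maf_band` (no strand-flip rescue
#' is attempted: both exact and swapped pairs are assumed forward-strand).
#'
#' @param t1,t2 [sumstats_table()] objects.
#' @param drop_palindromic_maf_band length-2 numeric MAF band inside which
#'   palindromic variants are removed (default `c(0.40, 0.50)`); `NULL`
#'   disables the rule.
#' @return List with elements `t1` and `t2`, identical variant order.
#' @export
harmonise_pair <- function(t1, t2, drop_palindromic_maf_band = c(0.40, 0.50)) {
  if (nrow(t1) == 0L || nrow(t2) == 0L) stopf("cannot harmonise empty tables")
  shared <- intersect(t1$id, t2$id)
  d1 <- as.data.frame(t1)[match(shared, t1$id), , drop = FALSE]
  d2 <- as.data.frame(t2)[match(shared, t2$id), , drop = FALSE]

  exact <- d1$ea == d2$ea & d1$nea == d2$nea
  swapped <- d1$ea == d2$nea & d1$nea == d2$ea & !exact
  keep <- exact | swapped

  if (any(swapped)) {
    d2$beta[swapped] <- -d2$beta[swapped]
    d2$eaf[swapped] <- 1 - d2$eaf[swapped]
    tmp <- d2$ea[swapped]
    d2$ea[swapped] <- d2$nea[swapped]
    d2$nea[swapped] <- tmp
  }

  if (!is.null(drop_palindromic_maf_band)) {
    pal <- (d1$ea == "A" & d1$nea == "T") | (d1$ea == "T" & d1$nea == "A") |
           (d1$ea == "C" & d1$nea == "G") | (d1$ea == "G" & d1$nea == "C")
    have_eaf <- is.finite(d1$eaf) & is.finite(d2$eaf)
    maf1 <- pmin(d1$eaf, 1 - d1$eaf)
    maf2 <- pmin(d2$eaf, 1 - d2$eaf)
    band <- drop_palindromic_maf_band
    in_band <- (maf1 >= band[1] & maf1 <= band[2]) |
               (maf2 >= band[1] & maf2 <= band[2])
    keep <- keep & !(pal & have_eaf & in_band)
  }

  d1 <- d1[keep, , drop = FALSE]
  d2 <- d2[keep, , drop = FALSE]
  if (nrow(d1) == 0L) stopf("empty intersection after harmonisation")
  ord <- order(d1$pos)
  list(t1 = rebuild_sumstats(d1[ord, ], t1),
       t2 = rebuild_sumstats(d2[ord, ], t2))
}

#' Filter on meta-analysis study coverage
#'
#' Drops records reported by fewer than `min_fraction` of the contributing
#' studies. Records with missing coverage are retained (single-cohort data
#' carry no meta-analysis coverage).
#'
#' @param table a [sumstats_table()].
#' @param min_fraction minimum coverage fraction in `[0, 1]` (default 0.8).
#' @return Filtered `sumstats_table`.
#' @export
study_coverage_filter <- function(table, min_fraction = 0.8) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  keep <- is.na(table$coverage) | table$coverage >= min_fraction
  rebuild_sumstats(as.data.frame(table)[keep, , drop = FALSE], table)
}

#' Approximate conditional adjustment on lead signals
#'
#' Adjusts regional z-scores for a set of independent lead variants using the
#' summary-statistics conditional decomposition
#' \deqn{z'_j = z_j - R_{jS} R_{SS}^{-1} z_S}
#' where \eqn{S} is the lead set and \eqn{R} the LD (correlation) matrix.
#' Adjusted effects are reconstructed as `z' * se` with standard errors kept
#' fixed (a first-order approximation); the lead variants themselves obtain
#' `z' = 0`. P-values are recomputed from the adjusted z.
#'
#' @param table a [sumstats_table()].
#' @param ld an [ld_matrix()] covering the table's variants.
#' @param lead_ids character vector of lead variant ids to condition on;
#'   empty vector returns the table unchanged.
#' @param max_condition maximum allowed condition number of the lead LD
#'   submatrix (default `1e8`); beyond it the leads are declared collinear.
#' @return Adjusted `sumstats_table`.
#' @export
conditional_adjust <- function(table, ld, lead_ids, max_condition = 1e8) {
  if (length(lead_ids) == 0L) return(table)
  if (!all(lead_ids %in% table$id))
    stopf("lead id(s) absent from table: %s",
          paste(setdiff(lead_ids, table$id), collapse = ", "))
  if (!all(lead_ids %in% ld$ids))
    stopf("lead id(s) absent from LD matrix: %s",
          paste(setdiff(lead_ids, ld$ids), collapse = ", "))
  ids <- table$id
  common <- ids[ids %in% ld$ids]
  if (!all(ids %in% ld$ids))
    warnf("%d variant(s) not in LD matrix are left unadjusted", sum(!ids %in% ld$ids))

  R <- ld$r[common, common, drop = FALSE]
  z <- table$beta / table$se
  names(z) <- ids

  Rss <- R[lead_ids, lead_ids, drop = FALSE]
  kap <- kappa(Rss, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stopf("lead LD submatrix is singular or near-singular (condition number %.3g); collinear leads: %s",
          kap, paste(lead_ids, collapse = ", "))
  zS <- z[lead_ids]
  adj <- drop(R[, lead_ids, drop = FALSE] %*% solve(Rss, zS))
  z_new <- z
  z_new[common] <- z[common] - adj[common]
  z_new[lead_ids] <- 0

  df <- as.data.frame(table)
  df$beta <- unname(z_new * df$se)
  df$p <- z_to_p(z_new)
  rebuild_sumstats(df, table)
}

#' Write a harmonised regional table as TSV
#'
#' Fixed column order `ID CHR POS EA NEA EAF BETA SE P N COVERAGE`.
#'
#' @param table a [sumstats_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  out <- data.frame(ID = table$id, CHR = table$chrom, POS = table$pos,
                    EA = table$ea, NEA = table$nea, EAF = table$eaf,
                    BETA = table$beta, SE = table$se, P = table$p,
                    N = table$n, COVERAGE = table$coverage)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
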