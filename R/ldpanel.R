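#' Reference genotype panel
#'
#' Wraps a samples-by-variants dosage matrix (entries in `[0, 2]`, `NA`
#' allowed) with sample and variant identifiers. Stands in for an external
#' LD reference such as a cohort subset or a 1000 Genomes ancestry panel.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variant_ids character vector of variant ids (defaults to column
#'   names of `dosages`).
#' @param sample_ids optional sample identifiers.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(dosages, variant_ids = colnames(dosages),
                           sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(variant_ids)) stopf("variant ids required")
  if (length(variant_ids) != ncol(dosages))
    stopf("variant_ids length (%d) != number of dosage columns (%d)",
          length(variant_ids), ncol(dosages))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stopf("dosages must lie in [0, 2]")
  miss <- colMeans(is.na(dosages))
  if (any(miss > 0.10))
    stopf("%d variant(s) exceed 10%% missingness; clean the panel first",
          sum(miss > 0.10))
  colnames(dosages) <- variant_ids
  structure(list(dosages = dosages,
                 variant_ids = variant_ids,
                 sample_ids = sample_ids %||% paste0("S", seq_len(nrow(dosages)))),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants\n",
              nrow(x$dosages), length(x$variant_ids)))
  invisible(x)
}

#' Read a genotype panel from a dosage TSV or a VCF
#'
#' TSV input holds one variant per column (header = variant ids) and one
#' sample per row. VCF input (requires the `vcfR` package) converts GT fields
#' to alternate-allele dosage; variant ids are taken from the ID column,
#' falling back to `chrom:pos:ref:alt`.
#'
#' @param path file path (`.tsv`/`.txt`, optionally gzipped, or `.vcf`[.gz]).
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stopf("reading VCF panels requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
    fix <- vcfR::getFIX(v)
    ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":"),
                  fix[, "ID"])
    genotype_panel(t(dos), variant_ids = unname(ids))
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    genotype_panel(as.matrix(dt))
  }
}

#' Pairwise LD matrix
#'
#' Container for the symmetric matrix of Pearson correlations `r` between
#' variant dosages, with unit diagonal.
#'
#' @param r symmetric correlation matrix with dimnames set to variant ids.
#' @return An `ld_matrix` object with fields `ids` and `r`.
#' @export
ld_matrix <- function(r) {
  r <- as.matrix(r)
  if (is.null(rownames(r))) stopf("LD matrix needs variant ids as dimnames")
  if (max(abs(r - t(r))) > 1e-12) stopf("LD matrix not symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stopf("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-12) stopf("|r| must be <= 1")
  structure(list(ids = rownames(r), r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d variants\n", length(x$ids)))
  invisible(x)
}

#' Compute LD from a genotype panel
#'
#' Pearson correlation of dosages with pairwise-complete handling of missing
#' genotypes. Zero-variance variants are excluded with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param variant_ids variants to include (default: all in the panel).
#' @return An [ld_matrix()].
#' @export
compute_ld <- function(panel, variant_ids = panel$variant_ids) {
  missing_ids <- setdiff(variant_ids, panel$variant_ids)
  if (length(missing_ids))
    stopf("variant(s) absent from panel: %s",
          paste(utils::head(missing_ids, 5L), collapse = ", "))
  X <- panel$dosages[, variant_ids, drop = FALSE]
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  zero <- !is.finite(v) | v == 0
  if (any(zero)) {
    warnf("excluding %d zero-variance variant(s): %s", sum(zero),
          paste(utils::head(variant_ids[zero], 5L), collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  if (ncol(X) == 0L) stopf("no variants with positive variance")
  r <- stats::cor(X, use = "pairwise.complete.obs")
  r[r > 1] <- 1; r[r < -1] <- -1
  r <- (r + t(r)) / 2
  diag(r) <- 1
  ld_matrix(r)
}

#' Squared LD between two variants
#'
#' @param ld an [ld_matrix()].
#' @param id1,id2 variant ids present in `ld`.
#' @return `r^2` in `[0, 1]`.
#' @export
r2 <- function(ld, id1, id2) {
  for (id in c(id1, id2))
    if (!id %in% ld$ids) stopf("variant '%s' not in LD matrix", id)
  unname(ld$r[id1, id2]^2)
}

#' Find LD proxies of a variant
#'
#' Returns all variants with `r^2` strictly greater than `r2_min` with the
#' query (the query itself excluded), sorted by descending `r^2`.
#'
#' @param ld an [ld_matrix()].
#' @param id query variant id.
#' @param r2_min strict lower `r^2` bound in `(0, 1]` (default 0.8).
#' @return data.frame with columns `id`, `r2`.
#' @export
find_proxies <- function(ld, id, r2_min = 0.8) {
  if (!id %in% ld$ids) stopf("variant '%s' not in LD matrix", id)
  stopifnot(r2_min > 0, r2_min <= 1)
  rr <- ld$r[id, ]^2
  rr <- rr[names(rr) != id]
  hit <- rr > r2_min
  out <- data.frame(id = names(rr)[hit], r2 = unname(rr[hit]))
  out[order(-out$r2, out$id), , drop = FALSE]
}
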