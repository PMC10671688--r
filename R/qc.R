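#' QC configuration
#'
#' Marker and sample filter thresholds. Exclusion is strict: individuals are
#' removed when missingness is *greater than* `max_individual_missing`; SNPs
#' are removed when call rate, MAF or HWE p-value is *below* the respective
#' threshold. Values exactly at a threshold are retained.
#'
#' @param autosome_max largest chromosome code treated as autosomal
#'   (26 for sheep)
#' @param max_individual_missing maximum tolerated per-individual missing
#'   fraction
#' @param min_snp_call_rate minimum per-SNP call rate
#' @param min_maf minimum minor allele frequency
#' @param hwe_alpha minimum exact Hardy-Weinberg p-value
#' @param hwe_midp use the mid-p variant of the exact test
#' @return a `qc_config` list
#' @export
qc_config <- function(autosome_max = 26, max_individual_missing = 0.10,
                      min_snp_call_rate = 0.90, min_maf = 0.05,
                      hwe_alpha = 1e-4, hwe_midp = FALSE) {
  fr <- c(max_individual_missing, min_snp_call_rate, min_maf, hwe_alpha)
  if (any(fr < 0 | fr > 1)) stop("QC fractions must lie in [0, 1]")
  structure(list(autosome_max = autosome_max,
                 max_individual_missing = max_individual_missing,
                 min_snp_call_rate = min_snp_call_rate,
                 min_maf = min_maf, hwe_alpha = hwe_alpha,
                 hwe_midp = hwe_midp),
            class = "qc_config")
}

#' Restrict a dataset to autosomal SNPs
#'
#' @param ds a [genotype_dataset()]
#' @param autosome_max largest autosomal chromosome code
#' @return the dataset with only SNPs on chromosomes `1..autosome_max`,
#'   column order preserved
#' @export
filter_autosomes <- function(ds, autosome_max = 26) {
  keep <- ds$snps$chr >= 1 & ds$snps$chr <= autosome_max
  if (!any(keep)) message("filter_autosomes: no autosomal SNPs retained")
  subset_dataset(ds, snps = keep)
}

#' Per-SNP call rate
#'
#' @param calls one SNP's calls (a column of the call matrix)
#' @return fraction of non-missing calls, in \[0, 1\]
#' @export
snp_call_rate <- function(calls) {
  if (length(calls) == 0) stop("empty call column")
  mean(!is.na(calls))
}

#' Per-individual missingness
#'
#' @param calls one individual's calls (a row of the call matrix)
#' @return fraction of missing calls, in \[0, 1\]
#' @export
individual_missingness <- function(calls) {
  if (length(calls) == 0) stop("empty call row")
  mean(is.na(calls))
}

#' Minor allele frequency from genotype counts
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (missing excluded);
#'   vectors recycle together
#' @return `min(p, 1 - p)` where `p` is the reference-allele frequency;
#'   in \[0, 0.5\]
#' @export
minor_allele_freq <- function(n_hom_ref, n_het, n_hom_alt) {
  total <- n_hom_ref + n_het + n_hom_alt
  if (any(total < 1)) stop("MAF undefined for an all-missing SNP")
  p <- (2 * n_hom_ref + n_het) / (2 * total)
  pmin(p, 1 - p)
}

genotype_counts <- function(calls) {
  # columns: n_hom_ref, n_het, n_hom_alt for each SNP
  cbind(colSums(calls == HOM_REF, na.rm = TRUE),
        colSums(calls == HET, na.rm = TRUE),
        colSums(calls == HOM_ALT, na.rm = TRUE))
}

#' Apply the full QC filter cascade
#'
#' Filters are applied in a fixed order, each computed on the data surviving
#' the previous steps: (1) autosome restriction, (2) individual missingness,
#' (3) SNP call rate, (4) minor allele frequency, (5) exact HWE. Sample
#' filters run before the SNP frequency filters because high-missingness
#' individuals distort MAF and HWE. A SNP left with zero non-missing calls
#' at step 4 (possible only when `min_snp_call_rate = 0`) is treated as
#' MAF 0.
#'
#' @param ds a [genotype_dataset()]
#' @param config a [qc_config()]
#' @return list with elements `dataset` (filtered [genotype_dataset()]) and
#'   `report` (a `qc_report`: per-filter removal counts and ID lists)
#' @export
apply_qc <- function(ds, config = qc_config()) {
  validate_genotype_dataset(ds)
  n_snp_in <- nrow(ds$snps); n_ind_in <- nrow(ds$samples)

  keep_chr <- ds$snps$chr >= 1 & ds$snps$chr <= config$autosome_max
  rm_nonauto <- ds$snps$snp_id[!keep_chr]
  ds <- subset_dataset(ds, snps = keep_chr)

  miss <- if (nrow(ds$snps) > 0) rowMeans(is.na(ds$calls)) else
    rep(0, nrow(ds$samples))
  keep_ind <- miss <= config$max_individual_missing
  rm_ind <- ds$samples$iid[!keep_ind]
  ds <- subset_dataset(ds, individuals = keep_ind)

  cr <- if (nrow(ds$samples) > 0) colMeans(!is.na(ds$calls)) else
    rep(0, nrow(ds$snps))
  keep_cr <- cr >= config$min_snp_call_rate
  rm_cr <- ds$snps$snp_id[!keep_cr]
  ds <- subset_dataset(ds, snps = keep_cr)

  gc3 <- genotype_counts(ds$calls)
  tot <- rowSums(gc3)
  p_ref <- ifelse(tot > 0, (2 * gc3[, 1] + gc3[, 2]) / (2 * pmax(tot, 1)), 0)
  maf <- pmin(p_ref, 1 - p_ref)
  keep_maf <- maf >= config$min_maf
  rm_maf <- ds$snps$snp_id[!keep_maf]
  ds <- subset_dataset(ds, snps = keep_maf)
  gc3 <- gc3[keep_maf, , drop = FALSE]

  hwe_p <- rep(1, nrow(gc3))  # no genotypes -> no evidence against HWE
  nonzero <- rowSums(gc3) > 0
  if (any(nonzero))
    hwe_p[nonzero] <- hwe_exact_pvalue(gc3[nonzero, 1], gc3[nonzero, 2],
                                       gc3[nonzero, 3],
                                       midp = config$hwe_midp)
  keep_hwe <- hwe_p >= config$hwe_alpha
  rm_hwe <- ds$snps$snp_id[!keep_hwe]
  ds <- subset_dataset(ds, snps = keep_hwe)

  report <- structure(list(
    input = c(individuals = n_ind_in, snps = n_snp_in),
    removed = list(non_autosomal_snps = rm_nonauto,
                   high_missing_individuals = rm_ind,
                   low_call_rate_snps = rm_cr,
                   low_maf_snps = rm_maf,
                   hwe_failing_snps = rm_hwe),
    retained = c(individuals = nrow(ds$samples), snps = nrow(ds$snps)),
    config = config,
    filter_order = c("autosomes", "individual_missingness", "snp_call_rate",
                     "maf", "hwe")), class = "qc_report")
  if (nrow(ds$samples) == 0 || nrow(ds$snps) == 0) {
    cond <- simpleError("QC removed every individual or every SNP")
    cond$report <- report
    stop(cond)
  }
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n  input:   ", x$input["individuals"], "individuals,",
      x$input["snps"], "SNPs\n")
  for (nm in names(x$removed))
    cat(sprintf("  removed %-26s %d\n", paste0(nm, ":"),
                length(x$removed[[nm]])))
  cat("  retained:", x$retained["individuals"], "individuals,",
      x$retained["snps"], "SNPs\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per filter with the removal count and the semicolon-joined IDs.
#'
#' @param report a `qc_report` from [apply_qc()]
#' @param path output path
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(filter = names(report$removed),
                   n_removed = lengths(report$removed),
                   ids = vapply(report$removed, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
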