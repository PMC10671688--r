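#' Genotype call codes
#'
#' Calls are stored as an integer matrix with one row per individual and one
#' column per SNP. `0` = homozygous for the reference allele, `1` =
#' heterozygous, `2` = homozygous for the alternate allele, `NA` = missing.
#' The pipeline is orientation-agnostic (only hom/het/missing matters), so
#' the reference allele at each SNP is simply the lexicographically smaller
#' observed allele.
#'
#' @name call-codes
NULL

HOM_REF <- 0L
HET <- 1L
HOM_ALT <- 2L

#' Construct a genotype dataset
#'
#' Bundles a sample roster, a SNP map and a call matrix into the container
#' that every pipeline stage consumes and produces.
#'
#' @param samples data.frame with columns `fid`, `iid`, `pat`, `mat`, `sex`,
#'   `phenotype` and optionally `population` (defaults to `fid`).
#'   `(fid, iid)` pairs must be unique.
#' @param snps data.frame with columns `chr` (integer code; 1-26 are ovine
#'   autosomes, larger codes are sex/mt/unmapped and pass through I/O
#'   untouched), `snp_id` (unique), `cm` (genetic distance, pass-through) and
#'   `pos` (1-based bp). Must be sorted by `(chr, pos)`.
#' @param calls integer matrix, `nrow(samples)` x `nrow(snps)`, of
#'   [call codes][call-codes].
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, snps, calls) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(samples$population)) samples$population <- samples$fid
  storage.mode(calls) <- "integer"
  ds <- structure(list(samples = samples, snps = snps, calls = calls),
                  class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

validate_genotype_dataset <- function(ds) {
  need_s <- c("fid", "iid", "pat", "mat", "sex", "phenotype")
  if (!all(need_s %in% names(ds$samples)))
    stop("samples roster is missing columns: ",
         paste(setdiff(need_s, names(ds$samples)), collapse = ", "))
  need_m <- c("chr", "snp_id", "cm", "pos")
  if (!all(need_m %in% names(ds$snps)))
    stop("SNP map is missing columns: ",
         paste(setdiff(need_m, names(ds$snps)), collapse = ", "))
  if (anyDuplicated(paste(ds$samples$fid, ds$samples$iid, sep = "\r")))
    stop("duplicate (fid, iid) pairs in sample roster")
  if (anyDuplicated(ds$snps$snp_id))
    stop("duplicate snp_id in map: ",
         ds$snps$snp_id[anyDuplicated(ds$snps$snp_id)])
  if (nrow(ds$snps) > 0 && any(ds$snps$pos < 0))
    stop("negative bp positions in map")
  if (nrow(ds$snps) > 1) {
    dc <- diff(ds$snps$chr)
    if (!all(dc > 0 | (dc == 0 & diff(ds$snps$pos) >= 0)))
      stop("SNP map is not sorted by (chr, pos)")
  }
  if (!identical(dim(ds$calls), c(nrow(ds$samples), nrow(ds$snps))))
    stop("call matrix is ", nrow(ds$calls), "x", ncol(ds$calls),
         " but roster implies ", nrow(ds$samples), "x", nrow(ds$snps))
  bad <- !(ds$calls %in% c(HOM_REF, HET, HOM_ALT)) & !is.na(ds$calls)
  if (any(bad)) stop("call matrix contains codes outside {0, 1, 2, NA}")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "individuals x",
      nrow(x$snps), "SNPs on", length(unique(x$snps$chr)), "chromosome(s)\n")
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              if (length(x$calls)) 100 * nm / length(x$calls) else 0))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param ds a [genotype_dataset()]
#' @param individuals row indices or logical mask over individuals
#' @param snps column indices or logical mask over SNPs
#' @return the subset `genotype_dataset`; relative order is preserved.
#' @export
subset_dataset <- function(ds, individuals = NULL, snps = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nrow(ds$samples))
  if (is.null(snps)) snps <- seq_len(nrow(ds$snps))
  genotype_dataset(ds$samples[individuals, , drop = FALSE],
                   ds$snps[snps, , drop = FALSE],
                   ds$calls[individuals, snps, drop = FALSE])
}
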