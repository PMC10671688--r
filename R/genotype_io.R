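#' Read a PLINK-dialect MAP file
#'
#' Each non-empty line holds four whitespace-separated fields: chromosome
#' code, SNP identifier, genetic distance (pass-through) and bp position.
#' Records are returned sorted by `(chr, pos)`; unsorted input is sorted
#' with a warning unless `strict_sorted = TRUE`, in which case it is an
#' error.
#'
#' @param path path to the MAP file
#' @param strict_sorted reject rather than silently sort unsorted input
#' @return data.frame with columns `chr`, `snp_id`, `cm`, `pos`
#' @export
read_map <- function(path, strict_sorted = FALSE) {
  if (!file.exists(path)) stop("MAP file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    return(data.frame(chr = integer(), snp_id = character(),
                      cm = numeric(), pos = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4))
    stop("MAP parse error at line ", lineno[which(nf != 4)[1]],
         ": expected 4 fields, found ", nf[which(nf != 4)[1]])
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  chr <- suppressWarnings(as.integer(m[, 1]))
  cm <- suppressWarnings(as.numeric(m[, 3]))
  pos <- suppressWarnings(as.numeric(m[, 4]))
  for (col in list(list(chr, "chromosome"), list(cm, "genetic distance"),
                   list(pos, "position"))) {
    if (anyNA(col[[1]]))
      stop("MAP parse error at line ", lineno[which(is.na(col[[1]]))[1]],
           ": non-numeric ", col[[2]])
  }
  if (any(pos < 0))
    stop("MAP parse error at line ", lineno[which(pos < 0)[1]],
         ": negative position")
  dup <- anyDuplicated(m[, 2])
  if (dup) stop("duplicate snp_id in MAP: ", m[dup, 2])
  map <- data.frame(chr = chr, snp_id = m[, 2], cm = cm, pos = as.integer(pos),
                    stringsAsFactors = FALSE)
  o <- order(map$chr, map$pos)
  if (!identical(o, seq_len(nrow(map)))) {
    if (strict_sorted) stop("MAP is not sorted by (chromosome, position)")
    warning("MAP was not sorted by (chromosome, position); sorting")
    map <- map[o, , drop = FALSE]
    rownames(map) <- NULL
  }
  map
}

#' Read a PLINK-dialect PED file
#'
#' Each line holds six roster fields (family ID, individual ID, paternal and
#' maternal IDs, sex, phenotype) followed by two allele symbols per SNP.
#' Allele symbols may be ACGT (GenomeStudio export) or 1/2; `0` means
#' missing. Per SNP the lexicographically smaller observed allele is taken
#' as the reference, giving [call codes][call-codes] 0/1/2/NA.
#'
#' @param path path to the PED file
#' @param snps SNP map as returned by [read_map()] (column order of the PED
#'   genotypes must match it)
#' @return a [genotype_dataset()]
#' @export
read_ped <- function(path, snps) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  n_snp <- nrow(snps)
  want <- 6L + 2L * n_snp
  if (length(lines) == 0) {
    return(genotype_dataset(
      data.frame(fid = character(), iid = character(), pat = character(),
                 mat = character(), sex = integer(), phenotype = character(),
                 stringsAsFactors = FALSE),
      snps, matrix(integer(), 0, n_snp)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != want))
    stop("PED parse error at line ", lineno[which(nf != want)[1]],
         ": expected ", want, " fields for a ", n_snp,
         "-SNP map, found ", nf[which(nf != want)[1]])
  m <- matrix(unlist(fields), nrow = length(lines), byrow = TRUE)
  samples <- data.frame(fid = m[, 1], iid = m[, 2], pat = m[, 3],
                        mat = m[, 4],
                        sex = suppressWarnings(as.integer(m[, 5])),
                        phenotype = m[, 6], stringsAsFactors = FALSE)
  a1 <- m[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
  a2 <- m[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  ok <- c("A", "C", "G", "T", "1", "2", "0")
  bad <- !(a1 %in% ok) | !(a2 %in% ok)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, ]
    stop("PED parse error at line ", lineno[j[1]], ", SNP ",
         snps$snp_id[j[2]], ": allele symbol not in {A,C,G,T,1,2,0}")
  }
  calls <- matrix(NA_integer_, nrow(m), n_snp)
  for (j in seq_len(n_snp)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- sort(setdiff(unique(c(x1, x2)), "0"))
    if (length(obs) > 2)
      stop("more than two alleles observed at SNP ", snps$snp_id[j], ": ",
           paste(obs, collapse = ","))
    miss <- x1 == "0" | x2 == "0"
    if (length(obs) > 0) {
      ref <- obs[1]
      g <- (x1 != ref) + (x2 != ref)
      g[miss] <- NA_integer_
      calls[, j] <- as.integer(g)
    }
  }
  genotype_dataset(samples, snps, calls)
}

#' Write a genotype dataset as PED/MAP files
#'
#' Alleles are emitted in the 1/2 dialect (`1` = reference, `2` = alternate,
#' `0 0` = missing), so [read_map()] + [read_ped()] of the written files
#' reconstructs an equal dataset up to per-SNP allele relabeling (a SNP at
#' which only one allele is observed is re-read with that allele as
#' reference).
#'
#' @param ds a [genotype_dataset()]
#' @param ped_path,map_path output paths
#' @return invisibly, the two paths
#' @export
write_ped_map <- function(ds, ped_path, map_path) {
  validate_genotype_dataset(ds)
  map_lines <- sprintf("%d %s %s %d", ds$snps$chr, ds$snps$snp_id,
                       format(ds$snps$cm, trim = TRUE, scientific = FALSE),
                       ds$snps$pos)
  writeLines(map_lines, map_path)
  n <- nrow(ds$samples)
  if (n == 0) {
    writeLines(character(), ped_path)
    return(invisible(c(ped = ped_path, map = map_path)))
  }
  sym <- rbind(`0` = c("1", "1"), `1` = c("1", "2"), `2` = c("2", "2"))
  geno <- matrix("0", n, 2L * max(ncol(ds$calls), 0L))
  if (ncol(ds$calls) > 0) {
    idx <- ds$calls + 1L
    g1 <- matrix(c("1", "1", "2")[idx], n)
    g2 <- matrix(c("1", "2", "2")[idx], n)
    g1[is.na(ds$calls)] <- "0"
    g2[is.na(ds$calls)] <- "0"
    geno[, seq(1, by = 2, length.out = ncol(ds$calls))] <- g1
    geno[, seq(2, by = 2, length.out = ncol(ds$calls))] <- g2
  }
  roster <- cbind(ds$samples$fid, ds$samples$iid, ds$samples$pat,
                  ds$samples$mat, ds$samples$sex, ds$samples$phenotype)
  writeLines(apply(cbind(roster, geno), 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read gene intervals from BED or GFF3
#'
#' Intervals are normalized to 1-based closed bp coordinates. BED input is
#' 0-based half-open with the gene name in column 4; GFF3 is 1-based closed
#' with the gene name taken from the attribute key `name_attr` of rows whose
#' feature type is in `feature_types`.
#'
#' @param path annotation file
#' @param dialect `"bed"` or `"gff3"`
#' @param name_attr GFF3 attribute key holding the gene name
#' @param feature_types GFF3 feature types to keep
#' @return data.frame with columns `chr`, `start`, `end`, `gene`
#'   (1-based closed)
#' @export
read_gene_intervals <- function(path, dialect = c("bed", "gff3"),
                                name_attr = "Name", feature_types = "gene") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0)
    return(data.frame(chr = integer(), start = integer(), end = integer(),
                      gene = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t")
  if (all(lengths(fields) == 1))  # fall back to whitespace-separated BED
    fields <- strsplit(trimws(lines), "[ \t]+")
  if (dialect == "bed") {
    if (any(lengths(fields) < 4))
      stop("BED line with fewer than 4 columns")
    chr <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1)))
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
    gene <- vapply(fields, `[`, "", 4)
    if (anyNA(chr) || anyNA(start) || anyNA(end))
      stop("non-numeric coordinates in BED file")
    out <- data.frame(chr = chr, start = as.integer(start + 1),
                      end = as.integer(end), gene = gene,
                      stringsAsFactors = FALSE)
  } else {
    if (any(lengths(fields) != 9))
      stop("GFF3 line without 9 tab-separated columns")
    type <- vapply(fields, `[`, "", 3)
    fields <- fields[type %in% feature_types]
    if (length(fields) == 0)
      return(data.frame(chr = integer(), start = integer(), end = integer(),
                        gene = character(), stringsAsFactors = FALSE))
    chr <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1)))
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
    if (anyNA(chr) || anyNA(start) || anyNA(end))
      stop("non-numeric coordinates in GFF3 file")
    attr_str <- vapply(fields, `[`, "", 9)
    pat <- paste0("(^|;)\\s*", name_attr, "=([^;]*)")
    mm <- regmatches(attr_str, regexec(pat, attr_str))
    gene <- vapply(mm, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
    if (anyNA(gene))
      stop("GFF3 record without a '", name_attr, "' attribute")
    out <- data.frame(chr = chr, start = as.integer(start),
                      end = as.integer(end), gene = gene,
                      stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop("gene interval with start > end")
  out <- out[order(out$chr, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
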