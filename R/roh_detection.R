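#' ROH detection parameters
#'
#' Defaults reproduce a PLINK-1.07-style sliding-window scan: 15-SNP
#' windows tolerating at most one heterozygous and one missing call, a
#' per-SNP window-support threshold of 0.05, and segment filters of 1 Mb
#' minimum length, 15 homozygous SNPs, at most 100 kb per SNP average
#' spacing and at most 250 kb between consecutive SNPs of a run.
#'
#' @param window_snps sliding window size, in SNPs
#' @param window_max_missing maximum missing calls per homozygous window
#' @param window_max_het maximum heterozygous calls per homozygous window
#' @param window_threshold minimum fraction of homozygous windows covering a
#'   SNP for that SNP to be flagged
#' @param min_snps minimum homozygous SNPs per segment
#' @param min_length_kb minimum segment length (kb)
#' @param max_density_kb_per_snp maximum average kb per homozygous SNP in a
#'   segment
#' @param max_gap_kb maximum gap (kb) between consecutive SNPs of a run
#' @param het_terminates if `TRUE` (default) a heterozygous call always ends
#'   a candidate run even when its window support passes; if `FALSE`,
#'   flagged heterozygous SNPs may sit inside a run (like missing calls they
#'   do not count toward `min_snps`)
#' @return a `roh_params` list
#' @export
roh_params <- function(window_snps = 15, window_max_missing = 1,
                       window_max_het = 1, window_threshold = 0.05,
                       min_snps = 15, min_length_kb = 1000,
                       max_density_kb_per_snp = 100, max_gap_kb = 250,
                       het_terminates = TRUE) {
  if (window_snps < 1) stop("window_snps must be >= 1")
  if (min_snps < 1 || min_length_kb <= 0 || max_density_kb_per_snp <= 0 ||
      max_gap_kb <= 0 || window_threshold <= 0)
    stop("ROH thresholds must be positive")
  structure(list(window_snps = as.integer(window_snps),
                 window_max_missing = as.integer(window_max_missing),
                 window_max_het = as.integer(window_max_het),
                 window_threshold = window_threshold,
                 min_snps = as.integer(min_snps),
                 min_length_kb = min_length_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 het_terminates = isTRUE(het_terminates)),
            class = "roh_params")
}

#' Homozygous-window flags along one chromosome
#'
#' Slides a `window_snps`-wide window over one individual's calls on one
#' chromosome; a window is homozygous (TRUE) when it contains at most
#' `window_max_het` heterozygous and at most `window_max_missing` missing
#' calls.
#'
#' @param calls one individual's [call codes][call-codes] on one chromosome,
#'   aligned to the sorted SNP positions
#' @param params a [roh_params()]
#' @return logical vector of length `length(calls) - window_snps + 1`
#'   (length 0 if the chromosome has fewer SNPs than the window)
#' @export
window_flags <- function(calls, params = roh_params()) {
  n <- length(calls)
  w <- params$window_snps
  if (n < w) return(logical(0))
  ch <- cumsum(c(0L, !is.na(calls) & calls == HET))
  cm <- cumsum(c(0L, is.na(calls)))
  i <- seq_len(n - w + 1)
  (ch[i + w] - ch[i]) <= params$window_max_het &
    (cm[i + w] - cm[i]) <= params$window_max_missing
}

#' Per-SNP window support
#'
#' For each SNP, the fraction of homozygous windows among the windows that
#' physically contain it; SNPs near chromosome ends sit in fewer windows and
#' the denominator shrinks accordingly. A SNP is flagged when its support
#' reaches `window_threshold`.
#'
#' @param flags output of [window_flags()]
#' @param n_snps number of SNPs on the chromosome
#' @param params a [roh_params()]
#' @return list with numeric `proportion` and logical `flagged`, each of
#'   length `n_snps`
#' @export
snp_support <- function(flags, n_snps, params = roh_params()) {
  w <- params$window_snps
  nw <- length(flags)
  if (nw == 0) {
    if (n_snps > 0)
      warning("chromosome shorter than one window: no SNP can be flagged")
    return(list(proportion = rep(0, n_snps),
                flagged = rep(FALSE, n_snps)))
  }
  stopifnot(nw == n_snps - w + 1)
  cf <- cumsum(c(0L, flags))
  j <- seq_len(n_snps)
  lo <- pmax(1L, j - w + 1L)          # first window containing SNP j
  hi <- pmin(nw, j)                   # last window containing SNP j
  prop <- (cf[hi + 1L] - cf[lo]) / (hi - lo + 1L)
  list(proportion = prop, flagged = prop >= params$window_threshold)
}

empty_segments <- function() {
  data.frame(fid = character(), iid = character(), chr = integer(),
             start_bp = numeric(), end_bp = numeric(), n_snps = integer(),
             length_bp = numeric(), stringsAsFactors = FALSE)
}

#' Call ROH segments on one chromosome of one individual
#'
#' Candidate runs are maximal stretches of consecutive flagged SNPs whose
#' own call is homozygous or missing (a heterozygous call terminates a run
#' under the default `het_terminates = TRUE`; missing calls may sit inside a
#' run but do not count toward `n_snps`). Runs are split wherever two
#' consecutive member SNPs lie more than `max_gap_kb` apart, then trimmed so
#' they start and end on homozygous calls. Surviving runs must carry at
#' least `min_snps` homozygous SNPs, span at least `min_length_kb`, and
#' average at most `max_density_kb_per_snp` per homozygous SNP. Segment
#' boundaries are the positions of the first and last SNP of the run;
#' `length_bp = end_bp - start_bp + 1`.
#'
#' @param flagged per-SNP flags from [snp_support()]
#' @param calls the individual's calls on this chromosome
#' @param positions sorted bp positions of the chromosome's SNPs
#' @param params a [roh_params()]
#' @param fid,iid,chr identifiers copied into the output rows
#' @return data.frame of segments (`fid`, `iid`, `chr`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`), sorted by start
#' @export
call_segments <- function(flagged, calls, positions, params = roh_params(),
                          fid = "0", iid = "0", chr = 0L) {
  n <- length(calls)
  stopifnot(length(flagged) == n, length(positions) == n)
  if (n == 0) return(empty_segments())
  is_hom <- !is.na(calls) & calls != HET
  member <- flagged & (is_hom | is.na(calls) |
                         (!params$het_terminates & calls == HET))
  member[is.na(member)] <- FALSE
  # break points: non-member SNPs, plus gaps > max_gap between neighbours
  gap_ok <- c(TRUE, diff(positions) <= params$max_gap_kb * 1000)
  run_id <- cumsum(!member | !gap_ok)
  idx <- which(member)
  if (length(idx) == 0) return(empty_segments())
  out <- list()
  for (piece in split(idx, run_id[idx])) {
    hom_in <- which(!is.na(calls[piece]) & calls[piece] != HET)
    if (length(hom_in) == 0) next
    piece <- piece[seq(hom_in[1], hom_in[length(hom_in)])]  # trim to hom ends
    n_hom <- sum(!is.na(calls[piece]) & calls[piece] != HET)
    len <- positions[piece[length(piece)]] - positions[piece[1]] + 1
    if (n_hom < params$min_snps) next
    if (len < params$min_length_kb * 1000) next
    if (len / n_hom > params$max_density_kb_per_snp * 1000) next
    out[[length(out) + 1]] <- data.frame(
      fid = fid, iid = iid, chr = as.integer(chr),
      start_bp = positions[piece[1]], end_bp = positions[piece[length(piece)]],
      n_snps = n_hom, length_bp = len, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_segments())
  res <- do.call(rbind, out)
  res[order(res$start_bp), , drop = FALSE]
}

#' Detect runs of homozygosity in a genotype dataset
#'
#' Runs the sliding-window scan ([window_flags()], [snp_support()],
#' [call_segments()]) over every individual on every chromosome of a
#' (QC-filtered) dataset. Deterministic given its inputs.
#'
#' @param ds a [genotype_dataset()]
#' @param params a [roh_params()]
#' @return data.frame of segments across all individuals and chromosomes
#' @export
detect_roh <- function(ds, params = roh_params()) {
  validate_genotype_dataset(ds)
  chrs <- unique(ds$snps$chr)
  out <- vector("list", length(chrs) * nrow(ds$samples))
  k <- 0L
  for (c_ in chrs) {
    cols <- which(ds$snps$chr == c_)
    pos <- ds$snps$pos[cols]
    for (i in seq_len(nrow(ds$samples))) {
      calls <- ds$calls[i, cols]
      fl <- window_flags(calls, params)
      sup <- suppressWarnings(snp_support(fl, length(cols), params))
      seg <- call_segments(sup$flagged, calls, pos, params,
                           fid = ds$samples$fid[i], iid = ds$samples$iid[i],
                           chr = c_)
      if (nrow(seg) > 0) {
        k <- k + 1L
        out[[k]] <- seg
      }
    }
  }
  if (k == 0L) return(empty_segments())
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(match(res$iid, ds$samples$iid), res$chr, res$start_bp), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a segment table written by [write_segments()]
#'
#' @param path TSV path
#' @return data.frame in the [detect_roh()] layout
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, colClasses = c(FID = "character",
                                               IID = "character"))
  data.frame(fid = df$FID, iid = df$IID, chr = as.integer(df$CHR),
             start_bp = df$START_BP, end_bp = df$END_BP,
             n_snps = as.integer(df$N_SNPS),
             length_bp = df$LENGTH_KB * 1000, stringsAsFactors = FALSE)
}

#' Write a segment table as TSV
#'
#' PLINK `.hom`-like layout: FID, IID, CHR, START_BP, END_BP, N_SNPS,
#' LENGTH_KB.
#'
#' @param segments data.frame from [detect_roh()]
#' @param path output path
#' @export
write_segments <- function(segments, path) {
  df <- data.frame(FID = segments$fid, IID = segments$iid,
                   CHR = segments$chr, START_BP = segments$start_bp,
                   END_BP = segments$end_bp, N_SNPS = segments$n_snps,
                   LENGTH_KB = segments$length_bp / 1000)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
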