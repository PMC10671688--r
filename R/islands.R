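utils::globalVariables(c("x", "y", "shade"))

#' Per-SNP ROH occurrence profile
#'
#' For every SNP of the map, the number (and percentage) of individuals with
#' at least one ROH segment covering the SNP's position (same chromosome,
#' `start_bp <= pos <= end_bp`). An individual contributes at most 1 per
#' SNP even if handed overlapping segments.
#'
#' @param segments data.frame from [detect_roh()]
#' @param snps the post-QC SNP map the segments were called on
#' @param n_individuals occurrence denominator: number of individuals
#'   surviving QC
#' @return data.frame aligned to `snps` with columns `chr`, `snp_id`, `pos`,
#'   `count`, `percent`
#' @export
snp_occurrence <- function(segments, snps, n_individuals) {
  count <- integer(nrow(snps))
  if (nrow(segments) > 0) {
    if (!all(segments$chr %in% snps$chr))
      stop("segment chromosome absent from the SNP map")
    for (c_ in unique(segments$chr)) {
      cols <- which(snps$chr == c_)
      pos <- snps$pos[cols]
      seg_c <- segments[segments$chr == c_, , drop = FALSE]
      cov_count <- integer(length(cols))
      for (ind in unique(seg_c$iid)) {
        s <- seg_c[seg_c$iid == ind, , drop = FALSE]
        covered <- logical(length(cols))
        for (r in seq_len(nrow(s))) {
          lo <- findInterval(s$start_bp[r] - 0.5, pos) + 1L
          hi <- findInterval(s$end_bp[r] + 0.5, pos)
          if (hi >= lo) covered[lo:hi] <- TRUE
        }
        cov_count <- cov_count + covered
      }
      count[cols] <- cov_count
    }
  }
  data.frame(chr = snps$chr, snp_id = snps$snp_id, pos = snps$pos,
             count = count,
             percent = if (n_individuals > 0) 100 * count / n_individuals
             else rep(0, nrow(snps)),
             stringsAsFactors = FALSE)
}

#' Select the top percentage of SNPs by ROH occurrence
#'
#' With `k = ceiling(pct/100 * n_snps)`, selects every SNP whose occurrence
#' reaches the k-th largest occurrence value; ties at the cutoff are all
#' included, so the selection can exceed k SNPs. An all-zero profile yields
#' an empty selection with a warning.
#'
#' @param profile data.frame from [snp_occurrence()]
#' @param pct percentage of SNPs to select (default 1, the "top 1%")
#' @return list with `selected` (logical over the map), `cutoff` (the
#'   occurrence count used) and `k`
#' @export
select_top_percent <- function(profile, pct = 1) {
  n <- nrow(profile)
  if (n == 0) stop("empty occurrence profile")
  if (all(profile$count == 0)) {
    warning("all-zero occurrence profile: nothing to select")
    return(list(selected = rep(FALSE, n), cutoff = NA_real_,
                k = ceiling(pct / 100 * n)))
  }
  k <- ceiling(pct / 100 * n)
  cutoff <- sort(profile$count, decreasing = TRUE)[k]
  list(selected = profile$count >= cutoff, cutoff = cutoff, k = k)
}

#' Merge selected SNPs into ROH islands
#'
#' Consecutive selected SNPs on the same chromosome are merged into one
#' island while their bp distance is at most `max_island_gap_kb`; islands
#' with fewer than `min_island_snps` selected SNPs are dropped. Island
#' bounds are the first and last selected SNP positions, also reported in
#' Mb rounded to 2 decimals.
#'
#' @param selected logical vector over the map (from [select_top_percent()])
#' @param snps the SNP map
#' @param max_island_gap_kb merge distance in kb
#' @param min_island_snps minimum selected SNPs per island
#' @return data.frame with columns `chr`, `n_snp`, `start_bp`, `end_bp`,
#'   `start_mb`, `end_mb`
#' @export
build_islands <- function(selected, snps, max_island_gap_kb = 1000,
                          min_island_snps = 3) {
  stopifnot(length(selected) == nrow(snps))
  idx <- which(selected)
  empty <- data.frame(chr = integer(), n_snp = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      start_mb = numeric(), end_mb = numeric(),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0) return(empty)
  chr <- snps$chr[idx]
  pos <- snps$pos[idx]
  new_island <- c(TRUE, diff(chr) != 0 | diff(pos) > max_island_gap_kb * 1000)
  grp <- cumsum(new_island)
  out <- lapply(split(seq_along(idx), grp), function(g) {
    if (length(g) < min_island_snps) return(NULL)
    data.frame(chr = chr[g[1]], n_snp = length(g),
               start_bp = pos[g[1]], end_bp = pos[g[length(g)]],
               start_mb = round(pos[g[1]] / 1e6, 2),
               end_mb = round(pos[g[length(g)]] / 1e6, 2),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chr, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate islands with overlapping genes
#'
#' A gene is assigned to an island when their bp intervals overlap by at
#' least 1 bp; gene names are listed in position order.
#'
#' @param islands data.frame from [build_islands()]
#' @param gene_intervals data.frame from [read_gene_intervals()] (may be
#'   empty or `NULL`)
#' @return `islands` with an added list-column `genes` and a `genes_str`
#'   column (semicolon-joined)
#' @export
annotate_islands <- function(islands, gene_intervals = NULL) {
  if (is.null(gene_intervals))
    gene_intervals <- data.frame(chr = integer(), start = integer(),
                                 end = integer(), gene = character())
  genes <- lapply(seq_len(nrow(islands)), function(i) {
    hit <- gene_intervals$chr == islands$chr[i] &
      gene_intervals$start <= islands$end_bp[i] &
      gene_intervals$end >= islands$start_bp[i]
    g <- gene_intervals[hit, , drop = FALSE]
    g$gene[order(g$start)]
  })
  islands$genes <- genes
  islands$genes_str <- vapply(genes, paste, "", collapse = ";")
  islands
}

#' Write the island report as TSV
#'
#' Layout: CHR, N_SNP, START_MB, END_MB, GENES (semicolon-joined).
#'
#' @param islands annotated islands from [annotate_islands()]
#' @param path output path
#' @export
write_islands <- function(islands, path) {
  df <- data.frame(CHR = islands$chr, N_SNP = islands$n_snp,
                   START_MB = islands$start_mb, END_MB = islands$end_mb,
                   GENES = if (!is.null(islands$genes_str)) islands$genes_str
                   else "",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Manhattan-style plot of ROH occurrence
#'
#' Per-SNP occurrence percentage against cumulative genomic position, with
#' chromosomes alternately coloured and a horizontal line at the selection
#' cutoff; selected SNPs are highlighted.
#'
#' @param profile data.frame from [snp_occurrence()]
#' @param selection list from [select_top_percent()] (optional)
#' @param path output image path (extension picks the device, e.g. `.pdf`
#'   or `.png`)
#' @param n_individuals denominator used to express the cutoff in percent
#' @return the path, invisibly
#' @export
occurrence_plot <- function(profile, selection = NULL, path,
                            n_individuals = NULL) {
  chr_f <- factor(profile$chr)
  offsets <- c(0, cumsum(tapply(profile$pos, chr_f, max)))
  df <- data.frame(
    x = profile$pos + offsets[as.integer(chr_f)],
    y = profile$percent,
    shade = as.integer(chr_f) %% 2 == 0,
    sel = if (!is.null(selection)) selection$selected else FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(ggplot2::aes(colour = shade), size = 0.4,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "cumulative genomic position (bp)",
                  y = "SNPs in ROH (%)") +
    ggplot2::theme_minimal()
  if (any(df$sel))
    p <- p + ggplot2::geom_point(data = df[df$sel, ], colour = "firebrick",
                                 size = 0.6)
  if (!is.null(selection) && !is.na(selection$cutoff)) {
    cut_pct <- if (!is.null(n_individuals) && n_individuals > 0)
      100 * selection$cutoff / n_individuals else selection$cutoff
    p <- p + ggplot2::geom_hline(yintercept = cut_pct, linetype = "dashed")
  }
  ggplot2::ggsave(path, p, width = 9, height = 3.2, units = "in")
  invisible(path)
}
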