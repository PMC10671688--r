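#' Length-class scheme for ROH statistics
#'
#' Length classes are derived from a set of strictly increasing Mb edges
#' (default 1, 2, 4, 8, 16) in two views: cumulative classes `>= e` per edge
#' ("1+", "2+", ... in the descriptive tables) and interval classes
#' `[e_i, e_{i+1})` with a final open class `>= e_last`.
#'
#' @param edges_mb strictly increasing positive Mb thresholds
#' @return a `length_class_scheme` list
#' @export
length_class_scheme <- function(edges_mb = c(1, 2, 4, 8, 16)) {
  if (any(edges_mb <= 0) || is.unsorted(edges_mb, strictly = TRUE))
    stop("edges_mb must be strictly increasing and positive")
  n <- length(edges_mb)
  interval_labels <- c(if (n > 1) sprintf("[%g,%g)", edges_mb[-n], edges_mb[-1]),
                       sprintf(">=%g", edges_mb[n]))
  structure(list(edges_mb = edges_mb,
                 cumulative_labels = sprintf("%g+", edges_mb),
                 interval_labels = interval_labels),
            class = "length_class_scheme")
}

#' Autosomal genome span covered by the SNP map
#'
#' The F_ROH denominator L_aut: summed per chromosome, last SNP position
#' minus first SNP position plus one. A chromosome carrying a single SNP
#' contributes 1 bp.
#'
#' @param snps SNP map (sorted, autosomal, post-QC)
#' @return total span in bp
#' @export
autosomal_span <- function(snps) {
  if (nrow(snps) == 0) stop("empty SNP map: L_aut undefined")
  spans <- tapply(snps$pos, snps$chr, function(p) max(p) - min(p) + 1)
  if (any(spans == 1))
    message("autosomal_span: chromosome(s) with a single SNP contribute 1 bp")
  sum(spans)
}

#' Assign ROH segments to length classes
#'
#' @param segments data.frame from [detect_roh()]
#' @param scheme a [length_class_scheme()]
#' @return list with `interval` (factor over interval-class labels; the
#'   interval classes partition the segments) and `cumulative` (logical
#'   matrix, one column per cumulative class `>= e`)
#' @export
classify_segments <- function(segments, scheme = length_class_scheme()) {
  mb <- segments$length_bp / 1e6
  edges <- scheme$edges_mb
  if (any(mb < edges[1]))
    stop("segment shorter than the smallest class edge (", edges[1], " Mb)")
  interval <- cut(mb, breaks = c(edges, Inf), right = FALSE,
                  labels = scheme$interval_labels)
  cumulative <- outer(mb, edges, `>=`)
  colnames(cumulative) <- scheme$cumulative_labels
  list(interval = interval, cumulative = cumulative)
}

per_individual_class_stats <- function(segments, samples, scheme) {
  # one row per individual x cumulative class, zero-filled
  iids <- samples$iid
  edges <- scheme$edges_mb
  cls <- if (nrow(segments)) classify_segments(segments, scheme)$cumulative else
    matrix(FALSE, 0, length(edges))
  grid <- expand.grid(iid = iids, class = scheme$cumulative_labels,
                      stringsAsFactors = FALSE)
  grid$n_roh <- 0
  grid$total_mb <- 0
  if (nrow(segments)) {
    for (e in seq_along(edges)) {
      sel <- cls[, e]
      if (!any(sel)) next
      cnt <- tapply(rep(1, sum(sel)), segments$iid[sel], sum)
      len <- tapply(segments$length_bp[sel] / 1e6, segments$iid[sel], sum)
      rows <- grid$class == scheme$cumulative_labels[e]
      m <- match(grid$iid[rows], names(cnt))
      grid$n_roh[rows] <- ifelse(is.na(m), 0, cnt[m])
      grid$total_mb[rows] <- ifelse(is.na(m), 0, len[m])
    }
  }
  grid
}

#' Per-population descriptive statistics of ROHs
#'
#' For each population and each cumulative length class, the mean, sample
#' standard deviation (n-1; reported as 0 for single-individual groups),
#' minimum and maximum over individuals of the per-individual ROH count and
#' total ROH length (Mb). Individuals with zero segments contribute zeros.
#'
#' @param segments data.frame from [detect_roh()]
#' @param samples sample roster of the QC-filtered dataset (its `population`
#'   column defines the cohorts)
#' @param scheme a [length_class_scheme()]
#' @return data.frame with one row per population x class x metric
#' @export
summarize_population <- function(segments, samples,
                                 scheme = length_class_scheme()) {
  if (nrow(samples) == 0) stop("no individuals to summarize")
  if (nrow(segments) && !all(segments$iid %in% samples$iid))
    stop("segments refer to individuals absent from the roster")
  per <- per_individual_class_stats(segments, samples, scheme)
  per$population <- samples$population[match(per$iid, samples$iid)]
  out <- list()
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  for (pop in unique(samples$population)) {
    for (cl in scheme$cumulative_labels) {
      sub <- per[per$population == pop & per$class == cl, ]
      for (metric in c("n_roh", "total_mb")) {
        x <- sub[[metric]]
        out[[length(out) + 1]] <- data.frame(
          population = pop, class = cl,
          metric = if (metric == "n_roh") "count" else "length_mb",
          n_individuals = nrow(sub), mean = mean(x), sd = sd0(x),
          min = min(x), max = max(x), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' F_ROH genomic inbreeding coefficients for one individual
#'
#' `F_ROH = sum(L_ROH) / L_aut`, computed per length threshold: for each
#' edge `e` the numerator sums the lengths of segments strictly longer than
#' `e` Mb (matching "F_ROH > e Mb" column heads).
#'
#' @param segments one individual's segments
#' @param l_aut autosomal span in bp ([autosomal_span()])
#' @param edges_mb length thresholds in Mb
#' @return named numeric vector of F_ROH values, one per threshold,
#'   non-increasing in the threshold
#' @export
compute_froh <- function(segments, l_aut, edges_mb = c(1, 2, 4, 8, 16)) {
  if (l_aut <= 0) stop("l_aut must be positive")
  if (nrow(segments) && any(segments$length_bp > l_aut))
    stop("segment longer than the autosomal span: inconsistent inputs")
  f <- vapply(edges_mb, function(e)
    sum(segments$length_bp[segments$length_bp > e * 1e6]) / l_aut, numeric(1))
  names(f) <- sprintf("froh_gt_%gmb", edges_mb)
  f
}

#' Per-individual F_ROH table
#'
#' @param segments data.frame from [detect_roh()]
#' @param samples sample roster (zero-segment individuals get zeros)
#' @param l_aut autosomal span in bp
#' @param edges_mb length thresholds in Mb
#' @return data.frame with `fid`, `iid`, `population` and one F_ROH column
#'   per threshold
#' @export
froh_table <- function(segments, samples, l_aut, edges_mb = c(1, 2, 4, 8, 16)) {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    seg_i <- segments[segments$iid == samples$iid[i], , drop = FALSE]
    as.list(compute_froh(seg_i, l_aut, edges_mb))
  })
  cbind(data.frame(fid = samples$fid, iid = samples$iid,
                   population = samples$population,
                   stringsAsFactors = FALSE),
        do.call(rbind, lapply(rows, as.data.frame)))
}

#' Population means of F_ROH per threshold
#'
#' @param froh data.frame from [froh_table()]
#' @return data.frame with one row per population
#' @export
froh_population_means <- function(froh) {
  cols <- grep("^froh_gt_", names(froh), value = TRUE)
  agg <- stats::aggregate(froh[cols], by = list(population = froh$population),
                          FUN = mean)
  agg
}

#' Write the per-individual and population ROH statistics as TSV
#'
#' @param froh data.frame from [froh_table()]
#' @param pop_summary data.frame from [summarize_population()]
#' @param froh_path,summary_path output paths
#' @export
write_roh_stats <- function(froh, pop_summary, froh_path, summary_path) {
  utils::write.table(froh, froh_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pop_summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(froh_path, summary_path))
}
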