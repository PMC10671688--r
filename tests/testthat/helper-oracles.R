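# Independent oracles used by the unit and acceptance tests. These share no
# code with the implementation paths they check: the HWE oracle enumerates
# the conditional distribution from the direct log-gamma formula, and the
# segment oracle evaluates a declarative interval predicate over every
# (start, end) pair instead of running the sequential scan.

# Exact HWE p-value by direct summation over all heterozygote counts
# compatible with the observed allele counts.
oracle_hwe_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logu <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
      h * log(2)
  }, numeric(1))
  prob <- exp(logu - max(logu))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# Per-SNP window support by literal recount: for each SNP, loop over every
# window that physically contains it and count het/missing calls directly.
oracle_snp_flags <- function(calls, params) {
  n <- length(calls)
  w <- params$window_snps
  if (n < w) return(rep(FALSE, n))
  nw <- n - w + 1
  vapply(seq_len(n), function(j) {
    wins <- seq(max(1, j - w + 1), min(nw, j))
    good <- vapply(wins, function(s) {
      win <- calls[s:(s + w - 1)]
      sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
        sum(is.na(win)) <= params$window_max_missing
    }, logical(1))
    mean(good) >= params$window_threshold
  }, logical(1))
}

# Exhaustive-enumeration segment oracle: a core interval [i, j] must start
# and end on a homozygous call, contain only eligible SNPs (flagged, and
# homozygous/missing -- plus heterozygous in the lenient mode), and have no
# neighbour gap over max_gap_kb. Maximal cores not contained in any other
# core are then filtered by the min_snps / min_length / density thresholds.
oracle_segments <- function(calls, positions, params) {
  n <- length(calls)
  flagged <- oracle_snp_flags(calls, params)
  hom <- !is.na(calls) & calls != 1
  eligible <- flagged & (hom | is.na(calls) |
                           (!params$het_terminates & !is.na(calls) & calls == 1))
  bad_gap <- c(FALSE, diff(positions) > params$max_gap_kb * 1000)
  cum_inel <- cumsum(!eligible)
  cum_gap <- cumsum(bad_gap)
  starts <- which(hom & eligible)
  cores <- list()
  for (i in starts) {
    js <- starts[starts >= i]
    ok <- (cum_inel[js] - cum_inel[i]) == 0 &   # all of (i, j] eligible
      (cum_gap[js] - cum_gap[i]) == 0           # no bad gap inside (i, j]
    js <- js[ok & eligible[i]]
    if (length(js)) cores[[length(cores) + 1]] <- c(i, max(js))
  }
  if (length(cores) == 0)
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer()))
  cm <- do.call(rbind, cores)
  # maximality: (i, jmax(i)) is contained in another core iff some earlier
  # start reaches at least as far
  keep <- logical(nrow(cm))
  for (r in seq_len(nrow(cm)))
    keep[r] <- !any(cm[, 1] < cm[r, 1] & cm[, 2] >= cm[r, 2])
  cm <- cm[keep, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(cm))) {
    i <- cm[r, 1]; j <- cm[r, 2]
    n_hom <- sum(hom[i:j])
    len <- positions[j] - positions[i] + 1
    if (n_hom < params$min_snps) next
    if (len < params$min_length_kb * 1000) next
    if (len / n_hom > params$max_density_kb_per_snp * 1000) next
    out[[length(out) + 1]] <- data.frame(start_bp = positions[i],
                                         end_bp = positions[j],
                                         n_snps = n_hom)
  }
  if (length(out) == 0)
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer()))
  res <- do.call(rbind, out)
  res[order(res$start_bp), , drop = FALSE]
}

# Run the implementation chain (window_flags -> snp_support -> call_segments)
# on one chromosome vector.
impl_segments <- function(calls, positions, params) {
  fl <- window_flags(calls, params)
  sup <- suppressWarnings(snp_support(fl, length(calls), params))
  seg <- call_segments(sup$flagged, calls, positions, params)
  seg[, c("start_bp", "end_bp", "n_snps")]
}

expect_same_segments <- function(impl, oracle, info = NULL) {
  expect_equal(nrow(impl), nrow(oracle), info = info)
  if (nrow(impl) > 0 && nrow(impl) == nrow(oracle)) {
    rownames(impl) <- rownames(oracle) <- NULL
    expect_equal(impl$start_bp, oracle$start_bp, info = info)
    expect_equal(impl$end_bp, oracle$end_bp, info = info)
    expect_equal(impl$n_snps, oracle$n_snps, info = info)
  }
}

# Random single-chromosome detection instance.
rand_instance <- function(max_snps = 200) {
  n <- sample(30:max_snps, 1)
  positions <- cumsum(c(sample.int(1e5, 1),
                        sample(5e3:1.2e5, n - 1, replace = TRUE)))
  pr <- c(hom_ref = runif(1, 0.2, 0.55), het = runif(1, 0.05, 0.3),
          hom_alt = runif(1, 0.2, 0.4))
  miss <- runif(1, 0, 0.1)
  pr <- c(pr * (1 - miss) / sum(pr), miss = miss)
  calls <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE, prob = pr)
  params <- roh_params(
    window_snps = sample(5:20, 1),
    window_max_missing = sample(0:2, 1),
    window_max_het = sample(0:2, 1),
    window_threshold = runif(1, 0.01, 0.2),
    min_snps = sample(5:20, 1),
    min_length_kb = sample(200:1500, 1),
    max_density_kb_per_snp = sample(50:200, 1),
    max_gap_kb = sample(100:500, 1),
    het_terminates = sample(c(TRUE, FALSE), 1))
  list(calls = calls, positions = positions, params = params)
}

# Random genotype dataset for I/O and QC property tests.
rand_dataset <- function(n_ind = 20, n_snp = 100, n_chr = 2,
                         miss_rate = 0.05, nonauto_frac = 0) {
  chr <- sort(sample(seq_len(n_chr), n_snp, replace = TRUE))
  if (nonauto_frac > 0) {
    k <- round(nonauto_frac * n_snp)
    chr[sample.int(n_snp, k)] <- sample(c(27L, 28L, 0L), k, replace = TRUE)
    o <- order(chr, na.last = TRUE)
  }
  pos <- unlist(lapply(split(seq_along(chr), chr), function(ix)
    sort(sample.int(5e7, length(ix)))), use.names = FALSE)
  chr <- sort(chr)
  snps <- data.frame(chr = chr, snp_id = sprintf("m%d", seq_len(n_snp)),
                     cm = 0, pos = pos, stringsAsFactors = FALSE)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), n_ind * n_snp, replace = TRUE,
                         prob = c((1 - miss_rate) * c(0.35, 0.35, 0.3),
                                  miss_rate)),
                  n_ind, n_snp)
  samples <- data.frame(fid = rep("F1", n_ind),
                        iid = sprintf("i%03d", seq_len(n_ind)),
                        pat = "0", mat = "0", sex = 1L, phenotype = "-9",
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, snps, calls)
}

# PED/MAP round-trip equality up to per-SNP reference-allele relabeling.
expect_calls_equivalent <- function(a, b) {
  expect_equal(dim(a), dim(b))
  for (j in seq_len(ncol(a))) {
    same <- identical(a[, j], b[, j])
    swapped <- identical(a[, j], 2L - b[, j])
    expect_true(same || swapped,
                info = paste("column", j, "differs beyond relabeling"))
  }
}
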