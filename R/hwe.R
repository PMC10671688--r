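#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on one biallelic SNP's genotype counts, conditional
#' on the observed allele counts: the p-value is the sum of the conditional
#' probabilities of every heterozygote count (with the same allele counts
#' and sample size) whose probability does not exceed that of the observed
#' count. Probabilities are computed with a multiplicative recurrence over
#' heterozygote counts — no factorials of large n — and normalized, so the
#' test is stable for chip-scale samples.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (vectors recycle
#'   together); missing genotypes must already be excluded
#' @param midp if `TRUE`, return the mid-p variant (half weight on the
#'   observed outcome)
#' @return p-value(s) in (0, 1]
#' @export
hwe_exact_pvalue <- function(n_hom_ref, n_het, n_hom_alt, midp = FALSE) {
  k <- cbind(n_hom_ref, n_het, n_hom_alt)
  if (any(k < 0) || anyNA(k)) stop("genotype counts must be non-negative")
  n <- k[, 1] + k[, 2] + k[, 3]
  if (any(n < 1)) stop("at least one genotype required")
  rare <- pmin(2 * k[, 1] + k[, 2], 2 * k[, 3] + k[, 2])
  key <- paste(n, rare)
  p <- numeric(length(n))
  for (g in split(seq_along(n), key)) {
    dist <- hwe_het_distribution(n[g[1]], rare[g[1]])
    obs_idx <- match(k[g, 2], dist$het)
    p_obs <- dist$prob[obs_idx]
    # relative tolerance so mathematically tied outcomes are always included
    p[g] <- vapply(seq_along(g), function(i) {
      inc <- dist$prob <= p_obs[i] * (1 + 1e-9)
      pv <- sum(dist$prob[inc])
      if (midp) pv <- pv - 0.5 * p_obs[i]
      min(pv, 1)
    }, numeric(1))
  }
  p
}

# Conditional distribution of the heterozygote count given n genotypes and
# `rare` copies of the minor allele. Probabilities are proportional to
#   n! / (n_hr! n_het! n_hc!) * 2^n_het
# and are built by the ratio
#   P(h+2) / P(h) = 4 * n_hr(h) * n_hc(h) / ((h+2) * (h+1)),
# anchored at the largest admissible heterozygote count and normalized.
hwe_het_distribution <- function(n, rare) {
  common <- 2 * n - rare
  h_max <- min(rare, common)
  h_min <- rare %% 2
  het <- seq(h_max, h_min, by = -2)
  u <- numeric(length(het))
  u[1] <- 1
  if (length(het) > 1) {
    for (i in seq(2, length(het))) {
      h <- het[i]  # going down: P(h) = P(h+2) * (h+2)(h+1) / (4 * hr(h) * hc(h))
      hr <- (rare - h) / 2
      hc <- n - h - hr
      u[i] <- u[i - 1] * (h + 2) * (h + 1) / (4 * hr * hc)
      if (u[i] > 1e280) {  # renormalize to keep the recurrence in range
        u[seq_len(i)] <- u[seq_len(i)] / u[i]
      }
    }
  }
  list(het = het, prob = u / sum(u))
}
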