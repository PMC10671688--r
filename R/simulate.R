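#' Simulation configuration
#'
#' Describes a chip-like diploid population with known autozygosity truth:
#' a SNP map with roughly uniform spacing, per-SNP allele frequencies shared
#' by all individuals (one panmictic base population), per-individual
#' autozygous tracts (forced-homozygous intervals) whose number follows a
#' Poisson law and whose lengths follow `tract_min_mb + Exp(tract_mean_mb -
#' tract_min_mb)` so the realized mean is `tract_mean_mb`, optional shared
#' tracts at fixed loci (recoverable islands), genotyping error and
#' missingness, and optional planted QC failures.
#'
#' The default desk scale (3 chromosomes x 2000 SNPs x 100 individuals,
#' ~50 kb SNP spacing, tract load tuned to a true autozygous fraction of
#' 0.05) simulates in seconds; `chip_scale = TRUE` switches to 26 ovine
#' autosomes with ~47k SNPs and 281 individuals.
#'
#' @param n_individuals number of individuals
#' @param chromosomes data.frame with columns `length_bp`, `n_snps` and
#'   optionally `chr` (chromosome codes; default `1..nrow`)
#' @param maf_range minor-allele-frequency range sampled uniformly per SNP
#' @param tract_n_mean Poisson mean of random autozygous tracts per
#'   individual; see [tract_load_for_f()]
#' @param tract_mean_mb,tract_min_mb tract length model (Mb)
#' @param planted_islands `NULL` or data.frame with columns `chr`,
#'   `start_bp`, `end_bp`, `carrier_fraction`
#' @param het_error_rate probability a tract site is rendered heterozygous
#' @param missing_rate probability any site is missing
#' @param qc_spike `NULL` or list with counts `n_low_call_rate`,
#'   `n_low_maf`, `n_hwe_fail` (SNPs) and `n_high_missing_individuals`
#' @param population_sizes `NULL` (single cohort "POP1") or named integer
#'   vector summing to `n_individuals`
#' @param seed RNG seed used by [simulate_population()]
#' @param chip_scale use the chip-scale preset
#' @return a `sim_config` list
#' @export
sim_config <- function(n_individuals = 100,
                       chromosomes = data.frame(length_bp = rep(1e8, 3),
                                                n_snps = rep(2000L, 3)),
                       maf_range = c(0.05, 0.5),
                       tract_n_mean = NULL,
                       tract_mean_mb = 4, tract_min_mb = 2,
                       planted_islands = NULL,
                       het_error_rate = 0, missing_rate = 0.01,
                       qc_spike = NULL, population_sizes = NULL,
                       seed = 1, chip_scale = FALSE) {
  if (chip_scale) {
    n_individuals <- 281
    chromosomes <- data.frame(length_bp = round(seq(2.8e8, 0.5e8,
                                                    length.out = 26)),
                              n_snps = 0L)
    chromosomes$n_snps <- as.integer(round(chromosomes$length_bp / 55e3))
  }
  rates <- c(het_error_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (is.null(chromosomes$chr)) chromosomes$chr <- seq_len(nrow(chromosomes))
  if (anyDuplicated(chromosomes$chr)) stop("duplicate chromosome codes")
  chromosomes <- chromosomes[order(chromosomes$chr), , drop = FALSE]
  rownames(chromosomes) <- NULL
  if (any(chromosomes$n_snps > chromosomes$length_bp))
    stop("more SNPs than bp on a chromosome")
  if (tract_mean_mb < tract_min_mb)
    stop("tract_mean_mb must be >= tract_min_mb")
  cfg <- structure(list(n_individuals = n_individuals,
                        chromosomes = chromosomes, maf_range = maf_range,
                        tract_n_mean = tract_n_mean,
                        tract_mean_mb = tract_mean_mb,
                        tract_min_mb = tract_min_mb,
                        planted_islands = planted_islands,
                        het_error_rate = het_error_rate,
                        missing_rate = missing_rate, qc_spike = qc_spike,
                        population_sizes = population_sizes, seed = seed),
                   class = "sim_config")
  if (is.null(cfg$tract_n_mean))
    cfg$tract_n_mean <- tract_load_for_f(0.05, cfg)
  if (!is.null(planted_islands)) {
    row <- match(planted_islands$chr, chromosomes$chr)
    if (anyNA(row)) stop("planted island on an unknown chromosome code")
    L <- chromosomes$length_bp[row]
    if (any(planted_islands$start_bp < 1) || any(planted_islands$end_bp > L))
      stop("planted island outside chromosome bounds")
  }
  cfg
}

#' Poisson tract load for a target autozygous fraction
#'
#' @param target_f desired expected true autozygous fraction
#' @param config a [sim_config()] (its genome size and tract length model
#'   set the conversion)
#' @return Poisson mean number of tracts per individual
#' @export
tract_load_for_f <- function(target_f, config) {
  target_f * sum(config$chromosomes$length_bp) / (config$tract_mean_mb * 1e6)
}

#' Simulate a SNP map
#'
#' Per chromosome, `n_snps` positions are drawn uniformly without
#' replacement from `1..length_bp` and sorted; SNP IDs are deterministic
#' from (chromosome, index). Consumes the global RNG stream.
#'
#' @param config a [sim_config()]
#' @return SNP map data.frame (`chr`, `snp_id`, `cm`, `pos`)
#' @export
simulate_map <- function(config) {
  maps <- lapply(seq_len(nrow(config$chromosomes)), function(c_) {
    n <- config$chromosomes$n_snps[c_]
    L <- config$chromosomes$length_bp[c_]
    code <- config$chromosomes$chr[c_]
    pos <- sort(sample.int(L, n))
    data.frame(chr = code, snp_id = sprintf("snp%d_%d", code, seq_len(n)),
               cm = 0, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Sample one individual's autozygous tracts
#'
#' Draws a Poisson number of random tracts (length `tract_min_mb +
#' Exp(tract_mean_mb - tract_min_mb)` Mb, placed uniformly on a chromosome
#' chosen proportionally to its length), non-overlapping with each other and
#' with any pre-planted tracts, by rejection sampling with a retry cap.
#' Consumes the global RNG stream.
#'
#' @param config a [sim_config()]
#' @param planted data.frame of pre-planted tracts for this individual
#'   (columns `chr`, `start_bp`, `end_bp`), or `NULL`
#' @param retry_cap rejection-sampling retries per tract
#' @return data.frame with columns `chr`, `start_bp`, `end_bp`
#' @export
sample_tracts <- function(config, planted = NULL, retry_cap = 1000) {
  tracts <- if (is.null(planted))
    data.frame(chr = integer(), start_bp = numeric(), end_bp = numeric())
  else planted[, c("chr", "start_bp", "end_bp"), drop = FALSE]
  n_new <- stats::rpois(1, config$tract_n_mean)
  if (n_new == 0) return(tracts)
  L <- config$chromosomes$length_bp
  codes <- config$chromosomes$chr
  for (i in seq_len(n_new)) {
    placed <- FALSE
    for (try in seq_len(retry_cap)) {
      len_mb <- config$tract_min_mb +
        stats::rexp(1, 1 / max(config$tract_mean_mb - config$tract_min_mb,
                               1e-9))
      c_ <- sample.int(length(L), 1, prob = L)
      len <- min(round(len_mb * 1e6), L[c_])
      start <- sample.int(L[c_] - len + 1, 1)
      end <- start + len - 1
      same <- tracts[tracts$chr == codes[c_], , drop = FALSE]
      if (!any(same$start_bp <= end & same$end_bp >= start)) {
        tracts <- rbind(tracts, data.frame(chr = codes[c_], start_bp = start,
                                           end_bp = end))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a non-overlapping tract after ", retry_cap,
           " retries; reduce the tract load or lengthen the genome")
  }
  tracts[order(tracts$chr, tracts$start_bp), , drop = FALSE]
}

#' Simulate one individual's genotype calls
#'
#' Outside tracts, genotypes are drawn from Hardy-Weinberg proportions of
#' the per-SNP allele frequencies; inside tracts a single allele is drawn by
#' frequency and the genotype made homozygous for it. Heterozygote error is
#' then applied inside tracts at `het_error_rate`, and missingness
#' everywhere at `missing_rate`. Consumes the global RNG stream.
#'
#' @param map SNP map from [simulate_map()]
#' @param p_ref per-SNP reference-allele frequencies in (0, 1)
#' @param tracts data.frame from [sample_tracts()]
#' @param config a [sim_config()]
#' @return integer vector of [call codes][call-codes]
#' @export
simulate_genotypes <- function(map, p_ref, tracts, config) {
  stopifnot(length(p_ref) == nrow(map), all(p_ref > 0 & p_ref < 1))
  q <- 1 - p_ref
  n <- nrow(map)
  calls <- stats::rbinom(n, 2, q)  # ALT allele count = call code under HWE
  if (nrow(tracts) > 0) {
    in_tract <- rep(FALSE, n)
    for (r in seq_len(nrow(tracts)))
      in_tract <- in_tract | (map$chr == tracts$chr[r] &
                                map$pos >= tracts$start_bp[r] &
                                map$pos <= tracts$end_bp[r])
    m <- sum(in_tract)
    if (m > 0) {
      calls[in_tract] <- 2L * stats::rbinom(m, 1, q[in_tract])
      if (config$het_error_rate > 0) {
        err <- stats::runif(m) < config$het_error_rate
        calls[in_tract][err] <- HET
      }
    }
  }
  if (config$missing_rate > 0)
    calls[stats::runif(n) < config$missing_rate] <- NA_integer_
  as.integer(calls)
}

#' Simulate a population with known autozygosity truth
#'
#' Seeds the RNG from `config$seed` (fully deterministic), builds the map
#' and allele frequencies, plants island tracts in a random carrier subset,
#' samples each individual's random tracts and genotypes, and finally
#' injects any configured QC failures. The truth record stores every
#' planted tract, each individual's true autozygous fraction (total tract
#' bp over total genome bp), island carrier IDs and spiked QC failure IDs.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_result` with elements `dataset`
#'   (a [genotype_dataset()]), `truth` (list with `tracts`, `true_f`,
#'   `island_carriers`, `qc_spike_ids`) and `config`
#' @export
simulate_population <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_individuals
  map <- simulate_map(config)
  maf <- stats::runif(nrow(map), config$maf_range[1], config$maf_range[2])
  p_ref <- ifelse(stats::runif(nrow(map)) < 0.5, maf, 1 - maf)

  pops <- if (is.null(config$population_sizes)) c(POP1 = n) else
    config$population_sizes
  if (sum(pops) != n) stop("population_sizes must sum to n_individuals")
  fid <- rep(names(pops), pops)
  iid <- sprintf("ind%03d", seq_len(n))
  samples <- data.frame(fid = fid, iid = iid, pat = rep("0", n),
                        mat = rep("0", n), sex = rep(0L, n),
                        phenotype = rep("-9", n), population = fid,
                        stringsAsFactors = FALSE)

  islands <- config$planted_islands
  carriers <- list()
  planted_by_ind <- rep(list(NULL), max(n, 1))
  if (!is.null(islands) && n > 0) {
    for (r in seq_len(nrow(islands))) {
      who <- sample.int(n, round(islands$carrier_fraction[r] * n))
      carriers[[r]] <- iid[sort(who)]
      for (i in who) {
        planted_by_ind[[i]] <- rbind(
          planted_by_ind[[i]],
          data.frame(chr = islands$chr[r], start_bp = islands$start_bp[r],
                     end_bp = islands$end_bp[r]))
      }
    }
  }

  calls <- matrix(NA_integer_, n, nrow(map))
  tract_rows <- list()
  genome_bp <- sum(config$chromosomes$length_bp)
  true_f <- numeric(n)
  for (i in seq_len(n)) {
    tr <- sample_tracts(config, planted = planted_by_ind[[i]])
    g <- simulate_genotypes(map, p_ref, tr, config)
    calls[i, ] <- g
    true_f[i] <- sum(tr$end_bp - tr$start_bp + 1) / genome_bp
    if (nrow(tr) > 0)
      tract_rows[[length(tract_rows) + 1]] <- cbind(iid = iid[i], tr)
  }
  tracts <- if (length(tract_rows)) do.call(rbind, tract_rows) else
    data.frame(iid = character(), chr = integer(), start_bp = numeric(),
               end_bp = numeric())

  spike_ids <- list(low_call_rate_snps = character(),
                    low_maf_snps = character(), hwe_fail_snps = character(),
                    high_missing_individuals = character())
  sp <- config$qc_spike
  if (!is.null(sp) && n > 0) {
    avail <- seq_len(nrow(map))
    take <- function(k) {
      j <- sample(avail, k)
      avail <<- setdiff(avail, j)
      j
    }
    if (!is.null(sp$n_low_call_rate) && sp$n_low_call_rate > 0) {
      j <- take(sp$n_low_call_rate)
      for (s in j) calls[sample.int(n, ceiling(0.15 * n)), s] <- NA_integer_
      spike_ids$low_call_rate_snps <- map$snp_id[sort(j)]
    }
    if (!is.null(sp$n_low_maf) && sp$n_low_maf > 0) {
      j <- take(sp$n_low_maf)
      for (s in j) {
        calls[, s] <- HOM_REF
        calls[sample.int(n, 1), s] <- HET  # MAF = 1/(2n) < 0.05 for n >= 11
      }
      spike_ids$low_maf_snps <- map$snp_id[sort(j)]
    }
    if (!is.null(sp$n_hwe_fail) && sp$n_hwe_fail > 0) {
      j <- take(sp$n_hwe_fail)
      calls[, j] <- HET  # all-heterozygous: extreme HWE departure, MAF 0.5
      spike_ids$hwe_fail_snps <- map$snp_id[sort(j)]
    }
    if (!is.null(sp$n_high_missing_individuals) &&
        sp$n_high_missing_individuals > 0) {
      who <- sample.int(n, sp$n_high_missing_individuals)
      for (i in who)
        calls[i, sample.int(nrow(map), ceiling(0.15 * nrow(map)))] <-
          NA_integer_
      spike_ids$high_missing_individuals <- iid[sort(who)]
    }
  }

  ds <- genotype_dataset(samples, map, calls)
  structure(list(dataset = ds,
                 truth = list(tracts = tracts,
                              true_f = stats::setNames(true_f, iid),
                              island_carriers = carriers,
                              qc_spike_ids = spike_ids),
                 config = config),
            class = "sim_result")
}

#' Write a simulation to disk
#'
#' Emits PED/MAP via [write_ped_map()] plus two truth TSVs: per-tract
#' (IID, CHR, TRACT_START_BP, TRACT_END_BP) and per-individual (IID,
#' TRUE_F).
#'
#' @param sim a `sim_result` from [simulate_population()]
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return named vector of the four paths, invisibly
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- file.path(dir, paste0(prefix, ".ped"))
  map <- file.path(dir, paste0(prefix, ".map"))
  write_ped_map(sim$dataset, ped, map)
  tr <- sim$truth$tracts
  tr_path <- file.path(dir, paste0(prefix, "_truth_tracts.tsv"))
  utils::write.table(
    data.frame(IID = tr$iid, CHR = tr$chr, TRACT_START_BP = tr$start_bp,
               TRACT_END_BP = tr$end_bp),
    tr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  f_path <- file.path(dir, paste0(prefix, "_truth_f.tsv"))
  utils::write.table(
    data.frame(IID = names(sim$truth$true_f), TRUE_F = sim$truth$true_f),
    f_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ped = ped, map = map, tracts = tr_path, true_f = f_path))
}
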