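#!/usr/bin/env Rscript
# Stage 1: simulate the study population with known autozygosity truth.
# Writes PED/MAP genotypes and the truth tables under results/analysis/data.
library(rohscan)

cfg <- read_pipeline_config("analysis/config.yml")
sc <- cfg$simulate
sc$chromosomes <- as.data.frame(sc$chromosomes)
if (!is.null(sc$planted_islands))
  sc$planted_islands <- as.data.frame(sc$planted_islands)
if (!is.null(sc$population_sizes))
  sc$population_sizes <- unlist(sc$population_sizes)
if (is.null(sc$tract_n_mean)) {
  # tune the random tract load to a true autozygous fraction of 0.05
  tmp <- do.call(sim_config, sc)
  sc$tract_n_mean <- tract_load_for_f(0.05, tmp)
}
config <- do.call(sim_config, sc)

sim <- simulate_population(config)
out <- "results/analysis/data"
paths <- write_simulation(sim, out, "sim")

message(sprintf("simulated %d individuals x %d SNPs on %d chromosomes",
                nrow(sim$dataset$samples), nrow(sim$dataset$snps),
                nrow(config$chromosomes)))
message(sprintf("mean true autozygous fraction: %.4f (planted island on chr%d, %.0f%% carriers)",
                mean(sim$truth$true_f), config$planted_islands$chr[1],
                100 * config$planted_islands$carrier_fraction[1]))
message("wrote: ", paste(paths, collapse = ", "))
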