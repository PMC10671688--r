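#!/usr/bin/env Rscript
# Stage 4: length-class descriptive statistics and F_ROH genomic inbreeding
# coefficients per individual and per population.
library(rohscan)

cfg <- read_pipeline_config("analysis/config.yml")
data_dir <- "results/analysis/data"
ds <- read_ped(file.path(data_dir, "filtered.ped"),
               read_map(file.path(data_dir, "filtered.map")))
segments <- read_segments("results/analysis/roh_segments.tsv")

# population labels come from the family IDs written by the simulator
ds$samples$population <- ds$samples$fid
l_aut <- autosomal_span(ds$snps)
froh <- froh_table(segments, ds$samples, l_aut, cfg$edges_mb)
summ <- summarize_population(segments, ds$samples,
                             length_class_scheme(cfg$edges_mb))
write_roh_stats(froh, summ, "results/analysis/froh_individuals.tsv",
                "results/analysis/roh_population_summary.tsv")

means <- froh_population_means(froh)
message(sprintf("L_aut = %.1f Mb", l_aut / 1e6))
for (r in seq_len(nrow(means)))
  message(sprintf("%s: F_ROH>1Mb = %.4f, F_ROH>8Mb = %.4f",
                  means$population[r], means$froh_gt_1mb[r],
                  means$froh_gt_8mb[r]))
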