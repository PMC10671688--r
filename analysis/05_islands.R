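#!/usr/bin/env Rscript
# Stage 5: per-SNP ROH occurrence, top-1% island extraction, gene
# annotation against the bundled synthetic gene intervals, and the
# Manhattan-style occurrence plot.
library(rohscan)

cfg <- read_pipeline_config("analysis/config.yml")
data_dir <- "results/analysis/data"
ds <- read_ped(file.path(data_dir, "filtered.ped"),
               read_map(file.path(data_dir, "filtered.map")))
segments <- read_segments("results/analysis/roh_segments.tsv")

profile <- snp_occurrence(segments, ds$snps, nrow(ds$samples))
sel <- select_top_percent(profile, cfg$islands$pct)
islands <- build_islands(sel$selected, ds$snps,
                         cfg$islands$max_island_gap_kb,
                         cfg$islands$min_island_snps)
genes <- read_gene_intervals(
  system.file("extdata", "synthetic_ovine_genes.bed", package = "rohscan"),
  "bed")
islands <- annotate_islands(islands, genes)
write_islands(islands, "results/analysis/roh_islands.tsv")
occurrence_plot(profile, sel, "results/analysis/occurrence.pdf",
                n_individuals = nrow(ds$samples))

message(sprintf("selection cutoff: occurrence count >= %d (top %g%% of %d SNPs)",
                sel$cutoff, cfg$islands$pct, nrow(profile)))
message(sprintf("%d island(s):", nrow(islands)))
for (r in seq_len(nrow(islands)))
  message(sprintf("  chr%-2d %7.2f-%7.2f Mb  n_snp=%-3d genes=%s",
                  islands$chr[r], islands$start_mb[r], islands$end_mb[r],
                  islands$n_snp[r],
                  if (nzchar(islands$genes_str[r])) islands$genes_str[r]
                  else "-"))
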