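#!/usr/bin/env Rscript
# Stage 2: marker and sample quality control. Reads the simulated PED/MAP,
# applies the filter cascade and writes the filtered genotypes + QC report.
library(rohscan)

cfg <- read_pipeline_config("analysis/config.yml")
data_dir <- "results/analysis/data"
ds <- read_ped(file.path(data_dir, "sim.ped"),
               read_map(file.path(data_dir, "sim.map")))

res <- apply_qc(ds, cfg$qc)
print(res$report)
write_ped_map(res$dataset, file.path(data_dir, "filtered.ped"),
              file.path(data_dir, "filtered.map"))
write_qc_report(res$report, "results/analysis/qc_report.tsv")
message(sprintf("retained %d individuals and %d SNPs",
                res$report$retained["individuals"],
                res$report$retained["snps"]))
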