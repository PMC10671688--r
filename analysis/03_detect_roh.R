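#!/usr/bin/env Rscript
# Stage 3: sliding-window ROH detection on the QC-filtered genotypes.
library(rohscan)

cfg <- read_pipeline_config("analysis/config.yml")
data_dir <- "results/analysis/data"
ds <- read_ped(file.path(data_dir, "filtered.ped"),
               read_map(file.path(data_dir, "filtered.map")))

segments <- detect_roh(ds, cfg$roh)
write_segments(segments, "results/analysis/roh_segments.tsv")
message(sprintf("detected %d ROH segments (%.1f per individual; mean length %.2f Mb)",
                nrow(segments), nrow(segments) / nrow(ds$samples),
                mean(segments$length_bp) / 1e6))
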