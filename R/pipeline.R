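#' Read and validate a pipeline configuration file
#'
#' YAML with nested sections `qc`, `roh`, `stats`, `islands`, `simulate`,
#' `io`; every key must match a known parameter (unknown keys are an error
#' naming the key) and missing keys take the package defaults. The returned
#' object echoes the fully resolved parameters, so a run is auditable.
#'
#' @param path YAML file path
#' @return list with `qc` ([qc_config()]), `roh` ([roh_params()]),
#'   `edges_mb`, `islands` (list `pct`, `max_island_gap_kb`,
#'   `min_island_snps`), `simulate` (raw list passed to [sim_config()]) and
#'   `io` (paths)
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- list(qc = names(formals(qc_config)),
                roh = names(formals(roh_params)),
                stats = "edges_mb",
                islands = c("pct", "max_island_gap_kb", "min_island_snps"),
                simulate = names(formals(sim_config)),
                io = c("ped", "map", "genes", "genes_dialect", "out_dir"))
  bad_sec <- setdiff(names(raw), names(known))
  if (length(bad_sec))
    stop("unknown config section: ", paste(bad_sec, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(bad))
      stop("unknown config key in '", sec, "': ", paste(bad, collapse = ", "))
  }
  list(qc = do.call(qc_config, raw$qc %||% list()),
       roh = do.call(roh_params, raw$roh %||% list()),
       edges_mb = raw$stats$edges_mb %||% c(1, 2, 4, 8, 16),
       islands = list(pct = raw$islands$pct %||% 1,
                      max_island_gap_kb = raw$islands$max_island_gap_kb %||% 1000,
                      min_island_snps = raw$islands$min_island_snps %||% 3),
       simulate = raw$simulate %||% list(),
       io = raw$io %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full ROH analysis pipeline in memory
#'
#' QC -> sliding-window ROH detection -> length-class statistics and F_ROH
#' -> occurrence profile, top-percent islands and gene annotation.
#' Deterministic given its inputs.
#'
#' @param ds a [genotype_dataset()]
#' @param qc a [qc_config()]
#' @param roh a [roh_params()]
#' @param edges_mb length-class edges in Mb
#' @param island_pct top percentage of SNPs kept as island candidates
#' @param max_island_gap_kb,min_island_snps island merging parameters
#'   (see [build_islands()])
#' @param genes gene intervals from [read_gene_intervals()], or `NULL`
#' @return list with `qc_report`, `dataset` (post-QC), `segments`, `l_aut`,
#'   `froh`, `froh_means`, `pop_summary`, `profile`, `selection`, `islands`
#' @export
roh_pipeline <- function(ds, qc = qc_config(), roh = roh_params(),
                         edges_mb = c(1, 2, 4, 8, 16), island_pct = 1,
                         max_island_gap_kb = 1000, min_island_snps = 3,
                         genes = NULL) {
  qcres <- apply_qc(ds, qc)
  clean <- qcres$dataset
  segments <- detect_roh(clean, roh)
  l_aut <- autosomal_span(clean$snps)
  scheme <- length_class_scheme(edges_mb)
  froh <- froh_table(segments, clean$samples, l_aut, edges_mb)
  pop_summary <- summarize_population(segments, clean$samples, scheme)
  profile <- snp_occurrence(segments, clean$snps, nrow(clean$samples))
  selection <- if (all(profile$count == 0)) {
    warning("no SNP lies in any ROH: no islands can be reported")
    list(selected = rep(FALSE, nrow(profile)), cutoff = NA_real_,
         k = ceiling(island_pct / 100 * nrow(profile)))
  } else select_top_percent(profile, island_pct)
  isl <- build_islands(selection$selected, clean$snps,
                       max_island_gap_kb, min_island_snps)
  isl <- annotate_islands(isl, genes)
  list(qc_report = qcres$report, dataset = clean, segments = segments,
       l_aut = l_aut, froh = froh,
       froh_means = froh_population_means(froh),
       pop_summary = pop_summary, profile = profile, selection = selection,
       islands = isl)
}

#' Write the full report bundle of a pipeline run
#'
#' TSV reports for QC, segments, per-individual F_ROH, population summary
#' and islands, plus a Manhattan-style occurrence plot and a plain-text run
#' manifest (package version, parameters actually used, per-stage row
#' counts; no timestamps, so identical runs produce identical bundles).
#'
#' @param result list from [roh_pipeline()]
#' @param out_dir output directory (created if needed)
#' @param plot_file occurrence plot file name
#' @return named vector of written paths, invisibly
#' @export
write_report_bundle <- function(result, out_dir,
                                plot_file = "occurrence.pdf") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    qc = write_qc_report(result$qc_report, file.path(out_dir, "qc_report.tsv")),
    segments = write_segments(result$segments,
                              file.path(out_dir, "roh_segments.tsv")))
  write_roh_stats(result$froh, result$pop_summary,
                  file.path(out_dir, "froh_individuals.tsv"),
                  file.path(out_dir, "roh_population_summary.tsv"))
  paths["froh"] <- file.path(out_dir, "froh_individuals.tsv")
  paths["pop_summary"] <- file.path(out_dir, "roh_population_summary.tsv")
  paths["islands"] <- write_islands(result$islands,
                                    file.path(out_dir, "roh_islands.tsv"))
  paths["plot"] <- occurrence_plot(result$profile, result$selection,
                                   file.path(out_dir, plot_file),
                                   n_individuals = nrow(result$dataset$samples))
  manifest <- c(
    paste0("rohscan_version: ",
           as.character(utils::packageVersion("rohscan"))),
    paste0("individuals_post_qc: ", nrow(result$dataset$samples)),
    paste0("snps_post_qc: ", nrow(result$dataset$snps)),
    paste0("n_segments: ", nrow(result$segments)),
    paste0("l_aut_bp: ", format(result$l_aut, scientific = FALSE)),
    paste0("n_islands: ", nrow(result$islands)),
    paste0("island_cutoff_count: ", result$selection$cutoff))
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  paths["manifest"] <- file.path(out_dir, "run_manifest.txt")
  invisible(paths)
}
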