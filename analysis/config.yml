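# Study conditions for the worked ROH analysis. QC and detection parameters
# follow the standard SNP-chip defaults built into the package; the
# simulated population is the desk-scale preset (3 chromosomes x 2000 SNPs,
# ~50 kb spacing, 100 sheep in three cohorts) with a shared autozygous
# tract planted on chromosome 2 so the island stage has a known signal.
simulate:
  n_individuals: 100
  population_sizes: {POP1: 40, POP2: 35, POP3: 25}
  # chromosome codes 2, 6 and 13 so the bundled synthetic gene intervals
  # (placed on ovine autosomes) can annotate the recovered islands
  chromosomes:
    chr: [2, 6, 13]
    length_bp: [100000000, 100000000, 100000000]
    n_snps: [2000, 2000, 2000]
  tract_mean_mb: 4
  tract_min_mb: 2
  planted_islands:
    chr: [13]
    start_bp: [50000000]
    end_bp: [52000000]
    carrier_fraction: [0.5]
  het_error_rate: 0.0
  missing_rate: 0.01
  seed: 20260919
qc:
  # a tract forced homozygous in half the cohort is an extreme HWE
  # violation at every SNP it covers, so the HWE filter is disabled for
  # this island-bearing simulation; see the methods vignette
  hwe_alpha: 0.0
roh:
  min_snps: 15
  min_length_kb: 1000
islands:
  pct: 1
  max_island_gap_kb: 1000
  min_island_snps: 3
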