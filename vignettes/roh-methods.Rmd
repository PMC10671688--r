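---
title: "Methods: sliding-window ROH detection, F_ROH and ROH islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window ROH detection, F_ROH and ROH islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

# The analysis

Runs of homozygosity (ROHs) are contiguous stretches of homozygous
genotypes along one individual's genome. Long runs arise when both
haplotypes descend from a recent common ancestor (autozygosity), so their
number, length distribution and genomic placement summarize a population's
inbreeding history: many short runs point to ancient inbreeding, few long
runs to recent inbreeding, and loci where runs pile up across individuals
("ROH islands") are candidate selection signatures.

`rohscan` implements the complete chain for diploid SNP-chip genotypes in
PLINK-dialect PED/MAP text files, as typically produced for livestock
arrays such as the ovine 50K chip (26 autosomes, ~50 kb marker spacing):

1. **QC** (`apply_qc`): autosome restriction, per-individual missingness,
   per-SNP call rate, minor allele frequency, exact Hardy–Weinberg test.
2. **Detection** (`detect_roh`): a PLINK-style sliding-window scan.
3. **Statistics** (`summarize_population`, `froh_table`): length-class
   descriptive tables and the genomic inbreeding coefficient F_ROH.
4. **Islands** (`snp_occurrence`, `select_top_percent`, `build_islands`,
   `annotate_islands`): per-SNP ROH occurrence, top-1% selection, island
   merging and gene annotation.

Because SNP-chip studies rarely deposit raw genotypes, the package also
ships a simulator (`simulate_population`) that generates chip-like datasets
with *known* autozygosity, so the whole chain can be validated by parameter
recovery rather than by comparison to an unavailable dataset.

# Quality control

Filters run in a fixed order, each computed on the survivors of the
previous step: (1) autosomes only, (2) individuals with missingness
> `max_individual_missing` (default 0.10), (3) SNPs with call rate
< `min_snp_call_rate` (default 0.90), (4) SNPs with MAF < `min_maf`
(default 0.05), (5) SNPs with exact HWE p-value < `hwe_alpha` (default
1e-4). Sample filters precede the frequency filters because
high-missingness individuals distort MAF and HWE estimates; exclusion is
strict (values exactly at a threshold are retained). MAF and HWE use
non-missing calls only, pooled over all retained individuals.

The HWE test is the two-sided exact test conditional on the observed
allele counts: the p-value sums the probabilities of all heterozygote
counts no more probable than the observed one. Probabilities come from a
multiplicative recurrence over heterozygote counts (no factorials of large
n) with renormalization, so the test is stable at chip-scale sample sizes;
a mid-p variant is available (`hwe_midp`). Ties are detected with a 1e-9
relative tolerance so mathematically equal outcomes are always included.

# ROH detection model

The scan follows the window heuristic of PLINK 1.07 with every choice
exposed as a parameter of `roh_params()`:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 15 | sliding window size (SNPs) |
| `window_max_het` | 1 | heterozygous calls tolerated per window |
| `window_max_missing` | 1 | missing calls tolerated per window |
| `window_threshold` | 0.05 | fraction of homozygous windows for a SNP to be flagged |
| `min_snps` | 15 | homozygous SNPs required per segment |
| `min_length_kb` | 1000 | minimum segment span |
| `max_density_kb_per_snp` | 100 | maximum average spacing inside a segment |
| `max_gap_kb` | 250 | maximum gap between consecutive SNPs of a run |
| `het_terminates` | TRUE | a heterozygous call always ends a run |

Per chromosome and individual, every `window_snps`-wide window is marked
homozygous when it holds at most `window_max_het` heterozygous and
`window_max_missing` missing calls. Each SNP's support is the fraction of
homozygous windows among the windows that *physically contain it* — near
chromosome ends the denominator shrinks accordingly — and the SNP is
flagged at support ≥ `window_threshold`. Candidate runs are maximal
stretches of consecutive flagged SNPs whose own call is homozygous or
missing; runs are split where neighbouring SNPs lie more than `max_gap_kb`
apart, trimmed to start and end on homozygous calls, and kept when they
satisfy `min_snps`, `min_length_kb` and the density cap. Segment bounds
are the first and last SNP positions (no extension into flanking
inter-SNP space); `length_bp = end - start + 1`.

Two contested choices are made explicit rather than inherited silently
from any one tool (PLINK and detectRUNS differ in their window mechanics,
and published analyses often do not say which produced the final
segments):

* **Heterozygote termination.** By default a heterozygous call ends a run
  even if window smoothing would bridge it — the strict reading of "runs
  of homozygosity". With `het_terminates = FALSE` a *flagged* heterozygous
  call may sit inside a run, like a missing call; in both modes only
  homozygous calls count toward `n_snps`, which keeps the density rule
  meaning "one homozygous SNP per `max_density_kb_per_snp`".
* **Missing calls** may sit inside a run but never start or end one and
  never count toward `n_snps`.

Both modes are verified, instance for instance, against an exhaustive
oracle that enumerates every candidate sub-interval and keeps maximal
intervals satisfying the declarative segment predicate.

# Length classes and F_ROH

Length classes derive from Mb edges (default 1, 2, 4, 8, 16) in two views:
cumulative classes "≥ e" (the "1+, 2+, ..." columns of descriptive
tables) and interval classes [e_i, e_{i+1}) plus a final open class. The
descriptive tables report mean, sample SD (n−1; 0 for single-individual
cohorts), minimum and maximum of per-individual counts and total lengths,
with zero-segment individuals contributing zeros (dropping them would bias
cohort means upward).

The genomic inbreeding coefficient is

$$F_{ROH} = \frac{\sum L_{ROH}}{L_{aut}}$$

per length threshold, where the numerator sums segments *strictly longer*
than the threshold (matching "F_ROH > 1 Mb" column heads) and L_aut is the
autosomal span actually covered by the post-QC map (per chromosome, last
SNP minus first SNP plus one) — not a fixed genome constant, which keeps
simulated and real datasets on the same footing. Computed this way from a
single segment set, F_ROH is necessarily non-increasing in the threshold;
published tables that violate this monotonicity can only arise from
re-running detection per class, which this package deliberately does not
do.

# ROH islands

Occurrence is the fraction of (post-QC) individuals whose ROHs cover each
SNP, pooled over all cohorts. The top `pct`% (default 1%) of SNPs by
occurrence are selected with inclusive tie handling at the cutoff
(deterministic and order-independent; the selection can exceed
`ceiling(pct/100 · n)` SNPs). Selected SNPs on the same chromosome merge
into an island while consecutive selected SNPs lie within
`max_island_gap_kb` (default 1000 kb); islands with fewer than
`min_island_snps` (default 3) selected SNPs are dropped. The merge
distance and minimum size are declared defaults, not values inferred from
any published analysis — island tables in the literature (typically one to
several Mb wide with tens of SNPs) are consistent with generous merging
but cannot disambiguate the rule. A gene
is annotated to an island when their bp intervals overlap by at least
1 bp; the gene interval file (BED or GFF3) is treated as authoritative for
coordinates, since chip positions are genome-build-dependent.

Reports print Mb to 2 decimals; all internal coordinates are 1-based
closed bp (BED converted on read).

# The simulator and what passing tests show

`simulate_population` emulates a chip-like dataset: per chromosome, SNP
positions drawn uniformly without replacement; per-SNP minor allele
frequencies uniform on [0.05, 0.5] shared by all individuals (one
panmictic base population); genotypes drawn from Hardy–Weinberg
proportions outside autozygous tracts. Tracts are forced homozygous for a
single allele drawn by frequency — autozygosity by construction rather
than by pedigree simulation, which gives exact control of the true
autozygous fraction F and of island truth. Tract counts are Poisson; tract
lengths are `tract_min_mb + Exp(tract_mean_mb − tract_min_mb)` so the
configured mean is the realized mean; tracts are placed uniformly,
non-overlapping by rejection sampling (capped at 1000 retries, so the true
F stays additive). Shared tracts can be planted at fixed loci in a random
carrier subset to create recoverable islands, heterozygote error can be
injected inside tracts, missingness everywhere, and QC failures of every
kind can be spiked with known identities.

The default desk scale — 3 chromosomes × 2000 SNPs (~50 kb spacing) × 100
individuals — simulates and analyses in roughly a second, which is the
problem size used throughout the tests and the acceptance script (10–20
replicates per experiment); `chip_scale = TRUE` gives 26 autosomes, ~47k
SNPs and 281 individuals for slower end-to-end runs.

What the simulator does *not* emulate: linkage disequilibrium and
haplotype structure, allele-frequency spectra of real chips, pedigree
relationships, batch effects, or clustered genotyping error. Passing
recovery tests therefore demonstrate that the detection chain measures
what it claims under its own assumptions — they do not certify accuracy
on a real chip, where background identity-by-state runs (driven by LD)
inflate short-ROH counts.

Two systematic effects are visible in the recovery experiments and worth
knowing about:

* **Boundary snapping and gap splitting.** Detected segments start and end
  on SNPs, so each tract loses about one marker spacing per side; and at
  50 kb mean spacing roughly 0.7% of inter-SNP gaps exceed 250 kb, each
  splitting a run and dropping the gap from the summed length. Detected
  mean F_ROH therefore sits a few percent *below* true F (about −0.004 at
  F = 0.10 at desk scale) — well inside the ±0.015 recovery tolerance, and
  shrinking as marker density grows.
* **HWE filtering versus islands.** A tract forced homozygous in a large
  fraction of individuals (60% in the recovery experiment) is an extreme
  Hardy–Weinberg violation at every SNP it covers — as any strong
  selection signature is — so the default `hwe_alpha = 1e-4` removes
  exactly those SNPs before detection. Island-recovery experiments
  therefore run QC with `hwe_alpha = 0`; with real data, a strict HWE
  filter can erase exactly the signatures an island scan is looking for,
  and the filter exists to catch genotyping artifacts, not selection.

# Numerical and degenerate-input choices

* Call codes: 0 = hom-reference, 1 = het, 2 = hom-alternate, `NA` =
  missing; the reference allele per SNP is the lexicographically smaller
  observed allele (the pipeline is orientation-agnostic, so any
  deterministic rule serves; a SNP whose written PED file shows only one
  allele is re-read with that allele as reference, which is the only
  ambiguity of the round trip).
* Unsorted MAP input is sorted with a warning; `strict_sorted = TRUE`
  rejects it instead. Duplicate SNP IDs, triallelic SNPs, malformed lines
  and field-count mismatches are errors naming the offending line or SNP.
* A chromosome shorter than one window yields no windows, hence no flagged
  SNPs (logged); a chromosome with a single SNP contributes 1 bp to
  L_aut (logged).
* An all-missing SNP surviving the call-rate filter (possible only at
  `min_snp_call_rate = 0`) is treated as MAF 0 at the MAF step and as
  carrying no HWE evidence (p = 1).
* QC that removes every individual or every SNP raises an error carrying
  the report, rather than returning an empty dataset.
* Zero detected segments propagate cleanly: zero-filled F_ROH tables, an
  all-zero occurrence profile (with a warning), and an empty island table.

# Reproducibility

`simulate_population` seeds R's RNG from `config$seed` and is
byte-reproducible; detection and all downstream stages are deterministic
given their inputs, so pipeline reruns produce identical report bundles
(`write_report_bundle` writes no timestamps). The numbered scripts under
`analysis/` run the stages over a YAML configuration whose unknown keys
are rejected by `read_pipeline_config`, and every stage prints the
parameters it actually used.
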