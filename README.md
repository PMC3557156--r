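# sweepscan

Genome-wide selective-sweep scans from phased SNP haplotypes.

`sweepscan` detects signatures of recent directional selection in phased
SNP-array haplotype panels, the way classic livestock and human
selection-scan studies did it:

1. **Marker filtering** — drop unplaced and monomorphic markers and those
   with minor allele frequency below 0.05.
2. **Core-region detection** — classify every nearby marker pair by
   likelihood-based confidence bounds on |D′| (the Gabriel rule: a pair is
   in *strong LD* when the 90% CI has lower bound ≥ 0.70 and upper bound
   ≥ 0.98), then assemble maximal runs of markers in which ≥ 95% of
   informative pairs are strong into non-overlapping core regions.
3. **EHH / REHH testing** — for every core haplotype (distinct allele
   string over a region) with at least two carriers, compute extended
   haplotype homozygosity at the first marker at least 1 Mb beyond the
   region boundary, on both flanks, together with EHH̄ (the pooled EHH of
   all non-carrier chromosomes) and their ratio REHH = EHH/EHH̄.
4. **Significance** — bin tests into 20 core-haplotype frequency bins and
   assign within-bin p-values, either empirical ranks (default) or an
   upper-tail log-normal fit to ln REHH; tests with frequency ≥ 0.25 and
   p < α are reported as significant. A Benjamini–Hochberg column is
   emitted for convenience but never drives the significant flag.
5. **Annotation and contrast** — overlap significant regions with BED
   interval files (regions without features carry `/`), and compare core
   haplotype frequencies between two populations with a chi-square
   contingency test (rare haplotypes pooled).

The package also ships a forward Wright–Fisher simulator of phased panels
(neutral, selective-sweep, and divergently selected two-line modes), used
both for its own statistical calibration and as a general test-data
source.

## Quick start

Simulate a genome containing one hard sweep and scan it:

```r
library(sweepscan)

params <- sweep_sim_params(
  pop_size = 500, n_haplotypes = 200, n_chromosomes = 2,
  chrom_length_bp = 5e6, target_n_snps = 225, n_founders = 100,
  n_generations = 10,
  sweep = list(selection_coefficient = 0.1, start_frequency = 0.3,
               final_frequency_range = c(0.4, 0.8))
)
sim <- simulate_sweep(params, seed = 15)
sim$truth$focal_pos
#> [1] 2500000

scan <- genome_scan(sim$panel, scan_config(bin_scheme = "count",
                                           p_mode = "lognormal",
                                           max_pair_span_bp = 1.2e6))
scan
#> sweep_scan: 91 core regions, 572 REHH tests (294 at freq >= 0.25),
#>             4 significant at p < 0.01

head(scan$significant[order(scan$significant$p_value),
     c("chrom", "core_start", "core_end", "frequency", "rehh", "p_value")])
#>     chrom core_start core_end frequency rehh p_value
#> 281     1    4375729  4388439     0.460 17.3 0.00148
#> 287     1    4460008  4460537     0.460 17.2 0.00153
#> 161     1    2500000  2534550     0.535 46.8 0.00400
#> 191     1    3112070  3122890     0.530 37.3 0.00675
```

The region starting at 2,500,000 contains the simulated sweep's focal
site (note that the ±2 Mb swept segment also lifts REHH at neighbouring
core regions — adjacent hits are expected, exactly as published sweep
maps report clusters of significant cores).

Real data enter through `read_phased_vcf()` (phased, biallelic,
GT-only VCF) or `read_hap_legend()` (IMPUTE-style `.hap`/`.legend`),
both returning the same `haplotype_panel` object.

## Pipeline and CLI

File-based stages wrap the same functions and log a JSON manifest with
md5 digests and record counts:

```r
run_scan("panel.vcf", "out/")          # tests.tsv, per_chrom_counts.tsv,
                                       # significant_regions.tsv,
                                       # manhattan.tsv, filter_report.tsv
run_annotate("out/", "qtl.bed")        # annotated_regions.tsv
run_contrast(panel_a, panel_b, "out/", "contrast_out/")
```

or from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/sweepscan.R", package="sweepscan"))') \
  scan --input panel.vcf --out out --alpha 0.01 --bin-scheme count
```

Subcommands: `simulate`, `scan`, `annotate`, `contrast`; `--version`.
Reruns on identical inputs produce byte-identical TSVs.

## Calibration

`calibration_design()` freezes the synthetic study conditions used by the
package's own validation (also exercised by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`):

- `evaluate_type_i_error()` — neutral genome, ~3000 tests: the fraction of
  p-values below 0.01 matches the nominal rate within binomial tolerance.
- `evaluate_sweep_power()` — 20 replicate genomes with s = 0.1: the core
  region overlapping the sweep is flagged significant in a large majority
  (18/20 at the frozen design).
- `evaluate_contrast_null()` — exchangeable (label-permuted) two-line
  null: chi-square p-values are uniform to mildly conservative.
- `evaluate_line_divergence()` — divergently selected lines: the focal
  between-line frequency difference exceeds the genome-wide 95th
  percentile in essentially every replicate.

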