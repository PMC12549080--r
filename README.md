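# bsamapr

Bulked-segregant mapping of a mutant locus and population-scale transposon
genotyping, as a tidyverse-native R package.

## What it does, and for whom

Geneticists mapping a monogenic mutant — the motivating case is a dominant
EMS-induced mottled-rind mutation in melon — typically (i) test the F2
segregation ratio, (ii) resequence two phenotype-extreme bulks and scan the
ΔSNP index along the genome, (iii) narrow the locus with recombinant
genotyping and intersect independently mapped intervals, and (iv) genotype
a candidate structural variant (here a transposon insertion) across a
germplasm panel and test its association with the phenotype. `bsamapr`
implements that desk-side pipeline end to end, plus a synthetic-data module
that simulates every input (F2 crosses with a planted causal locus, pooled
allele counts, EMS-spectrum variants, junction reads, accession panels),
so the whole pipeline is testable without any sequencing data.

## The statistics at its core

* **SNP index** of a pool at a site: alt/(ref+alt); **ΔSNP index** =
  index(mutant pool) − index(wild pool). For a dominant mutant allele the
  causal-site expectation is 2/3 (carrier bulk is Aa:aa = 2:1) vs 0 in the
  wild bulk, decaying as E[Δ] = 2/3 − (4/3)r with the Haldane
  recombination fraction r.
* **Scan filters**: keep EMS-canonical G→A/C→T sites with index ≤ 0.8 in
  the wild-type pool and ≥ 0.2 in the mutant pool; five-SNP sliding
  windows centered at the first/fifth-SNP midpoint; high-confidence sites
  have Δ > 0.6 and per-pool depth > 10; nearby high-confidence sites merge
  into candidate regions.
* **TE genotyping**: a sample contains the insertion iff ≥ 2 reads span an
  insertion breakpoint (exact containment of ≥ 20 bp on each side of the
  junction, either orientation), after verifying the 200-bp flanks are
  unique in the genome on both strands.
* **Association**: Pearson χ² (no continuity correction) for segregation
  ratios and for the 2×2 TE-status × phenotype table, with row-conditional
  percentages rounded half-up to 2 decimals.

## Worked example

```r
library(bsamapr)

# F2 inheritance: 257 mottled vs 75 nonmottled against 3:1
segregation_chi2(257, 75)
#> Segregation test: 257 : 75 observed vs 3 : 1 expected
#> chi-square = 1.03 (df = 1), P = 0.31

# simulate a bulk experiment with a causal locus planted at 9.5 Mb
cfg <- sim_config(seed = 42)           # 20+20 bulks, ~30x, dominant allele
f2  <- simulate_f2(cfg)
v   <- simulate_bulk_counts(f2, cfg,
                            marker_positions = seq(5000, 1e7, by = 1e4))
scan <- bsa_scan(v)
scan
#> <bsa_scan> 805 filtered SNPs, 801 windows, 266 high-confidence SNPs, 1 candidate region(s)
glance(scan)
#> # A tibble: 1 x 6
#>   n_snps n_windows n_hc_snps n_regions peak_center peak_mean_delta
#>    <int>     <int>     <int>     <int>       <dbl>           <dbl>
#> 1    805       801       266         1     9100000           0.784
autoplot(scan)   # delta scatter + window line + shaded candidate region
```

The candidate region contains the planted position (9.5 Mb); the window
peak sits on the Δ ≈ 2/3 plateau around it. A TE-status panel is analysed
the same way:

```r
pan <- simulate_panel(panel_sim_spec(seed = 1))   # 650 accessions
cs  <- contingency_summary(pan)                   # phenotyped subset only
tidy(cs); glance(cs)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/bsamapr.R` (subcommands `simulate`, `scan`, `delimit`,
`intersect`, `genotype-te`, `assoc`, `segregation`).

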