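---
title: "Bulked-segregant mapping of a dominant mutant locus and transposon genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant mapping of a dominant mutant locus and transposon genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

## The problem this package addresses

A dominant mutation — here the mottled-rind phenotype of a melon EMS
mutant — is mapped by bulked-segregant analysis (BSA): two pools of
phenotypically extreme F2 individuals are resequenced and the mutant-allele
read fraction (the *SNP index*) is compared between pools along the genome.
Near the causal locus the pools differ maximally; far from it, segregation
is independent of the phenotype and the difference vanishes. The package
implements the full desk-side pipeline around that idea:

* a **synthetic-data module** that simulates the cross, the pooled read
  counts, the EMS mutation spectrum, junction reads over a transposon
  insertion, and an accession panel — so every downstream stage is testable
  without any external sequencing data;
* the **ΔSNP-index scan** with EMS-aware filtering, five-SNP sliding
  windows and candidate-region calling;
* **recombinant-based interval delimitation** and interval intersection;
* **transposon presence/absence genotyping** from breakpoint-spanning
  reads, with flank-uniqueness verification;
* the **segregation and association statistics** that accompany such a
  study (3:1 χ² test, 2×2 TE-by-phenotype contingency summary).

## The model

### SNP index and its expected values

For a pool with `ref` and `alt` read counts at a site, the SNP index is
`alt / (ref + alt)`. With a dominant mutant allele *a*, the
mutant-phenotype bulk contains genotypes *Aa* and *aa* in a 2:1 ratio, so
its expected mutant-allele frequency at the causal site is

$$\frac{2 \cdot 1 + 1 \cdot 2}{2 \cdot 3} = \tfrac{2}{3},$$

while the wild-phenotype bulk is pure *AA* and has expectation 0. The
ΔSNP index (mutant pool minus wild pool) therefore peaks at 2/3 — not 1,
as it would for a recessive mutation — and decays with the recombination
fraction *r* toward an unlinked expectation of 0 as

$$E[\Delta] = \tfrac{2}{3} - \tfrac{4}{3} r.$$

Both limits are verified in the test suite against an exhaustive
enumeration of the genotype classes, and by simulation.

### Recombination and read-count model

Gametes recombine as a Poisson crossover process along the chromosome (no
interference), so the marginal recombination fraction between two points at
map distance *d* Morgans is the Haldane value `r = (1 - exp(-2d))/2`.
`simulate_bulk_counts()` derives every bulk individual's marker genotypes
from its causal genotype by simulating that crossover process per homolog,
conditional on the causal-locus allele; `simulate_marker_table()` uses the
same process at the whole-gamete level for recombinant fine-mapping input.
Sequencing depth per site per pool is Poisson (`mean_depth`, truncated at
≥ 1) and the alt count is binomial in the pool allele frequency. There is
no read-level error model, no indels and no quality scores; variants are
biallelic SNVs throughout.

### The scan

Per-site points are filtered to canonical EMS transitions (G→A, C→T on the
sequenced strand), then to sites with SNP index ≤ 0.8 in the wild-type
pool and ≥ 0.2 in the mutant pool (inclusive bounds, as conventionally
printed). Sliding windows of five consecutive SNPs (step one SNP) report
the mean Δ at the floor of the midpoint between the first and fifth SNP.
Sites with Δ > 0.6 (strict) and both pool depths > 10 (strict, per pool)
are high-confidence; consecutive high-confidence sites closer than 1 Mb
are merged into candidate regions ranked by supporting SNP count.

Two interpretation notes. The index filter's published phrasing labels the
wild-type pool "dominant" although the mutant phenotype is the dominant
one; the filter is implemented exactly as printed, with the pool mapping
(`mut_pool` = mottled bulk, `wt_pool` = nonmottled bulk) fixed and
documented rather than reinterpreted. The per-pool reading of the depth
rule is a deliberate choice: a site unobserved in one pool has an
undefined index there, so both pools must clear the threshold.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bulk_size` | 20 | individuals per phenotype pool |
| `mean_depth` | 30 | reads/site/pool (truncated Poisson) |
| `n_f2` | 332 | F2 population size from which bulks are drawn |
| `recomb_rate` | 4e-8 M/bp | ≈ 4 cM/Mb, a typical cucurbit genome-wide rate |
| `frac_canonical_ems` | 0.8 | fraction of simulated variants that are G→A/C→T |
| `wt_index_max`, `mut_index_min` | 0.8, 0.2 | per-pool index filter (inclusive) |
| `delta_min`, `depth_min` | 0.6, 10 | high-confidence rules (strict) |
| `window_snps`, `window_step_snps` | 5, 1 | sliding-window geometry |
| `region_merge_gap` | 1 Mb | gap merged into one candidate region |
| `min_overlap` | 20 bp | junction overlap required of a spanning read |

The defaults for bulk size, depth, read geometry (150-bp reads, 350-bp
inserts), element length (4231 bp), flank length (200 bp) and the
two-read presence rule are the conditions of the motivating study design;
`n_f2 = 332` matches the size of a phenotyped F2 in such a design and is
also the scale at which 20 + 20 individuals of both phenotype classes are
reliably available under 3:1 segregation. The simulated chromosome is
10 Mb with the causal locus at 9.5 Mb — a deliberately scaled-down,
terminally located locus; marker density in the shipped analyses is one
SNP per 10 kb.

## What the simulator does and does not show

The generator reproduces the statistical skeleton of a BSA experiment:
Mendelian segregation, dominance, distance-dependent allele-frequency
decay with the correct joint correlation along the chromosome, realistic
pool depths, an EMS-biased spectrum, junction-read geometry, and
genotype-dependent panel phenotypes. It does **not** model sequencing
error, mapping artefacts, repeat-induced mismapping, segregation
distortion, multiple chromosomes, or phenotyping error (a
`max_discordant` tolerance exists for the last). Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artefact of real resequencing data.

## Resolution of the scan: an honest account

With 20 + 20 individuals per pool, each pool holds 40 homologs, so every
crossover in a pool steps its allele frequency by 1/40 = 0.025. At
4 cM/Mb the expected crossover spacing within a 40-homolog pool is about
625 kb. Near the causal locus the deterministic slope of the Δ profile is
`(4/3) · dr/dx` ≈ 0.05 per Mb — the same order as the frequency steps.
The Δ profile around a dominant causal locus is therefore a broad plateau
with megabase-scale correlated noise, and the *single best window* wanders
correspondingly: across 100 simulated data sets at the default
conditions, the top candidate region contains the causal position
essentially always, but the argmax window lands within 500 kb of it only
~60–70% of the time. Control simulations raising `bulk_size` to 100 push
that rate to 90–95% (while raising depth tenfold at `bulk_size = 20`
does not), confirming that pool-composition sampling — not the
implementation or read depth — limits single-window resolution. This is
why practitioners treat the called region, not the peak window, as the
mapping output, and refine it with recombinant genotyping
(`delimit_interval()`), exactly as the pipeline's fine-mapping stage does.

## Numerical and design choices

* **Window centers** use the floor of the midpoint between the first and
  last SNP; indices are kept at full precision internally and rounded only
  on output.
* **Region ranking** is by supporting high-confidence SNP count, ties by
  mean Δ.
* **Segregation and independence tests** call `stats::chisq.test()` with
  no continuity correction by default: the uncorrected Pearson statistic
  reproduces the conventional printed values (e.g. 257:75 against 3:1
  gives χ² = 1.03), whereas the Yates-corrected statistic (≈ 0.90) does
  not. The correction and Fisher's exact test are available as options.
* **Percentages** in contingency summaries are rounded half-up to two
  decimals (base `round()` is banker's rounding and would print 68.67 for
  some inputs).
* **Junction spanning** is exact substring containment (either
  orientation) of `min_overlap` bases on each side of the junction. Exact
  matching keeps the decision auditable against a brute-force oracle; a
  mismatch allowance would require an alignment model and is intentionally
  not the default. Presence evidence uses the two TE junctions; the
  reference junction is available via `junction = "absent"`.
* **Flank uniqueness** counts occurrences on both strands; a
  reverse-complement-palindromic flank planted once counts twice and is
  reported non-unique — a documented edge rather than a special case.
* **Coordinates** are 1-based inclusive internally; BED output converts to
  0-based half-open, and interval length is `end − start + 1`.
* **Delimitation endpoints** are the flanking recombinant-marker
  positions (matching the field's "between marker X and marker Y"
  phrasing), not midpoints; a block reaching the outermost markers is
  flagged open on that side.
* **Seeds**: every stochastic operation takes an explicit seed and a
  data set is fully determined by (spec, seed); the bulk-count step
  defaults to `config$seed + 1` so population and read sampling are
  decoupled but jointly reproducible.
* **Bulk composition** is by phenotype only, as in the emulated design —
  no genotype confirmation precedes pooling.

## Problem sizes in the shipped analyses

The test suite and the reproduction script use 100 simulated data sets for
locus-recovery rates, 200 for the ΔSNP-index limits, 1000 random fixtures
for the window oracle, 2000 null panels (n = 250) for type-I calibration,
and 50-sample TE panels at 30× and 1× — sizes chosen to give Monte-Carlo
standard errors comfortably below the tolerances being asserted while
keeping a full run in the minutes range on one core.

## Worked example

```{r example, eval = FALSE}
library(bsamapr)

cfg <- sim_config(seed = 1)
f2 <- simulate_f2(cfg)
variants <- simulate_bulk_counts(f2, cfg,
                                 marker_positions = seq(5000, 1e7, 1e4))
scan <- bsa_scan(variants)
top_region(scan)
autoplot(scan)

# refine with recombinants
tab <- simulate_marker_table(cfg, marker_positions = seq(8e6, 1e7, 2.5e5))
delimit_interval(tab)

# inheritance and panel statistics
segregation_chi2(257, 75)
contingency_summary(simulate_panel(panel_sim_spec(seed = 1)))
```

## Known limitations

Single chromosome, biallelic SNVs only, no error model, exact-match
junction detection, and absence treated as the no-evidence class in TE
genotyping (undersequenced carriers drift toward "absent" — quantified in
the tests as a rising false-absent rate at 1× coverage). The
marker-concordance step assumes phenotypes are observed for all
individuals; missing genotypes are tolerated per marker.
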