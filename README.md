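# radsexscan

Sex-association genome scans for RAD-sequenced F2 intercrosses.

Many fishes — zebrafish among them — lack heteromorphic sex chromosomes,
and gonadal sex segregates as a polygenic, partially penetrant trait. A
classic way to locate sex-associated regions (*sar*) is an F2 intercross
between two divergent strains genotyped genome-wide by RAD (restriction
site associated DNA) sequencing, analysed both as a linkage scan and as
a per-SNP case/control scan. radsexscan packages that entire analysis as
tested, reusable R functions, together with a forward simulator of the
cross so every stage is verifiable without any sequencing data.

## What it computes

* **Genotype calling** (`call_genotype()`, `call_matrix()`): for each
  site, the multinomial read-count likelihood of all 10 diploid genotypes
  is profiled over a *bounded* per-nucleotide error rate
  ε ∈ [0.001, 0.1] (homozygote *ii*: P(i) = 1 − ε, others ε/3;
  heterozygote *ij*: P(i) = P(j) = (1 − 2ε/3)/2), and a genotype is
  assigned only when the likelihood ratio between the two best genotypes
  is significant (χ²₁, α = 0.01). The bound keeps true heterozygotes with
  uneven read counts from being miscalled homozygous; the LRT doubles as
  an implicit depth filter.
* **Per-SNP sex scan** (`run_sexscan()`): G-test of independence,
  G = 2 Σ O ln(O/E), on sex × genotype tables for every SNP called in at
  least 20 males and 20 females, with Benjamini–Hochberg q-values within
  family and flags at q < 0.001.
* **Binary-trait LOD scan** (`run_lodscan()`, `binary_lod()`): per-class
  penetrance likelihood ratio, LOD = log₁₀(L₁/L₀), on phase-known
  four-way genotypes; genome-wide 5%/10% thresholds from permutation of
  the sex vector; 1.5-LOD support intervals with conservative flanking
  markers; haplotype-by-sex tables and Fisher's exact test.
* **Recombination** (`estimate_rf()`, `kosambi_cm()`,
  `sliding_window_rate()`): sex-specific recombination fractions from
  gametic origin switches, Kosambi conversion
  d = 25 ln((1+2r)/(1−2r)), and 3-marker sliding-window cM/Mb profiles.
* **Enrichment** (`enrichment_summary()`): observed vs expected element
  counts in a genomic region under uniform placement, percent-in-region,
  and an upper-tail binomial test.
* **Simulation** (`sim_config()`, `simulate_cross()`): reciprocal F2
  families with sex-specific maps (including male recombination
  suppression near the sar), penetrance-based sex determination at one or
  two loci, and multinomial read counts over negative-binomial depth.
* **Pipeline** (`run_all()`): simulate (or ingest) → genotype → scans →
  recombination → enrichment → text report, byte-reproducible from
  (config, seed).

## Worked example

The genotype-by-sex table at the peak sar4 marker of the larger
published family — 70 C/C individuals, all male; 75 C/G heterozygotes,
63 of them female — is already a complete analysis input:

```r
library(radsexscan)
classes <- c(rep("CC", 70), rep("CG", 75))
sexes   <- c(rep("male", 82), rep("female", 63))
haplotype_sex_table(classes, sexes)
#>   class n_male n_female percent_male
#> 1    CC     70        0          100
#> 2    CG     12       63           16
binary_lod(classes, sexes)$lod
#> [1] 28.78619
```

100% of C/C fish are male, 84% of heterozygotes are female, and the
binary-trait LOD is 28.79 — against 28.78 from full interval mapping of
the original data, inside the package's declared ±0.05 single-marker
budget.

A complete in-silico cross at the default study conditions (145 F2, 200
markers on 5 chromosomes, a sar on chr4 with penetrance 1.0/0.16/0.0):

```r
sim <- simulate_cross(sim_config(), seed = 20)
calls <- call_matrix(sim$counts, sheet = sim$samples)
calls
#> Genotype calls: 29000 records, 200 markers; call rate 93.0%

run_sexscan(calls, sim$samples)
#> Sex-differentiation G-test scan: 181 SNPs, 22 significant at q < 0.001
#>  marker_id chrom   pos_bp     G df         p         q
#>  chr4_M039  chr4 58461538 106.0  2 9.758e-24 1.766e-21
#>  chr4_M038  chr4 56923077 103.8  2 2.824e-23 2.556e-21
#>  ...

run_lodscan(sim$geno, sim$samples, n_perm = 1000, seed = 21)
#> Binary-trait LOD scan: 200 markers, 1000 permutations
#>   peak LOD 26.22 at chr4_M039 (chr4, 67.3 cM)
#>   genome-wide thresholds: 5% = 3.76, 10% = 3.38
#>   1 support interval(s): chr4 66.0-68.6 cM
```

Both scans localise the simulated sex-associated region to the terminal
markers of chr4, the LOD peak clears the genome-wide 5% permutation
threshold by a wide margin, and the 1.5-LOD interval brackets the true
locus (chr4_M039 at 67.3 cM). Enrichment arithmetic reproduces published
-style table cells:

```r
enrichment_summary(436, 261, 0.0226)[c("expected_display",
                                       "percent_display")]
#>   expected_display percent_display
#> 1              9.9            59.9
```

(436 genome-wide copies × 2.26% of the assembly → 9.9 expected; 261
observed is 59.9% of all copies.)

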