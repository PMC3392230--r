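---
title: "Methods: models, parameters and design choices in radsexscan"
author: "radsexscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in radsexscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsexscan)
```

# The problem

Zebrafish and several other fishes lack heteromorphic sex chromosomes, and
gonadal sex in laboratory strains behaves as a polygenic, partially
penetrant trait. A standard design for locating sex-associated regions
(sar) is an F2 intercross between two divergent strains, genotyped
genome-wide by RAD (restriction-site associated DNA) sequencing: F0
grandparents from each strain are crossed to F1s, F1 siblings are mated,
and each F2 carries a mosaic of grandparental haplotypes. Because founder
strains are close to fixed for different alleles at many RAD sites, F2
genotypes can be recoded as a *phase-known four-way cross*: at every
informative marker the maternal and the paternal gamete each carry either
a grandsire-strain (G1) or a granddam-strain (G2) allele.

radsexscan implements the full desk-side analysis for such a design:
genotype calling from read counts, a per-SNP case/control scan, a
binary-trait linkage scan, recombination-rate profiling, and
element-enrichment bookkeeping — plus a forward simulator so that every
stage can be exercised and calibrated without any external data.

# Genotype calling from read counts

At one site in one individual the data are the four nucleotide read
counts $(n_A, n_C, n_G, n_T)$, $n = \sum_i n_i$. Reads are modelled as
multinomial draws with per-read probabilities determined by the true
diploid genotype and a per-nucleotide sequencing error rate
$\varepsilon$:

* homozygote $ii$: $P(i) = 1 - \varepsilon$, each other base
  $\varepsilon/3$;
* heterozygote $ij$: $P(i) = P(j) = (1 - 2\varepsilon/3)/2$, other bases
  $\varepsilon/3$.

For each of the 10 unordered genotypes the log-likelihood is profiled
over $\varepsilon$ restricted to a bounded range
$[\varepsilon_{\min}, \varepsilon_{\max}] = [0.001, 0.1]$ by default.
The interior maximiser is closed-form (homozygote:
$\hat\varepsilon = (n - n_i)/n$; heterozygote with $m = n_i + n_j$:
$\hat\varepsilon = 3(n-m)/(2n)$), clipped to the bounds; the multinomial
coefficient is identical across genotypes and omitted. A genotype is
assigned only when the likelihood-ratio statistic between the two best
genotypes, $2(\ln L_1 - \ln L_2)$, reaches the $\chi^2_1$ critical value
at $1-\alpha$ (6.6349 at the default $\alpha = 0.01$); zero depth or an
exact tie yields no call.

Two properties are worth spelling out. First, the LRT criterion is an
*implicit depth filter*: a site with three or four reads can never
separate the best two genotypes significantly, so no explicit depth
cut-off is applied. Second, the upper bound on $\varepsilon$ protects
heterozygotes with uneven read counts. Without the bound, a true
heterozygote observed as, say, 40:10 can be explained as a homozygote
with an inflated error rate; capping $\varepsilon$ at 0.1 makes that
explanation expensive, and the set of count vectors miscalled homozygous
is strictly contained in the unbounded caller's set (the test suite
verifies this by enumeration at depth 50).

Choices that were genuinely open: the test's reference distribution is
taken as $\chi^2$ with 1 df (configurable); ties are always resolved to
no-call, because a tie means the data cannot distinguish genotypes; and
all 10 genotypes are evaluated at every site rather than only those
supported by observed nucleotides — with 4 observed bases the extra
likelihoods are cheap and the ranking is unaffected.

# The per-SNP sex-differentiation scan

Within one family, each called SNP is cross-tabulated as sexes (rows) by
genotype classes (columns); all-zero columns are dropped, and SNPs
genotyped in fewer than 20 males or fewer than 20 females are removed
before testing. The test is the G-test of independence,
$G = 2\sum O \ln(O/E)$ over cells with $O > 0$, with
$df = (r-1)(c-1)$ and no continuity or Williams correction; cells with
$O = 0$ contribute zero (the standard limit). Genotypic tables are the
default because per-genotype counts are the natural unit for a
partially penetrant binary trait; an allelic $2\times2$ mode is provided
behind a flag for comparison. Multiple testing is controlled with
Benjamini–Hochberg q-values computed *within family* (never pooled
across families), and the scan flags SNPs at $q < 0.001$ — the
"0.1 percent FDR" line.

# The binary-trait LOD scan

On phase-known four-way classes the trait model is binomial: under the
alternative each genotype class $g$ has its own penetrance
$\hat p_g = m_g/(m_g + f_g)$ (males $m_g$, females $f_g$), under the
null all classes share the pooled $\hat p = M/(M+F)$, and
$\mathrm{LOD} = \log_{10}(L_1/L_0)$ with $0\ln 0 = 0$. This is a
*single-marker* scan: with dense, fully informative phase-known markers
the hidden-genotype machinery of interval mapping adds nothing between
markers, and at the peak marker the two approaches agree closely — on
the published sar4 genotype-by-sex table (70/0 vs 12/63) the
single-marker LOD is 28.79 against the interval-mapped 28.78, inside
the declared ±0.05 budget.

Genome-wide significance comes from a permutation test: the sex vector
is shuffled among individuals (preserving genotype correlation), the
genome-wide maximum LOD is recorded per permutation, and the 95th/90th
percentiles (quantile type 7, fixed for bit-reproducibility given a
seed) are the 5%/10% thresholds. Internally the permutation engine
evaluates the same likelihood through class-indicator matrix products,
so thousands of permutations over hundreds of markers run as a handful
of BLAS calls; the scalar and vectorised paths are tested against each
other.

Support intervals use the 1.5-LOD drop rule: from the peak outward to
the outermost marker with $\mathrm{LOD} \ge \mathrm{peak} - 1.5$, then
one marker beyond on each side as a conservative flank, clamped at
chromosome ends. The flank width and drop are configurable.

# Recombination rates

For the chosen parent's gametes, the recombination fraction between two
markers is the fraction of individuals whose grandparental origin
switches; estimates at or above 0.5 are capped at 0.4999 (the Kosambi
transform diverges at 0.5), and individuals missing either marker are
dropped pairwise. Map distance uses the Kosambi function
$d = 25\ln\frac{1+2r}{1-2r}$ cM with inverse
$r = \tfrac12\tanh(2d/100)$. Rate profiles use a sliding window of
3 markers advancing 1 marker per estimate:
$\mathrm{rate} = \Delta\mathrm{cM}/\Delta\mathrm{Mb}$ across the
window, anchored at the middle marker (anchoring is a reporting choice;
the spanned interval is what carries information).

# Element enrichment

For an element class with $n$ genome-wide copies and a region covering
fraction $f$ of the assembly, the expected count under uniform placement
is $nf$, the percent-in-region is $100\,\mathrm{obs}/n$, and an
upper-tail binomial p-value quantifies enrichment. Elements are counted
by their 0-based start position (half-open region; an any-overlap rule
is available). Display rounding is half-away-from-zero, one decimal
below 10 and integer at 10 or above for expected counts — matching how
such tables are conventionally printed. The region fraction is an input
(2.26% for the published heterochromatic-arm analysis), not recomputed
from assembly sizes.

# The simulator and what it does (not) emulate

`sim_config()` defaults define the study conditions used across the test
suite:

* **n_f2 = 145** — the mapped-family size of the larger published cross.
* **Genome**: 5 chromosomes × 60 Mb × 40 evenly spaced markers
  (200 markers). This is a deliberate desk-scale reduction of a
  25-chromosome, ~4,800-marker design; it preserves marker density per
  cM where it matters (around the sar) while keeping the Monte-Carlo
  suites inside minutes.
* **Maps**: 94 cM per chromosome for females (scaling the ~2,350 cM
  25-chromosome female map), male map half as long genome-wide —
  reproducing the qualitative male recombination reduction — with the
  terminal 10% of the sar chromosome compressed 5-fold in males,
  emulating recombination suppression around the sex-associated region.
  Gametes are generated interval-wise with no interference, each
  interval's recombination fraction being the Kosambi inverse of its
  sex-specific cM span; interval-wise r recovery is the testable
  contract, and no interference model is asserted beyond that.
* **Sex determination**: penetrance lookup at the sar genotype —
  defaults (1.0, 0.16, 0.0) for (G1G1, G1G2, G2G2), the rates implied by
  the published peak-marker table (all grandsire-homozygotes male, 84%
  of heterozygotes female). Two-locus designs take an explicit joint
  3×3 table; no epistasis functional form is imposed.
* **Reads**: negative-binomial depth (mean 30, dispersion 5 — the
  published analysis reports a 20× criterion for map markers, not a
  depth distribution, so these are this package's choices), zeroed with
  probability 0.05, and multinomial counts at a true error rate of 0.01
  (the published data's true error rate is unknown; 0.01 is a
  conventional Illumina-era figure, flagged here as a choice).
* **founder_allele_freq_diff = 0.9** — the fraction of markers fixed for
  different nucleotides between founder strains.

What the simulator does **not** emulate: read-level sequence artefacts
(PCR duplicates, allele-specific capture bias beyond the symmetric
multinomial error), segregation distortion, genotyping batch effects,
mis-assembled reference regions, and environmental effects on sex.
Passing tests therefore demonstrate statistical correctness and
calibration of the methods under the stated generative model — not
robustness to every artefact of real RAD data.

# Numerical and procedural choices

* Profile likelihoods are closed-form; the suite checks them against a
  dense $\varepsilon$-grid (step $10^{-5}$) to $10^{-6}$.
* Permutation and simulation sizes in the test suite: the FDR-control
  property uses 200 families × 10,000 null SNPs; the type-I check uses
  200 replicates of 500 markers × 1,000 permutations; power/localisation
  uses 100 replicates at n = 145 with 1,000 permutations. The
  acceptance script runs reduced versions (50/50/30 replicates, 500
  permutations) sized to finish in well under a minute while keeping
  Monte-Carlo error small relative to the bands checked.
* One RNG stream per pipeline stage, derived from the master seed by
  fixed offsets, so changing the permutation count never perturbs the
  simulation draws and stage outputs are byte-reproducible.
* Degenerate inputs: zero depth and likelihood ties give no-call;
  single-class markers give LOD 0 with a warning; zero-margin G-test
  tables are the caller's responsibility to drop (the scan drops them);
  r = 0.5 caps at 0.4999; zero-physical-span windows are skipped with a
  warning; a family with no females reports its sex ratio as
  `"undefined"` rather than infinity.

# Known limitations

* The LOD scan is single-marker; between-marker peaks are not
  interpolated, so support intervals are resolved only to marker
  positions.
* The G-test relies on the asymptotic $\chi^2$ distribution; with 20+
  individuals per sex this is adequate (the null-uniformity property is
  tested), but very sparse genotype classes at a SNP are dropped rather
  than exact-tested.
* Multi-allelic sites beyond the 10-genotype enumeration and
  base-quality-aware likelihoods are out of scope.
* The enrichment module treats region fraction as exact and elements as
  exchangeable; it implements uniform-placement bookkeeping, not a
  composition-aware null.
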