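---
title: "Methods and design notes for fluctspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for fluctspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

fluctspec implements a complete desk pipeline for detecting mutator
phenotypes in *Saccharomyces cerevisiae*: mutation-rate estimation from
fluctuation assays, mutation calling from pooled-mutant amplicon
sequencing, mutation-spectrum analysis of panel polymorphisms, and an
exact Monte-Carlo comparison of spectra. This vignette records the models,
the parameter choices, and the design decisions that were genuinely open,
so that a maintainer can see why the code is the way it is.

## The Lea-Coulson model and its estimator

A fluctuation assay grows many parallel cultures from a small inoculum to
`Nt` cells and selects for loss-of-function mutants of a reporter gene.
Under the Lea-Coulson formulation of the Luria-Delbrück process, mutation
events arrive as a Poisson process proportional to population size
(expected total `m` per culture) and each mutant lineage grows as a birth
process inside the exponentially expanding wild-type population. This
yields a compound-Poisson count: Poisson(`m`) clones with i.i.d. sizes
`P(K = k) = 1/(k(k+1))`, equivalent to the Ma-Sandri-Sarkar recursion used
in `lea_coulson_pmf()`. The heavy `1/k^2` clone-size tail is the familiar
jackpot phenomenon.

`estimate_m()` maximizes the log-likelihood by bracketed 1-D optimization
(tolerance `1e-6` in `m`). Numerical choices:

- **Jackpot binning.** Counts at or above `cap` (default 150) contribute
  through the tail mass `P(R >= cap)` rather than their exact
  probabilities. The pmf recursion to very large counts is both slow and
  numerically delicate, and counts that large carry almost no information
  about `m` beyond "a jackpot happened"; 150 is far above the counts that
  drive the likelihood at the `m` values assays are designed for (m of
  order 0.1 to a few).
- **Degenerate input.** All-zero counts give `m_hat = 0` with a one-sided
  profile interval; the likelihood is `exp(-Cm)`, so the upper bound is
  `qchisq(0.95, 1) / (2C)` for `C` cultures. A positive count makes the
  MLE strictly positive, so no boundary test is needed elsewhere.
- **Confidence intervals** come from the profile-likelihood ratio
  (chi-squared, 1 df). Replicate assays are reported individually plus
  as a mean in the analysis drivers; per-assay intervals are a convenience
  the underlying assay literature usually replaces with across-replicate
  spread.
- **Partial plating.** When a fraction `eps < 1` of each culture is
  plated, the observed count given a latent count `k` is
  `Binomial(k, eps)`; the latent pmf is computed to `cap` and thinned.
  The default is `eps = 1`: the assay protocol this emulates dilutes
  cultures one- to four-fold before plating but fits the plain
  Lea-Coulson model, and `eps = 1` reproduces that behavior. The
  parameter exists because the thinned model is the principled treatment
  when the plated fraction is known.

The per-division rate is `m / Nt`, with `Nt = colonies x dilution factor`
from a colony-count plating; confidence bounds scale identically.

## The fluctuation simulator

`simulate_fluctuation()` uses synchronous deterministic doubling of the
culture with Poisson-thinned mutation events per generation; mutant
lineages double deterministically afterwards. `m_true = rate * (nt - n0)`
is exact by construction. This discrete-generation process has a
lattice-valued clone-size law (powers of two) rather than the continuous
`1/(k(k+1))` law, so it is a deliberately *independent* data-generating
mechanism rather than a sampler of the fitted distribution: parameter
recovery under the Lea-Coulson fit is then a genuine robustness check.
Empirically the fit is well calibrated against it (median absolute error
< 0.1 at `m = 1` with 96 cultures; 95% profile intervals cover in ~95% of
replicates). The package's test suite verifies `lea_coulson_pmf()` itself
against a separate Monte Carlo of the two-type branching process (clone
sizes `1 + Geometric(U)`), which samples the exact Lea-Coulson law.

## Pooled-mutant calling

Thresholds default to the published pipeline values and are all
configurable through `pool_config()`:

| parameter | default | meaning |
|---|---|---|
| frequency window | `[0.65/N, 0.95]` | below: sequencing error; above: fixed strain SNP |
| `min_depth` | 200 | per-site depth filter (>= retained) |
| `min_callable_fraction` | 0.40 | pool QC on the fraction of amplicon positions passing |
| `mnm_window` | 10 bp | maximum MNM member distance |
| `mnm_freq_tol` | 0.09 | absolute frequency difference for MNM candidates |
| `mnm_cooccur_min` | 0.70 | read-pair co-occurrence support |
| `indel_merge_tol` | 0.10 | absolute frequency difference for adjacent-indel merging |
| `multiplicity_sd_k` | 2 | SDs above the mean frequency for multiplicity > 1 |

Decisions that the thresholds alone do not settle:

- **Boundary semantics.** The frequency window is closed on both ends
  (`f >= 0.65/N` and `f <= 0.95`), and `depth >= 200` is retained;
  "between A and B" is read inclusively.
- **Absolute vs relative tolerances.** The +/-9% MNM tolerance and the
  <10% indel-merge tolerance are interpreted as absolute frequency
  differences (0.09 and 0.10), since frequencies are the quantities being
  compared; both are configurable if a relative reading is wanted.
- **The 40% rule** is implemented as pool-level QC (fraction of the
  amplicon passing the depth filter), since a single site cannot cover
  40% of an amplicon.
- **Multiplicity statistics** use the mean and *population* SD (divide by
  n) of all called frequencies in the pool, outliers included.
- **Complex MNMs** are the transitive closure of pairwise MNMs over shared
  members; a candidate pair with no co-occurrence record is flagged
  unresolvable and never merged.
- **Indel merging** joins only same-kind runs at directly adjacent
  positions; a merged run keeps the leftmost position, the mean frequency
  and a width equal to the run length, and widths > 1 are excluded from
  single-bp indel spectra.
- **Coordinates.** Pileups and calls are 1-based; BED masks 0-based
  half-open; the reporter ORF's strand relative to the amplicon is carried
  by the amplicon map, and spectra are always strand-collapsed to the six
  A/C-centered classes.

Consequence annotation is a small codon-table classifier over the supplied
CDS (standard genetic code, ORF strand-aware): synonymous, missense,
nonsense, indel, noncoding. It deliberately handles only single-base
substitutions within a single ORF - all this pipeline needs - rather than
general transcript-model annotation.

## The pool simulator

`simulate_pool()` plants one mutation per pooled mutant (or a 2-site MNM
for a stated fraction of mutants), each at expected frequency `1/N`, and
draws per-position allele counts multinomially at fixed depth with a
uniform strand-symmetric per-base miscall channel. Co-occurrence records
for planted pairs within the MNM window have support near 1 for same-mutant
pairs and near 0 otherwise. What it does *not* model: depth variation along
the amplicon, strand bias, quality-score structure, PCR jackpots, indel
sequencing errors, or unequal pooling. Passing recall/precision tests on
these pools therefore demonstrates the calling logic under the stated
noise model, not robustness to library-prep artifacts; the generator
refuses configurations where `1/N <= 2 x error rate`, which would be
uncallable by design.

## Polymorphism spectra

Polarization requires an allele fixed in at least 4 of the 5 outgroup
genomes that also matches the panel's ref or alt; sites where the outgroup
is split, or fixed for a third allele, are uncallable and excluded.
Filtering keeps biallelic SNPs with missingness strictly below 0.20,
inside the mappable mask, outside repeats, with derived allele frequency
strictly below 0.5 (both thresholds strict; the DAF rule guards against
ancestral misidentification, which would otherwise mirror classes).

Weighting conventions, per counting mode: all-variant spectra weight
homozygous-derived genotypes 2 and heterozygous 1 (diploid convention);
rare-variant spectra (`AC` 2-4) weight every carrier 1 regardless of
zygosity; singletons must be homozygous in haploid/homozygous-diploid
strains and heterozygous otherwise. Rare-variant spectra additionally
exclude variants private to a single strain: private variants are the most
likely to be sequencing artifacts, and a hom-private variant in a haploid
strain would otherwise slip into the `AC = 2` bin.

Close relatives are excluded before allele counts are interpreted:
repeatedly take the closest pair under the 8000-difference threshold and
drop the member with more sub-threshold neighbors (ties: the
lexicographically later name). The greedy order is not canonical; this
variant is chosen for determinism and because dropping hubs first retains
more strains.

PCA subsamples at most 30 strains per population (seeded) to limit uneven
sampling, excludes strains with fewer than 8 contributing variants
(rare/singleton spectra of tiny totals are mostly noise), centers but does
not scale the class proportions, and fixes signs so each component's
largest-magnitude loading is positive - PCA is sign-ambiguous and a fixed
convention makes results reproducible across platforms.

**C>A enrichment.** Strains are ranked by the C>A fraction of their
rare-variant spectra; the top 5% are flagged. The bootstrap null resamples
each strain's rare-variant count from the panel-pooled rare-variant class
distribution with add-one smoothing,
`p = (1 + #{resampled fraction >= observed}) / (B + 1)`. The choice of
null is a design decision (the alternative - resampling from each clade's
own distribution - would absorb exactly the clade-level signal being
sought); since only the C>A fraction is scored, multinomial resampling
reduces to a binomial draw with the pooled C>A probability, which is how
it is computed. `ca_by_ac_bin()` profiles the C>A fraction across derived
allele-count bins (cutoffs 2, 4, 6, 8, then open); a recently activated
mutator shows enrichment concentrated in the youngest (lowest-AC) bins.

## The panel simulator

`simulate_panel()` emulates a clade-structured panel: variants originate
in a clade, draw their carrier count from a `1/k` law (k <= 20), and are
carried (heterozygously) by strains of that clade first - enough sharing
structure to cluster spectra by clade without simulating a coalescent. One
clade's rare variants (`AC <= 4`) draw classes from the base spectrum with
C>A multiplied (default 3x) and renormalized: base C>A 0.10 becomes
0.3/1.2 = 0.25. Default sizes are 8 clades x 20 strains with ~2000
variants per strain, which yields roughly 300 rare variants per strain -
the scale at which spectrum differences of this magnitude are detectable.
The simulator also emits imperfect inputs on purpose: ~10% of sites are
ref/alt-swapped relative to the ancestral state, the outgroup occasionally
disagrees (making sites uncallable), and genotypes have ~1% missingness,
so polarization and filtering are genuinely exercised. Not modeled:
linkage, coalescent tree structure, introgression, sequencing error in
the panel genotypes beyond missingness.

## The spectrum test

Two spectra are compared as a 2xK margin-fixed table. The conditional null
is multivariate hypergeometric; the point probability
`prod_j C(c_j, a_j) / C(n, r_1)` is computed in log space, and random
tables are drawn by sequential hypergeometric column filling (vectorized,
seeded). The p-value counts tables *at most as probable* as the observed
one, with add-one smoothing so p is never 0. The source description of
this test counts tables with *higher* probability than the observed, which
would give the modal table p near 0 and invert extremity; we implement the
standard Monte-Carlo exact test instead and note the discrepancy here.
Bonferroni-corrected p-values published for this test family are
reproduced exactly by the correction arithmetic regardless of the
direction convention. Degenerate margins (an empty row, or a single
non-empty column) make the table unique and give p = 1. Ties in table
probability are compared with a small log-space tolerance (1e-9) so that
equal-probability tables count as ties rather than falling to
floating-point noise.

The mutational target size uses the fact that nonsense mutations have an
exactly enumerable target: every substitution in the CDS creating a
premature stop, in bp-equivalents (count/3, the terminal stop codon
excluded). Scaling by observed total/nonsense point-mutation counts gives
the effective target; the formula is a reconstruction of the
missense-to-nonsense approach cited for reporter-gene assays, and is scale
invariant in the observed counts.

## Problem sizes in the test suite

The suite validates at the following scales, chosen to match the designs
the methods are meant for while keeping a full run to a few minutes: pmf
vs branching-process Monte Carlo at 10^6 replicates (TV < 0.01 at m in
{0.1, 1, 5}); 200 experiments of 96 cultures for MLE recovery and CI
coverage; 20 pools of 38 mutants at 2000x depth and 0.3%/base error for
caller validation (>= 37/38 recall, zero false positives); 500 null pairs
and 200 shifted pairs of n = 300 spectra for calibration and power; and
100 replicate panels at the default 8x20 layout for end-to-end mutator
recovery.

## Known limitations

- The rate model assumes equal wild-type and mutant growth (no
  differential-fitness variants) and no post-plating phenotypic lag.
- The caller consumes pileup and co-occurrence tables; read-level
  processing (mapping, trimming, base quality) is upstream and out of
  scope, as is assembling inserted sequence.
- Consequence annotation covers single ORFs and SNVs only.
- The bootstrap null for C>A enrichment is exchangeable across strains;
  population structure within the panel can make it anti-conservative for
  strains from unusually C>A-rich clades.
- The synthetic panels have no linkage, so PCA separations observed there
  are cleaner than real panels would give.
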