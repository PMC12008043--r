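---
title: "Models and methods behind gbspopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbspopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbspopgen)
```

gbspopgen analyses reduced-representation (GBS) SNP data sampled along an
urbanization gradient. A GBS library yields thousands of short loci (~74
genotyped nucleotide sites each) with at most a handful of SNPs per locus;
after filtering, one SNP per locus is kept. The pipeline asks two
questions: does urbanization structure genetic diversity and
differentiation in space, and what does the site-frequency spectrum say
about the history of effective population size, in particular about recent
declines. This vignette records the models, the defaults, and the design
decisions, in the order the pipeline runs them.

## Data model and filtering

A `geno_matrix` holds diploid genotypes as alternate-allele counts (0, 1,
2, `NA`) plus a per-SNP table (locus, chromosome, 1-based position,
alleles) and the number of genotyped nucleotide sites per locus (variant
plus invariant). The per-locus site counts matter: per-site diversity
statistics divide by *all* genotyped sites, including loci that carry no
SNP at all. Dropping SNP-less loci from that denominator inflates
diversity estimates several-fold, so the container deliberately retains
them.

Two filter presets mirror the two standard dataset designs
(`filter_presets()`):

* **permissive** (diversity and demography): minimum minor-allele
  frequency `2/(2n)` — a variant must be present in at least two allele
  copies — and calls in at least 50% of individuals;
* **strict** (structure and inbreeding): MAF at least 5% and calls in at
  least 75% of individuals.

MAF is computed over non-missing allele copies; the call-rate is a
fraction of individuals. One SNP per locus (smallest position; ties broken
by ref then alt allele) removes intra-locus linkage. The one-SNP rule is
applied after the frequency and completeness filters, mirroring how a
`--write-single-snp` style step behaves downstream of site filters.
Because the *first retained* SNP of a locus can differ between presets,
the strict set is a subset of the permissive set only when the one-SNP
rule is disabled; the test suite checks the subset property in that form.

Relatedness pruning uses a method-of-moments genomic-relationship estimate
(`relatedness_matrix()`), the average over SNPs of
$(g_i - 2p)(g_j - 2p) / (2p(1-p))$. Its expectations are ~1 for
duplicates, ~0.5 for parent–offspring or full sibs, ~0.25 for half sibs.
Two caveats are documented rather than hidden: with in-sample allele
frequencies and a few dozen individuals the estimates shrink noticeably
below the pedigree values, and rare-variant-dominated panels are noisy, so
a common-variant subset is the better input. Pairs falling inside the
configured identity interval (default 0.25–0.75, "at least half-sibs")
lose the member with more missing data; ties remove the
lexicographically larger id so reruns are deterministic.

## Urbanization metrics

Distance from the city center (default: downtown Toronto, 43.6563 N,
79.3809 W) is the haversine great-circle distance on a sphere of radius
6371.0088 km; at the ~100 km scale of an urban gradient the difference
from an ellipsoidal geodesic is far below the 30 km classification
threshold, so the sphere is used throughout. A site is *urban by distance*
iff its distance is at most 30 km (boundary inclusive) and *urban by
score* iff its externally supplied urbanization score is strictly
positive. The score is consumed as data; computing it from imagery is out
of scope. All samples of a site share its labels; conflicting coordinates
within a site (>1 km apart) trigger a warning and the centroid is used.

## Diversity statistics

Per unit (site, habitat, or the entire sample):

* nucleotide diversity $\pi$: per variant site
  $2a(n-a)/(n(n-1))$ over non-missing allele copies, summed and divided by
  the total genotyped sites (all-sites denominator by default — this is
  what makes GBS $\pi$ values land in the $10^{-3}$ range; a variant-only
  denominator is available);
* Watterson's $\theta_W = S/(a_1 L)$, with $a_1$ evaluated at the unit's
  median allele-copy count — a deterministic compromise for unequal
  missingness that avoids projecting at this stage;
* observed/expected heterozygosity and $F_{IS} = 1 - H_o/H_e$ with the
  small-sample correction $n/(n-1)$ on $H_e$; monomorphic-in-unit sites
  are excluded from the $F_{IS}$ average (configurable), since their
  0/0 ratio carries no information;
* Tajima's D in 100 kb windows tiling each chromosome from position 1
  (half-open, last partial window kept), with the canonical constants at
  the window's median copy count; windows with fewer than two segregating
  sites are flagged and excluded from the t-tests. One-sample t-tests
  against zero per group and a Welch t-test between habitats follow.

The urbanization regression treats per-site $\pi$ (or $F_{IS}$) as the
response with the urbanization metric and the number of genotyped
individuals as fixed effects, fitted by least squares. Sites with a single
genotyped individual are excluded — a single diploid cannot separate
within-site diversity from noise. Inference is reported as a type-II Wald
chi-square per term; with single-df continuous predictors and no
interactions this equals the squared coefficient t-statistic, so no
separate sums-of-squares machinery is needed.

## Differentiation

Hudson's $F_{ST}$ uses the ratio-of-averages form: numerators
$(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$ and denominators
$p_1(1-p_2)+p_2(1-p_1)$ are summed across SNPs before dividing. Ratio of
averages, not average of ratios: the latter is badly behaved at low
per-SNP information. `n` defaults to allele copies; an individual-count
convention is available, under which single-individual sites divide by
zero — they are excluded under either convention, which also mirrors how
such sites must be dropped in practice.

AMOVA partitions squared Euclidean distances between individual
allele-count vectors (missing entries mean-imputed per SNP) across
habitat/site/individual. Mean imputation keeps every individual in the
analysis at the price of shrinking high-missingness individuals toward
the centroid; this is the same convention the PCA uses, so distance-based
results are mutually consistent. Variance components follow the standard
hierarchical decomposition with unequal-size coefficients; the identity
between the distance formulation and an explicit ANOVA on the imputed
matrix is exact and is asserted in the tests at 1e-8. Permutation tests
exchange the units appropriate to each component — whole sites among
groups for the among-group component, individuals among sites within
groups for the among-site component, individuals among all sites for
$\Phi_{ST}$ — and use the add-one rule $p = (1+\#\{stat_{perm} \ge
stat_{obs}\})/(1+B)$. PERMANOVA and PERMDISP are delegated to vegan
(`adonis2`, `betadisper` with the spatial median), seeded for
reproducibility.

## Spatial structure

PCA runs on the mean-imputed, centered genotype matrix. Mantel
correlograms (vegan's engine) use Sturges distance classes with
progressive Holm correction; classes beyond the one containing the median
geographic distance are not tested, the usual reduced-power convention.
Moran eigenvector maps are built from pairwise great-circle distances
truncated at the largest minimum-spanning-tree edge (distances beyond
become four times the threshold); the positive-eigenvalue eigenvectors of
the doubly centered matrix form an orthonormal spatial basis. Forward
selection against the genotype PC scores (enough PCs for 80% of variance,
configurable) uses permutation tests with a double stopping rule — a
global significance gate before any selection, then stop at the first
non-significant candidate or when the cumulative Ezekiel-adjusted
R-squared exceeds the global model's. The gate is what keeps the
false-selection rate low on panmictic data. When nothing is selected and
the among-group AMOVA component is small, the pipeline reports a
single-population verdict.

## Demographic reconstruction from the folded SFS

GBS data give no reliable ancestral states, so the spectrum is folded.
`build_folded_sfs()` projects each SNP's allele count down to an even
`n_chrom` (default 0.8x the maximum called copies) by spreading its full
hypergeometric mass — a deterministic expected projection; a sampled mode
exists for experiments. SNPs with fewer called copies than the projection
size are dropped and counted, as is mass landing in the monomorphic
classes.

The estimator is stairway-style composite likelihood: folded counts are
treated as independent Poisson with means given by the exact expected
spectrum under a piecewise-constant $N_e$ history. The expectation engine
integrates the lineage-count death process epoch by epoch using
uniformization (numerically stable at any sample size, unlike the
classical alternating-sum formulas) and converts expected interval
lengths to branch lengths subtending $i$ of $n$ leaves through the
combinatorial weights $\binom{n-i-1}{k-2}/\binom{n-1}{k-1}$. For a single
constant epoch it reproduces $E[\xi_i] = \theta L / i$ to machine
precision, and a Monte Carlo mode (branch lengths averaged over simulated
genealogies) cross-checks the piecewise case.

The time grid is log-spaced over generations, scaled to the data through
the Watterson estimate $N_0$ (defaults: 14 epochs from $0.005\,N_0$ to
$4\,N_0$ generations; the most ancient epoch extends to infinity).
Model complexity is the number of free size parameters: change points are
inserted greedily on the grid, each placed where the training likelihood
is highest, and an insertion is kept only if it improves the held-out
likelihood — 67% of segregating sites train, 33% test — by more than
`sel_margin` (default 5) composite-log-likelihood units. The margin is
deliberately conservative: SNPs on one GBS locus share a genealogy, which
correlates the two halves of the split and would otherwise let noise buy
extra parameters. Near-ties in placement (within 0.05 units) resolve to
the earliest cut, which puts the most coalescent signal behind the weakly
constrained ancient block. After selection, the change points are
re-placed on the full data and the sizes refit.

Uncertainty comes from SNP-resampling bootstrap: each replicate redraws
the spectrum multinomially, re-places each change point within two grid
positions of the full-data solution and refits the sizes; the trajectory
is summarised by the per-epoch median and 2.5/97.5 percentiles. When the
genotype data were filtered with a minimum minor-allele-count rule (the
permissive preset censors singletons), the lowest folded class is excluded
from the likelihood (`mask_low = 1`); fitting a censored class as if it
were observed manufactures a sharp spurious recent crash, which is easy to
demonstrate and easy to avoid.

Default rates follow the herbaceous-perennial literature: mutation rate
$1.8\times10^{-8}$ per site per generation and a two-year generation time;
`sensitivity_sweep()` re-runs the inference over grids of both
(years scale with generation time exactly; sizes scale as $1/\mu$).
Absolute $N_e$ levels inherit every bias of the input spectrum — most
importantly, single-SNP-per-locus thinning removes variant sites while
their loci stay in the denominator — so trajectories from filtered data
are interpreted through their *shape* (relative changes, timing), not
their absolute level.

## Breakpoint analysis of ln(Ne)

Under exponential growth or decay at rate $r$ per year,
$N_{e,t} = N_{e,0}(1+r)^t$, so $\ln N_e$ against years before sampling is
piecewise linear with slope $b = \ln(1+r)$ per period; because the
trajectory runs backward in time the reported rate reverts the sign:
$r = -(e^b - 1)$, and the confidence limits swap under this decreasing
transform. The trajectory is read at a fixed systematic grid — every year
1–100, every 19th year to 2,000, every 130th year to 15,000; exactly 300
years after deduplicating the joint years — using step-function semantics
(the most recent step value at or before each grid year), because a
stairway-style trajectory is piecewise constant by construction.

`fit_piecewise()` implements the iterative-linearization estimator: with
current breakpoints $\psi_k$, regress on $\{1, t, (t-\psi_k)_+,
-\mathbf{1}[t>\psi_k]\}$ and update $\psi_k \leftarrow \psi_k +
\gamma_k/\beta_k$ until the largest update is below `tol` (default 1e-6
years). Initial breakpoints come from staged fits inside the three
subsampling ranges, pooled — the three ranges differ in resolution by an
order of magnitude each, and a single quantile initialization tends to
starve the recent range. Degeneracies are handled rather than fatal:
breakpoints whose difference-in-slope collapses are dropped (a perfectly
linear series reduces to the 0-breakpoint fit with identical RSS), and
breakpoints that approach within fewer than two observations merge with a
warning. Segment slopes carry 95% confidence intervals from the final
linear fit; breakpoint standard errors use the delta method on
$\gamma/\beta$. A slope whose |rate| is below $10^{-8}$ per year is
treated as numerically zero when the pipeline asks whether a significant
decline exists: over 15,000 years such a rate changes $N_e$ by 0.015%.

## The coalescent simulator

Each locus is one genealogy (no intra-locus recombination at 74 nt;
independent loci match the one-SNP-per-locus analysis). The single-deme
model supports arbitrary piecewise-constant $N_e$; the two-deme island
model adds symmetric migration, with the scaled parameter $M$ calibrated
so the equilibrium expectation of Hudson's $F_{ST}$ between the demes is
exactly $1/(1+M)$ (per-lineage migration probability $M/(8N)$ for two
demes, from the pairwise coalescence-time recursions). Mutations are
Poisson on branch lengths with infinite-sites placement inside the locus;
if a locus draws more mutations than it has sites, the surplus is dropped
and counted (finite-sites truncation — relevant only at unrealistically
high $\theta$ per locus). Presets: `null_panmixia`, `fragmentation`
(M = 1), `facilitation` (M = 24), and `decline` — ancestral
$N_e = 25{,}000$ dropping 100-fold to 250 at 500 generations before
sampling. The decline's absolute scale was chosen so the bottleneck is
severe but does not erase the genealogy (scaled recent duration
$500/(2\cdot250) = 1$), the regime in which a folded spectrum still
carries timing information; a bottleneck that wipes out all lineage
survival leaves the decline magnitude unidentifiable no matter the
estimator.

The landscape generator mirrors a two-density sampling design: one site
per 2.5 km cell within 30 km of the center, one per 10 km cell beyond (to
80 km), 1–5 individuals per site at least 3 m apart (closer ramets risk
being the same clonal genet). Every simulated dataset is byte-reproducible
from its seed, and a truth sidecar (JSON) records the scenario, the seed
and genealogy summaries.

## Evaluation scales and what passing shows

The test suite exercises the pipeline at desk scale: neutral calibration
uses 200 replicates of 2,000 loci at 40 allele copies (expected ~3,000
segregating sites, matching the permissive dataset's order of magnitude);
island-model checks use 5,000 loci over 50 seeds; the decline recovery
uses 50 individuals and 12,000 loci with the mutation rate raised to
$2\times10^{-7}$ so that a tractable locus count carries the information
content of a much larger GBS panel; bootstraps are scaled to 50
replicates. The simulator emulates the statistical structure the methods
assume — independent non-recombining loci, missingness at random, clean
biallelic calls — and not the failure modes of real GBS data (allele
dropout correlated with restriction-site polymorphism, depth-dependent
genotyping error, clonal resampling, reference bias). Passing therefore
demonstrates correctness of the estimators under their own assumptions
and calibration of their null distributions, not robustness to those
artifacts.

Known limitations worth restating: composite likelihood ignores linkage
within loci (the selection margin compensates empirically, not
theoretically); absolute $N_e$ from filtered spectra is biased by design;
the AMOVA permutation strategy tests components marginally, not jointly;
and MEM forward selection controls selection-wise error only through its
global gate.
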