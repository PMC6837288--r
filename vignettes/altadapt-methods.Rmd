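---
title: "Methods: demographically informed selection scans, clines and gene-set shifts"
author: "altadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographically informed selection scans, clines and gene-set shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

altadapt implements the population-genetic toolkit used in studies of local
adaptation along elevational gradients, with the deer mouse (*Peromyscus
maniculatus*) *Epas1*/HIF-2α system as the motivating example: a selection
scan based on the population branch statistic with a coalescent-simulated
neutral null, folded 2D-SFS demographic inference, equilibrium
allele-frequency cline fitting over elevation, and a permutation-calibrated
test for concerted expression shifts of candidate gene sets. This vignette
documents the models, the defaults and why they are what they are, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## 1. Per-site statistics and the PBS scan

Pairwise differentiation at a biallelic SNP is measured with the Weir &
Cockerham (1984) variance-component estimator
$\hat\theta = a/(a+b+c)$ computed from complete-case genotype counts per
population (`weir_fst_site()`). Multi-site summaries report the mean and
standard error of per-site $\hat\theta$ (the headline, matching how such
values are usually printed) together with the ratio-of-sums estimator
$\sum a / \sum(a+b+c)$, which is the better-behaved genome-wide quantity.

The population branch statistic for a focal population $A$ with outgroups
$B$ and $C$ is
$$\mathrm{PBS} = \tfrac{1}{2}\left(T_{AB} + T_{AC} - T_{BC}\right),
\qquad T_{XY} = -\ln(1 - F_{ST}^{XY}),$$
the focal branch length on the log-FST scale. Numerical conventions:

* negative per-site $\hat\theta$ (and undefined sites) are floored at 0
  before the log transform, as PBS scans conventionally do;
* $\hat\theta \ge 1 - 10^{-12}$ is clamped to $1 - 10^{-12}$ so branch
  lengths stay finite at fixed differences;
* PBS itself is **not** floored — negative values are retained because the
  neutral null distribution needs its left tail.

A site enters the scan when every population has at least one called
diploid and per-population missingness is at most 50% (configurable), the
usual "called in at least half the individuals" rule. Outliers are flagged
against the empirical distribution or a supplied simulated null, using the
smallest value whose empirical CDF reaches the requested level
(`quantile_threshold()`, the left-continuous step-function convention —
with 500,000 simulated SNPs the 99.9% threshold is the 500th largest
value). The Hardy–Weinberg filter is Levene's exact conditional test
(`hwe_exact_test()`, standard two-sided tail, no mid-p), LD is the squared
dosage correlation, and candidate-set enrichment is the one-sided
hypergeometric (Fisher) tail.

## 2. The structured-coalescent simulator

`simulate_snps()` draws independent single-locus genealogies from the
structured coalescent: within a deme of $N$ diploids a pair of lineages
coalesces at rate $1/(2N)$ per generation, lineages hop between demes
backwards in time, and at each split time the derived deme's lineages merge
into the parent (optionally with a new parent size). Waiting times are
exponential within epochs; there is no recombination and no selection —
per-SNP PBS treats sites as exchangeable draws, so one locus is one
genealogy.

**Migration units.** The user supplies symmetric *migrants per generation*
$M$; internally a lineage in deme $i$ hops at rate $M/N_i$ per generation
(the fraction of deme $i$ replaced by immigrants each generation). For the
two-deme island model this gives the exact closed form
$F_{ST} = 1/(1+8M)$ (from $E[T_\text{within}] = 4N$ and
$E[T_\text{between}] = 4N + N/M$), which the test suite checks against
simulation, alongside a frozen cross-check of the joint folded SFS against
an independent, widely used coalescent simulator.

**Mutation placement.** The default (`mutation_model = "infinite_sites"`)
gives each genealogy a Poisson number of mutations with mean proportional
to its total branch length (the constant is calibrated from a 200-tree
pilot so the mean is ~1), each placed on a branch chosen proportionally to
length; simulation continues until the requested number of SNPs is
reached. This reproduces the neutral infinite-sites frequency spectrum
exactly — for $n$ lineages the expected unfolded spectrum is
$\propto 1/i$. The alternative `"one_per_tree"` places exactly one
segregating site per genealogy (the `ms -s 1` convention); it is retained
because simulation pipelines often use it, but note it over-weights short
genealogies and therefore inflates the singleton class (at $n = 4$ the
singleton share rises from $6/11 \approx 0.545$ to about 0.58).

**Diploid genotypes.** Because leaves within a deme are exchangeable given
the genealogy, haploids are paired into diploids by random assignment of
the derived alleles given the per-deme derived count; FST on simulated data
then uses the same Weir–Cockerham estimator as the real data (Hudson's
estimator is available).

**The printed three-population model.** `deer_mouse_model()` encodes the
study's stitched model: Mt. Evans / Lincoln / Merced at 368k / 220k / 371k
diploids, Lincoln splitting from the Mt. Evans lineage 217k generations ago
and Merced 190k generations ago (the source fits are pairwise and do not
state which split is older; the chronology of the printed times is used),
high-class migration 1.75 (Evans–Lincoln) and 2.07 (Evans–Merced)
migrants/generation, low-class 0.08, no direct Lincoln–Merced gene flow,
and 85% of loci in the high class. The ancestral size is not printed
anywhere; the ancestral lineage is kept at the Mt. Evans size (368k), a
choice that affects mainly the shared deep branches, which largely cancel
in PBS. Note that under this model as printed, the extreme tail of the
simulated PBS null is dominated by the 15% low-migration loci, whose
differentiation at these sizes and split times is substantial; the 99.9th
percentile of the mixture is consequently several-fold larger than its
99th percentile. `scripts/acceptance.R` reports both.

## 3. Folded 2D-SFS demographic inference

`build_folded_2dsfs()` drops sites with more than 25% missing data in
either population, projects each remaining site down to the requested
haploid sample sizes with hypergeometric weights (cells are therefore
fractional), folds to minor-allele counts, and masks the fixed and
fold-redundant cells. The composite likelihood treats unmasked cells as
independent Poisson counts with mean $\theta \cdot E_{ij}$, where $E$ is
the model-expected spectrum and $\ln(n!)$ is evaluated by `lgamma` so
fractional cells are handled; $\theta$ is profiled analytically as
$\hat\theta = \sum n / \sum E$.

The expected spectrum is computed by coalescent Monte Carlo in diffusion
units (sizes $\nu_i$ relative to the ancestral population, time $T$ in
$2N_{anc}$ generations, migration $M = 2N_{anc}m$): the mean branch length
subtending each joint frequency class over a set of genealogies, which is
the branch-form of the expectation and needs no mutation sampling. Three
nested families are provided: `no_mig`, `one_mig` (one symmetric rate), and
`two_mig_classes` (rates $M_{high}, M_{low}$ with a proportion $P$ of loci
in the high class — the heterogeneous-gene-flow model). A deliberately
simple PDE-free design: the diffusion solver used by ∂a∂i is not
reimplemented.

Numerical choices that matter here:

* **Zero-cell floor.** A finite Monte-Carlo run can miss a rare cell; the
  normalized expected spectrum is floored at $10^{-8}$ per cell (then
  renormalized) so observed counts in such cells are heavily but finitely
  penalized rather than sending the likelihood to $-\infty$.
* **Common random numbers.** Within an optimization run every likelihood
  evaluation replays the same RNG stream, so the objective is a
  deterministic function of the parameters.
* **Jensen bias correction.** $E[n \ln \hat E] = n\ln E - n\,
  \mathrm{Var}(\hat E)/(2E^2) + O(\text{sims}^{-2})$; the per-cell
  Monte-Carlo variance is accumulated alongside the mean and the estimated
  deficit added back (capped at the point where the expansion breaks
  down). Without this, parameter regions whose spectra are noisier score
  systematically worse at small simulation budgets.
* **Search strategy.** Starts are drawn log-uniformly over the study's
  uniform prior box ($0 < 2N_em < 10$, $0.01 < T < 10$, $0.1 < \nu < 10$,
  $0.5 < P < 1$; the proportion $P$ uniformly), because uniform-on-natural
  draws almost never land below 1 and the small-parameter basin would be
  systematically missed. All starts are screened in one shared
  high-precision stream, the best few are polished by Nelder–Mead in
  box-logit space at the working budget, and finalists are re-ranked and
  briefly re-polished at 8× the working budget. The default is 25 screened
  restarts, 2000 genealogies per evaluation, 3 polished candidates.

The likelihood-ratio comparison between nested families is the plain
$2\Delta\ell$ chi-square test; composite likelihoods violate its
assumptions (adjacent SFS cells share genealogical history), so its
p-values are anti-conservative ranking devices, and the
Godambe-information adjustment used in the source workflow is deliberately
out of scope. Uncertainty comes instead from a nonparametric SNP bootstrap
(`bootstrap_ci()`): SNPs spaced at least 10 kb apart are resampled with
replacement, the spectrum rebuilt, and the model refit with a few restarts
seeded at the point estimate; intervals are percentile-based.
`calibrate()` converts $\hat\theta$ to natural units via
$N_{anc} = \theta/(4\mu L)$ (default study mutation rate
$5.4\times10^{-9}$ per base per generation is the user's to supply),
$t = 2N_{anc}T$ generations, and migrants/generation $= M/2$.

## 4. Equilibrium clines over elevation

The cline core is the hyperbolic-tangent sigmoid
$$p(x) = p_{min} + (p_{max}-p_{min})\,
\frac{1 + \tanh\!\big(2(x-c)/w\big)}{2},$$
with center $c$ (the elevation of the frequency midpoint) and width $w$
(inverse of the maximal slope); elevation itself is the spatial axis. Ten
variants combine frequency scaling (fixed 0–1 or free
$p_{min}, p_{max}$) with exponential tails (none, left, right, mirrored,
both) — a documented subset of the fifteen models of the hzar tradition.
The tail beyond $c \pm \delta$ matches the sigmoid's value at the junction
and decays exponentially with initial slope $\tau$ times the sigmoid's
slope there ($0 < \tau \le 1$); this parameterization is continuous and
monotone by construction.

Counts are binomial, $k_i \sim \mathrm{Bin}(2n_i, p(x_i))$, with expected
frequencies clamped to $[10^{-9}, 1-10^{-9}]$ so fixed localities under
boundary parameters stay finite. Fitting is Gaussian random-walk
Metropolis–Hastings on the natural scale with flat priors inside broad
bounds (center within the data range extended by one range; width up to
20 ranges; proposals violating bounds or $p_{min} > p_{max}$ are
rejected). Parameters are updated one at a time; proposal scales adapt
every 200 burn-in sweeps toward 20–40% acceptance and are frozen
afterwards, keeping the post-burn-in chain a valid MH sampler. Defaults
are 100,000 sweeps with a 10,000-sweep burn-in (the study's burn-in). The
MAP is the highest-likelihood posterior sample; intervals are equal-tail
posterior quantiles (the printed intervals' construction is not stated in
the source; equal-tail quantiles are the transparent choice, and AICc
$= -2\ell_{MAP} + 2k + 2k(k+1)/(N-k-1)$ ranks variants, skipping any with
too few localities).

## 5. Gene-set expression shifts

The question is not whether any single gene is differentially expressed —
in the motivating data none survives FDR correction — but whether a
candidate set shows a small *concerted* shift. The pipeline
(`geneset_shift_test()`): genes below a mean of 10 library-size-normalized
reads per individual are dropped; per-sample effective scaling factors are
library size × TMM composition factor (computed by edgeR's
`calcNormFactors`, the tool used on the original data), normalized to
geometric mean 1; per-gene log2 fold-changes between genotype groups are
normalized group means with a pseudocount of 0.5 (the quasi-likelihood GLM
fold-changes of the original workflow are deliberately replaced by this
transparent estimator — the bespoke part, the K-S/permutation machinery,
is preserved); the signed two-sample Kolmogorov–Smirnov $D$ compares the
candidate set against the background with candidates excluded, signed by
the median difference; and the null is built from 1000 uniform random gene
sets of the same size, each scored against its own complement. The
decision rule is $D > q_{99}$ of the null (left-continuous quantile). With
1000 draws this fires with probability $11/1001 \approx 1.1\%$ for a
random set, which the calibration test verifies. The asymptotic K-S
p-value (Kolmogorov distribution at $\sqrt{nm/(n+m)}\,D$) is reported for
reference but the permutation quantile is the decision.

`directional_contrast()` compares mean fold-changes of known positive vs
negative regulators of a pathway by label permutation (full enumeration
when there are at most 10,000 assignments). `de_test_naive()` is a
deliberately simple per-gene exact binomial (Poisson-style) screen with BH
correction; it ignores biological overdispersion and is not a substitute
for a negative-binomial GLM analysis.

## 6. What the synthetic generators emulate

Because the study's raw sequencing data cannot ship with a package, every
input has a generator whose defaults are the study's conditions:

* `gen_scan_dataset()` — neutral SNPs from the coalescent under a chosen
  demographic model (mixing the two migration classes), plus "selected"
  sites made by displacing the focal deme's allele frequency of a neutral
  draw and re-sampling genotypes binomially. PBS responds to
  allele-frequency differentiation directly, so displacement injects a
  selection-like signal without committing to selection coefficients.
* `gen_cline_dataset()` — binomial counts around a chosen cline.
* `gen_expression_counts()` — log-normal baseline means (meanlog 4, sdlog
  1.2, i.e. a median of ~55 reads), negative-binomial counts at dispersion
  0.1 (typical for TagSeq-scale data), genotype groups defaulting to the
  study's 3 LL / 8 HL / 8 HH, and a candidate set carrying an additive
  allele-dosage shift (HL halfway between LL and HH) so `shift` is the
  HH-vs-LL log2 fold-change.
* The packaged `inst/extdata/epas1_cline_synthetic.tsv` is a labelled
  synthetic stand-in for the study's deposited 23-locality sampling table
  (266 mice): a 10-locality Great Plains→Rocky Mountains transect drawn
  from a cline centered at 1399.5 m (width 400 m, $p_{min}$ 0.02,
  $p_{max}$ 0.84, consistent with the printed highland frequency of 0.83)
  plus 13 regional localities with additional logit-normal between-site
  scatter (sd 1) representing geographic structure off the transect.
  `scripts/make_extdata.R` regenerates it (seed 20191).

What passing tests on these generators shows is that the estimators
recover what they claim from data satisfying their own assumptions —
independent sites, binomial sampling, NB counts with common dispersion.
Real exomes add linkage, batch structure, reference bias and genotyping
error, none of which the generators emulate; conclusions about power on
real data need the real data.

## 7. Problem sizes and runtime choices

The test suite and acceptance script run everything at desk scale, chosen
so the whole suite completes in minutes while keeping Monte-Carlo error
well inside the asserted tolerances: 50,000 simulated SNPs for the neutral
PBS null and for each demographic-recovery replicate; 50,000 genealogies
for SFS validity checks; 20 replicate fits for the recovery experiments
(cline chains 16,000 sweeps there, 100,000 by default); 200 null
replicates for the gene-set calibration check; 1,200 genealogies per
likelihood evaluation (×8 for finalists) in the scaled-down recovery
fits. The two-migration-class mixture-proportion recovery experiment
(recovering $P$ itself) needs an order of magnitude more computation per
fit and is not part of the routine suite.

## 8. Known limitations

* The coalescent core supports at most four demes and no recombination,
  gene conversion, or selection.
* The composite likelihood's chi-square LRT is anti-conservative (no
  Godambe adjustment); use the bootstrap for uncertainty.
* Migration-rate classes are a two-point mixture; continuous variation in
  effective migration is not modelled.
* The exact invariance of fold-changes under global depth scaling holds
  only without the pseudocount; with it, the dependence is bounded by the
  prior's weight on weakly expressed genes.
* With a single-gene background the permutation K-S D is dominated by that
  gene's rank — degenerate set sizes are valid inputs but not meaningful
  tests.
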