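---
title: "Methods: comparing genomic, climatic and geographic descriptors of local adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing genomic, climatic and geographic descriptors of local adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`genecol` implements a genecological analysis pipeline for widespread,
wind-pollinated plant populations sampled across a climatic gradient and
phenotyped in a common garden: which data source — genomic markers, climate
normals, or geographic coordinates — best describes locally adaptive
variation, which climate variables drive it, and whether the underlying
allele-frequency clines are rangewide or localized. This vignette documents
the models, the tunable parameters, the synthetic-data generator used for
validation, and the numerical and design choices behind the implementation.

## The data model

Four tables describe a study:

* a **genotype matrix** of biallelic SNP codes 0/1/2 (copies of a counted
  allele) for seedlings from many source populations, with each locus
  assigned to a contig and to either a putatively neutral **control** class
  (intergenic markers used for structure correction and calibration) or a
  **candidate** class (the loci actually scanned);
* a **population panel** (latitude, longitude, elevation, sample size);
* a **climate table** of 19 bioclimatic normals per population (MAT, MWMT,
  MCMT, TD, MAP, MSP, AHM, SHM, DD_0, DD5, NFFD, FFP, bFFP, eFFP, PAS, EMT,
  EXT, Eref, CMD) — deliberately not pruned for collinearity, since
  identifying the driving variable among correlated ones is part of the
  question;
* a **phenotype table** of one or more traits measured on individual
  seedlings grown in a blocked common garden.

## Stage 1 — removing the experimental design from phenotypes

Raw phenotypes contain nuisance variation from the garden layout. The model
is a two-level nested random-intercept mixed model,

$$Y_{ijk} = \mu + B_j + L(B)_{jk} + e_{ijk},$$

with block $B_j \sim N(0, \sigma^2_B)$, location-within-block
$L(B)_{jk} \sim N(0, \sigma^2_{L(B)})$ and residual
$e_{ijk} \sim N(0, \sigma^2_e)$. Variance components are estimated by REML
(via lme4) with non-negativity enforced by the parameterization; block and
location effects are predicted as BLUPs, subtracted from the observations,
and the residuals are z-standardized **across all individuals of the
trait**. Standardizing within some stratum instead would change population
means by a constant factor per stratum; across-all is the most direct
reading of "z-standardized residuals" and is what `adjusted_phenotypes()`
does. Traits measured on a subset of seedlings (cold injury is often scored
on fewer) use their available rows only. A single-block design is singular
for this model and falls back to plain centering/scaling with a warning.

## Stage 2 — structure objects

Two structure corrections are shared by the scans, both estimated **from
control loci only** so that candidate signal does not absorb itself:

* the **genomic relationship matrix** (GRM), VanRaden form: genotypes
  centered at $2p$ and scaled to variance $2p(1-p)$, missing values
  mean-imputed, $K = ZZ'/L$;
* the **population covariance** $\Omega$ of standardized allele
  frequencies $x_k = (p_k - \bar p)/\sqrt{\bar p(1-\bar p)}$, where
  $\bar p$ is the across-population mean. Each "run" takes the sample
  covariance over a bootstrap resample of control loci, augments the
  diagonal with the mean binomial sampling variance $1/(2n_k)$ (an
  approximation to the within-population sampling noise an MCMC estimator
  integrates over), and adds a ridge $\varepsilon = 10^{-6}\,
  \mathrm{tr}(\Omega)/P$ for positive definiteness. Three runs are averaged
  for the point estimate; the individual runs double as independent
  "chains" for consensus filtering, preserving the average-of-three-runs
  design of MCMC-based tools without their runtime.

## Stage 3 — genotype–phenotype association (GPA)

Each candidate locus is tested against an adjusted trait under the mixed
linear model $y = \mu + x\beta + g + e$, $g \sim N(0, \sigma^2_g K)$. The
two variance components are estimated **once on the null model** by REML
through the eigendecomposition of $K$ (a one-dimensional profile-likelihood
optimization in $\lambda = \sigma^2_g/\sigma^2_e$), then held fixed while
every locus gets a generalized-least-squares estimate and a Wald $\chi^2_1$
p-value — the standard "MLMA" convention, which trades a small loss of
per-locus exactness for a single $O(n^3)$ factorization. Setting
`lambda = 0` reduces every test to ordinary least squares, which the test
suite exploits as an oracle.

Post-processing applies three selection rules:

1. **one per contig**: within each contig keep the locus with the smallest
   p-value (physical-linkage redundancy);
2. **bottom 1%**: keep the $\lceil 0.01 \times \text{pool}\rceil$ smallest
   p-values — with the ceiling convention a pool of 18,525 yields exactly 186
   candidates;
3. **PEA polarization**: report each effect per copy of the
   positive-effect allele (the allele whose count increases the trait,
   read off the slope sign), so downstream cline analyses share an
   orientation.

Ties are always broken deterministically (p-value, then $|\beta|$
descending, then locus id).

## Stage 4 — genotype–environment association (GEA)

For one centered-and-standardized climate variable $e$ and the standardized
frequency vector $x$ of a locus, the environmental-effect model
$x = \beta e + \text{drift}$, $\beta \sim N(0, \tau^2)$, has marginal
$x \sim N(0, \Omega + \tau^2 ee')$, giving the closed-form Bayes factor

$$\mathrm{BF}(\tau) =
  \frac{N(x;\, 0,\, \Omega + \tau^2 ee')}{N(x;\, 0,\, \Omega)}
  = (1 + \tau^2 q)^{-1/2}
  \exp\!\left(\tfrac{1}{2}\,
  \frac{\tau^2 (e'\Omega^{-1}x)^2}{1 + \tau^2 q}\right),
  \qquad q = e'\Omega^{-1}e,$$

averaged over the prior-scale grid $\tau \in \{0.01, 0.1, 1\}$. This is the
exact marginal-likelihood ratio the MCMC-based estimator targets, computed
by a rank-one update, and it is verified against brute-force numerical
quadrature in the test suite. A nonparametric companion statistic $\rho$ is
the Spearman correlation of the whitened vectors $L^{-1}x$ and $L^{-1}e$
($L$ the Cholesky factor of $\Omega$), robust to single outlier
populations.

One calibration property deserves a note. Under the null, $E[\mathrm{BF}] =
1$ exactly, but the *median* null BF at prior scale $\tau$ carries the
Occam factor $(1+\tau^2 q)^{-1/2}$, and $q$ grows like
$P/\mathrm{diag}(\Omega)$ — several hundred for dozens of weakly
differentiated populations. The grid-averaged median null BF is therefore
around 0.5, not 1; "median BF ≈ 1" holds only for the weak-prior component
($\tau^2 q \lesssim 1$), which is how the suite tests calibration. None of
the pipeline's decisions depend on the BF's absolute scale: candidates are
selected by **rank**, where the Occam factor cancels across loci.

Candidate filtering uses consensus rules: a locus is a
candidate for a variable only if it is in the top $K = 300$ by BF in *each*
of the three chains **and** in the top 300 by $|\rho|$ in each chain (the
intersection of six top-$K$ lists). Contig deduplication keeps the locus
with the best mean of its six ranks, and the per-variable "top 300" for
driver analysis is ordered by the same mean rank.

## Stage 5 — explained-variance curves

Predictor sets of very different dimensionality (3 geographic coordinates,
19 climate normals, thousands of allele frequencies) are compared on equal
terms by principal components: PCs are extracted **once** from each full
predictor table (population-level observations; genomic tables are
population-mean allele frequencies so that rows align with population-mean
phenotypes), then for $m = 1, 2, \dots$ the population-mean trait is
regressed on the first $m$ PCs with fivefold cross-validation over
populations. $R^2_{cv} = 1 - \sum \mathrm{SSE}/\sum \mathrm{SST}$ is pooled
over held-out folds (SST around each fold's training mean) rather than
averaged per fold: per-fold $R^2$ is unstable with ~12 populations per
fold, and the pooled form equals ordinary $R^2$ in the training-mode limit
(`folds = 1`), which the tests assert at full rank against plain OLS.
$R^2_{cv}$ may legitimately be negative for uninformative predictors.

Two calibrations make the comparison fair:

* **control rarefaction**: the control set is split into
  $\lfloor\text{pool}/186\rfloor$ mutually exclusive subsamples of 186 loci
  (the candidate-set size) and the curve spread across subsamples is
  reported;
* **climate-association threshold**: each control locus's frequency is
  regressed on the first five climate PCs, and the 99.7th percentile of
  the resulting null $R^2$ distribution becomes the cutoff above which a
  GPA candidate is called *climate-associated* (on data of the
  kind the generator emulates this percentile falls near 0.35).

## Stage 6 — climate-driver ranking and congruence

The direction of regression flips: each climate variable becomes the
response. Genomic predictors are the first four PCs of the population-mean
minor-allele frequencies of that variable's top-300 GEA loci (minor-allele,
not PEA, so the predictors are trait-agnostic); phenotypic predictors are
the four population-mean standardized traits used directly (no PCA — there
are only four); provenance-trial predictors are per-site population-mean
heights. The per-variable $R^2_{cv}$ vectors are ranked within source, and
**congruence** between two sources is the Pearson correlation of their
$R^2$ vectors across the 19 variables (Spearman alongside). A single
shared CV configuration is applied to all sources. For long-term trial
data the package also provides the site-wise quadratic fit: height on
climate with adjusted $R^2 = 1-(1-R^2)(n-1)/(n-3)$, averaged over sites.

## Stage 7 — cline structure and standing variation

Climate-associated trait candidates are clustered by **Euclidean k-means on
absolute PEA frequency profiles** (SNPs as observations, populations as
variables, best of 50 seeded restarts). Absolute — not centered —
frequencies are the point: two SNPs with parallel but offset clines belong
to different clusters even when perfectly correlated, which distinguishes
this from LD-based clustering. Cluster ids are relabeled by ascending
grand-mean frequency so labels are deterministic. `k` is user-set (default
6); the package reports within-cluster spread to inform the choice but does
not automate it, since the choice is best made by inspecting cline
homogeneity.

Averaging SNPs within a cluster shrinks the cline's across-population
spread. The default **variance restoration** rescales deviations around
the cluster-mean's own level so the restored cline's SD equals the mean
across-population SD of the member SNPs:

$$\text{restored}(c,k) = \bar g_c + (m_c(k) - \bar g_c)\,
  \frac{\bar s_c}{\mathrm{sd}_k(m_c)},$$

clipped to $[0,1]$. The procedure is sometimes described as "multiplying
the cluster-mean frequency by the mean member SD"; taken literally that
collapses the frequency scale toward zero, so we treat it as shorthand for
spread restoration, implement both
(`restore_variance(method = "literal")` gives the literal form), and
default to the deviation form. The rescaling identity
$\mathrm{sd}(\text{restored}) = \bar s_c$ (before clipping) is asserted at
$10^{-10}$ in the tests.

Standing variation is summarized by expected heterozygosity
$H_e = 2p(1-p)$ per PEA per population and **proportional polymorphism**:
the fraction of a cluster's SNPs with $H_e > 0$ in each population.

Finally, each restored cline is classified **rangewide / localized /
flat** by a four-parameter logistic fit
($p_0 + (p_1-p_0)\,\mathrm{expit}((x - c)/w)$, `nls` with an `nlsLM`
fallback): the *active range* is the env interval covering the 10–90%
points of the total change, $[c - w\ln 9,\; c + w\ln 9]$, intersected with
the observed span. A cluster is flat if its fitted total change is ≤ 0.1
(or the fit fails, with a warning), localized if the active range is
narrower than half the gradient span, rangewide otherwise. The
0.5-span cutoff and the 0.1 minimum change are deliberate, reported
defaults (`span_fraction`), not fitted quantities.

## The synthetic-data generator

All validation runs on data from `simulate_dataset()`, whose defaults
emulate the study design the pipeline targets: **280 populations × 10
seedlings** on a one-dimensional gradient (a mean-annual-temperature proxy
spanning −4 to 8 °C, monotone in latitude), **4,000 control and 4,000
candidate SNPs**, weak neutral structure (Balding–Nichols with
$F_{ST} = 0.016$, typical of widespread wind-pollinated conifers; per-locus
ancestral frequencies Uniform(0.05, 0.95)), genotypes Binomial(2, p) with
2% missingness, and the 19 named climate variables as affine functions of
the gradient with correlated noise and MAT as the designated driving
variable (noise a tenth of the others').

Planted adaptive loci follow four-parameter logistic clines — the simplest
monotone saturating form consistent with the rangewide-versus-localized
dichotomy the classification stage addresses. Defaults plant two rangewide
groups (10–90% transitions spanning 80% and 60% of the gradient) and one
localized group (8% of the gradient), 40 loci each, frequencies 0.05–0.95,
with Balding–Nichols jitter around the cline so members are not copies of
one another. Traits are additive over their group's loci (default effect
0.15–0.2 trait units per allele copy — enough to differentiate populations
without overwhelming the residual; among-population heritability of real
studies varies, so these are config-exposed, not hard-coded), with block SD 0.5, location SD 0.3 and residual SD 1 in a
garden of 8 blocks × 10 locations; cold injury is scored on 60% of
seedlings to exercise subset handling.

What the generator deliberately does **not** emulate: linkage and
recombination (contigs group loci for deduplication, but loci are drawn
independently), migration–selection dynamics (clines are imposed, not
evolved), hybrid-zone introgression, spatially structured sampling beyond
the single gradient, genotyping error beyond uniform missingness, and
climate surfaces with topography. Passing tests therefore demonstrate that
the statistical machinery recovers planted truth under the model's own
assumptions — not that those assumptions hold in any particular real
dataset.

## Problem sizes used in validation

The test suite validates most operations on 40–100-population simulations
and runs the end-to-end guarantees at the emulated study scale: the
uniformity of null mixed-model p-values at 280 populations × 2,800
seedlings × 4,000 loci (median KS p over 10 replicates), dual-rank
recovery of a planted 40-locus cline group at $K = 60$ (10 replicates),
driving-variable identification among the 19 climate normals (10
replicates), and cline clustering/classification on 100-population
three-group plants (10 replicates). The acceptance script additionally
re-runs a null scan at full marker-set scale (32,407 SNPs on
18,525 contigs) to reproduce the selection-rule counts. These sizes keep a
complete run on a single CPU within minutes while leaving rank statistics
(top-300 of thousands) meaningful.

## Known limitations

* $\Omega$'s binomial diagonal augmentation approximates what an MCMC
  covariance estimator integrates over; with very unequal sample sizes a
  per-population treatment inside the likelihood would be preferable.
* MLMA reuses null-model variance components for every locus; loci with
  very large effects have slightly conservative standard errors (the
  standard trade-off of the approximation).
* The cline classifier fits cluster summaries, not individual SNPs; a
  cluster mixing rangewide and localized members is labeled by its mean.
* PC-regression compares *linear* explanatory content; a nonlinear
  regressor can be substituted for the CV engine, but none is bundled.
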