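---
title: "Modelling GLAI dynamics and mapping their QTLs in a maize MAGIC panel"
author: "glaiQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GLAI dynamics and mapping their QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaiQTL)
```

# The scientific problem

The green leaf area index (GLAI, m^2^ of green leaf per m^2^ of soil) of a
maize canopy rises during vegetative growth, plateaus around flowering and
declines through senescence. The whole trajectory — not just its maximum —
carries agronomic information: how fast a canopy closes, how long it stays
green during grain filling ("stay-green"), and how quickly it senesces all
modulate light capture and hence yield, especially under drought. This
package treats the GLAI trajectory on a thermal-time axis (growing degree
days above 6 °C, GDD6) as the phenotype, derives a fixed set of 24
dynamics traits from it, and carries those traits through a complete
quantitative-genetics pipeline in a 16-founder multi-parent (MAGIC)
doubled-haploid panel: adjusted means, heritability, variance
decomposition, univariate and multivariate mixed-model GWAS, LD-based SNP
clustering, multi-environment QTL selection, colocalization, and finally
the share of grain-yield variance that GLAI QTLs explain across a
multi-environment drought network.

Because no public data set accompanies this problem, the package ships a
first-class synthetic generator that produces genotypes, field layouts,
GLAI observations and agronomic traits with the statistical structure the
analysis assumes, together with a ground-truth record, so that every stage
can be validated by recovery rather than by eyeballing.

# The GLAI curve model and the 24 traits

## Phases and bent-cable segmentation

A trajectory is segmented into five phases: early vegetative (EV), late
vegetative (LV), flowering plateau (F), slow senescence (SS) and rapid
senescence (RS). The two vegetative phases and the two senescence phases
are delimited by *bent-cable* regressions,

$$f(t) = b_0 + b_1 t + b_2\, q(t;\tau,\gamma), \qquad
q(t;\tau,\gamma) = \begin{cases}
0 & t \le \tau-\gamma\\
(t-\tau+\gamma)^2/(4\gamma) & |t-\tau| < \gamma\\
t-\tau & t \ge \tau+\gamma,
\end{cases}$$

two straight lines of slope $b_1$ and $b_1+b_2$ joined by a quadratic bend
of half-width $\gamma$ centred at $\tau$. The abscissa $\tau$ of the
intersection of the two linear parts is the phase boundary. The incoming
and outgoing slopes of the vegetative fit give S~EV~ and S~LV~; the
senescence fit gives S~SS~ and S~RS~.

The remaining boundaries are rule-based: emergence `t_e` is the first grid
time with positive GLAI; `t_M` is the (earliest) time of the maximum;
senescence onset `t_o` is the first time after the maximum at which GLAI
drops *strictly below 95%* of it; complete senescence `t_z` is the first
subsequent zero, or the end of the grid with a `truncated` flag when the
canopy never fully senesces (traits are still computed in that case). From
the six boundaries come eight durations (D~EV~, D~LV~, D~V~, D~F~, D~SS~,
D~RS~, D~S~, D~C~), eight trapezoidal areas under the curve (AUC~EV~ ...
AUC~C~), the maximum GLAI~M~, and the total time spent at or above 75/50/25%
of the maximum (D~75~, D~50~, D~25~) — 24 traits in all.

Two readings of D~75/50/25~ are defensible (total time above the relative
threshold, or time from the peak to the downward crossing); the package
uses *total time above the threshold*, which is invariant to curve
rescaling and well defined for non-monotone plateaus. Likewise the AUCs
integrate the observed (or interpolated) curve itself, not the
bent-cable linearisation, so that the additivity identities
(e.g. AUC~V~ + AUC~F~ + AUC~S~ = AUC~C~) hold to numerical precision; the
trapezoid handles fractional phase boundaries by linear interpolation for
exactly this reason.

## Numerical choices

The nonlinear pair $(\tau,\gamma)$ is profiled on a grid — $\tau$ over (a
thinning of) the interior observation times, $\gamma$ over a geometric
grid from 1 GDD6 to half the time range — with the linear coefficients
solved in closed form at each node from cross-sums, followed by a local
fine-grid pass at data resolution and Nelder-Mead polish. A bend is
declared unidentifiable when it improves on a single straight line by less
than $10^{-6}$ in relative residual sum of squares (the estimates are
still returned). Fits on dense unit grids are thinned to at most 300
points; the bend is located to sub-grid precision by the refinement, and
the exhaustive-oracle test in the suite confirms agreement with a brute
force $(\tau,\gamma)$ lattice within one lattice step. Bend centres are
clipped into their fitting windows so the boundary ordering
$t_e \le t_1 \le t_M \le t_o \le t_2 \le t_z$ holds by construction.

When only sparse "flight" observations are available, a monotone
(Fritsch-Carlson) cubic interpolant maps them onto the 1-GDD6 grid first,
with linear tails to zero when the series starts or ends above zero. This
is deliberately a generic interpolant: reconstructing GLAI from
reflectances with a physiological canopy model is out of scope here.

# The synthetic MAGIC panel and trial generator

The generator is the package's stand-in for the field: its defaults *are*
the study conditions used by the tests and the acceptance script.

**Genotypes.** 324 doubled-haploid lines on 10 chromosomes (2 × 10^8^ bp
each) descend from 16 founders; founder 1 plays the role of B73, and all
marker effects downstream are reported for the *B73-allele carrier
indicator*, so signs are directly comparable across markers. Each line
chromosome is a Markov mosaic of founder segments with a
Poisson(`recombRate = 6`) number of breakpoints — a funnel cross
compresses several meioses into one mosaic, so the rate is per-line, not
per-meiosis. Funnel family structure is approximated by 8 families sharing
a founder-preference prior, which reproduces the within- vs between-family
kinship contrast of a real funnel. Founder allele frequencies are drawn
per marker from U(0.1, 0.9); markers with minor allele frequency below
3.5% are removed, matching the panel-building convention this analysis
assumes. Doubled haploids are fully homozygous, so dosages are 0/2 and the
identity-by-state kinship has unit diagonal.

**Phenotypes.** For every genotype × environment, the seven curve
parameters (t~e~, τ~v~, t~M~, GLAI~M~, t~o~, τ~s~, t~z~) are the
environment baseline plus independent genotype main effects, G×E
deviations, and planted QTL effects; water-deficit (WD) environments
multiply GLAI~M~ by 0.8 and advance the three senescence times by 60 GDD6,
the phenomenology of a pre-flowering drought. Each plot observes its
genotype's curve at 10 flight times (150–1800 GDD6) plus a block effect, a
separable AR1×AR1 spatial field over the row × column grid, and
independent noise of SD 0.20 m^2^ m^-2^ — the error structure the spatial
adjustment model assumes, at magnitudes typical of UAV-derived GLAI. Grain
yield is built causally from the true curve (weights on AUC~F~ and
AUC~S~), female flowering from the true vegetative duration, and kernel
number/weight and anthesis-silking interval as correlated derivatives. The
`TruthSet` records planted QTLs, per-genotype true parameters and the
analytic true traits.

The generator does *not* emulate sequence-level LD decay, dominance or
epistasis, weather, or the reflectance-to-GLAI step. Passing recovery
tests therefore shows the *statistical machinery* is correct under the
assumed error structure; it cannot certify behaviour under model
misspecification that real canopies may exhibit.

**Analytic truth.** True trait values are computed from the planted
parameters with the same definitions as the extraction but on the
closed-form curve (exact piecewise antiderivatives for AUCs, root
bracketing for threshold crossings), giving a cross-module oracle that is
independent of the grid code path.

# Phenotypic statistics

**Adjusted means.** Per trait × environment, genotype and block are fixed
effects and the residual covariance is
$\sigma^2\,\mathrm{AR1}(\rho_r)\otimes\mathrm{AR1}(\rho_c)$ over the plot
grid — the standard separable field-trial model. $(\rho_r,\rho_c)$ are
chosen by profiling the REML criterion over $\{0,0.1,\dots,0.9\}^2$; the
adjusted mean is the overall mean plus the sum-to-zero genotype effect. A
genotype absent from an environment yields a missing value with a reason,
not a failure.

**Heritability.** Generalized (Cullis) heritability
$H^2 = 1 - \bar v_\Delta / (2\hat\sigma^2_g)$ uses the mean prediction
error variance of pairwise genotype-BLUP differences from the
mixed-model equations (all pairs up to 400 genotypes, 10,000 sampled pairs
beyond), clipped to [0, 1]. In a balanced iid design this reduces to
$1/(1+\sigma^2_e/(r\sigma^2_g))$, which the tests verify. At the network
scale the BLUPs come from the multi-environment model below.

**Variance decomposition.** `value ~ environment + (1|genotype) +
(1|genotype:environment)` by REML (lme4), each random term tested by a
restricted likelihood-ratio test against the model without it, with the
boundary-corrected $\tfrac12\chi^2_0+\tfrac12\chi^2_1$ reference — the
reference distribution is a package choice, as is the AR1×AR1 reading of
"autocorrelated errors"; both are the standard options for this design.
CV~g~ = 100·σ~g~/μ. Trait relationships are summarised by a standardized
PCA over genotype-in-environment rows (listwise deletion; constant columns
dropped with a warning) and by pairwise Pearson correlations with t-tests
per environment.

# Mixed-model GWAS

**Kinship.** Identity-by-state: the fraction of shared genotypes between
two lines, computed globally and leaving each chromosome out in turn
(LOCO). Markers on chromosome *c* are always tested against
$K^{(-c)}$, which avoids proximal contamination — a marker never helps
build the relatedness it is tested against.

**Univariate scan.** $y = \mu + x\beta + u + e$ with
$u \sim N(0, \sigma^2_g K^{(-c)})$. Per chromosome the kinship is
eigendecomposed once; the variance ratio $\delta$ is REML-estimated under
the null by one-dimensional search on $\log_{10}\delta \in [-5,5]$ and
reused for every marker (an `exact` flag re-optimises per marker — the
default trades a negligible approximation for an order-of-magnitude
speed-up, the same trade mainstream LMM scanners make). Each marker is
tested by a likelihood-ratio test against $\chi^2_1$; monomorphic markers
get p = 1 and a flag. Effects are on the B73-allele scale.

**Multivariate scan.** For *t* ≤ 10 traits jointly (the default list of 8:
D~V~, D~S~, GLAI~M~, AUC~V~, AUC~F~, AUC~S~, GY, FF), the matrix-variate
model has a between-trait genetic covariance V~g~ scaled by kinship and a
residual covariance V~e~. Both are estimated per chromosome by an EM
algorithm in the kinship eigenbasis, accelerated by simultaneously
diagonalising (V~g~, V~e~) so every E-step and every per-marker
generalized-least-squares solve is elementwise; convergence is declared at
a relative log-likelihood change below 10^-6^ (1000-iteration cap, with a
warning — the fit at the cap is monotone-improved and used rather than
discarded), and non-positive-definite updates are projected to the nearest
PSD matrix with an eigenvalue floor of 10^-8^. The fixed effects are
re-profiled each EM iteration, i.e. the likelihood is maximised jointly
over fixed effects and covariances; with a single intercept at n = 324
this differs from a REML fit only at O(1/n). The marker test is a Wald
test of all *t* effects against $\chi^2_t$; genetic correlations come from
V~g~. Rows with any missing trait are dropped (listwise deletion), and
markers passing the joint screen are assigned a-posteriori to the traits
whose per-trait Wald statistic exceeds the $\chi^2_1$ 0.99 quantile
(markers with an empty set are flagged unassigned).

**Multiplicity.** Storey q-values with the smoother $\hat\pi_0$ (natural
cubic smoothing spline over $\lambda = 0.05,\dots,0.95$, evaluated at
0.95, clipped to (0,1]); q ≤ 0.05 declares significance. Below 100 tests
the smoother is unstable and $\hat\pi_0$ is fixed at 1 with a warning.
The screen is applied per trait-environment for the univariate scan and
per environment (joint test) for the multivariate scan, so an
"association" is a trait × SNP × environment combination in both.

# From SNPs to QTLs

**Clustering.** Per trait × environment × chromosome, significant SNPs are
clustered greedily: the most significant unassigned SNP seeds a cluster
that absorbs every unassigned significant SNP with $R^2 \ge 0.6$ against
it (squared Pearson correlation of dosages — appropriate for homozygous
lines); overlapping clusters are then aggregated, and clusters spanning
more than 30% of their chromosome are discarded as artifacts. The cited
clustering method is named but not specified in detail in the literature
this follows; the greedy peak-seeded reading is the package's
interpretation, with single-linkage chaining available behind
`method = "chain"`. The peak is the member with the smallest p (ties to
the smaller position). Intervals are half-open, 1-based.

**Backward selection.** Candidates (deduplicated by peak marker) enter a
multi-environment model on the genotype × environment adjusted means:
environment-specific fixed allele effects per candidate plus an iid random
genotype effect (a kinship-correlated genotype effect is a flag away, but
the iid form keeps the repeated refits tractable). Each candidate is
tested by a joint Wald test of its environment effects *when added last*
(type-III, from the fixed-effect covariance); the least significant
candidate is dropped and the model refitted until all survive at
α = 0.01. Survivors are QTLs; their per-environment effects and Wald
tests (α = 0.01) come from the final model. Identical carrier vectors are
collinear: the one with the smaller single-candidate joint p is kept.
Elimination is order-invariant because the added-last tests come from one
joint fit per round.

**Intervals, colocalization, variance explained.** Each retained cluster
interval is extended at both extremities to the most distant marker within
a 1 Mb window in LD ($R^2 \ge 0.6$) with the extremity member — "local LD
extent" operationalised as a farthest-qualifying-marker rule. Two QTLs
colocalize when their extended half-open intervals overlap on a
chromosome; direction concordance compares B73-allele effect signs in the
environments where both are significant. Variance explained is
$1 - \mathrm{RSS(peaks)}/\mathrm{RSS(intercept)}$ on adjusted means per
environment, and on environment-centred means with all peaks jointly at
the network scale, with per-QTL partial r² by leave-one-out.

# Grain yield from GLAI QTLs

GLAI QTLs from all six retained dynamics traits are merged into unique
genomic regions (connected components of the interval-overlap graph, each
represented by its overall-smallest-p peak), then submitted to the same
backward selection on grain-yield adjusted means across an 11-environment
water-deficit network at the less conservative α = 0.05, with a-posteriori
per-environment Wald tests at the same level. The reported r² comes from a
fixed-effects refit on environment-centred adjusted means — the mixed
model selects, the fixed-effect refit quantifies — because an r² defined
through random-effect shrinkage would not be comparable across QTL sets.
The synthetic network plants direct yield effects at chosen markers and
calibrates the residual so the planted architecture explains a target
fraction (default 0.18) of the environment-centred variance, with
heterogeneous environment means, effect scalings and optional
sign-flipping markers emulating unstable QTLs.

# Design decisions worth knowing

* **Hybrids vs lines.** The field evaluation this emulates phenotypes
  test-cross hybrids with a common tester; with purely additive effects
  the tester contributes a constant, so the generator and all models use
  the DH dosage directly as the genetic predictor.
* **Null calibration under LOCO.** A "fully null" simulation places the
  polygenic background on the chromosomes *other than* the scanned one:
  under LOCO, genetic signal on the scanned chromosome is (by design)
  detectable, so a genome-wide background would not be a null for size
  checks.
* **Open model details** (exact single-trial and multi-environment model
  structures, covariates beyond the intercept, trait standardisation in
  the multivariate fit) are resolved as: AR1×AR1 spatial errors,
  intercept-only fixed effects besides environment/block, and traits
  analysed on their natural scales.
* **Problem sizes.** The test suite and the acceptance script run the
  panel at its native 324 lines with ~2,000 markers on the scanned
  chromosome for calibration checks, 20–50 seeds for operating
  characteristics, and reduced 120–200-line panels for unit tests; these
  sizes give Monte-Carlo error comfortably inside the asserted tolerances.

# Known limitations

* The IBS kinship is an affine rescaling of allele sharing, not a
  centred genomic relationship matrix; with strongly structured panels
  the univariate LOCO scan is calibrated (the suite checks λ~GC~) but not
  identical to a GRM-based scanner.
* The multivariate EM can be slow to converge when V~g~ is nearly
  singular at small n; the iteration cap then yields a slightly
  conservative null fit (the suite's null-mean check bounds the effect).
* Backward selection power at α = 0.01 depends on carrier frequency; very
  rare planted alleles (MAF near the 3.5% filter) will be under-retained
  relative to the common-allele operating characteristics quoted here.
* The spatial model assumes a complete rectangular plot grid per
  environment; highly irregular layouts fall back to whatever subset of
  plot pairs exists, which weakens the REML profile over the correlation
  grid.

# A minimal run

```{r, eval = FALSE}
library(glaiQTL)
res <- runPipeline(smallPipelineConfig(), "glaiqtl-smoke")
res$qtls              # selected QTLs with intervals and peak markers
res$gyPrediction      # yield variance explained by GLAI QTLs
```

Every artifact (VCF, dosage and map TSVs, observation and trait CSVs,
association TSVs, cluster/QTL/colocalization tables, JSON reports and a
manifest with file checksums) is written under the output directory, and a
rerun with the same configuration is bit-identical.
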