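---
title: "Models and methods behind sweepmode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sweepmode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepmode)
```

# The scientific problem

When the same phenotype — here, herbicide resistance in an agricultural
weed — evolves repeatedly in separate populations, three genetic routes can
produce the repetition: each population acquires its own new mutation
(*independent mutation*), a single beneficial allele spreads between
populations by gene flow (*migration*), or an allele that had been
segregating neutrally in all populations (*standing variation*) is swept up
when selection begins. The three routes leave different fingerprints in the
covariance of allele frequencies among populations near the selected site,
and in haplotype sharing, diversity, and linkage disequilibrium around it.

`sweepmode` implements the full chain of analyses used to read those
fingerprints from multi-population SNP data: windowed diversity and
differentiation statistics, an empirical outlier scan with a
randomized-grouping null, delimitation of outlier-enriched regions,
gene-family enrichment by genome resampling, haplotype-group assignment,
composite linkage-disequilibrium summaries, and a composite-likelihood
comparison of the three convergence models against a neutral baseline.
A seeded synthetic-data generator provides ground truth for every stage.

# The neutral model: coancestry of allele frequencies

The backbone of both simulation and inference is a coancestry matrix
$F$ ($K \times K$ for $K$ populations). At a site with ancestral frequency
$\varepsilon$, the vector of population allele frequencies is modelled as

$$ x \sim \mathcal{N}\!\big(\varepsilon\,\mathbf{1},\;
   \varepsilon(1-\varepsilon)\,F\big), $$

with sampling noise $\varepsilon(1-\varepsilon)/(2 n_k)$ added on the
diagonal for $n_k$ sampled diploids. `estimateF()` is the moment estimator
that replaces the unknown $\varepsilon$ with the across-population mean
$\bar{x}$:

$$ \hat{F}_{k\ell} = \overline{
   \frac{(x_k - \bar{x})(x_\ell - \bar{x})}{\bar{x}(1 - \bar{x})} }. $$

Because $\bar{x}$ is itself estimated, frequencies carry information only
about the mean-centred projection $C F C^\top$ with
$C = I - \mathbf{1}\mathbf{1}^\top/K$: adding a constant to a row and
column of $F$ shifts every population equally and is unobservable. The
estimator therefore recovers the centred matrix (the package's
moment-recovery tests use a centred generating $F$, for which recovery is
element-wise accurate to well under 0.02 at 50,000 sites), and all
downstream likelihoods operate in the same centred, rank-$(K-1)$ space, so
the centred plug-in is exactly what they need. An estimated $F$
legitimately carries small negative off-diagonals; covariance entries are
therefore clipped to $[-1, 1]$, not $[0, 1]$, so the neutral limit
$F'(d) \to F$ survives clipping.

# Sweep models

Let $d$ be the distance from a candidate selected site, $r$ the per-bp
recombination rate, and $\tau = \log(1/p_0)/s$ the sweep duration from
starting frequency $p_0$ ($1/2N_e$ for a new mutation or a migration
source; the standing frequency $g$ for a standing variant). The
probability that a neutral lineage stays attached to the sweeping
haplotype is the hitchhiking probability

$$ y(d) = \exp(-r\,d\,\tau). $$

`modelCovariance()` modifies $F$ within the selected populations:

* **independent mutation** — sweeps share no lineages between populations:
  only diagonals move, $F'_{ii} = y^2 + (1-y^2)F_{ii}$.
* **migration** — recipients decay faster than the source by
  $\delta = \log(1/m)/s$: $y_i = e^{-r d (\tau + \delta)}$ for recipients,
  $y_c = e^{-r d \tau}$ for the source, and every selected pair obeys
  $F'_{ij} = y_i y_j + (1 - y_i y_j) F_{ij}$.
* **standing variation** — with $K_s = 1/(2 N_e g)$, lineages sampled in
  different populations coalesce on the standing haplotype with
  probability $P_{\text{coal}} = \frac{K_s}{K_s + 2rd}
  (1 - e^{-(K_s + 2rd)t})$ or pass through unrecombined with probability
  $P_{\text{through}} = e^{-(K_s + 2rd)t}$; within populations
  $F'_{ii}$ mixes by $y^2 (P_{\text{coal}} + P_{\text{through}})$ and
  between populations by $y^2 e^{-2rdt}$.

At $t = 0$ the standing model coincides exactly with migration at
$\delta = 0$; the composite-likelihood identity between the two is one of
the package's standing tests. These formulas are deliberately simplified,
normative versions of the published convergence framework (no staggered
sweep onset; a deterministic sweep duration; the migration lag folded into
$\delta$): the acceptance surface is self-consistency on the package's own
simulator, not numerical agreement with the original software.

`compositeLoglik()` scores a model by summing per-SNP log-densities of the
centred, projected frequency vector under
$\varepsilon(1-\varepsilon)(F'(d) + \mathrm{diag}(1/2n_k))$, with
$\hat\varepsilon$ the across-population mean and frequencies clipped to
$[0.01, 0.99]$ to avoid zero-variance degeneracy. Composite likelihoods
treat SNPs as independent, which is valid for ranking models but not for
chi-square calibration, so the package reports ratios and ranks, never
p-values, from this machinery. The per-site loop exploits the fact that
$F'(d)$ is linear in a handful of per-site scalars and runs in compiled
code. `convergenceGridSearch()` maximises over a parameter grid and a set
of candidate positions; `refineStandingTime()` re-profiles $t$ on a dense
grid at the grid maximum.

# The synthetic-data generator

`simulateNeutralFreqs()` draws frequencies from the truncated-Gaussian
model above — the inference model's own distribution, chosen for
self-consistency rather than coalescent realism. `injectSweep()` redraws
sites within reach of a sweep ($y \ge 10^{-6}$); its default
`"haplotype"` draw gives each selected population a latent swept
haplotype (a Bernoulli($\varepsilon$) allele per site, shared across
populations according to the model) and mixes it with the neutral
frequency as $y A + (1 - y) x$. This matches the model covariance exactly
in the leading $y$ terms and to $O(F)$ in the residual, and — unlike a
pure Gaussian draw, which spreads frequencies — actually fixes
frequencies near the selected site, as a hard sweep does. The
`"gaussian"` draw reproduces the exact model covariance and backs the
likelihood self-consistency studies.

When genotypes are generated for sweep regions, swept haplotypes are laid
down as contiguous gamete segments: each gamete descends from the swept
haplotype at the selected site and carries it to an exponential
recombination-escape breakpoint (rate $r\tau$ per bp per side). The
per-site carrier probability is exactly $y(d)$, so marginal frequencies
are unchanged, but alleles become collinear along the chromosome — the
elevated-LD block and the shared multi-locus haplotype of a real sweep.
Elsewhere genotypes are binomial(2, $x$) per individual under
within-population Hardy-Weinberg, and the ancestral allele is the
reference allele by construction, so derived-allele statistics need no
outgroup.

## The default scenario

`makeDefaultScenario()` fixes the study conditions: eight populations
(four resistant with survival proportions 0.83, 1, 1, 0.71; four
susceptible with 0.1, 0.18, 0.15, 0.2 — class means 89% and 16%), ten
diploids each, five 400-Mb chromosomes, and one sweep per convergence
mode at position 200 Mb of chromosomes 1 (independent, $s=1$), 2
(migration, $s=1$, $m=1$, source WG), and 3 (standing, $s=1$,
$g=10^{-6}$, $t=5000$ — the old-standing regime). Chromosomes 4 and 5
stay neutral and serve as the coancestry estimation panel. The default
coancestry has drift variance 0.1, background covariance 0.02, and an
elevated 0.08 between the two populations known to exchange migrants.

Marker panels mirror a targeted-capture design: 1,200 background SNPs per
chromosome plus dense panels over the candidate regions — 300 SNPs across
±2 Mb for the migration sweep, and for the independent/standing sweeps
250 SNPs across ±2 Mb plus 250 tiling the ±80 kb core. The asymmetry is
deliberate: a migration sweep is class-coherent across its whole
footprint, while independent-mode sweeps leave a class-level signal only
in the narrow core where lineages fix, and the shared top-1% outlier
budget must accommodate all three regions. In the migration region the
susceptible populations additionally segregate two balanced haplotype
classes (the standing swept haplotype and its divergent counterpart, each
on about half the gametes), emulating the balanced variation empirically
observed among non-adapted populations at such loci; this supplies the
susceptible group's haplotype structure, its strongly positive Tajima's D
and Fay & Wu's H, and the region's elevated-LD block.

Two generator constants deserve comment. The effective size
$N_e = 7.5\times10^5$ and split time 289,000 generations are the study
system's standing constants. The recombination rate defaults to
$10^{-7}$ per bp per generation: with $\tau \approx 14$ at $s = 1$ this
puts the hitchhiking footprint at roughly 1–2 Mb, the scale of
empirically delimited sweep regions, and keeps sweeps local (statistics
more than 5 Mb away are indistinguishable from the neutral background);
an order of magnitude slower recombination would smear a strong sweep
over tens of megabases.

# Windowed statistics and their nulls

`windowStats()` works in consecutive, non-overlapping 25-SNP windows per
chromosome (trailing partial windows dropped; the window step is a
convention, stated rather than inherited). Within pooled resistant and
susceptible sample groups it reports $\theta_\pi$ (summed unbiased
per-site heterozygosity $2c(n-c)/n(n-1)$), Tajima's D with the standard
constants evaluated at the rounded mean non-missing allele count,
unnormalised Fay & Wu's $H = \theta_\pi - \theta_H$ with
$\theta_H = \sum 2 c_d^2 / n(n-1)$ over derived counts (sites lacking an
ancestral call are skipped for H only, and $\theta_\pi$ inside H uses the
same sites so the difference is coherent), the $\log_{10}$ ratio
$\pi_S/\pi_R$, and mean per-site Nei $G_{ST}$ between the pooled groups.
Windows without segregating sites report D and H as `NA`, never zero.
Pooling populations within resistance class ignores substructure
deliberately; these statistics are comparatively insensitive to moderate
substructure, and the pooled contrast is the quantity of interest.

Null calibration needs care because the generator's default frequency
spectrum is flat (common variants, as in ascertained SNP panels), under
which D is strongly positive by design. `epsNeutralSFS()` draws
$\varepsilon \propto 1/\varepsilon$ — the neutral mutation-drift
spectrum — and the calibration runs with the frequency clip matched to
the sampler support ($[0.001, 0.999]$): a clip floor above the sampler
floor piles clipped rare variants into an atom (mean D near $-0.27$),
while a floor at 0.01 with no tail below it starves the singleton classes
(mean D near $+0.4$). With the matched support, |mean D| and |mean H|
stay near 0.05 over hundreds of windows.

# Outlier scan, regions, enrichment

`resistanceScan()` ranks SNPs by two empirical criteria: a
differentiation score (pooled resistant-versus-susceptible Nei $G_{ST}$ —
a documented stand-in for a Bayes factor from an MCMC differentiation
model, preserving the joint-threshold structure) and the Spearman
correlation $\rho$ between per-population allele frequency and the
environment (class coded $-1/+1$ by default, or the survival proportion).
A SNP is an outlier iff its score is in the top 1% and $|\rho|$ in the
top 5% of their empirical distributions, so the null flag rate is capped
at 1% by construction. Quantiles are computed on the thinned SNP set
(`thinSnps()`, one random SNP per kb), matching the thin-before-test
order. `randomizedGroupingNull()` re-runs scan and delimitation over
balanced random population groupings (34 admissible splits for eight
populations, excluding the true grouping and its complement) and reports
how often random groupings reach the observed region and outlier counts.

`delimitRegions()` replaces delimitation by eye with a deterministic
rule: single-linkage clustering of outlier positions with gap at most
2 Mb, keeping clusters of at least five, each region spanning its first
to last member outlier. The defaults were chosen so the default scenario
recovers the injected regions; both knobs are exposed.
`familyEnrichment()` places the observed region lengths uniformly and
non-overlapping on the genome, re-counts family genes, and reports the
plus-one empirical p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$,
which never returns zero. The resampling reproduces region sizes but, as
inherited from the original procedure, "does not account well for
variation in gene density" along the genome.

# Haplotype groups and linkage

`haplotypeGroups()` chains pairwise dosage distance (count of differing
dosage codes over pairwise-complete sites, via `ape::dist.gene`), classical
MDS to two dimensions (`stats::cmdscale`; negative eigenvalues discarded
with a message), and best-of-20 k-means with $k=2$. The cluster containing
fewer susceptible-population individuals is the R (resistant-associated)
haplotype group; an exact tie is reported as ambiguous rather than broken
arbitrarily. `ldR2()` estimates LD as the squared Pearson correlation of
dosage vectors (the composite genotype-correlation $r^2$, appropriate for
called genotypes and a stated substitution for a genotype-uncertainty
likelihood method designed for low-coverage data), after filtering to MAF
$\ge 5\%$ and missingness $< 20\%$; it reports the chromosome mean and
third quartile and detects elevated spans as maximal runs of consecutive
10-SNP windows with mean pairwise $r^2 > 0.25$ (span windows are finer
than the 25-SNP diversity windows so compact blocks resolve).

# Validation studies and problem sizes

`modeRecoveryStudy()` is the package's self-consistency study: 20
replicate regions per mode at strong-signal settings (200 SNPs over 4 Mb,
$s = 1$, 50 diploids per population, the model-exact Gaussian draw), with
coancestry re-estimated from companion neutral sites in every replicate,
asking how often the generating model attains the top composite-likelihood
ratio. Two design points matter. First, sampling noise must be small
relative to the drift covariance for the modes to be distinguishable at
all, hence the larger per-population sample in this study. Second, the
migration simulations use $m = 10^{-4}$: at $m = 1$ the migration process
coincides *exactly* with standing variation at $t = 0$ (the underlying
framework's own degeneracy, visible in empirical analyses as "similarly
high" likelihoods for the two models), so ranking between them would be a
coin toss; a low rate makes the source/recipient decay asymmetry
informative. Under these conditions each mode is recovered in well over
80% of replicates. The dense-$t$ refinement checks run where each answer
is sharp: recent gene flow at $m = 1$ (refined $\hat t = 0$) and an old
standing variant ($g = 10^{-6}$, $t = 5000$) on a 300-SNP, 1-Mb region,
since lower bounds on $t$ need SNPs at the scale $1/(2rt)$.

Desk-scale problem sizes throughout (a few thousand background SNPs, 200
null replicates, 1000 resamples/bootstraps, 20 recovery replicates per
mode) were chosen so the whole validation suite runs in minutes on one
core while keeping Monte-Carlo error comfortably inside the asserted
tolerances.

# What passing tests do and do not show

The generator is self-consistent with the inference machinery by
construction: it draws from (or near) the model family the likelihood
assumes. Passing recovery tests therefore demonstrates that the
estimators and search are implemented correctly and are mutually
consistent — not that the model family describes any particular organism.
Real data differ in ways the generator deliberately omits: coalescent
frequency spectra and LD, variable recombination and gene density,
ascertainment, genotyping error and depth-dependent missingness, and
selection regimes outside the three stylised modes. Known limitations:
the migration/standing($t=0$) degeneracy is intrinsic and the package
reports both ratios rather than forcing a choice; composite-likelihood
ratios are not chi-square calibrated; the enrichment resampling ignores
gene-density variation; and the region-delimitation defaults, while
exposed, were calibrated on the synthetic scenario, not on any empirical
dataset.
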