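---
title: "Candidate-gene amplicon analysis in a mass-cross cohort: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene amplicon analysis in a mass-cross cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`amplipop` implements a complete candidate-gene association workflow for
long-range-PCR amplicon resequencing of a mass-cross aquaculture cohort:
sequencing-performance modelling, SNP quality control, nucleotide
diversity and neutrality statistics, linkage-disequilibrium (LD) decay,
EM-based haplotype association, and mixed-linear-model (MLM) marker
association with gene-action classification. Because per-individual
genotypes for this kind of study are rarely deposited, the package ships
a synthetic mass-cross generator whose statistical structure matches the
cohorts these methods target; every downstream stage is exercised and
tested against it.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic world does and does not
establish.

## The study design being modelled

A mass cross: a modest founder pool (by default 12 dams and 29 sires)
spawns together, and a sample of offspring (default 159) is genotyped by
amplicon sequencing over four candidate gene fragments of 4.3--5.6 kbp.
Parent pairs are unrecorded, so the cohort is a mix of full sibs, half
sibs, and unrelated individuals with latent substructure -- the reason
the association stage needs both a kinship covariance and admixture
covariates. Twelve morphometric traits are recorded (weight, lengths,
depths; plus the condition factor K = 100 BWT / SL^3).

## Coverage and the Boltzmann sensitivity curve

Per amplicon (individual x fragment) we compute the mean fold depth and
the *sensitivity*: the fraction of positions covered at >= 10-fold (the
"effective site" threshold; `min_depth` in `pipeline_params()`).
Variance in amplicon performance is apportioned by an additive two-way
ANOVA (individual + fragment, interaction = error; `two_way_anova()`),
with method-of-moments variance components available via
`anova_variance_components()`.

Sensitivity S as a function of mean depth x is fitted by nonlinear least
squares to a Boltzmann sigmoid with asymptotes pinned at 0 and 1:

$$S(x) = 1 - \frac{1}{1 + e^{(x - x_0)/d_x}}$$

`x0` is the depth at half sensitivity (fold), `dx` the transition width
(fold). Only these two parameters are free; fitting is multi-start
(`x0` in {10, 20, 50}, `dx` in {5, 15}) because the initialisation is
not identifiable from context, and the best residual sum of squares
wins. A 95% prediction band is derived by the delta method from the
parameter covariance plus residual variance. Step-like inputs can drive
`dx` toward zero and make the Jacobian singular; the fit is still
returned, with `NA` standard errors.

## SNP quality control

Site-level criteria reject a record outright: Phred base quality >= 20,
mapping quality >= 20, variant (site) quality >= 20, and indels are
excluded. The read-depth criterion (>= 10-fold) applies *per genotype*:
a failing call becomes missing rather than discarding the site, and a
site is retained while at least one individual still carries a
high-quality variant call. This per-genotype reading matches a
calling pipeline in which SNPs are determined individually. Genotypes
are (re)called from the variant-read fraction: within [0.10, 0.90]
heterozygous, above homozygous variant, below homozygous reference --
the interval is read as closed at both ends. For association, sites are
further restricted to MAF strictly > 0.05 and missingness strictly
< 20%, the thresholds printed in the source criteria.

Exonic SNPs are classified synonymous/non-synonymous by substituting the
alternate allele into the reference codon (standard genetic code);
non-exonic SNPs are "silent". Site classes drive the per-class diversity
table.

## Diversity and neutrality

All diversity statistics run on phased haplotypes (2n sequences).

* **pi** -- mean pairwise differences per site; computed per site class
  with fractional class lengths (synonymous/non-synonymous site counts
  are Nei--Gojobori fractional counts from the reference CDS; "silent"
  = non-coding + synonymous).
* **Watterson's theta** -- S / (a_n L).
* **Tajima's D** -- with the standard 1989 normalising constants; `NA`
  when S = 0 (including the degenerate n = 2 case where the variance
  term vanishes).
* **Fu's Fs** -- theta is estimated by the mean pairwise difference;
  the Ewens probability of at least the observed number of distinct
  haplotypes is computed from unsigned Stirling numbers of the first
  kind evaluated in log space (a recurrence over rows keeps n in the
  hundreds overflow-free); Fs = ln(S'/(1-S')). Its p-value comes from
  neutral coalescent simulation at the estimated theta (1000 seeded
  replicates by default, without recombination), counting replicates
  with Fs at or below the observed value.
* **dN/dS** -- Nei--Gojobori pathway counting with Jukes--Cantor
  correction; multi-hit codons average over all shortest pathways (all
  pathways are included, stop-codon intermediates are not excluded).
  Changes *to* stop codons count as non-synonymous so that N + S equals
  exactly 3 x codons. The dN = dS null is tested by a codon-bootstrap
  Z-test (1000 replicates by default).

The package includes its own neutral coalescent sampler
(`sim_coalescent()`), used both for Fu's Fs p-values and as an
independent oracle in the test suite (neutral Tajima's D centred on
zero; pi and theta agreeing in expectation).

## LD decay

Pairwise r^2 is computed within fragments for sites with MAF > 0.1
(strict, following the printed wording "greater than 0.1" over the
looser "at least 10%" phrasing elsewhere; a flag toggles it). From
phased haplotypes r^2 is the squared allele-frequency correlation; from
unphased genotypes a two-site EM resolves the double-heterozygote
ambiguity, Haploview-style. The decay model is the expected r^2 under a
mutation--recombination--drift model,

$$E(r^2) = \frac{10 + C}{(2 + C)(11 + C)}\left[1 +
\frac{(1 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right],$$

with a single per-bp coefficient fitted by least squares through
C(d) = C_hat d. Note the large-C limit of this expectation is the 1/n
sampling floor, not zero. The half-length is the distance where the
fitted curve halves relative to its value at d = 1 bp (the curve
baseline, not the maximum observed r^2 -- the alternative reading of
"mean r^2 dropped by 50%"), solved by bisection; a flat fit
(C_hat = 0 boundary) reports `NA`.

## Haplotypes: EM, imputation, trend regression

Window haplotype frequencies come from the classical
expectation-maximisation over all diplotype expansions compatible with
the observed genotypes (missing genotypes expand over both alleles).
Windows are capped at 8 sites (4^8 expansions worst case); convergence
is a maximum frequency change below 1e-6 or 500 iterations, with seeded
random restarts and deterministic tie-breaking by restart order. The
EM log-likelihood is non-decreasing -- a property test in the suite
caught a genuine accumulation bug here during development, which is
exactly what such tests are for.

Missing genotypes and phase come from `impute_missing()`: consecutive
7-site chunks are phased by the window EM and the posterior-mode
diplotype fills missing calls; chunks overlap by 3 sites and each
individual's chunk orientation is chained by majority vote over the
shared sites (an all-homozygous overlap leaves phase locally ambiguous
but deterministic). Because the enumeration bound discards long-range
context -- and a mass-cross individual is essentially a pair of founder
haplotypes -- a second pass collects the assembled fragment haplotypes
into a frequency-weighted library and re-imputes each missing genotype
from the posterior over library pairs compatible with all observed
genotypes of that individual (a PHASE-like copying shortcut). PHASE's
coalescent-informed Gibbs sampler is deliberately replaced by this
deterministic EM scheme; the substitution is a documented design
decision, adequate for fragments with modest SNP counts.

Haplotype trend regression (`htr_test()`) regresses a trait on the
posterior dosages of the window's common haplotypes (frequency > 1%;
rarer haplotypes are pooled, not dropped, preserving n; the most
frequent haplotype is the baseline). Significance uses 1000 trait
permutations with the add-one correction p = (1 + #{F* >= F})/(1 + B),
so p is never exactly zero. Sliding windows are 4 markers wide, step 1,
never spanning fragments; the pipeline reports every window and flags
the minimum-p one, since the original block-selection rule is unstated.

## Mixed-model association

The marker model is y = mu + Q v + marker + u + e with
u ~ N(0, sigma_g^2 G), G = 2 x kinship. Kinship uses the Loiselle
multilocus estimator (negative estimates truncated to zero, diagonal
0.5), the common choice of the named software when no estimator is
printed. Admixture proportions Q come from a maximum-likelihood EM on
the binomial admixture model (no linkage), 20 seeded restarts; the
number of subpopulations is chosen by the largest successive
log-likelihood gain with an AIC-flavoured plateau guard (the MCMC-based
original is replaced by this EM -- a documented substitution; the
delta-K logic on the likelihood trace is retained).

Variance components are estimated by REML once per trait under the null
model, on the spectral decomposition of G, and reused across markers
(P3D); `exact_reml = TRUE` re-estimates per marker. The marker enters
as a genotype-class factor (2 df when all three classes are observed) so
that additive and dominance contrasts are estimable and the F-test
matches the class-model marker test of standard MLM software; an
additive 1-df coding is available by flag. Marker R^2 is the marker's
sequential sum of squares over the total sum of squares in the
GLS-whitened model, x100. Note two consequences, both visible in the
simulations: the polygenic term absorbs part of a real QTL's signal
when kinship is estimated from the candidate markers themselves (the
study design avoided this by estimating kinship and structure from
independent genome-wide markers, and the tests mirror that choice), and
the whitened R^2 is mildly attenuated relative to the generating
variance fraction.

FDR control is Benjamini--Hochberg over the whole marker x trait family
(matching a single Q column spanning traits; per-trait is a toggle).
Gene action uses the class means: 2a = |G_BB - G_bb|,
d = G_Bb - (G_BB + G_bb)/2, with |d/a| <= 0.5 additive,
0.5 < |d/a| < 1.25 partial-to-full dominance, >= 1.25
over/underdominance. The class means are raw trait means per genotype
class, per the printed footnote definitions, not model-adjusted means.

## The synthetic world

`simulate_dataset()` draws, per fragment, a Poisson number of
segregating sites with Watterson expectation theta L a_n
(theta = 0.003/site by default, matching the low diversity of a
hatchery cohort), placed uniformly (infinite sites). Derived-allele
counts follow the neutral frequency spectrum P(i) proportional to 1/i,
so the marginal site-frequency spectrum is neutral by construction and
the mean Tajima's D of founder pools is centred on zero. Three
mechanisms shape LD and local haplotype structure:

* a **carrier-set permutation** reshuffled at `mix_rate` (default
  0.005/bp) along the fragment -- nearby sites share carrier sets,
  distant ones decorrelate. The default was calibrated once against the
  stated world's LD scale (half-decay within about 2 kbp; measured
  half-lengths 1.1--1.5 kbp) and not revisited;
* **count copying** (`count_cor` = 0.7): a site's derived-allele count
  is copied from its neighbour with this probability, emulating
  mutations on a shared genealogical background; this produces the
  few-common-haplotypes-per-window block structure seen in real
  amplicon data while leaving the marginal SFS untouched;
* a **deme-ordered permutation** for a `div_prop` = 0.15 fraction of
  sites, mixing only within demes, giving two divergent founder
  subpopulations whose marker sites are mutually correlated (a crude
  ancestral split). Setting `div_prop = 0` recovers the neutral,
  unstructured world used by the neutrality oracles.

Offspring draw a dam and a sire (with probability `assort` = 0.9 from
the same deme -- a panmictic mass cross over pooled demes would erase
the subpopulation signal the analysis is supposed to correct for), and
receive one recombinant gamete per parent (Poisson crossovers, uniform
placement, no interference). The planted QTL is the non-deme-marker
site with MAF closest to 0.25 in the first fragment, with additive
effect a = 1 cm and dominance d = 0.4 cm on the latent growth value
that drives standard length; allometric trait construction (weight
scaling as SL^2.8) yields the positively correlated morphometrics and a
condition factor that falls with length. Defaults put the realized
marker R^2 near 0.15 of SL variance. The polygenic term has covariance
2 x pedigree kinship and accounts for 30% of non-QTL variance; a 0.5 cm
ancestry shift completes the structure. Read depth is log-normal with
individual, fragment, and residual effects (fragment-to-individual
effect-variance ratio about 2.6), a linear taper at amplicon ends and
per-base log-normal dispersion; `base_cv = 0` with zero taper gives
deterministic flat profiles, which the degenerate-case tests use.

What a green test does establish: the estimators agree with brute-force
oracles; the pipeline's thresholds act exactly as printed; parameter
recovery works at cohort scale under this world's LD, structure, and
noise. What it does not establish: behaviour under sequencing error,
reference bias, indel misalignment, or pedigree errors -- none of which
the generator models (read-level simulation is out of scope) -- nor
numerical agreement with the original study's tables, whose underlying
genotypes were never deposited.

## Reproducibility

Every stochastic routine takes an explicit seed; a fixed seed makes the
generator byte-identical, permutation p-values bit-reproducible, and
`run_pipeline()` outputs byte-for-byte repeatable (a property test
asserts this). The pipeline writes a JSON report echoing the seed,
package version, every threshold, and per-stage status; a stage failure
aborts its downstream stages and is recorded rather than silently
skipped.
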