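---
title: "Inferring heterogamety, sex-linked regions and their ancestry in full-sib families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring heterogamety, sex-linked regions and their ancestry in full-sib families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmap)
```

## The problem

Young plant sex chromosomes — such as those of dioecious *Silene* species,
where both female (ZW) and male (XY) heterogamety occur in closely related
lineages — leave a characteristic signature in the genotypes of a
two-parent full-sib family. A variant on the sex-limited chromosome (W or
Y) is carried by the heterogametic parent and by every offspring of that
parent's sex, and by no one else. A variant between the two shared
chromosomes (Z or X) of the homogametic parent makes offspring of the
hemizygous sex carry exactly one paternal (or maternal) allele and never
appear heterozygous. Pseudoautosomal (PAR) variants show the same
patterns broken by occasional recombinants. `hetmap` turns these
signatures into a chain of inferences: site classification, a
heterogamety verdict, a genetic map placing the sex-determining locus,
Bayesian reconstruction of the ancestral heterogamety state over a set
of species trees, and a strict-clock conversion of synonymous divergence
into ages.

## Site classification

For a site with mother call $G_m$, father call $G_f$ and offspring calls
$G_{o}$, in ZW mode:

* **W-linked**: an allele present in $G_m$ and in every daughter, absent
  from $G_f$ and every son. Hemizygotes are reported by diploid callers
  as homozygous-looking single-allele calls, so the heterogametic parent
  typically appears heterozygous only because the Z/W (or X/Y)
  gametologs co-assemble.
* **Z-linked**: father heterozygous, mother single-allele; no daughter
  heterozygous (each daughter is hemizygous for one paternal Z) and
  every son carries the maternal allele.
* A pattern violated by 1 to `par_max_inconsistent` offspring with both
  parental configurations informative is a **PAR candidate** — a
  screening label only; definitive pseudoautosomal status comes from
  linkage to the sex locus on the map.

XY mode is the exact mirror; classification is invariant to offspring
order and to consistently swapping the two allele labels.

Two classification subtleties deserve explanation.

*Opposite-pattern precedence.* A site whose calls perfectly match the
sex-limited presence pattern of the opposite system (say, a paternal
allele in every son and in no female, inspected in ZW mode) is
Mendelian-consistent with complete X linkage as well: nothing in the
offspring genotypes contradicts it. Calling it Z/X-linked would let
every fully W-linked site masquerade as X-linked when the mirrored model
is (wrongly) assumed, and the model comparison below would lose its
discriminating power. Such sites are therefore left `UNCLASSIFIED` in
the non-matching mode. For a *true* Z- or X-linked site the gate
misfires only when all offspring of one sex inherit the same parental
allele twice over — probability $2^{-2k}$ for $k$ offspring per sex,
about $2.4\times10^{-4}$ at six per sex.

*Thresholds.* `max_inconsistent = 0` defines "complete" linkage (no
recombinants in the family); `max_missing` defaults to 25% of the
offspring; both are configurable. Expression-based detection of
sex-specific transcripts uses `min_count = 5` and `max_leak = 0` by
default, and requires the pattern in *every* requested tissue — the
two-tissue intersection that separates constitutively sex-limited
transcripts from tissue-specific expression.

## Heterogamety verdict

`infer_heterogamety()` classifies the table under both models and
compares the numbers of completely sex-linked sites: a verdict requires
at least `min_count = 5` complete sites and at least `min_ratio = 3`
times the mirrored count. Anything less is `AMBIGUOUS` — appropriate
for a species with no prior genetic information, where both models must
be entertained.

## Linkage mapping

Phenotypic sex enters the two-point analysis as a testcross pseudo-marker
heterozygous in the heterogametic parent. Only a heterozygous parent's
meioses are informative; recombination fractions come from direct
recombinant counts under the maximum-likelihood phase (the phase
minimising $\hat r$), or, for marker pairs heterozygous in both parents,
from a bounded one-dimensional maximisation of the full multinomial
likelihood over the four phase combinations. Linkage groups are
single-linkage components of the graph with edges at LOD > 4, with

$$\mathrm{LOD} = R\log_{10}\hat r + (n-R)\log_{10}(1-\hat r) + n\log_{10}2 .$$

The $R=0$ limit is taken exactly ($n\log_{10}2$) and $\hat r \ge 0.5$
gives exactly 0, which keeps the invariant $\mathrm{LOD}\ge 0$ with
equality only at independence. Distances are Haldane,
$d = -50\ln(1-2r)$ cM (no interference; the Kosambi function is
deliberately not offered, matching common practice for outbred full-sib
designs). Ordering uses greedy seriation from the tightest pair,
refined by adjacent swaps until no improvement — a deliberate,
documented replacement for proprietary regression-mapping machinery;
the reproducible features are the order, the cumulative positions and
the LOD grouping, not any particular vendor's optimiser. Completely
linked markers collapse onto a single position, so a fully sex-linked
region appears as a point flanked by recombining PAR arms.

Note a structural fact of one-family mapping: Z-linked (mirror:
X-linked) markers segregate only through the homogametic parent, whose
meioses carry no information about offspring sex. They can never join
the SEX linkage group — only markers heterozygous in the heterogametic
parent (W-type and PAR markers) map against the sex locus. Note also
that a complete-linkage LOD over $n$ meioses is $n\log_{10}2$, so at
least 14 offspring are needed to clear the threshold of 4; mapping
examples in this package use family sizes of 55–500, in the range of
real mapping families for such studies.

## Ancestral heterogamety

Tip states {ZW, XY, N (non-dioecious)} evolve under a three-state
continuous-time Markov model with six free rates. The likelihood is
computed by Felsenstein pruning with a uniform root prior; ambiguous
tips (dioecious but heterogamety unknown, written `ZW|XY`, or `?`)
contribute partial likelihood 1 for each allowed state. An ancestral
constraint ("fossilisation") conditions an internal node — located as
the MRCA of a tip set — on one state by zeroing the other partials; it
is conditioning, not an added pseudo-tip, so the three constrained
likelihoods at any node sum exactly to the unconstrained one.

Rates carry a hierarchical prior: i.i.d. Gamma with mean $m$ and
variance $v$, mapped to shape $m^2/v$ and rate $m/v$, with
$m \sim U(0,10)$ and $v \sim U(0,10)$. Sampling uses
Metropolis–Hastings with log-normal multiplicative rate moves, random
walks on $m$ and $v$, a uniformly resampled tree index per sweep
(uncertainty in the species tree is integrated by averaging over the
supplied tree set), and a joint move that shifts $m$ while rescaling
all rates by $m'/m$ (with its $(m'/m)^6$ Jacobian). The joint move
matters: the hierarchy couples the rates to $m$ in a funnel that
componentwise walks traverse too slowly, which is visible as failure to
recover the prior when the likelihood is flat — one of the package's
tests.

Marginal likelihoods come from stepping-stone sampling along the ladder
$\beta_k = (k/K)^{1/\alpha}$ with $\alpha = 0.3$, combining stone
ratios in log-sum-exp form; the reported standard error treats draws as
independent and is therefore a lower bound under autocorrelation. Nine
scenarios — each combination of {ZW, XY, N} at two nested focal
ancestors — are ranked by Bayes factor against the best,
$BF_i = \exp(\ln mL_{best} - \ln mL_i)$, with differences of at least
2 ln units flagged as significant (the conventional strong-evidence
reading of the Kass–Raftery scale). All nine runs share one RNG seed:
with common random numbers the Monte-Carlo error of the *differences*
— which is what ranking and Bayes factors use — is much smaller than
each run's absolute error. Defaults are desk-scale (8 stones of a few
hundred iterations); production analyses of the kind this pipeline
supports have used chains of $10^9$ states, and convergence checking is
left to the user.

## The synthetic-data generator

`simulate_family()` emulates the statistical structure the classifier
assumes: exact hemizygous Mendelian transmission of fully sex-linked
sites (alternating the W-type and Z-type SNP configurations),
pseudoautosomal sites recombining with the sex locus at planted
fractions via a no-interference crossover chain (so the marginal
fractions are exactly the planted ones and inter-marker fractions are
Haldane-consistent), autosomal sites, then symmetric per-allele-copy
genotyping error and genotype-independent missingness. One integer
seed drives a single RNG stream; identical designs and seeds give
byte-identical output, including the VCF.

Deliberate generator choices:

* The default family is 2 parents + 6 daughters + 6 sons with 10
  sex-linked sites, one PAR site at $r = 0.1$ and 20 autosomal sites —
  the shape of an RNA-seq mapping design of parents plus six progeny of
  each sex. Error and missingness default to 0.5% and 2%: the source
  studies do not report their magnitudes, so these are stated knobs,
  not estimates, and validation runs that need exact truth comparisons
  set them to zero.
* Autosomal sites are planted in the intercross configuration (both
  parents heterozygous), which can never satisfy a complete sex-linkage
  pattern. This makes the classifier's specificity on clean data a
  deterministic 1 rather than a probabilistic statement: a
  paternal-testcross autosomal site would mimic complete Z linkage with
  probability $2^{-k}$ for $k$ daughters.
* Sites are transmitted independently given their truth labels. Real
  fully sex-linked variants are physically linked through the
  homogametic parent; independence is the assumption the classifier
  makes anyway, and it keeps every site an independent trial in
  sensitivity/specificity estimates.
* A PAR site that happens to show zero recombinants in a small family
  is *genuinely* indistinguishable from complete sex linkage
  ($P = (1-r)^{12} \approx 0.28$ at $r = 0.1$ with 12 offspring), which
  is why definitive PAR status is assigned by mapping, not by the
  classifier, and why truth-comparison runs plant PAR sites only where
  recombinants are expected.

What the generator does not emulate: read-level noise (no FASTQ, no
alignment), allele-specific expression, paralogous co-assembly beyond
the clean gametolog case, linkage disequilibrium among sex-linked
sites, and population structure. Passing tests therefore demonstrate
correctness of the inference rules under their stated model, not
robustness to assembly artefacts in real RNA-seq data.

`simulate_mk_characters()` draws characters by simulating the embedded
jump chain from a uniform root state, and supports arbitrary state
counts; its two-state closed-form and long-branch stationary behaviour
are tested against analytic values.

## Numerical choices and degenerate inputs

* $\hat r$ is clipped to $[0, 0.5]$; adjacent map distances clip
  $\hat r$ at 0.499 (≈ 310 cM) to avoid infinite Haldane distances.
* Ties in phase at $\hat r = 0.5$ resolve to "coupling".
* Transition matrices use the scaling-and-squaring matrix exponential;
  tiny negative entries from round-off are clamped to zero.
* Likelihood work in the pruning core is vectorised across characters,
  so multi-character MCMC costs one set of per-edge transition matrices
  per evaluation.
* Empty tables classify to empty results; an empty marker set or a
  marker set with no SEX-linked partner raises
  `"no informative markers"`.
* Stepping-stone estimates of a constant likelihood are exact by
  construction, which the tests assert to machine precision.

## Validation problem sizes

The test-suite and acceptance runs use: 6+6 offspring for
classification and heterogamety (50 ZW + 50 XY families), 55 offspring
for LOD-grouping examples, 500 offspring for order recovery and
recombination-fraction accuracy, 300–1000 random ≤5-tip trees against
the exhaustive-enumeration oracle, 16 stones × 1000 iterations for the
conjugate stepping-stone check, and 3000 MCMC sweeps over 200 simulated
characters on 8 tips for rate recovery. These sizes give stable
verdicts at interactive runtimes.

## Known limitations

* Two-point mapping only: no multipoint likelihood, no interference
  model, no cross-family map integration.
* The heterogamety verdict assumes a single full-sib family with both
  parents genotyped.
* Stepping-stone SEs underestimate under strong autocorrelation; for
  publishable Bayes factors run longer chains and check convergence
  externally.
* dS-based dating takes the divergence values as given (with their
  per-gene spread); it does not estimate dS from alignments.
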