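---
title: "Hierarchical pollen pool differentiation: model, assumptions, and design choices"
author: "pollenflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical pollen pool differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenflow)
```

## The scientific problem

When a plant's seeds are genotyped together with their known mother, each
seed's genotype can be split into a maternal and a paternal contribution. The
haploid paternal gametes sampled by one mother constitute her *pollen pool*.
Comparing pollen pools across a nested sampling design — mothers within
sites, sites across a landscape — reveals the spatial structure of effective
pollen movement: pollinators that repeatedly service particular plants along
long routes leave a signature of strong pollen-pool differentiation *among
neighboring mothers* combined with weaker differentiation *among sites*,
whereas short-range territorial pollinators produce the opposite pattern.

`pollenflow` implements this two-generation analysis end to end: maternal
subtraction, hierarchical AMOVA on the inferred gametes with
Φ-statistics, stratified permutation tests, paternity-adjacent summary
statistics, seed-filtering model constructions, and a synthetic-data
generator plus Monte Carlo harness with which the whole design can be
calibrated (type-I error) and sized (power).

## Gamete inference by maternal subtraction

For each seed and locus with mother genotype $\{a,b\}$ and seed genotype
$\{x,y\}$:

* a homozygous seed $\{x,x\}$ carrying a maternal allele fixes the paternal
  allele to $x$;
* a heterozygous seed with exactly one non-maternal allele fixes the paternal
  allele to that allele;
* a seed sharing no allele with its mother is a *mismatch* (genotyping error
  or null allele); the locus is recorded missing and counted;
* the ambiguous case is a heterozygous mother whose seed has her exact
  genotype $\{a,b\}$. Both transmission hypotheses have prior $1/2$, so under
  pollen-pool allele frequencies $p$ the posterior is
  $P(\text{paternal}=a) = p_a/(p_a+p_b)$.

Frequencies are estimated in a first pass from the unambiguous assignments
only, pooled over the whole data set (the overall pollen pool — using
per-site pools instead would bias the resolution toward local structure,
which is the very thing under test). A locus with no unambiguous assignment
falls back to uniform frequencies and is flagged.

### Why the default resolves by sampling, not argmax

Two resolution policies are provided: `"SAMPLE"` draws the paternal allele
from its posterior with the run's seeded generator (the default), `"MAP"`
takes the argmax. MAP looks attractive because it is deterministic and
maximizes per-locus accuracy, but it is statistically unsound for this
pipeline: *every* ambiguous seed of a given heterozygous mother receives the
*same* pooled-majority allele. That manufactures within-mother similarity
that covaries with the mothers' genotypes, i.e. artificial among-mother
differentiation. On the null world (no differentiation at all,
study-shaped design, 11 loci) the within-site permutation test's empirical
type-I error at $\alpha = 0.05$ was 0.40 under MAP with high marker
diversity and 0.96 with low diversity, versus 0.03–0.06 under sampling —
the nominal behaviour the field reports for this design. Sampling with a
fixed seed remains bit-reproducible, so nothing is lost for the headline
pipeline; MAP is kept for sensitivity analysis and for per-locus accuracy
questions where exchangeability does not matter. A useful side effect of
sampling: the recorded per-locus weight (the posterior of the chosen allele)
is *calibrated* — in a world where the resolving frequencies are correct,
the expected hit rate against the true gamete equals the expected recorded
weight, which the test suite checks.

## Distances, AMOVA, and Φ-statistics

Gametes are compared by the locus-identity squared distance
$d^2_{ij} = \sum_\ell \mathbf{1}[a_{i\ell} \neq a_{j\ell}]$ over loci
non-missing in both (missing loci contribute 0 by default; a mode rescaling
by the shared-locus fraction exists but breaks metric additivity and is off
by default). Any global rescaling of $d^2$ cancels in every Φ, so the 0/1
coding is not a substantive choice.

With $N$ gametes in $S$ mothers nested in $G$ sites, sums of squared
deviations follow the standard quadratic-form identities
($\mathrm{SSD_{total}} = \frac1N \sum_{i<j} d^2_{ij}$, within-group terms
analogous), and the method-of-moments components for the unbalanced design
use the coefficients

$$n' = \frac{N-\sum_g\sum_{k \in g} n_k^2/N_g}{S-G},\quad
  n'' = \frac{\sum_g\sum_{k \in g} n_k^2/N_g - \sum_k n_k^2/N}{G-1},\quad
  n''' = \frac{N-\sum_g N_g^2/N}{G-1},$$

giving $\sigma^2_c = \mathrm{SSD_{within}}/(N-S)$,
$\sigma^2_b = (\mathrm{MSD}_b-\sigma^2_c)/n'$, and
$\sigma^2_a = (\mathrm{MSD}_a-\sigma^2_c-n''\sigma^2_b)/n'''$. Components
are never truncated: small negative values are legitimate sampling outcomes
in the absence of differentiation and are reported with a flag. The
Φ-statistics are $\Phi_{CT} = \sigma^2_a/\sigma^2_{tot}$,
$\Phi_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c)$,
$\Phi_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_{tot}$. Because the expected
differentiation between two mothers from *different* sites is the sum of the
within- and among-site levels, the package also reports the additive total
$\Phi_{SC}+\Phi_{CT}$ and the shares
$\Phi_{SC}/(\Phi_{SC}+\Phi_{CT})$ and $\Phi_{CT}/(\Phi_{SC}+\Phi_{CT})$;
both totals are kept separate because the component-based and additive
conventions differ slightly.

### Permutation tests

Significance is assessed within the hierarchical strata:

* **among mothers within sites** (`PhiSC`): seed-to-mother assignment is
  permuted independently within each site, preserving per-mother counts and
  all site memberships;
* **among sites** (`PhiCT`): whole families (a mother with all her gametes)
  are permuted among sites, preserving the number of mothers per site.

p-values use the add-one convention $(\#\{\Phi^{perm} \ge \Phi^{obs}\}+1)/(n_{perm}+1)$,
valid under exchangeability regardless of ties. The default is 999
permutations; all Monte Carlo entry points take an explicit seed. Numerical
tie handling: the comparison uses a $10^{-12}$ slack so bit-level noise in
equal statistics does not flip the count. Only `SSD_within` moves under the
within-site permutation (site totals and all coefficients are invariant), so
that test runs on grouped submatrix sums; the among-site test recomputes the
full decomposition from mother-level pair sums because the unbalanced-design
coefficients change with site composition.

## Paternity-adjacent statistics and seed filtering

Per-locus probability of identity
$P_{ID} = \sum_i p_i^4 + \sum_{i<j}(2p_ip_j)^2$ and the known-mother
paternity exclusion probability (derived as an $O(k^2)$ closed form over
mother genotype classes and verified against full genotype-triple
enumeration at $10^{-12}$) summarize how informative the marker battery is;
their multilocus combinations are the product and
$1-\prod_\ell(1-P_{E,\ell})$ respectively.

Selfed seeds are flagged by a compatibility-plus-likelihood classifier: a
seed incompatible with two maternal gametes at any locus is outcrossed;
otherwise the posterior combines per-locus
$P(\text{seed}\mid\text{self})/P(\text{seed}\mid\text{outcross})$ ratios
with a prior selfing rate (default 0.1, configurable), calling selfed or
outcrossed at a 0.90 posterior threshold and ambiguous in between. This
deliberately replaces full-likelihood sibship reconstruction: it is
deterministic, desk-scale, and testable, and it preserves the inferential
goal (flagging selfed seeds). No agreement with full sibship software is
claimed.

Because seeds from one fruit may share a father (correlated paternity) and
selfed seeds mimic extreme local pollination, three analysis sets are built:
**Model A** drops selfed seeds then keeps one random seed per fruit,
**Model B** keeps one random seed per fruit, **Model C** keeps everything.
The A ordering (filter, then sample within fruit) maximizes the number of
fruits retaining an outcrossed representative. Comparing
$\Phi_{SC}$ across models quantifies how much apparent among-mother
differentiation is inflated by non-independent pollination events.

## The synthetic world

The generator emulates the statistical structure the analysis assumes — not
a landscape. Defaults state the emulated design once: 18 sites × 4 mothers ×
5 fruits × 2 seeds (720 seeds, near the field design's 71 mothers/720
seeds), 11 loci. Per locus, global frequencies are symmetric Dirichlet(1)
draws with allele counts 10–17 ("high" diversity, matching the observed 4–17
range's upper half) or 4–6 ("low"); site pollen pools differentiate from the
global pool at $F_{CT}$ and mother pollen pools from their site pool at
$F_{SC}$ via Balding–Nichols Dirichlet draws with concentration
$(1-F)/F$ (expected fixation index $F$, verified by a moment test). Mother
genotypes are HWE draws from the site frequencies, which yields mild adult
structure comparable to the field estimate ($F_{ST}\approx 0.02$) without
an extra parameter. Each fruit shares one paternal draw with probability
`fruitPaternityCorrelation`; each seed is selfed with probability
`selfingRate` (a second maternal gamete replaces the father). Default
$F_{CT}=0.03$, $F_{SC}=0.06$ bracket the observed Φ range (0.03–0.09);
default selfing 0.1 equals the observed selfing fraction; default fruit
correlation 0.1 matches the low observed correlated paternity
($r_p \approx 0.09$). The preset grid crosses diversity (high/low) with
$F_{CT}\in\{0,0.01,0.05\}$ and $F_{SC}\in\{0,0.01,0.08\}$; the exact
"low/high" levels of the original simulation live in an unavailable
supplement, so these values are stated once here and are config-overridable,
chosen to bracket the observed Φ magnitudes.

What a green test does *not* establish: the generator has no spatial
geometry, no pollinator behaviour, no genotyping error, no null alleles, and
its mother pools are exchangeable draws rather than route-structured sets of
fathers. Tests against it validate the statistical machinery, not any
ecological claim.

## Monte Carlo calibration

`estimateRejectionRates()` replays the full pipeline (simulate → infer →
test) over replicated worlds and reports empirical rejection rates with the
normal-approximation binomial band around the nominal level (for
$p=0.05, n=500$: 0.031–0.069, printing as 0.03–0.07; exact Clopper–Pearson
is available). On the fully null world the within-site test is nominal;
power under strong within-site differentiation ($F_{SC}\approx 0.1$, low
diversity) exceeds 0.95 for both tests.

An important calibration finding the harness exposes: when sites *are*
differentiated ($F_{CT}>0$) while mothers within sites are not, the
within-site test becomes mildly anticonservative (e.g. empirical level
$\approx 0.13$ at $F_{CT}=0.05$, high diversity, versus $0.04$ at
$F_{CT}=0$). The cause is the same exchangeability argument as for the MAP
policy, one level up: ambiguity resolution uses the *overall* pollen pool —
as the published procedure prescribes — so when a site's true pool deviates
from the global one, mothers with different heterozygous genotypes inside
that site are differentially miscalibrated, which reads as among-mother
structure. This is inherent to maternal subtraction with a pooled resolving
prior, not a property of the permutation machinery; simulations that
generate pollen haplotypes directly (skipping subtraction) will not show
it. Significant $\Phi_{SC}$ in data with known site structure therefore
deserves the same caution the field applies to $\Phi_{CT}$ under
within-site structure. These are recomputed, not quoted:
the acceptance script (`scripts/acceptance.R`) runs them at full size
(500/200 replicates × 199 permutations) and the test suite at reduced
replicate counts with bands recomputed for the scaled $n$.

Per-replicate seeds derive from one master seed via `sample.int`, the
idiomatic R equivalent of a counter-based stream; every public entry point
that uses randomness takes an explicit seed and the pipeline log records it.

## Numerical and degenerate-input choices

* Half-called loci (one missing allele) are treated as fully missing —
  half-calls in fragment data are unreliable, and the original missing-data
  policy is unstated.
* Zero pollen-pool mass on both alleles of an ambiguous pair resolves
  uniformly (weight 0.5) with a flag.
* A single site, or no replicate mothers within sites, is a degenerate
  design and errors with the stratum named; zero total variance flags every
  Φ as undefined rather than forcing 0/0.
* Allele labels are opaque strings; fragment-size ordering is never used.
* MAP ties (equal pollen frequencies) break toward the alphabetically first
  allele label, deterministically.

## Known limitations

* Φ-statistics are *tested*, not converted into effective father counts or
  pollination distances; that inference requires a sampling design this
  package does not assume.
* The among-site test inherits the design's known weakness: in the presence
  of strong within-site differentiation its type-I error can be inflated
  (the harness reproduces this), so significant among-site structure should
  be interpreted cautiously.
* The selfing classifier ignores genotyping error, so a single mistyped
  locus can turn a truly selfed seed into an outcrossed call.
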