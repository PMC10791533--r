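---
title: "Relatedness from genotype likelihoods and the inbreeding-avoidance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relatedness from genotype likelihoods and the inbreeding-avoidance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kinavoid asks a field-biology question with a statistical pipeline: in a
group-living animal society where some females breed in the group they were
born into, do those females avoid mating with their relatives? Answering it
needs four pieces that this package implements end to end: pairwise genetic
relatedness estimated from noisy low-coverage sequencing data; pedigree
relatedness to validate those estimates; a demographic null model that says
what relatedness *would* look like under random mating; and a regression
model that compares realized matings against that null.

## Relatedness from genotype likelihoods

Low-coverage sequencing of non-invasively collected samples does not support
confident genotype calls, so every downstream quantity works from genotype
*likelihoods*: for each individual and biallelic site, the probability of the
read data under 0, 1 or 2 copies of the minor allele. Pairwise relatedness is
estimated through the nine condensed Jacquard identity states, which describe
every way the four alleles carried by two individuals at a locus can be
identical by descent — including the states produced by inbreeding. For a
state $k$ with coefficient $\Delta_k$ and a site with minor-allele frequency
$p$, the genotype-pair probability $P(g_1, g_2 \mid k, p)$ follows from
drawing each distinct founder lineage independently from the allele
frequency; `pair_genotype_prob()` implements the resulting table and the
test-suite re-derives it by enumerating lineage assignments and by Monte
Carlo.

The likelihood of a pair's data is a mixture over the nine states,

$$\ell(\Delta) = \sum_s \log \sum_{g_1,g_2} L_A(g_1)\, L_B(g_2)
 \sum_{k=1}^{9} \Delta_k\, P(g_1,g_2 \mid k, p_s),$$

maximized over the simplex by EM (`em_estimate()`): the E-step computes
per-site posterior state probabilities, the M-step averages them. The
log-likelihood is non-decreasing every iteration — asserted in the tests —
and iteration stops when the change falls below `tol = 1e-6` or after 500
iterations. Because each site's likelihood is *linear* in $\Delta$, the
objective is concave on the simplex, so EM reaches the global optimum from
any interior start; the default is a single run from the barycentre, with
optional seeded random restarts retained purely as a numerical cross-check.
Restarts, when used, are symmetrized over the pair-swap permutation
($\Delta_3\!\leftrightarrow\!\Delta_5$, $\Delta_4\!\leftrightarrow\!\Delta_6$)
so that estimates for (A, B) and (B, A) are exact mirror images, a property
the tests check at 1e-8.

From $\Delta$ the kinship is
$\theta = \Delta_1 + \tfrac12(\Delta_3+\Delta_5+\Delta_7) + \tfrac14\Delta_8$
and the per-individual inbreeding coefficients are
$F_A = \Delta_1+\Delta_2+\Delta_3+\Delta_4$,
$F_B = \Delta_1+\Delta_2+\Delta_5+\Delta_6$. We report the Hedrick–Lacy
relatedness
$$r = \frac{4\theta}{2 + F_A + F_B},$$
kinship normalized by the pair's *arithmetic mean* self-kinship. This is the
normalization in Hedrick and Lacy's definition ($r = f_{xy}/\bar f_{self}$,
with $f_{xx} = (1+F_x)/2$); the pedigree-side coefficient of relationship
(`expected_relatedness()`) uses the classical geometric normalization
$2\theta/\sqrt{(1+F_A)(1+F_B)}$. The two agree exactly for outbred pairs, and
every closed-form value used in tests involves outbred pairs, so the choice
is inert there; it matters only for inbred individuals, where the arithmetic
form is the published definition.

**Allele frequencies** come from a reference panel distinct from the focal
community. Dense kin structure biases frequency estimates, and biased
frequencies bias relatedness; the simulator therefore emits an unrelated
panel drawn from the same site frequencies, and `site_filters()` applies the
missingness (≥ 90% of panel individuals with data), Hardy–Weinberg
(1-df likelihood-ratio test on hard-called panel genotypes, retain
$p \ge 0.001$) and minor-allele-frequency filters on the panel only. The MAF
floor defaults to 0.05 — a conventional choice, made once, not a reproduction
of any published threshold. No linkage pruning is applied: simulated sites
are unlinked, and for unlinked sites pruning only discards information.

## Pedigree relatedness and cryptic relatives

`kinship()` implements the standard recursion
$\theta(a,b) = \tfrac12[\theta(s_a,b) + \theta(d_a,b)]$ with
$\theta(x,x) = \tfrac12(1+F_x)$, memoized, under the founder assumption:
individuals with no recorded parents are treated as mutually unrelated and
non-inbred, and an individual with any unknown parent gets $F = 0$. The test
suite checks the recursion against an independent Wright path-counting oracle
(all common ancestors, all pairs of node-disjoint descent paths) on random
five-generation pedigrees. One caution surfaced by that oracle: *full* first
cousins have relatedness 1/8 (their kinship is 1/16); the value 1/16 as a
relatedness belongs to *half* first cousins. Both relationships appear in the
tests with their correct values.

`pedigree_depth()` counts complete ancestral generations (0 when any parent
is unknown), which is how shallow field pedigrees are diagnosed: a pedigree
of depth one cannot distinguish an unrelated pair from, say, half cousins.
`find_cryptic_pairs()` flags pairs with no pedigree connection but genetic
relatedness inside a band (defaults 0.1–0.35, exposed as parameters): above
the noise floor of unrelated pairs, below the parent–offspring/full-sib band,
exactly where unrecorded recent links live. The simulator plants such links
deliberately — immigrant females carry hidden two-generation outside
pedigrees and share outside parents with probability 0.3 — so recovery is
tested against known truth.

## The random-mating null and the avoidance model

Demography defines the null. Conception dates are birth dates minus 228 days
(the species' gestation length); an individual is reproductively aged from
10.5 years (the youngest observed age at first conception, rounded down);
immigrant females with unknown birth dates are assumed 13 years old on
arrival — the typical female dispersal age — so their birth date is imputed
as arrival minus 13 calendar years. For each offspring with both parents
genotyped, the *actual* pair is the mother with the sire, and the *potential*
pairs are the mother with every other genotyped, reproductively aged male
co-resident with her within ±15 days of the conception. "Co-resident" is
operationalized as at least one shared calendar day of community residency
inside that closed 31-day window; the records do not resolve sub-daily
presence, and requiring a single shared day is the weakest reading that still
means "both were there". Offspring with an unknown or ungenotyped parent
contribute no rows at all, keeping the actual and potential sets balanced
per offspring. Mothers are not themselves filtered on reproductive age: a
recorded birth proves the mother was reproducing, so the age filter applies
to candidate males only.

The female philopatry rate counts natal females who *reached* their 13th
birthday inside the study window (alive on the day) and, of those, the ones
that never emigrated. A female who died in the community did not disperse,
so death does not count against philopatry; emigration is inferred from a
terminated residency with no death date, with the observers' call taken as
given. Under the simulator's 0.5 emigration probability this definition
recovers ~50% philopatry, which is the internal consistency check the test
suite runs; the open-ended-residency reading (treating death as
non-philopatry) deflates the rate by cumulative mortality and breaks that
consistency.

The avoidance model is a logit-link beta regression on the shifted outcome
$y = r + 10^{-4}$ (zeroes are observed, and the beta density is undefined at
0; the shift is the smallest value that leaves the second decimal of percent
differences untouched):

$$y_i \sim \mathrm{Beta}(\mu_i \phi, (1-\mu_i)\phi), \qquad
\mathrm{logit}(\mu_i) = \alpha + \beta_A A_i + \beta_{nat[i]} +
\beta_{int[i]} A_i + u_{off[i]} + v_{m[i]} + v_{s[i]},$$

with $A$ the actual-pair indicator, natality contrasts against the natal
reference, offspring varying intercepts $u$, and *multi-membership*
individual effects $v$: mothers and males share one joint index, so both
members of a dyad contribute the same kind of individual-level effect. The
reference cell is (natal, potential), so $\beta_A$ is the natal
actual-versus-potential shift on the log-odds scale — the quantity that
measures avoidance.

Priors are weakly regularizing, chosen once on the scale of the data:
$\alpha \sim N(-4, 1.5)$ (logit of the typical mean relatedness ≈ 0.02),
$\beta \sim N(0,1)$, $\sigma_u, \sigma_v \sim \mathrm{Exp}(1)$,
$\log\phi \sim N(3, 2)$. Sampling uses JAGS with the varying effects in
non-centred form ($u = \sigma_u z_u$, $z_u \sim N(0,1)$). The fixed effects
are sampled through hierarchically centred per-group intercepts
($a_{nat} = \alpha + \beta_{nat}$, $b_{nat} = \beta_A + \beta_{int}$) — an
identical joint prior, algebraically, but each group intercept is informed
directly by its own rows, which removes the slow random-walk mixing of
one-at-a-time contrast updates; the contrasts are recovered
deterministically. `log_posterior()` implements the same posterior natively
in R (both parametrizations, equal up to the change-of-variables Jacobian)
and is tested against a term-by-term oracle, which pins the model JAGS is
asked to sample. Each chain gets its own seeded RNG stream derived from one
master seed, so fits are bit-reproducible; R-hat above 1.05 on any monitored
parameter is an error by default, never a silent return.

Predictions (`posterior_predict()`) set the varying effects to zero
(population-average pair) and summarize 1000 evenly thinned draws of $\mu$
per predictor combination as the median and an 89% *percentile* interval
(the convention of the modelling style this analysis follows; percentile
rather than HPDI, recorded in the output metadata). The headline quantity is
the percent difference between the actual and potential medians per natality
class, `100 (m_A - m_P)/m_P`, rounded to two decimals.

## What the simulator emulates, and what it does not

`simulate_community()` runs an annual event loop over a founding community
(default 30 founders, 35 years): immigration of 13-year-old females
(Poisson, mean 1/year) with hidden outside ancestry; dispersal-age
emigration of natal females (probability 0.5 at age 13); births (probability
0.25 per fertile female-year, fertile ages 12–45); and age-dependent
mortality (8% infant, 2% adult, 12% past age 35) — round numbers for a
long-lived, slowly reproducing primate with overlapping generations.
Founding-era females are labelled natality `unknown`, mirroring individuals
already present when observation starts. Sires are drawn with probability
$\propto \exp(-\gamma r)$ against the mother's *hidden* pedigree relatedness;
$\gamma = 0$ is exact random mating (the default, so the null is honest by
construction) and $\gamma \approx 30$ makes matings at $r = 0.25$ about
$e^{7.5} \approx 1800$ times rarer than unrelated ones.

Genotypes are gene-dropped down the full hidden pedigree (founders
$\mathrm{Binomial}(2, p)$ with $p \sim U(0.05, 0.5)$ per site; one uniformly
chosen allele per parent per site, independent across sites — unlinked
loci), and genotype likelihoods add sequencing noise: depth
$\sim \mathrm{Poisson}(\lambda)$, zero depth = missing, minor-allele reads
$\sim \mathrm{Binomial}(d, q_g)$ with $q_g \in \{\varepsilon, \tfrac12,
1-\varepsilon\}$, likelihoods the binomial probabilities normalized per
site.

Two deliberate simplifications matter for interpreting green tests. First,
sites are unlinked, so realized relatedness concentrates tightly around
pedigree expectations — much tighter than a real genome, where linkage
inflates the variance of realized kinship. The validation $R^2$ achieved on
simulated data is therefore an upper bound on what identical code achieves
on real data. Second, the noise model (Poisson depth, a single per-base
error rate, no mapping bias, no contamination, no allele-frequency
misspecification beyond panel sampling noise) is far cleaner than field
exome captures of faecal DNA. Passing tests demonstrate the estimator and
model are implemented correctly and calibrated under their own assumptions,
not that those assumptions hold in any particular field dataset.

One structural property of the null deserves note: under random mating the
*per-offspring* contrast (actual relatedness minus the mean over that
offspring's potential pool) has expectation exactly zero, and this is what
the model's $\beta_A$ estimates, since the offspring intercepts absorb
pool-level shifts. Raw pooled means of actual versus potential rows do
*not* agree under the null — offspring with larger pools contribute more
potential rows, and larger (later-era) pools are more related on average —
a weighting artifact worth remembering when eyeballing pair tables.

## Problem sizes and numerical choices

The shipped analyses and tests run at sizes chosen to exercise every code
path at full statistical fidelity while staying desk-scale: the validation
study uses 20,000 unlinked sites at mean depth 8, error 0.01, and 220
pedigree-labelled pairs across expected relatedness {0, 1/16, 1/8, 1/4,
1/2}; GLMM recovery checks use 20 replicates of ~600-row datasets with 2
chains × 1200 retained iterations. The end-to-end discrimination runs
(γ = 0 versus γ = 30) use a 16-founder, 26-year community at 4,000 filtered
sites — a deliberate power consideration: avoidance is only detectable when
candidate pools actually contain kin, and pool kinship builds up with
pedigree depth. In the default 30-founder community the potential pools are
nearly unrelated and even pedigree-perfect outcomes cannot separate γ = 30
from γ = 0 at a few hundred parent-pair rows, while very small founder
pools (≤ 12) make the null estimate wildly variable because one repeated
sire dominates the contrast. EM tolerance is
1e-6 in log-likelihood with at most 500 iterations per start; degenerate
inputs (zero shared sites, non-finite likelihoods, empty candidate pools,
undefined philopatry denominators) raise typed errors rather than returning
silent defaults. Ties in hard-calling (only possible with symmetric
likelihoods) resolve to the lowest genotype index, deterministically.

## Known limitations

* Founder alleles are assumed at Hardy–Weinberg proportions and founders
  mutually unrelated; background relatedness among founders is absorbed
  into the genetic estimates but invisible to the pedigree side.
* The beta regression treats dyadic outcomes as conditionally independent
  given the multi-membership effects; higher-order family structure
  (shared grandparents across dyads) is not modelled.
* The Hedrick–Lacy estimator assumes known allele frequencies; panel
  sampling noise propagates into a small positive floor on unrelated pairs'
  estimates (visible as the intercept of the validation regression).
* `run_pipeline()` executes one community analysis per call; there is no
  batch orchestration, caching, or parallelism.
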