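---
title: "Methods: karyotype additivity and the two-step dating of clonal lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype additivity and the two-step dating of clonal lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

karyoClock tests whether clonally transmitted hybrid karyotypes are the
exact additive combination of their parental haploid sets, and places the
clones and their parental species on a common absolute time scale. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Karyotype model

A karyotype is a count vector over the four Levan categories (metacentric,
submetacentric, subtelocentric, acrocentric). The additive expectation for
a hybrid with genome composition $c$ (a word over {E, T, N}, length 1–3)
is the category-wise sum of the haploid complements of its letters, read
from an external reference TSV so the module can be reused for other taxa.
Categories are taken as given labels: arm-ratio measurement is upstream
microscopy, not re-derived here. GISH assignment is a one-dimensional
threshold rule on the green-channel fraction of the two-channel signal;
signals exactly at the threshold (or inside a configurable dead zone
$\pm\varepsilon$, default 0) are reported as ambiguous rather than
force-assigned, because balanced signals in real experiments reflect
non-specific hybridization, not recombination evidence. How a per-
chromosome signal ratio is quantified from pixels is outside the package;
the ratio is the abstraction boundary.

## Clone age: infinite-sites coalescent by importance sampling

For a haploid, maternally inherited locus the scaled mutation rate is
$\theta = 2 N_f \mu$ ($\mu$ per locus per generation, $N_f$ the female
effective size), and one coalescent time unit is $N_f$ generations; each
lineage mutates at rate $\theta/2$ per unit. Samples are binary site
matrices under the infinite-sites assumption, checked by the four-gamete
test before any likelihood is computed.

The sample probability is estimated by Griffiths–Tavaré sequential
importance sampling over event histories: backwards in time the admissible
events are coalescence of two identical haplotypes (coefficient
$n_i(n_i-1)/2$) and removal of a private singleton mutation (coefficient
$(\theta/2)\,n'_g$, where $n'_g$ counts the haplotype that remains after
removal). The proposal samples events proportionally to these recursion
coefficients — the same proposal Genetree uses — and the product of
(coefficient sum)/$\tfrac{n(n-1+\theta)}{2}$ factors over the history is an
unbiased estimate of the sample probability. Conditional on the event
sequence, holding times are exponential in the total event rate, so each
particle also carries a genealogy height; the TMRCA posterior is the
importance-weighted distribution of those heights, summarised by the
weighted mean and the weighted 2.5/97.5 percentiles (inverse cumulative
weight function, atoms resolved by midpoints).

Parameters: the default particle count is $10^5$ for reported runs and
$10^4$ per grid point in the $\theta$ profile (the profile is log-spaced
0.05–50 by default, maximised by grid argmax plus golden-section
refinement between the flanking grid points, all evaluations under common
random numbers). A Stephens–Donnelly proposal was considered and not
implemented: at the sample sizes used here (n ≤ 50, S ≤ 30) the
Griffiths–Tavaré proposal's weight variance is modest, and matching the
reference tool's proposal keeps the estimator comparable. The Ewens
infinite-alleles ML estimator (solving $k=\sum_{i<n}\theta/(\theta+i)$) is
provided as an order-of-magnitude cross-check, not as the primary
estimator, since it discards the site configuration.

## Penalized-likelihood dating

A rooted phylogram with branch lengths $b_j$ (substitutions/site, $L$
sites) is ultrametricised by maximising a Poisson log-likelihood of the
continuous substitution counts $x_j = b_j L$ with mean $r_j t_j L$ (log-
gamma generalised factorial; no rounding, which would bias short branches)
minus $\lambda$ times a roughness penalty: squared rate differences
between each branch and its parent branch, plus the variance of the root's
child rates. Zero-length input branches are floored at $10^{-8}$
substitutions/site.

Ages are parameterised by proportional depths (each internal node a
logistic fraction of its parent's age), which enforces the topological
ordering by construction; the calibration node is pinned exactly by a
global rescale of the raw ages. Rates are log-transformed. The objective
is maximised jointly by BFGS with an analytic gradient and seeded restarts
(one start from subtree-height ages with per-branch saturated rates, one
from the global clock rate, plus random jitters). The prescription of
alternating age/rate blocks was dropped in favour of the joint update: with
the exact gradient the joint problem converges in a fraction of the time
and removes a tuning choice (block order and inner iteration counts).

Two properties worth knowing: the $\lambda\to\infty$ limit reproduces the
Langley–Fitch single-rate solution (total substitutions over total
duration), and the fit is exactly invariant under (ages $\times c$, rates
$/c$, $\lambda \times c^2$) — the $c^2$ on $\lambda$ because the penalty
is quadratic in rates. Rescaling the calibration age alone therefore
rescales ages and rates only up to a penalty-sized perturbation.

Cross-validation removes one tip at a time, refits, and scores the
chi-squared-style error $(x_i-\hat x_i)^2/\hat x_i$ of the tip's observed
substitution count against $\hat x_i = \hat r \,\hat t_P L$, with $\hat r$
the fitted rate of the branch the tip had been attached to (pruned fit)
and $\hat t_P$ the tip's parent-node age from the same-$\lambda$ full fit
— the attachment node does not exist in the pruned tree, and taking its
age from the matching full fit keeps the duration coherent across the
grid. The default grid is $10^{-3}\dots10^3$ in half-decade steps.
Selection on a single small tree is intrinsically noisy (the expected
score differences between well-smoothed fits are small compared with the
Poisson noise of eight terminal branches), so recovery claims about CV in
the test suite are made on the *expected* score curve, averaged over
replicate datasets after per-dataset mean normalisation.

On recovery accuracy: with 8-tip pure-birth trees calibrated at 16 MYA, a
clock rate of 0.0065/site/MYA and $L=1140$, the pooled median relative
node-age error is about 10.5% at $\lambda=100$ and about 6.4% when the
clock is enforced ($\lambda\to\infty$); ape's chronopl at the same
settings gives about 11%. At these rate magnitudes $\lambda=100$ buys
little smoothing (the penalty scales with squared rate differences, here
$\sim10^{-5}$), so a single mitochondrial-length locus simply does not
date young nodes of such trees to much better than ~10% without a clock
constraint. Expect accuracy of that order, not better, at comparable
depths and locus lengths.

The lineage-averaged rate is the arithmetic mean over the spanning subtree
from the tip set's MRCA to the tips (all branches a mutation on those
lineages could have traversed); a `terminalOnly` switch averages terminal
branches instead, since the narrower reading of "branches leading to the
species" cannot be excluded.

## Multispecies-coalescent dating

Speciation times for the fixed topology ((T,N),E) are estimated by MCMC
under the multispecies coalescent: parameters $\tau_{TNE} > \tau_{TN}$
(expected substitutions/site) and five population parameters
$\theta = 4N_e\mu$ (E, T, N, TN, TNE — all five are parameterised
explicitly). Sequences follow JC69 with stationary frequencies 1/4; rate
variation across loci is carried entirely by fixed per-locus scalars,
computed as each locus's mean ingroup–outgroup distance (JC-corrected by
default, p-distance behind a flag) divided by the grand mean, so the
scalars average to one. Within-locus rate heterogeneity is deliberately
not modelled.

The sampler is Metropolis-within-Gibbs: per-locus gene-tree re-simulation
from the coalescent prior (an independence move whose acceptance ratio is
the likelihood ratio), node-time slides within each node's population
interval, $\theta$ multipliers, a global scale move on
($\tau$, $\theta$, all gene-tree node times) with the appropriate
Jacobian, and a $\tau_{TN}$ slide that linearly rescales the coalescent
times contained in the T, N and TN populations (rubber-band style, with
per-node Jacobian factors). Priors are gamma(2, 2/mean) on $\tau_{TNE}$
and each $\theta$, with $\tau_{TN}\mid\tau_{TNE}$ uniform; hyper-means
default to pairwise-distance heuristics (half the mean between-species
distance; the mean within-species distance) and are overridable. Defaults:
25% burn-in, thinning to 2,000 retained samples, explicit seeds, and an
effective-sample-size floor below which the run warns rather than passing
silently. A prior-only run (no loci) reproduces the analytic prior means
and quantiles, which exercises every move's acceptance ratio. The sampler
supports 1–4 haplotypes per species per locus; it is a desk-scale tool,
not a replacement for a production MSC sampler at larger problem sizes.

## Calibration

All rates are carried per MYA internally; the single $10^6$ year/MYA
constant lives in one place. Clone age: $\mu_{gen} = r\cdot10^{-6}L g$,
$N_f = \theta/(2\mu_{gen})$, $t = \mathrm{TMRCA}\cdot N_f\, g$ years, with
the TMRCA interval endpoints mapped through the same monotone transform.
The locus length default is $L = 1140$ (canonical cytochrome *b*),
prominently configurable. By default $\theta$ enters as a plug-in point
estimate — the convention of reporting only the TMRCA interval — but at
n ≈ 30 the profile of $\theta$ is wide and the plug-in interval
undercovers the true age substantially (~65% instead of 95% in our
replicates). `cloneAgeYears(thetaProfile=)` therefore offers joint
propagation: $\theta$ resampled from the normalised profile likelihood,
TMRCA drawn over its interval, and the 2.5/97.5 quantiles of the implied
ages reported. The end-to-end coverage test uses this option; the plug-in
default is retained for comparability. Speciation times convert as
$\tau_{abs} = \tau/\tau_{out}\times$ outgroup age, per posterior sample.

## Synthetic data: what it emulates, what it does not

Generators are pure functions of (parameters, seed) and every dataset
carries its truth record. The coalescent generator draws Kingman
genealogies with Poisson($\theta/2\times$ branch length) mutations, each
at a new site — no recombination, selection, growth, or recurrent
mutation. The MSC generator censors exponential coalescences within
species-tree branches and evolves JC69 sequences — no migration, gene
flow, or alignment error. The phylogram generator offers a strict clock, a
log-normal rate walk along branches (step $\sigma$), and a clade shift
(one clade's rate multiplied by `fold`) — the last added because a
log-normal walk at large $\sigma$ produces nearly independent branch
rates, for which maximal smoothing is genuinely optimal, whereas the
smoothing-parameter contrast requires heritable, clade-level rate
variation. Passing recovery tests on these data shows the estimators are
correct under their own assumptions; it does not validate the
infinite-sites assumption, the JC69 model, or the clock-likeness of any
real alignment, and real mitochondrial data additionally violate
independence between sites.

Test and acceptance problem sizes were chosen as the smallest at which the
statistical claims are stable: 8-tip trees with $L=1140$ and 10–20
replicates for dating recovery; 9 loci × 500 sites × 2 haplotypes/species
and chains of 5,000 iterations for MSC coverage; $10^4$–$10^5$ particles
for the importance sampler.

## Known limitations

* The SIS likelihood degrades for very large samples or many segregating
  sites (weight degeneracy); exact recursion is used only as a test oracle
  for tiny configurations.
* CV selection of $\lambda$ on a single small phylogram is noisy; treat
  single-dataset selections as indicative and inspect the score curve.
* The MSC sampler fixes the species topology and assumes no migration; it
  reports ESS and warns on poor mixing but does not auto-tune.
* Ambiguity in the field conventions — terminal-only versus spanning-
  subtree rate averaging, plug-in versus propagated $\theta$ — is exposed
  as options rather than resolved silently.
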