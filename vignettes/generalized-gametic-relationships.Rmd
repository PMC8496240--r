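---
title: "Generalized gametic relationships and parent-of-origin variance components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized gametic relationships and parent-of-origin variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggrm)
```

## The model

Genomic imprinting makes the effect of an allele depend on its parental
origin: reciprocal heterozygotes differ in trait mean. Summed over all
imprinted loci affecting a quantitative trait, this produces an
*imprinting variance* that can be estimated from pedigreed populations
with a mixed model in which every individual carries two correlated
genetic effects per gamete: an effect *as sire* (expressed when the gamete
is transmitted paternally) and an effect *as dam*. Writing $\sigma_s^2$,
$\sigma_d^2$ for the variances of the effects under the two expression
patterns and $\sigma_{sd}$ for their covariance, the imprinting variance
is

$$\sigma_i^2 = \sigma_s^2 + \sigma_d^2 - 2\sigma_{sd},$$

the variance of the difference between the two expression patterns; it is
zero exactly when the two patterns coincide ($\sigma_{sd} =
\sigma_s\sigma_d$, $\sigma_s^2=\sigma_d^2$), which is Mendelian
inheritance.

A *classical gametic model* carries two gametic effects per individual per
expression pattern, so four random effects per pedigree member: flexible
(any individual may have records) but large. A *reduced model* keeps only
transmitting abilities — the average of an individual's two gametic
effects, i.e. half its breeding value — for parents, and absorbs the
offspring's Mendelian sampling into the residual: half the equations, but
records from parents no longer fit the framework directly.

This package implements the continuum between the two. Each individual is
flagged either `gametic` (keeps its pair of per-gamete effects; required
for individuals with own phenotypes) or `ta` (represented by one
transmitting ability per expression pattern). The covariance matrix of the
mixed effect vector is the **generalized gametic relationship matrix**

$$\bar G = K' G K,$$

where $G$ is the $2t \times 2t$ classical gametic relationship matrix and
$K'$ averages the two gametic slots of every `ta` individual (a row with
two entries $\tfrac12$) and keeps the slots of `gametic` individuals (unit
rows). Its blocks are: half the numerator relationship matrix
($\tfrac12 A$) among transmitting abilities, the classical gametic
relationships among gametic slots, and transmitting-ability-by-gamete
coancestries in between. The limiting cases are $\bar G = G$ (everybody
`gametic`) and $\bar G = \tfrac12 A$ (everybody `ta`).

```{r worked-example}
ped <- as_pedigree(data.frame(id = 1:4, sire = c(0, 0, 1, 1),
                              dam = c(0, 0, 2, 3), code = c(1, 1, 1, 2)))
generalized_matrix(ped)
```

## Direct inversion

Mixed-model equations need $\bar G^{-1}$, never $\bar G$.
`generalized_inverse()` accumulates one rank-one contribution
$u_i u_i' \delta_i$ per genetic effect, directly from the pedigree. The
vector $u_i$ holds 1 at the effect's own slot and negative coefficients at
the known parents' slots ($-\tfrac12$ per parental transmitting ability
and $-\tfrac14$ per parental gametic slot for a transmitting-ability
effect; $-1$ and $-\tfrac12$ respectively for a gametic effect). Twelve
cases arise from the combination of the effect's own kind and the
representations of its parents; `classify_effects()` labels them `a-00`
… `g-gg`.

The scalar $\delta_i$ is the inverse Mendelian sampling variance, the
reciprocal of the Schur complement
$\bar G_{ii} - q_i'\,\bar G_{\text{(parents)}}\, q_i$ with $q_i$ the
negated parental coefficients. Working this out per case collapses the 12
cases into five classes:

| class | cases | $\delta$ |
|---|---|---|
| founder TA | `a-00` | $2$ |
| one known parent, TA effect | `a-0a`, `a-a0`, `a-0gg`, `a-gg0` | $8/(3 - F_{\text{known}})$ |
| two known parents, TA effect | `a-aa`, `a-agg`, `a-gga`, `a-gggg` | $8/(2 - F_s - F_d)$ |
| known parent, gametic effect | `g-a`, `g-gg` | $2/(1 - F_{\text{parent}})$ |
| founder gamete | `g-0` | $1$ |

The one-known-parent and known-parent-gametic classes are occasionally
rendered ambiguously when written as nested reciprocals; the forms above
are the ones consistent with the Schur-complement definition, and the test
suite pins them against dense inversion of $\bar G$ (e.g. the
two-individual pedigree with one known parent has $(\tfrac12 A)^{-1}$
diagonal $8/3$, not $2$). The accumulated sum is order-independent, and on
hundreds of random pedigrees with mixed representations, missing parents
and multi-generation inbreeding it matches the dense inverse to better
than $10^{-9}$.

## The general weighted model

Phenotypes enter through one of four observation equation kinds. An
individual with a gametic pair gets coefficient 1 on its own paternal slot
in the as-sire design and maternal slot in the as-dam design, with residual
variance $\sigma_e^2$ (weight 1). A record linked to parental effects
(reduced and mixed kinds) has the composite residual
$r_i = m_{s_i} + m_{d_i} + e_i$ with variance

$$\tfrac12(1 - F_{s_i})\sigma_s^2 + \tfrac12(1 - F_{d_i})\sigma_d^2 +
\sigma_e^2,$$

handled as a precision weight $w_i = \sigma_e^2 / \text{var}(r_i)$. We
store $\operatorname{Var}(\varepsilon_i) = \sigma_e^2 / w_i$ and use
$\mathrm{diag}(w)$ as the precision multiplier in the mixed-model
equations; this convention makes the weighted coefficient blocks
$X'WX/\sigma_e^2$ etc. come out in the standard form. The $2\times 2$
coefficient matrix attached to $\bar G^{-1}$ in the random blocks is
$\Sigma^{-1}$ with $\Sigma = [[\sigma_s^2, \sigma_{sd}], [\sigma_{sd},
\sigma_d^2]]$.

Reduced equations are exactly equivalent to the gametic ones *only for
final progeny*: an individual with offspring transmits its Mendelian
sampling onward, so absorbing it into its own residual would double-count.
`poe_design(equations = "reduced")` therefore applies reduced equations to
final progeny only, keeps own-effect equations for phenotyped parents, and
prunes phenotyped final progeny from the effect set. With weights
evaluated at the same components, all these representations give the same
restricted likelihood, fixed effects and (mapped through $K'$) the same
predictions — the package tests assert this to $10^{-6}$ and tighter.

## REML, the Mendelian null and the RLRT

`fit_poe_reml()` maximises the restricted log-likelihood

$$-2\ell = \log|R| + \log|G^*| + \log|C| + y'Py \quad (+\ \text{const})$$

($C$ the mixed-model coefficient matrix, $G^* = \Sigma \otimes \bar G$
plus an optional i.i.d. litter block $\sigma_c^2 I$) by Nelder–Mead over
$(\log\sigma_s^2, \log\sigma_d^2, \operatorname{atanh} r,
\log\sigma_e^2[, \log\sigma_c^2])$, which keeps $\Sigma$ positive definite
by construction, so $\hat\sigma_i^2 \ge 0$ always. Sparse Cholesky
factorisations (Matrix) supply solutions and log-determinants. Inner
convergence uses a relative tolerance of $10^{-10}$ with up to 1500
simplex iterations and up to three restarts from the incumbent; when
reduced/mixed equations are present, an outer loop starts from equal
weights, recomputes $w$ from the current estimates and refits until the
log-likelihood changes by less than $10^{-6}$ (at most 50 passes). The
likelihood omits additive constants; only differences are interpreted.

The Mendelian null constrains $\sigma_s^2 = \sigma_d^2 = \sigma_{sd}$,
which makes $\Sigma$ singular; it is fitted as the equivalent
single-vector model with design $Z_s + Z_d$ and variance $\sigma_a^2 \bar
G$ — the familiar animal-model family. `rlrt()` compares the two fits with
$2\Delta\ell$ against $\chi^2_{df}$, $df = 2$ by default (the two extra
free parameters). This is the conventional approximation; at the boundary
of the parameter space the true null distribution is a mixture, so the
plain $\chi^2$ is somewhat conservative. Standard errors, when requested,
come from the numerical Hessian of the restricted likelihood on the
variance-component scale.

Derived parameters use $\sigma_p^2 = \sigma_s^2 + \sigma_d^2 + \sigma_c^2 +
\sigma_e^2$ as phenotypic variance, $h^2 = (\sigma_s^2 +
\sigma_d^2)/\sigma_p^2$, $i^2 = \sigma_i^2/(\sigma_s^2 + \sigma_d^2)$,
$c^2 = \sigma_c^2/\sigma_p^2$ and $r = \sigma_{sd}/\sigma_s\sigma_d$.
These denominators are a definitional choice, made for internal
consistency between $r$, $i^2$ and $h^2$ (e.g. $i^2 = 1 - 2rk/(1+k^2)$
with $k = \sigma_s/\sigma_d$), and are labelled as such wherever reported.

## Genomic counterpart

With phased genotypes, the $2t \times p$ matrix $C$ of mean-centred 0/1
haplotype indicators gives the genomic gametic relationship matrix $G_g =
CC'/s$, $s = \sum_j p_j(1 - p_j)$. When the parental origin of an
individual's haplotypes cannot be determined, its two centred rows are
replaced by their average $\bar c_i = \tfrac12(c_{i1} + c_{i2})$ — which
does not depend on the haplotype order — yielding the generalized genomic
matrix $\bar G_g = K' G_g K$ over the same mixed slot layout as the
pedigree version. Allele frequencies default to the sample (column means
over all haplotypes); base-population frequencies can be supplied
explicitly, since the appropriate reference population is
application-specific. Ordered/unordered status is likewise an explicit
per-individual input. Minor-allele orientation is not enforced: centring
makes $G_g$ invariant to allele relabelling (asserted by test). Markers
with missing or multi-allelic calls are not imputed; they are rejected, or
dropped with a count when requested.

## What the simulator emulates

`sim_pedigree()` generates discrete generations of full-sib litters with
random (optionally full-sib-avoiding) mating; phenotypes sit on the last
generation(s), mimicking populations where most records come from final
progeny and parents are largely unphenotyped. `sim_gene_drop()` drops
bivariate (as-sire, as-dam) gametic effects through the pedigree: founder
gametes i.i.d. $N(0, \Sigma)$, non-founder gametes the parental average
plus Mendelian sampling with covariance $\tfrac12(1 -
F_{\text{parent}})\Sigma$, so the realised effects have covariance $\Sigma
\otimes G$ by construction. Phenotypes add an overall mean, optional
generation effects, optional i.i.d. litter effects and Gaussian noise.
Marker gene dropping transmits each marker independently (free
recombination) from explicitly tracked parental haplotypes.

The simulator deliberately omits selection, linkage/genetic maps,
mutation, non-normal effects, maternal genetic effects and overlapping
generations. Passing tests therefore demonstrate internal correctness of
the algebra and estimation under the stated model, not robustness to
selection-induced disequilibrium or to confounding between imprinting and
maternal effects, which this model family cannot separate from reduced
equations alone.

## Numerical choices and scales

* Dense constructions (`numerator_matrix()`, `gametic_matrix()`,
  `generalized_matrix()`) are reference code with size guards (default $t
  \le 2000$ for the $2t$-sized matrices, $10^4$ for $A$); the sparse direct
  inverse is the production path. Inbreeding uses the vectorised tabular
  recursion on $A$ — at the pedigree sizes this package targets for dense
  work it is faster in interpreted R than element-wise path-counting
  algorithms, and the recursion is pinned against an independent recursive
  kinship oracle in the tests.
* Golden comparisons with quarter-valued matrices are made exactly after
  scaling by 4; floating-point comparisons elsewhere use $10^{-12}$ to
  $10^{-9}$ depending on conditioning.
* Unknown parents are treated as unrelated, non-inbred founders; the label
  `0` is reserved. Parents that never appear as a pedigree row are
  auto-inserted as founders with a warning.
* Validation scales: the inverse is checked against dense inversion on
  200 random pedigrees with $t \le 50$; model equivalences on simulated
  data with $t \approx 500$; parameter recovery and null calibration on 10
  replicates at $t \approx 1000$ with roughly 600 records each. These
  sizes give Monte-Carlo standard errors small enough to detect meaningful
  bias while keeping the default check fast.

## Known limitations

Maternal genetic effects are not modelled; when they are present, reduced
equations confound maternal and imprinting variance, and estimates of
$\sigma_i^2$ from this package should be read as an upper bound on the
imprinting contribution. Single-step blending of pedigree and genomic
generalized matrices, multi-trait and random-regression extensions, and
phasing itself (use external tools; this package consumes phased input)
are out of scope.
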