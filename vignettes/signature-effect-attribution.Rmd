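---
title: "Attributing cancer effect sizes to mutational signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing cancer effect sizes to mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigfx)
```

## Overview

`sigfx` estimates, for each recurrent somatic variant in a tumor cohort,
a cancer effect size (selection intensity) and the share of that effect
attributable to each mutational process active in the carrier tumors.
The chain has five stages, each usable on its own:

1. **Variant I/O and filtering** — MAF-style tables in, post-calling
   quality filters, trinucleotide-context annotation.
2. **Signature deconvolution** — per-tumor SBS-96 spectra, forward
   selection with non-negative least squares against a catalog.
3. **Rate model** — per-variant, per-tumor mutation rates from the
   tumor's context profile and gene-level baseline rates.
4. **Selection model** — maximum-likelihood effect sizes under a Poisson
   fixation model.
5. **Attribution** — posterior assignment of each effect to signatures,
   renormalized within tumors.

A synthetic-cohort generator with exact ground truth makes every stage
testable without external data.

## The fixation model and its likelihood

The central assumption is that a specific variant fixes in a tumor
lineage as a Poisson process with rate equal to its mutation rate
$\mu$ times its effect size $\gamma$: the probability a tumor carries
the variant is $1 - e^{-\mu\gamma}$. With carriers $i = 1..M$ and
eligible non-carriers $i = M{+}1..Z$,

$$\log L(\gamma) = \sum_{i=1}^{M} \log\!\big(1 - e^{-\mu_i\gamma}\big)
  \;-\; \gamma \sum_{i=M+1}^{Z} \mu_i .$$

For $0 < M < Z$ this is strictly concave with a unique interior
maximum; `mle_gamma()` finds it as the root of the score function
(monotone decreasing), bracketed around the homogeneous-rate closed form
$\hat\gamma = -\log(1 - M/Z)/\mu$ and solved by `uniroot` to relative
tolerance `tol` (default `1e-8`). With $M = 0$ the maximizer is
$\gamma = 0$; with $M = Z$ the likelihood increases monotonically, so
the estimate is capped at `gamma_max` (default $10^{12}$) and flagged
`unbounded` rather than reported as a finite optimum. Unbounded
estimates are excluded from attribution by default.

**Eligibility.** Tumors carrying a *different* variant of the same gene
enter neither the carrier nor the non-carrier group, on the assumption
that selection for a second mutation in an already-mutated driver gene
is negligible. A tumor carrying the focal variant stays a carrier
regardless of what else it carries. Variants receive estimates when
carried by at least `min_carriers` tumors (default 2, configurable) —
below that the likelihood is dominated by a single observation.

## Mutation rates

Stage 3 needs $\mu_i$: the expected rate at which tumor $i$ mutates to
this exact variant. We distribute the gene's expected mutation count
$R_g$ (a required input: simulated truth, or a user-supplied per-gene or
per-gene-per-tumor table) over the gene's possible substitutions in
proportion to the tumor's context profile $p = S w$:

$$\mu = R_g \; \frac{p_{c(v)}}{\sum_k n_g[k]\, p_k},$$

where $n_g[k]$ counts the gene positions at which channel $k$ is
possible (every usable position contributes exactly three
possibilities, one per alternate base). This form was chosen because it
conserves the gene rate exactly — summing $\mu$ over all possible gene
variants returns $R_g$ — and is invariant to rescaling $p$, so only the
*shape* of the tumor's mutational spectrum matters. Estimating $R_g$
from synonymous variation is deliberately out of scope.

## Signature deconvolution

Spectra are built over the 96 channels ordered substitution-class-major
(C>A, C>G, C>T, T>A, T>C, T>G), then 5′ flank, then 3′ flank — the
catalog row order — with purine-reference substitutions collapsed to the
pyrimidine strand. Channels are indexed 1..96 in the R API.

`fit_signatures()` runs greedy forward selection per tumor on the
normalized spectrum: at each step every remaining signature is trialled
by refitting all selected weights with non-negative least squares
(`pracma::lsqnonneg`), the best SSE reduction wins, and selection stops
when the best *relative* improvement falls below `stop_tol`
(default `1e-3`). Fitted weights below `min_weight` (default 0.06, the
conventional reporting floor for this style of deconvolution) are
zeroed. Signatures annotated as sequencing artifacts in the catalog may
absorb weight during fitting but are removed afterwards, and the
remaining weights renormalized to sum to 1 — weights express proportions
of *detected, non-artifact* mutational activity. Which signatures count
as artifacts is a catalog annotation, not hard-coded, and the
discoverable signature set is likewise a configuration input.

Two pre-fit conventions matter:

* **Recurrent variants are removed before spectrum building**
  (`remove_recurrent()`): variants present in two or more tumors are
  enriched for selection, which would otherwise bias the passenger
  spectrum toward driver contexts. The full cohort is retained for
  effect estimation.
* **No trinucleotide-abundance renormalization** is applied by default;
  an optional 96-vector scaling hook (`context_scaling`) is exposed for
  users whose catalog and data differ in context composition (e.g.
  exome versus genome).

## Attribution

Given a carrier tumor's weights $w$ and the variant's channel $c$, the
posterior that signature $s$ generated it is
$w_s S_{c,s} / \sum_{s'} w_{s'} S_{c,s'}$. The variant's $\hat\gamma$
times the posterior gives the attributed effect; within each tumor,
attributed effects are renormalized across all (variant, signature)
pairs to proportionate attributable effect sizes summing to 1. Both
normalizations are exact identities and are asserted to $10^{-9}$ in the
test suite. Tumors with no recurrent variants contribute to weight
summaries but are excluded from effect-share summaries, where their
proportion would be undefined. A channel emitted by no active signature
makes the posterior undefined; this is an error, not a silent zero
(with the bundled catalog it cannot occur, since every signature carries
a small uniform emission floor).

## The synthetic generator

`simulate_cohort()` is the generative converse of the estimator:

* per tumor, weights $w$ are drawn from a Dirichlet over the
  non-artifact signatures and a passenger count from a log-normal;
* passengers are placed **channel-first** — channels sampled from
  $S w$ restricted to channels with at least one matching reference
  position, then a uniform draw among matching positions — preserving
  the spectrum the deconvolution assumes while staying
  reference-consistent;
* each planted driver's $\mu$ is computed with the *same* rate equation
  the estimator uses, and the driver fixes with probability
  $1 - e^{-\mu\gamma^*}$ **in tumors with no other variant of its
  gene**. Conditioning on same-gene absence mirrors the estimator's
  eligibility rule: the exclusion of same-gene-mutated tumors assumes
  subsequent same-gene mutations are not selected, and the generator
  realizes exactly that assumption. An unconditional generator would
  plant drivers in tumors the estimator must ignore, inflating $M/Z$
  by construction;
* read counts, population frequencies and classifications are drawn so
  the default filters pass, and every draw is governed by one seed.

Defaults emulate a squamous-lung-like exome at desk scale: 40 genes of
450 nt (four named driver genes plus numbered background genes),
per-gene baseline rate 0.12 expected mutations per tumor, ~60 passengers
per tumor, APOBEC-like, smoking-like, clock-like, flat and artifact
signatures, and one planted APOBEC-context driver in NFE2L2 with
$\gamma^* = 1000$, which puts $\mu\gamma^*$ near 0.4 and the carrier
fraction near 0.3. The panel is deliberately wide so that per-gene
passenger hits stay sparse and eligible non-carrier pools are
non-trivial, as in a real exome.

**What the generator does not emulate:** indels and copy number,
subclonality, sequencing-error read models, regional mutation-rate
covariates, and realistic signature collinearity (the synthetic
signatures are more separable than COSMIC's). Passing recovery tests
therefore demonstrates correctness of the estimation chain under the
model's own assumptions, not robustness to everything real data does.

## Validation scales and numerical choices

The test suite and `scripts/acceptance.R` use these problem sizes,
chosen as the package's own validation conditions:

* effect-size recovery: 200 (tests) / 100 (script) independent cohorts
  of 500 tumors; the mean $\hat\gamma$ over replicates recovers the
  planted $\gamma^*$ within a few percent (asserted within 15%).
  Recovery here uses the generator's true weights for $\mu$, isolating
  the likelihood machinery; weight estimation error is measured
  separately;
* weight recovery: 25 tumors at ~3000 passengers each; mean absolute
  error per signature below 0.05. At this burden, and measured on
  spectra *without* recurrent-variant removal — on a mini-genome,
  cross-tumor position collisions are a genome-size artifact, whereas
  in real exomes recurrence genuinely indicates selection;
* closed-form agreement of the MLE to relative $10^{-6}$ over a grid of
  $(M, Z, \mu)$; conservation identities to $10^{-9}$.

Numerical details: $\log(1 - e^{-x})$ is computed via `expm1` for
stability; the score root is bracketed multiplicatively around the
homogeneous closed form and widened geometrically if needed; Fisher
exact tests use `stats::fisher.test` (validated in the tests against an
independent hypergeometric tail-sum enumeration); forward-selection ties
are broken by column order, and the fit is invariant to catalog column
permutation up to names.

## Filtering conventions

`apply_filters()` applies rules in a fixed order (gnomAD population
frequency, tumor VAF, normal VAF, tumor ALT reads, normal ALT reads,
panel of normals, off-target class, blacklisted genes, optional Fisher
allele-frequency test), counting each removed variant once under the
first failing rule so survivors plus per-rule removals always equal the
input count. Operator directions are literal (gnomAD strictly above
0.04%, tumor VAF strictly below 5%, normal VAF at or above 5%, tumor
ALT below 5 reads, normal ALT at 5 reads or more). A rule whose
annotation is missing for a variant is skipped for that variant rather
than removing it, so sparsely annotated (e.g. synthetic) data is not
penalized. The Fisher filter exempts COSMIC-reported variants; the
gnomAD rule carries no such exemption by default but accepts one via
configuration.

## Known limitations

* At low mutation burden (tens of mutations per tumor) deconvolved
  weights are noisy and flat-like signatures absorb weight from
  structured ones; because $\mu$ inherits this error, single-cohort
  effect estimates for variants in under-weighted contexts can be off
  by a factor of ~2. Averaging over cohorts, or higher burden, removes
  it.
* Effect sizes are reported as point estimates; the estimates table
  carries no intervals by default, but `profile_gamma_ci()` computes a
  profile-likelihood interval on demand.
* The rate model distributes gene rates by context only; regional
  covariates (replication timing, expression) are out of scope.
* `M = Z` variants have no finite maximizer and are reported capped and
  flagged, never silently truncated.
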