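---
title: "From co-occurrence to biotic interactions: the interaction-rate pruning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From co-occurrence to biotic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coprune)
```

## The model

Co-occurrence is a necessary condition for a trophic or mutualistic
interaction: a consumer and a resource that never share a spatial unit
cannot interact. The network of potential interactions therefore links
consumer $\alpha$ and resource $i$ whenever their co-occurrence frequency
$N_{\alpha i}$ — the number of sites where both are present — is at least
one, and the realized interaction network is a pruned subset of it with
$L_{\mathrm{int}} = f \cdot L_c$ links, $f \in (0, 1]$.

The interaction-rate (IR) model assumes a single per-site interaction rate
$p$: at every shared site the pair interacts independently with
probability $p$, so the pair-level probability of interacting anywhere is

$$P_{\alpha i} = 1 - (1-p)^{N_{\alpha i}}.$$

Links are drawn independently across resources for each consumer, and each
consumer's draw is conditioned on keeping at least one resource (a
consumer with no resource could not persist; empirical interaction
datasets contain no isolated consumers). The expected link count under
this conditional distribution is

$$E(L(p)) = \sum_\alpha \sum_i
  \frac{1-(1-p)^{N_{\alpha i}}}{1-(1-p)^{N_\alpha}},
  \qquad N_\alpha = \sum_i N_{\alpha i},$$

because conditioning independent Bernoulli draws on at least one success
rescales every marginal by the same factor. `expected_links()` evaluates
this formula; the unit tests verify it against brute-force enumeration of
all link configurations on small matrices ($10^{-10}$ agreement).

$E(L(p))$ is strictly increasing in $p$, from the *conditioning floor*
(the number of consumers, as $p \to 0^+$: each consumer still keeps one
expected link) to $L_c$ at $p = 1$. `calibrate_p()` solves
$E(L(p)) = f L_c$ by bisection on $(10^{-12}, 1]$ with relative tolerance
$10^{-10}$ on $E(L)$; uniqueness follows from monotonicity, and targets
below the floor or above $L_c$ are rejected as infeasible with an
explanation. `realize_ir()` samples the conditional distribution by
per-consumer rejection (redraw a consumer's row until it has a link),
which is exact because the rows are independent.

The null model against which the IR model is judged is *random pruning*:
every co-occurrence link is kept independently with probability $f$,
regardless of $N_{\alpha i}$, and — following the null's definition as a
fixed per-link keep probability — without consumer-level conditioning.
This is the IR model with all frequencies set to 1. Whether the original
analysis also conditioned the null's realizations on non-isolated
consumers is not documented; we follow each model's formula as written and
note that the difference only matters for consumers whose expected degree
under the null is near zero.

## Degree-distribution model selection

Degree distributions are summarized by the empirical CCDF
$P(K \ge x)$ (equal to 1 at the smallest observed degree) and compared
through four discrete families on support $\{1, 2, \dots\}$, fitted by
maximum likelihood with $x_{\min} = 1$:

| family | pmf (up to normalization) | parameters |
|---|---|---|
| exponential | $e^{-\lambda k}$ | rate $\lambda > 0$ |
| power law | $k^{-\gamma}$ | exponent $\gamma > 1$ |
| truncated power law | $k^{-\gamma} e^{-\kappa k}$ | $\gamma \ge 0$, cutoff $\kappa > 0$ |
| log-normal | $F(k{+}\tfrac12) - F(k{-}\tfrac12)$ | $\mu$, $\sigma > 0$ |

Isolated species are excluded before fitting (the support starts at one
link, matching a CCDF that starts at 1). Selection is by AIC
($2k - 2\log\hat L$, no small-sample correction), with exact ties broken
toward fewer parameters and then a fixed family order. Maximum likelihood
rather than least squares on the CCDF is used because AIC requires
likelihoods and CCDF regression has strongly autocorrelated errors.

Numerical choices worth knowing:

* The truncated power law's normalizer $Z(\gamma,\kappa)=\sum k^{-\gamma}
  e^{-\kappa k}$ is computed as a $10^4$-term partial sum plus an integral
  tail correction, accurate to roughly $10^{-10}$ across the ranges the
  optimizer visits. Optimization uses Nelder–Mead from three fixed starts
  (near the pure power-law solution, an intermediate regime, and the
  exponential boundary $\gamma = 0$), plus explicit boundary candidates,
  so the truncated family's likelihood never falls below its nested
  special cases (pure power law at $\kappa \to 0$, exponential at
  $\gamma = 0$). Fits are deterministic given the sample.
* The exponent of the truncated power law is constrained non-negative. A
  negative exponent would make the "power-law" head increasing — no longer
  a power law — and, just as importantly, it would place the exponential
  family in the *interior* of the truncated family's parameter space, in
  which case AIC spuriously prefers the truncated family on genuinely
  exponential data about 16 % of the time at any sample size. With the
  boundary constraint that rate is halved, and AIC picks `exponential` on
  true geometric samples of $n = 80$ about 88 % of the time — which is the
  practical ceiling for any generator tuned to an "exponential" regime.
* Model selection is a sample property, not a certainty: the acceptance
  suite verifies that the generating family (or its nesting superset) is
  recovered in at least 80 % of 50 replicates at $n = 1000$ for all four
  families; individual samples can and do select a neighbouring family.
* Rescaling a degree sample by a constant factor preserves the selected
  family for scale-free samples, but *rounding* a scaled geometric sample
  places it on a lattice whose gaps the support-1 exponential pmf cannot
  represent, and the log-normal absorbs it. The substantive invariant —
  proportional rescaling never manufactures a fat tail — holds and is what
  the test suite asserts.

## The synthetic generator

`simulate_metacommunity()` provides ground-truth data for every pipeline
stage. Species $s$ occupies site $t$ independently with probability
$q_s a_t$, with range propensity $q_s \sim \mathrm{Beta}$(`occupancy_shape`)
and site suitability $a_t \sim \mathrm{Beta}$(`site_shape`) shared by both
guilds; species are conditioned on occupying at least one site.
Interactions are then drawn *by the IR process itself* — per shared site,
per co-present pair, independently at rate `true_p`, with each consumer's
site-level draws redrawn until it interacts at least once. The generator
is therefore exactly the process whose conditional expectation
`calibrate_p()` inverts, which is what makes parameter recovery a
meaningful end-to-end check: across 50 default communities the calibrated
$p$ recovers `true_p = 0.08` with mean relative bias well under 1 %.

Defaults are `n_sites = 30`, `n_consumers = 80`, `n_resources = 120`,
`true_p = 0.08` — the scale of well-sampled plant–pollinator and
host–parasitoid community studies (a few thousand potential links, a few
hundred realized ones, $f \approx 0.1$).

One occupancy mechanism cannot produce every empirical feature at once.
Wide, overlapping ranges generate large co-occurrence frequencies (hence
strong IR pruning bias and superlinearity) but push the co-occurrence
degree distribution away from exponential; sparse, weakly overlapping
ranges do the reverse. The package therefore documents two regimes:

* **default** (`occupancy_shape = c(0.5, 1.2)`, `site_shape = c(0.35, 2.5)`):
  co-occurrence degrees are exponential-like — the AIC-best family is
  `exponential` in a majority (~60 %) of seeds, against the ~88 % ceiling
  noted above — and frequencies are mostly 1. Used for calibration
  recovery and for the random-pruning contrast (random pruning preserves
  the exponential family).
* **strong coupling** (`occupancy_shape = c(0.3, 0.5)`,
  `site_shape = c(0.5, 1)`): heavy-tailed ranges and hotspot sites create
  wide frequency variation; IR ensembles realize generalists' links
  disproportionately, with a mean log–log slope of realized on potential
  degree around 1.3.

Note that the log–log slope is pulled *below* its structural value by the
degree-$\ge 1$ conditioning (low-potential consumers are guaranteed a
link), so slopes near 1 under random pruning and above 1 under IR pruning
on coupled data are the meaningful comparison, not the absolute values.

A third option, `coupling_exponent` $> 1$, makes the true per-site rate
grow with the pair's co-occurrence frequency
($p \, N_{\alpha i}^{\theta - 1}$), i.e. a biotic–abiotic coupling
*stronger* than the IR model assumes. Fitting the IR model to such data
reproduces a diagnostic seen in empirical systems: the ensemble
underestimates the realized degree of the most generalist consumers
(in ~90 % of seeds at $\theta = 1.5$, versus chance on IR-generated data),
while the realized networks become robustly fat-tailed.

What the generator does *not* emulate: spatial gradients, dispersal
limitation or compositional turnover between sites (occupancy draws are
independent given $q_s a_t$); negative interactions or competitive
exclusion; observation error in either occurrences or interactions; and
abundance effects. Passing tests on synthetic data therefore demonstrate
the *inference machinery* — calibration, sampling, selection — not that
the IR model is the true generating process of any field dataset.

## Statistics in the report module

`run_pipeline()` composes the stages and adds two scalar summaries:
the *superlinearity exponent* (OLS slope of $\log$ realized on $\log$
potential degree over consumers with at least one realized link — a
package-defined summary of a relation the original analysis shows only
graphically) and the *frequency–generalism statistic* (Spearman rank
correlation between a consumer's number of potential partners and its
mean co-occurrence frequency with them; a smoother would serve only
visualization). Zero-realized-degree species are excluded from the
log–log fit and counted separately. `p_vs_f_correlation()` compares
calibrated rates with realized link fractions across datasets (Pearson),
requiring at least three datasets with variation in both quantities.

End-to-end determinism: all ensemble seeds derive from a master seed by a
fixed counter scheme, so `run_pipeline()` output — including the JSON
written by `write_report()` — is byte-identical across runs with the same
inputs and seed.

## Problem sizes used by the test and acceptance suites

Unit tests run on toy matrices and 15×25×35 communities; the acceptance
properties use the default 30×80×120 size with 50 seeds for parameter
recovery, 100 pruned realizations for the null-model contrast, and 50
replicates per family at $n = 1000$ for selection recovery. These sizes
keep the full suite under a minute on one core while leaving the
statistical assertions comfortably powered.

## Known limitations

* The per-site rate is uniform: no per-pair, per-species or per-site
  heterogeneity in $p$ (beyond the optional `coupling_exponent`), and no
  likelihood-based estimation of $p$ from partial interaction data.
* Calibration requires $f L_c \ge$ the number of consumers; datasets
  sparser than the conditioning floor are rejected rather than fitted.
* AIC selection among four flexible families is imperfect at small $n$;
  treat single-dataset family labels as evidence, not verdicts, and
  prefer the ensemble/multi-seed summaries.
* Long-format CSV cannot represent a site hosting no species; such sites
  vanish on a write/load round trip (they carry no co-occurrence
  information).
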