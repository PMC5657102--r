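---
title: "The rareburden selection model and simulation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rareburden selection model and simulation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareburden)
```

## The problem

Individually, rare germline variants and recurrent somatic mutations carry too
few carriers for per-site association tests: a deleterious variant with a
case-population frequency of a few times $10^{-4}$ appears in zero, one or two
of a thousand cases. Collapsing methods (burden tests) therefore merge a set
of candidate variants into a *virtual locus* — a sample is a carrier of the
locus if it carries any member variant — and test the locus-level carrier
counts for case/control association. The whole difficulty lives in the word
*candidate*: collapsing everything dilutes the signal with neutral variants,
while greedy per-dataset selection of case-enriched sites destroys the
calibration of the downstream test.

`rareburden` selects candidates with a hidden Markov random field (HMRF) over
the site axis. Three latent layers interact:

* $X_s \in \{0,1\}$ — is variant $s$ causal,
* $R_s \in \{\mathrm{background}, \mathrm{elevated}\}$ — does site $s$ lie in
  an *elevated region*, a stretch of sites harbouring interacting deleterious
  variants,
* $H_s$ — the hidden genotype state behind the observed carrier column
  $G_{\cdot,s}$, connected to $G$ through a mutation rate $\mu$.

Two structural constraints shape the field. First, interactions (and region
membership) never cross a four-gamete boundary: the site axis is partitioned
into intervals within which every pair of carrier columns passes the
four-gamete test, and the region chain restarts at each interval boundary.
Second, pairwise interaction weights $\omega_{s,s'} = 2 t_s t_{s'} / (t_s^2 +
t_{s'}^2)$ are derived from per-site paired $t$ statistics of tumour-vs-normal
variant allelic frequencies (VAFs), so that sites with concordant allelic
behaviour reinforce each other; somatic sites additionally interact only
within a VAF sub-clone.

## The per-site evidence model

Write $a_s$ and $b_s$ for the case and control carrier counts at site $s$,
$k_s = a_s + b_s$, $N$ for the cohort size and $w_0$ for the case fraction.
The model is a two-component description of the rare candidate sites
(sites whose carrier frequency exceeds `rare_max` — 2% by default — are
common variants and are background by fiat, the usual rare-variant MAF
filter):

* background: $k_s \sim \mathrm{Bin}(N, \mu_b)$, $a_s \mid k_s \sim
  \mathrm{Bin}(k_s, w_0)$ — carriers arise as independent mutation noise and
  scatter over cases and controls at the cohort ratio;
* elevated: $k_s \sim \mathrm{Bin}(N, \mu_e)$ with $\mu_e \ge \mu_b$, and
  $a_s \mid k_s \sim \mathrm{Bin}(k_s, w_1)$ with a *globally shared*
  case-share $w_1$.

The solo evidence at a site is the log-likelihood ratio $m_s$ of the two
components. Sharing $w_1$ across sites is what keeps the selection honest:
on null data the elevated component's case share collapses towards $w_0$ and
no individual site can look compelling merely by a lucky split, while on a
dataset with genuine signal $w_1$ is driven towards 1 by the collectively
case-exclusive carrier pattern and even single-carrier sites gain positive
evidence. Both component rates are estimated with winsorised carrier counts
(per-site contributions capped at the 90th percentile of candidate carrier
counts, at least 5), so a single moderately common site cannot capture the
elevated component.

The region chain over $R$ smooths this evidence along the site axis within
each compatible interval, with the persistence kernel
$P(\mathrm{stay}) = e^{-\theta d} + (1 - e^{-\theta d})/2$ (distance $d$ is 1
between adjacent sites unless physical coordinates are supplied). Scaled
forward–backward recursions give the elevated posterior $r_s$, pairwise
posteriors $\xi$, and the likelihood; $\theta$ is re-estimated each iteration
by one-dimensional maximisation of the expected transition log-likelihood,
and the per-site elevated probabilities $P^e_s$ track the clipped posterior.
In the recursions the chain sees a *truncated* solo potential,
$\max(m_s, \texttt{m\_floor})$: negative evidence at a zero-carrier site is
informative, but only boundedly so — an isolated monomorphic site inside a
strongly elevated neighbourhood remains rescuable. The same truncation
appears in the causal-status update below; bounded ("robust") potentials are
standard practice in random-field modelling, and here they also keep the
region structure comparable across effect sizes.

## Causal-status updates and the decision rule

Holding the field fixed, the iterated-conditional-modes (ICM) update flips
$X_s$ to causal when

$$\lambda + \max(m_s, \texttt{m\_floor}) + \tau B(P^e_s, P^b_s) +
\nu J \sum_{s' \in n(s)} \omega_{s,s'} (2 r_{s'} - 1) > 0,$$

where $\lambda$ is the prior log-odds implied by the current elevated mass,
$B$ is the Bernoulli log-odds $\log(P^e_s / P^b_s)$ (the natural
exponential-family choice for a two-state potential; a difference form is
available via `b_form`), $\tau = \nu = 1/2$ balance solo and interaction
terms, and $n(s)$ is the window of up to `window` = 3 sites on each side
within the same compatible interval. Pairs without an informative
interaction weight couple with unit weight — the weight modulates, rather
than gates, the prior coupling. The interaction strength $J$ (default 1.2)
sets how much a strongly elevated neighbourhood can compensate for absent
marginal evidence.

## The model-selection gate

Selection-then-testing is anti-conservative if the selection can latch onto
noise, so the fit refuses to select anything unless the two-component chain
earns its complexity: the gate statistic $2(\ell_{\mathrm{mix}} -
\ell_0)$ — the chain log-likelihood against a single-component fit with one
pooled carrier rate — must exceed `gate_mult` $\times \log M$ (a BIC-type
penalty for the elevated component's three parameters, default multiplier
3). On null-model data the gate passes in well under 1% of datasets, and
when it does pass the captured sites are case/control-balanced, so the
collapsed test still fails to reach significance; the dataset-level
false-report rate stays near zero, matching the behaviour reported for this
family of methods. On datasets simulated with any of the study's effect
sizes the gate statistic is one to two orders of magnitude above the
threshold, so power is unaffected.

After the fit, singular cases are removed: the per-sample per-site posterior
$\zeta(G_{i,s})$ of the observed genotype (normalised against its
complement) flags variants with $\zeta < 1/2$; the most-typical half of the
cases form a bootstrap pool for re-estimating the typical carrier profile,
and cases whose average flagged count exceeds the user threshold (default 5)
are excluded before the final collapse. The collapsed 2×2 carrier table is
tested with Pearson's $\chi^2$ (Fisher's exact test when an expected cell
drops below 5) at $P < 0.05$ in simulation mode or $P < 2.5 \times 10^{-6}$
(Bonferroni over 20,000 genes) in exome mode.

## The simulation framework

`generate_dataset()` implements the fixed-number strategy: $C$ of $M$ sites
are preset causal, control minor allele frequencies follow Wright's
distribution

$$f(\rho) \propto \rho^{\beta_i - 1} (1 - \rho)^{\beta_L - 1}
e^{\sigma - \rho \sigma},$$

with $\sigma = 12$, $\beta_i = 0.001$, $\beta_L = 0.00033$, and a causal
site's case frequency is lifted through the relative risk
$RR = \delta / ((1-\delta)\rho) + 1$ (equivalently $\theta = \delta +
\rho(1-\delta)$), where the marginal attributable risk $\delta$ is the group
PAR divided by $C$. Sites are independent — the design assumes no linkage
disequilibrium among rare variants — and genotypes are diploid 0/1/2 counts,
collapsed to carrier status by the model. The sampler inverts the Wright CDF
in three pieces (analytic power-law inversions at both endpoint spikes, a
tabulated log-grid in between); rejection sampling is hopeless at
$\beta_i = 0.001$.

Two consequences of these published parameters are worth stating plainly,
because they set what any method can achieve under this design. The
$\rho^{\beta_i - 1}$ spike concentrates almost all MAF mass at astronomically
small frequencies (99% of sites have $\rho < 10^{-6}$), so a typical causal
site's entire signal is the $\delta$ lift: at group PAR 0.02 a causal site
has a ≈44% chance of zero case carriers in 1000 cases, and at PAR 0.05
≈13%. A causal variant that recruited no carriers is statistically invisible
at the margin, which is why causal-miss rates in the thirties of percent are
the expected regime at PAR 0.02, not a defect. Conversely, fewer than 1% of
neutral sites are polymorphic at all, so neutral variants enter the selected
set almost exclusively through the region field — a neutral site flanked by
elevated sites is absorbed into the region, at rates that grow with the
density of detected causal sites and hence with PAR.

The read-count overlay (`overlay_read_counts()`) equips simulated cohorts
with tumour/normal depths (Poisson, mean 60, minimum 1) and supporting reads
(binomial at the carrier's VAF: 0.5/0.5 for germline heterozygotes, a
configurable sub-clonal fraction — default 0.4 — in tumour only for somatic
carriers, sequencing-error support at 0.001 otherwise). These defaults are
the package's own: the study datasets carry no reads, and the overlay exists
so the VAF-weighting path is exercised end to end. What passing tests on
these simulations do *not* show: robustness to linkage disequilibrium,
population stratification, copy-number-distorted VAFs, or depth profiles of
real exomes — none of which the generator emulates.

`generate_null_dataset()` draws every genotype as Bernoulli(0.005) with
fair-coin labels; it is the calibration instrument for the dataset-level
false-report rate.

## Numerical choices and degenerate inputs

* Forward–backward runs in scaled arithmetic; with the scaling used,
  $\sum_i \alpha_s(i) \beta_s(i) = 1$ at every site, checked to $10^{-9}$.
* The paired $t$ statistic at zero variance is capped at $\pm 37.62$
  (the magnitude at machine-precision p-values); sites with fewer than two
  informative pairs carry no weight and couple at the unit prior instead.
* `em_update_theta()` guards against non-unimodal objectives with a grid
  fallback, and a single-site chain returns the lower bound with a warning.
* The EM loop's M-steps are deliberately robustified (winsorised rates,
  Beta-style pseudocounts on $w_1$, clipped posteriors), so the likelihood
  trace is required to stabilise rather than ascend monotonically.
* Initialisation: $X_0$ from a liberal case-majority screen
  ($k_s > 0, a_s > b_s$), $\theta_0 = 1$, $P^e_0 = 0.5$, $\mu_0 = 0.01$;
  convergence when the parameter change drops below $10^{-4}$, at most 60
  iterations. $\theta$ is searched in $[0.05, 2]$.
* Ties and degenerate tables: empty selections test at $p = 1$; degenerate
  2×2 margins return $p = 1$; the mutation-rate update on an all-reference
  matrix is an error by contract.
* All generators and the pipeline are bit-reproducible under a fixed seed; a
  master seed feeds per-stage substreams through a polynomial string hash,
  so adding a stage never reshuffles another stage's randomness.

## Design decisions on genuinely open points

Several components of this model family are not pinned down by the
literature the package follows, and the implementation had to choose:

* $B(\cdot,\cdot)$ is the Bernoulli log-odds; $m(\cdot)$ is the
  two-component carrier log-likelihood ratio above (with read counts
  available it would be natural to add the binomial read-model term; the
  carrier form is what the simulation study exercises).
* The silent-state transition channels evaluate, as printed, to a
  non-positive permutation probability whenever $\theta d > 0$; `trans_J()`
  clips to $[0,1]$ per contract, and the working chain uses the normalised
  persistence kernel above, which preserves the duplicate channel's
  $e^{-\theta d}$ decay and redistributes the remainder uniformly.
* The per-site background probability update from $\xi(s,0,0)$
  (`em_update_pb()`) is provided as specified, but the fit tracks
  $P^e_s$ as the clipped marginal posterior — the two disagree only in
  bookkeeping, and the posterior form is numerically better behaved.
* ICM sweeps hold the neighbour field at the forward–backward posterior
  $r$, so the update typically reaches its fixed point in one sweep; an
  oscillation guard retains the best-scoring state.
* Site permutation equivariance holds for separable data (selection driven
  by marginal evidence) but not in general: the chain and the window are
  order-aware by construction.
* The maximal-cover reconstruction enumerates maximal compatible intervals
  around each core and takes the disjoint chain maximising covered sites by
  weighted-interval scheduling; the dynamic program is validated against
  exhaustive search on small instances.

## Problem sizes used in the checks

The replicate study runs 100 datasets per PAR configuration at the full
study scale (2000 samples × 100 sites) and 1000 null datasets; these sizes
hold the Monte-Carlo standard error of the reported rates near one
percentage point, which is small against the tolerances used to judge them.
Property checks (path-sum equivalence, exhaustive cover search) run at
$M \le 10$, where enumeration is exact.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(sim = sim_config(group_par = 0.02, n_causal = 50),
                  seed = 11)
res <- rareburden_pipeline(cfg)
res$test
glance(res$fit)
autoplot(res$fit)

study <- run_simulation_study(group_pars = c(0.02, 0.05), n_datasets = 20,
                              seed = 1)
study$summary
autoplot(study)
```

## Known limitations

The selection calibration targets the fixed-number design at cohort scales
around $10^3$ per arm; much smaller cohorts starve the evidence model.
Carrier collapse discards dosage information; the VAF model ignores copy
number; the sub-clone stand-in is a 1-D Gaussian mixture chosen by BIC, not
a clonal-architecture reconstruction; and real-cohort concerns (ancestry,
batch, relatedness) are out of scope of both the model and its tests.
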