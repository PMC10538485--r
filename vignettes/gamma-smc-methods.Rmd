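---
title: "Pairwise coalescence-time inference with gamma-projected SMC posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise coalescence-time inference with gamma-projected SMC posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammasmc)
```

## The model

Along a pair of homologous chromosomes, the time to their most recent common
ancestor (TMRCA) changes only at recombination breakpoints. Under the
sequentially Markovian coalescent (SMC) the TMRCA sequence is a Markov chain:
at each base pair, with probability $1 - e^{-\rho s}$ (scaled recombination
rate $\rho = 4 N_e r$ per bp, current TMRCA $s$) a recombination detaches one
lineage at a point uniform on $(0, s)$ and it re-coalesces at rate 1, giving

$$p(t \mid s) \;=\; e^{-\rho s}\,\delta(t - s)
  \;+\; (1 - e^{-\rho s})\,\frac{1}{s}\,(e^{\min(s,t)} - 1)\,e^{-t},$$

with time in coalescent units of $2 N_e$ generations, so the marginal prior
is $\mathrm{Exp}(1)$. Each base pair emits heterozygous with probability
governed by the scaled mutation rate $\theta = 4 N_e \mu$; we use the
linearised Poisson kernel $t^y e^{-\theta t}$ for observation
$y \in \{0, 1\}$, under which the emission update of a gamma density is the
exact conjugate step $\Gamma(\alpha, \beta) \to \Gamma(\alpha + y, \beta +
\theta)$.

The central approximation is to constrain the forward (filtering) density to
the two-parameter gamma family. After a transition, the one-step predictive
("compound") distribution

$$p_{\alpha, \beta}(t) = \int p(t \mid s)\, f_{\alpha, \beta}(s)\, ds$$

is no longer gamma and is projected back, giving a map
$F : (\alpha, \beta) \mapsto (\alpha', \beta')$. Decoding therefore costs
$O(1)$ work per site with no time discretisation, and the representable
time range is limited only by the grid below — TMRCAs orders of magnitude
away from the prior mean remain inferable.

Posteriors combine a forward and a backward pass. The backward pass is the
forward pass run on the reversed sequence, plus one extra flow transition:
the reversed filter at position $p+1$ approximates $\pi(t)\,
P(\text{data} > p \mid T_{p+1} = t)$, and one reverse transition (the chain
is reversible with respect to its $\mathrm{Exp}(1)$ prior up to $O(\rho^2)$)
turns it into $\pi(t)\,P(\text{data} > p \mid T_p = t)$. The extra
transition is applied to the reversed-filter state recorded *before* the
mirrored position, so forward and backward condition on disjoint observation
sets with the focal site counted exactly once; the product divided once by
the prior is $\Gamma(\alpha + \alpha' - 1,\; \beta + \beta' - 1)$. This
placement makes the $\rho = 0$ decoder agree with the Poisson-gamma closed
form to machine precision, which the test suite asserts.

## The flow field and its grid

$F$ is precomputed on a grid in $(\ell_\mu, \ell_C) = (\log_{10}
\text{mean}, \log_{10} \text{CV})$: 51 values of $\ell_\mu$ equally spaced
on $[-5, 2]$ and 50 values of $\ell_C$ on $[-2, 0]$. CV above 1 is excluded
(the gamma density would diverge at zero). Off-grid states are clipped to
the ranges and bilinearly interpolated; interpolation is done on the
$(\ell_\mu, \ell_C)$ images, which preserves positivity. The build depends
only on $\rho$ and is reusable across data sets; `write_flow_cache()`
serialises it together with the run-length caches keyed by
$(\rho, \theta, \text{grid}, \text{max\_len})$.

### Projection criterion

The projection of $p_{\alpha,\beta}$ onto the gamma family is not uniquely
defined, and we treat the criterion as a design choice:

* **Moment matching** (default): $\alpha' = M_1^2 / V$, $\beta' = M_1 / V$
  from closed-form mean and variance. The conditional moments
  $E[t \mid s]$ and $E[t^2 \mid s]$ integrate against $f_{\alpha,\beta}$
  through the exponential-tilt identity $e^{-\rho s} f_{\alpha, \beta}(s) =
  (\beta/(\beta+\rho))^{\alpha} f_{\alpha, \beta+\rho}(s)$, so no quadrature
  is needed at decode time. Terms are grouped so that the $O(1)$ constants
  cancel analytically as $\rho \to 0$; otherwise the tiny variance of
  concentrated small-mean states is lost to roundoff.
* **KL projection** (`method = "kl"`): matches the family's sufficient
  statistics $E[T]$ and $E[\log T]$, i.e. minimises
  $KL(p_{\alpha,\beta} \,\|\, \Gamma)$. $E[\log T]$ uses
  $E[\log(u + w)] = \log u + e^u E_1(u)$ for the recombination branch and
  fixed Gauss–Legendre quadrature in probability space (with a cubic
  substitution clustering nodes in the gamma tail). It is exposed for
  sensitivity analysis; on the benchmark simulations the two criteria give
  nearly identical decodes.

Both leave $\Gamma(1,1)$ fixed up to $O(\rho^2)$ and reduce exactly to the
identity at $\rho = 0$.

### The family-boundary clip

A subtle failure mode drove one genuine design decision. For a concentrated
state far below the prior mean ($\mu \ll 1$, e.g. after a long run of
homozygosity), one transition mixes in weight $w \approx \rho\mu$ of
prior-scale mass. The exact filter keeps that mass as a separate mixture
component which subsequent homozygous bases rapidly re-suppress (its kill
rate is $\theta \cdot \mathrm{Var}$, and the bimodal variance is of order
$w$). A single gamma with CV clipped at 1 cannot represent the bimodality:
any projection matching a mean-like functional absorbs the tail, capping
the kill rate at $\theta \mu^2 < \rho \mu$, and the state ratchets upward
to a spurious equilibrium near $\mu = \rho/\theta$ regardless of the data.
This destroys exactly the regime — TMRCAs far below the prior — that the
continuous state space is supposed to reach.

The default skip-cache rule (`clip = "family"`) therefore *defers* a
hom-run transition whenever the exact compound leaves the representable
family, i.e. when its CV exceeds 1 (equivalently, the moment-matched
$\alpha' < 1$); the emission still applies, and the transition resumes as
soon as the state re-enters the family's reach. Missing-run transitions
are never deferred: with no data, diffusion towards the prior is honest.
Two alternatives remain available: `clip = "entropy"` rejects images whose
differential entropy exceeds the honest mixture bound
$H + h(w) + w\,(H_{\mathrm{prior}} - H)^+$, and `clip = "none"` iterates
the projection unconditionally (and makes the cached trajectories exactly
equal to sequential `apply_flow()` + `emission_update()` stepping, which
the tests exploit). In our benchmarks the family rule preserves
well-specified accuracy while restoring the ability to track TMRCAs a
hundredfold below the prior mean and to detect recent-coalescence sweeps;
the unconditional rule loses both.

## Locus skipping

Observations are segmented at every heterozygous site, every requested
output position, and every `max_len` (default 10 kb) base pairs; a segment
is replayed as a missing run, then a hom run, then one terminal
transition-plus-emission. For each grid node and every run length up to
`max_len`, the cache stores the $(\ell_\mu, \ell_C)$ image of the iterated
per-bp update, so a run of any length costs one (interpolated) lookup;
longer runs chain in `max_len` chunks. Cached node trajectories are exact
by construction; off-node lookups add interpolation error that grows with
run length as neighbouring trajectories diverge (the tests bound it at
about $10^{-3}$ in $\ell_\mu$ and a few times $10^{-2}$ in $\ell_C$ over
runs of a few hundred bases). At $\rho = 0$ the transition is the identity
and the engine bypasses the cache entirely in favour of the exact conjugate
closed form.

## Parameters that matter

* `theta`, `rho` — scaled rates per bp. Defaults in examples follow a
  human-like setting $\theta = 0.00075$, $\rho = 0.0006$ ($\mu = 1.25
  \times 10^{-8}$, $r = 10^{-8}$, $N_e = 15{,}000$). If `theta` is absent
  it is estimated as mean pairwise heterozygosity per accessible bp;
  `rho` may be given as the ratio $\rho/\theta$.
* `Ne`, `generation_time` (default 30 yr) — only used to express posterior
  means in generations and years (1 coalescent unit = $2 N_e$ generations).
* `max_len` — segment cap and cache depth; 10 kb balances cache memory
  (about 0.8 GB at the default grid) against lookup chaining.
* grid ranges — $[-5, 2] \times [-2, 0]$ in $(\ell_\mu, \ell_C)$ spans
  seven decades of mean TMRCA; states outside are clipped to the edges.

## The synthetic-data generator

`simulate_smc_pair()` draws the TMRCA path from exactly the decoder's SMC
kernel (run-length encoded, geometric inter-breakpoint distances with
per-bp probability $1 - e^{-\rho t}$) and emits hets with probability
$1 - e^{-\theta t}$; `simulate_misspecified()` multiplies all true times by
a scale factor, with recombination and emission probabilities evaluated on
the output-scale times, as a genuinely smaller population would produce.
`simulate_sweep_panel()` builds a phased haplotype panel from independent
Kingman genealogies on recombination blocks of mean length $1/\rho$
(a renewal approximation across blocks), drops mutations on branches at
$\theta/2$ per bp per coalescent unit, and forces carrier haplotypes into
a star clade coalescing at `sweep_tmrca` within per-carrier exponential
escape distances of the focal site. An adapter around msprime (run through
the system `python`) provides an independent coalescent simulator — the
full ancestral recombination graph rather than the SMC approximation — for
a constant-size population and for a three-population out-of-Africa
history (Gutenkunst et al. 2009 parameterisation), returning the true
TMRCA path and het sites for one diploid.

What these fixtures deliberately do not emulate: variable recombination
and mutation maps, genotyping and phasing error, linked selection outside
the star-sweep approximation, and any within-panel demography. Passing
tests therefore demonstrate correctness of the inference machinery under
its own model class, not performance on real genomes.

## What the checks compute, and known limitations

The test suite verifies the closed forms against independent adaptive
quadrature of the transition mixture, the decoder against Poisson-gamma
conjugacy at $\rho = 0$, cached against sequential decoding, and the full
pipeline against simulated truth at fixed problem sizes chosen to keep the
suite fast: 3–5 Mb per pair for recovery and calibration properties, 30 Mb
single-diploid benchmarks for the accuracy studies (the scale used by
`scripts/acceptance.R`), and twenty 0.8-Mb eight-haplotype panels for the
sweep-detection property.

Three limitations are worth stating plainly.

1. **A uniform recombination map caps attainable accuracy.** With a
   constant $r$ and $\rho/\theta = 0.8$, a TMRCA segment carries on
   average barely more than one heterozygous site. An exact
   finely-discretised HMM smoother — implemented as an oracle during
   development — reaches only $r^2 \approx 0.58$ against simulated truth
   under these conditions; the gamma decoder sits just below it.
   Concentrating the same average recombination into hotspots (as real
   human maps do) lengthens the informative segments and raises accuracy
   substantially, so benchmark numbers obtained under uniform maps are
   systematically lower than what the same decoder achieves on
   human-map simulations.
2. **Credible intervals are approximate.** Central-50% coverage of the
   combined posterior sits below nominal with the family clip (deferred
   transitions make the posterior over-confident) and above nominal
   without it; the tests assert a wide honest band rather than exact
   calibration.
3. **Small-TMRCA tracking is biased low.** In the 100x-misspecified
   regime the family clip restores strong correlation with the truth, but
   the deferred relaxation biases posterior means downward by a factor of
   a few; rank-based uses (sweep scans, relative comparisons) are
   unaffected, absolute ages in that regime should be treated with care.

One further numerical guard concerns the combination step. In the exact
conjugate filter every pass has $\beta \ge 1$ (the prior's rate plus
accumulated $\theta$), so $\Gamma(\alpha + \alpha' - 1, \beta + \beta' - 1)$
is always proper. Projection and interpolation can however hand back pass
states with $\beta < 1$ (a mean above the prior at CV near 1, typically at
rare tight clusters of heterozygous sites), and if both passes do, the
combination degenerates ($\beta_f + \beta_b - 1 \le 0$: the formula
double-counts diffuseness beyond the prior). At such positions
`decode_pair()` falls back to the better-conditioned single pass (the one
with the larger rate) rather than failing; `combine_forward_backward()`
itself retains the strict error contract and names the offending
positions.

## The selection statistic

For a panel, all pairwise posterior-mean TMRCAs are decoded on a common
grid; the scan statistic at a position is the fraction of pairs with
posterior mean below $T$ generations, optionally averaged over a window
(10–100 kb). Recent positive selection forces carrier pairs to coalesce
recently and inflates the statistic near the swept site. Thresholds are
specified in generations (or years via the generation time); ROC/AUC
evaluation against neutral replicates uses a standard threshold sweep.
`scan_regions()` reports windows above an empirical quantile of the
genome-wide statistic (default top 0.1%) — the region-calling rule is an
operational choice, not a calibrated test.
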