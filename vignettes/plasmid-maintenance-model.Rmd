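---
title: "A generation-based stochastic model of high-copy plasmid maintenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generation-based stochastic model of high-copy plasmid maintenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidrift)
```

## The model

High-copy plasmids without active partition systems are inherited by
random segregation of their copies at cell division. Even so, cultures
grown without selection lose the plasmid far faster than the naive
binomial-segregation argument predicts, and the copy-number distribution
of the surviving population drifts over hundreds of generations.
`plasmidrift` implements a deliberately parsimonious model of this
process: a population is a distribution over per-cell plasmid counts, and
each generation every cell passes through three stages.

**Replication.** A cell carrying $n$ plasmid units doubles its complement
($R(n) = 2$ by default), minus a random number of replication-defective
units $n_\alpha = \lfloor -\alpha \ln U \rfloor$, $U \sim \mathrm{U}(0,1)$.
The failure count therefore follows the exact mass function
$P(k) = e^{-k/\alpha} - e^{-(k+1)/\alpha}$, a geometric law whose single
scale $\alpha$ summarizes all replication noise. $\alpha = 0$ turns
failures off. A saturating multiplier
$R(n) = 1 + a/(1 + b(n - n_{max}))$ is available for copy-number-capped
scenarios; it is clamped to $[1, 1+a]$ because the raw expression has a
pole, and the default analyses never use it.

**Division.** The post-replication complement $n'$ is split
deterministically as $\lfloor \delta n' \rfloor$ and $n' - \lfloor \delta
n' \rfloor$ with $\delta \in (0, 0.5]$. $\delta = 0.5$ is an even split
(odd units make the two daughters differ by one); smaller $\delta$ biases
one daughter. For high-copy plasmids the biological reading of
$\delta < 0.5$ is unresolved multimers: a dimer or tetramer segregates as
one molecule carrying several units, which is statistically equivalent to
an uneven split of units.

**Post-segregational killing.** A fraction $1 - \beta$ of plasmid-free
cells dies each generation (toxin–antitoxin or, here,
restriction–modification based killing). $\beta = 1$ disables the stage.

From the per-generation distribution the package computes the class
fractions $P(n, g)$, the stability $S(g)$ (fraction of cells with
$n \ge 1$ — what a colony-scoring retention assay measures) and the mean
copy number $PCN(g)$ (what droplet-digital PCR measures, averaged over
all cells including plasmid-free ones; `mean_pcn(bearing_only = TRUE)`
conditions on survivors for comparisons against assays that implicitly
do so).

## Class-level bookkeeping and its consequences

Cells are tracked as classes sharing a copy number, not as individuals.
One failure count is drawn per occupied class per generation, in
ascending class order, so a run is a pure function of its seed. Both
daughters inherit the whole class abundance (the population doubles each
generation). This class-level treatment is what makes 600-generation
simulations cheap; the cost is that within-generation heterogeneity
inside a class is ignored, which is why ensemble averaging (default 50
replicates, sub-seeded deterministically from a master seed) is part of
the protocol rather than an afterthought. A per-cell multinomial variant
is out of scope.

Raw cell counts double every generation and would overflow any integer
representation long before generation 600, so the default storage is
normalized class weights. Every observable is a ratio of abundances, so
normalization is exact, not an approximation. An integer-census mode is
retained for small populations and worked examples; there the
post-segregational survivor count is floored to whole cells, as is the
starter-culture census.

With $\alpha = 0$ the entire generation map (floor partition, killing,
renormalization) is deterministic. `simulate_ensemble()` detects this and
runs a single trajectory with zero reported spread — exactly what an
infinite ensemble would return.

## Initial populations

Starter cultures are grown under antibiotic selection, so no viable cell
is plasmid-free. Three initializers implement this: a zero-truncated
Poisson at the measured mean copy number $N_0$ (the default; the spread
of copy numbers tracks the mean, as observed for plasmid foci in single
cells), a zero-truncated discretized Gaussian with independent $\sigma$
(nearly identical to the Poisson for $N_0 > 10$ with $\sigma^2 = N_0$,
which the tests verify in total-variation distance), and a single-class
start for pedagogical runs. The truncated distributions are renormalized;
since all observables are scale-free this choice is immaterial to
results, and it keeps weights summing to one. Support is truncated where
the untruncated upper-tail mass falls below `support_eps` ($10^{-12}$ by
default); the tests confirm the first two moments move by less than
$10^{-6}$ when the cutoff shrinks a hundredfold.

## Numerical controls

Two controls bound the state size on long runs. Classes whose relative
weight falls below `prune_eps` ($10^{-12}$) are dropped and the weights
renormalized; copy numbers above `n_cap` ($10^4$) are merged into the
boundary class. Under $\delta < 0.5$ the upper support grows
geometrically, so some control is mandatory. Both sinks remove a tiny
amount of plasmid units: with defaults, the exactly-conserved quantity
$PCN(g)$ under $\alpha = 0, \beta = 1$ drifts by about $10^{-3}$ absolute
over 80 generations at $\delta = 0.42$ — negligible against the
unit-scale effects of interest, but visible to a strict equality test.
The conservation tests therefore disable both controls
(`prune_eps = 0`, large `n_cap`), where conservation holds to machine
precision; the stability series itself moves by less than $2 \times
10^{-8}$ between `prune_eps` $10^{-10}$ and $10^{-14}$ at the partition
operating point $\delta = 0.49$.

## Fitting stability curves

Observed curves are (generation, fraction-retaining) tables. Two
single-parameter scenarios are fit by grid search with a sum-of-squared-
errors objective, the simulated series linearly interpolated at the
observed generations:

* `fit_alpha()` — replication-failure scenario: $\delta$ fixed at 0.5,
  $\beta$ fixed (or a joint $\beta$ grid), grid over $\alpha$ (default
  0–2, step 0.05, ties to the smaller value).
* `fit_delta()` — partition scenario: $\alpha = 0$, grid over $\delta$
  (default 0.30–0.50, step 0.01, ties towards 0.5).

Grid search rather than a gradient method because the floors in
replication and partition make the objective piecewise-flat and, for
$\alpha > 0$, noisy; all grid points share one master seed so the
simulation noise is common across candidates and the surface is
comparable point to point. An optional refinement halves the grid step
around the minimizer. The goodness-of-fit criterion is a design choice —
plain SSE, undocumented alternatives having no obvious advantage for
10–20-point curves. $N_0$ is an explicit input (it is a measured
quantity, not a fit parameter), and curves may be read from CSV in
fraction or percent dialects.

Recovery behaviour, verified in the test suite on synthetic assays with
100-colony binomial scoring noise: over 20 curves each, the median
relative error of $\hat\alpha$ stays under the 15% relative uncertainty
the underlying study quotes for this parameter, and the median absolute
error of $\hat\delta$ under 0.02, its reported precision. The suite runs
these at reduced problem sizes chosen to keep the whole test run short —
grids bracketing the truth (α: 0.5–1.1 step 0.1 with 10-replicate
ensembles, horizon 160; δ: 0.36–0.48 step 0.01, horizon 140 — recall the
δ scenario is deterministic) — the estimator itself is identical at any
grid.

## The synthetic stability assay

`gen_stability_dataset()` emulates the colony-scoring assay behind
published stability curves: the true $S(g)$ comes from an ensemble run at
the chosen parameters, and each sampled timepoint reports
$\mathrm{Bin}(C, S(g))/C$ with $C$ colonies scored (default 100 — a
typical plating effort; the number is a convention of this package, not a
measured value). What it deliberately does not emulate: antibiotic
carry-over, plating efficiency differences between plasmid-bearing and
plasmid-free cells, growth-rate differences (the model ignores these
throughout — the measured doubling times of the motivating system are
identical within error), and between-day batch effects. Passing recovery
tests on these fixtures therefore demonstrates estimator correctness
under the model's own assumptions, not robustness to every feature of
real assay data.

## Densitometry of multimer ladders

Multimer formation is quantified from calibrated gel lane profiles
(intensity versus DNA size). A profile is modeled as a logistic
background step plus one asymmetric peak per rank $k$, centred at
$k x_0$ with $x_0$ the monomer size:

$$I(x) = \frac{T}{1 + e^{-(x - x_T)/c}} + \sum_{k=1}^{k_{max}}
\frac{N_k}{1 + \left(\frac{x - k x_0}{\sigma_k/2}\right)^2}
\cdot \frac{1}{1 + e^{-(x - k x_0)/b}}$$

a Lorentzian of half-width $\sigma_k/2$ times a logistic skew factor.
The printed source of this form typesets the two exponential divisors
ambiguously; they are implemented as the standard logistic scales shown
above, in a single code path (`peak_term()`) so an alternative reading
would be a one-line change. $\sigma_k/2$ as half-width (rather than
full-width) is likewise an explicit reading, flagged here. Peak centres
are fixed at $k x_0$ — the ladder geometry is known — leaving amplitudes,
widths, one shared asymmetry scale and three background parameters free;
`fit_multimer_profile()` estimates them by Levenberg–Marquardt least
squares with positivity kept by log-scale parameterization of widths.
Noise-free profiles are recovered to well under 1% in amplitude; at 2%
additive Gaussian noise the median amplitude error over 20 seeds stays
under 5%.

Two normalizations of the rank distribution $\rho_k$ are offered, because
the correct one is genuinely ambiguous: band intensity is proportional to
DNA mass, so a $k$-mer carries $k$ units of signal per molecule.
`weighting = "intensity"` uses integrated areas as-is (the distribution
of plasmid *units* across ranks); `weighting = "molecule"` divides each
area by $k$ first (the distribution of *molecules*). The rank correction
$PCN_{molecules} = \mathrm{ddPCR} / \bar\rho$ with $\bar\rho = \sum_k k
\rho_k$ is dimensionally consistent with the molecule weighting; both are
exposed and neither is claimed to reproduce any published figure's
convention. The default is "intensity", matching the reading of peak
amplitude as relative abundance.

## Operating points reproduced by the acceptance checks

Three published behaviours serve as end-to-end anchors, recomputed from
scratch by `scripts/acceptance.R` and the acceptance tests:

* the failure-law percentages at $\alpha = 1.20$ (25/11/5/2% for 1–4
  failures) and $\alpha = 0.51$ (86% failure-free);
* the worked three-cell census example advancing to exactly
  $\{0\!:\!2,\ 1\!:\!3,\ 2\!:\!1\}$;
* the long-run copy-number drift under uneven partition: from a Poisson
  start at $N_0 = 14$ with $\delta = 0.49$, $\beta = 0.95$, the
  population mean rises to ≈22 units at generation 250 and ≈32 at 600 —
  killing of plasmid-free segregants plus biased splitting steadily
  enriches high-copy lineages.

The Table-2-style fits (α ≈ 1.20 and δ ≈ 0.40 for the unstable
cer-less/RM-less plasmid in a wild-type host) are checked against
synthetic emulations of that stability assay generated by this package at
those operating points, since the original observed curves ship as a
separate supplement; the tests assert recovery within the study's own
uncertainties (15% relative for α, ±0.02 for δ).

## Known limitations

Class-level draws underestimate within-class variance relative to a
per-cell model; no growth-rate difference between plasmid-bearing and
plasmid-free cells; no explicit multimer species in the simulator
(multimerization enters only through $\delta$'s interpretation); no
continuous-time dynamics; no likelihood-based inference or bootstrap
intervals (the grid objective is an SSE, reported per grid point so the
flatness of the minimum is at least visible); gel image processing —
lane extraction and mobility-to-size calibration — is upstream of this
package (`assign_ladder()` helps map band positions to ranks once sizes
are calibrated).
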