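---
title: "Models and methods behind replidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind replidyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replidyn)
```

replidyn implements a complete chain for studying temporal programs of
genome replication and their evolution: population replication profiles from
windowed sequencing counts, origin calling, stochastic firing-kinetics
fitting, cross-species timing comparison, orthologous-origin families, and
gain/loss history on a species phylogeny. This vignette records the models,
the tunable parameters, and the places where the design was genuinely open —
and what was decided there and why.

## The stochastic kinetics model

A `kinetics_model` holds chromosome lengths, origin positions
$o_i$ (bp), per-origin firing rates $\lambda_i$ (min$^{-1}$), and one
genome-wide fork speed $v$ (bp/min). Firing is memoryless: in each cell,
origin $i$ fires at $T_i \sim \mathrm{Exp}(\lambda_i)$, independently.
Forks move bidirectionally at constant $v$, so the locus $x$ is replicated at

$$t(x) = \min_i \left( T_i + |x - o_i| / v \right),$$

and origin $i$ fires *actively* iff $T_i$ precedes every incoming fork,
$T_i < \min_{j \neq i}(T_j + |o_i - o_j|/v)$. Averaging over cells gives the
closed-form expected copy number

$$c(x, t) = 2 - \prod_i \exp\!\big(-\lambda_i \, (t - |x - o_i|/v)_+\big),$$

because the locus is still unreplicated only if no origin fired early enough
for its fork to have arrived. `copy_number_surface()` evaluates this
analytically or by Monte-Carlo cell simulation (exact per-cell interval
unions); `analytic_trep()` inverts $c(x,t) = 1.5$ exactly, exploiting that
$\sum_i \lambda_i (t - a_i)_+$ is piecewise linear in $t$. An origin's
*efficiency* is the fraction of simulated cells in which it fires actively
(`simulate_efficiencies()`, default $10^4$ cells, so the binomial standard
error is at most 0.005); its *characteristic time* is $1/\lambda_i$, which
is interference-free by construction. Assumptions worth keeping in mind: no
re-licensing or repeated firing, no fork stalling, a single global fork
speed, and a time-homogeneous firing probability.

## Synthetic sequencing

`sample_sequencing()` emulates the windowed read counts such experiments
produce: 0-based half-open 500 bp windows, counts Poisson-distributed with
mean `depth` × copy number (or exactly equal to it with `noise = "none"`),
one track per S-phase timepoint plus G1 (copy 1) and G2 (copy 2) references,
and an Expo/Stat pair for marker frequency analysis. The Expo sample mixes
cell ages $a \in [0,1]$ of an asynchronous exponential culture with density
$2\ln 2 \cdot 2^{-a}$ — younger cells are over-represented because each
division creates two — mapped linearly onto the S-phase window; the
stationary sample is non-replicating. The sample sheet carries each
timepoint's bulk DNA content as the genome-length-weighted *mean* copy
number, which is what bulk flow cytometry estimates. The generator does not
emulate read-level artifacts (mappability, GC bias, duplicated regions,
copy-number variants) or biological covariates such as rDNA loci; passing
tests on it therefore demonstrates correctness of the algorithms under the
model's own assumptions, not robustness to every artifact of real libraries.

Study-scale defaults used throughout the tests and the acceptance script
were fixed once: timepoints every 5 minutes from 2.5 to 67.5 (an S phase of
about an hour, sampled finely enough that the copy-number transition at a
strong origin spans several samples), and 2000 expected reads per 500 bp
window, i.e. roughly 40 M reads per 10 Mb genome sample — deep but routine
for modern sequencers.

## Trep and MFA profiles

`compute_trep()` follows the classical construction: per-window ratio of
S-phase counts to a G1 reference (a G2 reference is halved first; windows
with zero reference are dropped), a per-timepoint multiplicative adjustment
so the genome-wide centre of the ratios equals that timepoint's measured
bulk DNA content, a per-window linear rescale of the ratio trajectory to
$[1, 2]$, and the Trep defined as the linearly interpolated time of the
first upward crossing of 1.5. Loess smoothing (degree 2) is applied along
each chromosome with a span given in bp (default 30 kb, which preserves
peaks at the ~47 kb origin spacings typical of these genomes) and converted
to a per-chromosome fraction; missing windows are excluded from the fit and
bridged by prediction but never extrapolated beyond the observed range.

Two points were genuinely open and deserve their rationale:

* **Adjustment centre.** The literature describes matching the *median*
  ratio to the DNA content. Bulk DNA content is a population mean, and in
  early S the genome median lags the mean (only origin-proximal loci have
  replicated), so median-matching systematically inflates early-timepoint
  ratios; the inflated values then become each window's trajectory maximum,
  and the per-window $[1,2]$ rescale pins the 1.5 crossing to a constant in
  whole neighbourhoods of strong origins — flattening exactly the valleys
  the origin caller needs. `center = "mean"` (the default) is the consistent
  estimator when the supplied content is a mean; `center = "median"` keeps
  the robust variant for data where outlier windows dominate.
* **Rescale anchoring.** "Re-scaled between 1 and 2" can be read per window
  or per timepoint. The default anchors each window's own trajectory
  (guaranteeing a 1.5 crossing for monotone trajectories); the
  `rescale = "timepoint"` switch retains the alternative, which leaves the
  centred ratios on the copy-number scale.

Windows whose trajectory sits at 2 throughout are flagged
`early_saturated` and assigned the first timepoint; windows that never cross
1.5 are flagged and excluded from smoothing. `compute_mfa()` removes
windows whose counts are interquartile-range outliers (outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, per track), takes
the Expo/Stat ratio, and smooths identically. `normalize_timing()` maps any
profile linearly onto $[0,1]$ genome-wide, preserving ranks exactly.

## Origin calling

Origins are curvature features: local minima of the second derivative of a
working signal (MFA as-is; Trep negated so initiation sites have the same
curvature sign in both), located where the third derivative crosses zero
from negative to positive, with linear interpolation of the crossing.
Derivatives are difference quotients $(y_i - y_{i-1})/(x_i - x_{i-1})$
positioned at interval *midpoints*: positioning at the right endpoint would
translate every call by about 1.5 grid steps after three differentiations.

Three numerical choices matter in practice and were set from synthetic
experiments with known truth:

* **Derivative stride** (`deriv_step`, default 16 windows = 8 kb).
  Differencing the smoothed curve at the 500 bp grid amplifies residual
  grid-scale loess wiggles until they bury the curvature of true origins;
  origin features live at the 20–50 kb scale and survive coarse sampling
  untouched.
* **Candidate merging** (`merge_bp`, default 10 kb). Noise can split one
  broad curvature dip into several nearby zero crossings; the strongest
  candidate in each neighbourhood is kept.
* **Prominence threshold** (`min_prominence`, default half the chromosome's
  median $|d_2|$, plus an always-on floor of 2% of the chromosome's largest
  amplitude). At realistic origin densities — one origin per ~47 kb — the
  profile has no quiet baseline and the median $|d_2|$ is itself
  signal-scale, so a multiple *above* the median rejects genuine origins;
  conversely, on sparse chromosomes the median is nearly zero and the
  fraction-of-max floor removes smoothing and edge artifacts that sit orders
  of magnitude below any real dip.

`co_detect()` implements the stringency rule that a call requires support
from both profiles: greedy nearest-pair matching of Trep and MFA candidates
(smallest coordinate difference first, each candidate used once, ties broken
by position — which makes the operation symmetric in its arguments) within
`max_separation` (default 10 kb, generous against the ~1–5 kb inter-method
coordinate differences observed on synthetic data yet far below inter-origin
spacing). The consensus coordinate is the mean of the two source
coordinates; the summary reports the median and mean absolute coordinate
difference as a precision diagnostic. Note that the three-fold derivative
chain consumes roughly three coarse grid steps (~24 kb) at each chromosome
end, so calls within ~25 kb of a telomere are unreliable — mirroring the
practice of excluding subtelomeric origins from comparative analyses.

## Kinetics fitting

`fit_kinetics()` holds origin positions fixed and minimizes the mean squared
difference between the observed copy-number surface and the analytic model
surface over all windows and timepoints. Rates are initialized from the
early-timepoint slope at each origin's window ($c \approx 1 + \lambda t$
for small $t$; floored at $10^{-4}$/min), fork speed from a neutral guess.
The optimizer is deliberately simple and monotone: coordinate-wise proposals
with per-parameter step sizes that double on an accepted improvement and
halve on rejection, projection to $\lambda_i \ge 0$ and $v > 0$, stopping
when a sweep's relative improvement falls below $10^{-6}$ *and* all steps
have shrunk to numerical irrelevance (at most $10^4$ sweeps). The objective
trace is non-increasing by construction. On noiseless five-origin data the
truth is recovered to numerical precision; with Poisson noise at 100 reads
per window, rates come back within a few percent. Fork speed is a single
global constant — per-chromosome speeds were not implemented because the
data simulated here (and the biology assumed by the model) give no
identifiable signal for them.

## Cross-species comparison

`project_timing()` samples each species' profile at ortholog gene midpoints
(orientation-invariant) and pairs the values; `conservation_rho()` is the
Spearman correlation with mid-ranks for ties. The `offset_null()` control
re-computes the correlation after circularly shifting one genome's gene
coordinates by a uniform random offset, independently per chromosome —
circular shifts preserve each genome's timing multiset exactly while
destroying the positional correspondence; the offset is redrawn `n_offsets`
times in each direction (A shifted, then B). `local_rho()` computes
Spearman correlations in windows of five consecutive ortholog pairs placed
at a chosen gene offset inward from each synteny-block edge, subsampling the
deeper classes to the size of the smallest for a matched comparison.
`ortholog_origin_timing_diff()` reports |Δ normalized timing| between the
members of each origin family shared by two species (per-species means when
a family has several members in one genome).

## Origin families and the randomization null

`project_origins()` carries each origin across genomes through its two
flanking coding genes (nearest gene midpoints on each side): both flanks
must have orthologs in the same synteny block on the same target chromosome
— the conservative both-flank rule — and the projection lands at the
midpoint of the interval between the two orthologs. `pair_conserved()`
associates each projection with its nearest resident origin and emits a pair
only when projected and resident origins are at most `delta` *syntenic*
(ortholog-bearing) genes apart, in both directions (A→B and B→A
reciprocity; non-syntenic genes do not count, since the unit of the rule is
syntenic genes). `build_families()` takes the union of pairs over all
species pairs and returns the connected components (via igraph), with
singleton families for unpaired origins; components may legitimately hold
more than one origin of a species, and are reported as such rather than
split.

The null model (`randomize_origins()`) draws origin sets under three exact
constraints: (1) the inter-origin spacing multiset per chromosome equals
the observed one (spacings are permuted, never altered); (2) the first
origin lies in $(0, 2 f)$ where $f$ is the observed first position; (3) the
intragenic/intergenic composition matches the observed counts. Because any
per-origin "nudge" toward a gene or intergene would break constraint (1),
the sampler instead exploits the one remaining continuous degree of freedom:
for a given spacing permutation the whole chain is a rigid function of the
first position $x_0$, origin classifications are piecewise-constant in
$x_0$, and the admissible interval can be scanned exactly for the
sub-regions achieving the intragenic quota, from which $x_0$ is drawn
uniformly. Fresh permutations are tried (up to `max_attempts`) until the
quota is met exactly; the closest achievable composition is kept and flagged
otherwise. `calibrate_delta()` evaluates candidate thresholds 0–6 on real
versus randomized repertoires (conserved-pair excess, one-member-per-species
families, oversized families, multi-member proportion) and reports the full
table with a recommended delta rather than a silent choice.

## Gain/loss history

`infer_gain_loss()` reconstructs each family's history on a rooted binary
tree by weighted small parsimony (Sankoff dynamic programming) with gain
cost 2 and loss cost 1; presence at the root is charged one gain, since a
family must be created somewhere. All minimum-cost labelings are enumerated
by backtracking and per-branch event counts are averaged over ties, which
avoids committing to an arbitrary single labeling. More than one gain per
family is tolerated. Branches on which a loss cannot be distinguished from
a gain on the sister branch — the outgroup's terminal branch and its sister
internal branch — can be excluded by name; their events are tallied apart
from the headline totals. Family age (`assign_age()`) is the cumulated
branch length from the focal ancestor (by default the ingroup's most recent
common ancestor when an outgroup is excluded) to the *start* of the
origination branch; ancestral families have age 0, tied placements are
averaged and flagged. `classify_recent_events()` compares sister species:
families present in both are conserved; one-sided families are split into
terminal-branch gains versus losses according to the inferred history, and
events whose evidence origin was detected by only one profiling method
(Trep-only or MFA-only) are removed as dubious, together with the implied
counterpart event.

A calibration note from the end-to-end simulations: per-branch event totals
recovered from synthetic histories track the truth closely on all branches
*except* the two root-adjacent ones, where the gain/loss asymmetry of
parsimony (a stem gain at cost 2 beats root presence plus a loss at cost 3)
systematically reassigns events — precisely the ambiguity the excluded
"indistinguishable" branch pair formalizes.

## Property statistics

`annotate_origins()` computes distances to the centromere (missing, not
zero, when a chromosome has no annotation), the nearest telomere (chromosome
ends), the nearest rearrangement breakpoint, and the nearest other origin
with its category and efficiency; lost origins are expected at their
projected position in the extant genome, carrying their sister-genome
ortholog's functional values. `nearest_origin_analysis()` contrasts the
observed category composition of nearest neighbours with the global category
frequencies (the random-sampling expectation). `chisq_two_sample()` is the
classical binned two-sample chi-square,
$\sum_b (K_X x_b - K_Y y_b)^2/(x_b+y_b)$ with $K_X = \sqrt{N_Y/N_X}$,
$K_Y = \sqrt{N_X/N_Y}$ and $\mathrm{bins}-1$ degrees of freedom, on
equal-count quantile bins of the pooled values merged until every bin holds
at least five observations; its type-I error is verified by simulation to
sit at the nominal 5%. `efficiency_age_trend()` groups families by
origination branch and regresses group median efficiencies on group age.
`spacing_regularity()` scores the coefficient of variation of pooled
inter-origin spacings against a uniform-placement null with the same
per-chromosome counts (the CV is scale-free, so the z-score is invariant
under coordinate rescaling); exactly regular spacing gives CV 0 and a
strongly negative z, and under uniform placement the empirical p-value is
itself calibrated uniform.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, and identical seeds give
identical output. The test-suite and acceptance-script simulations use
problem sizes chosen to make the statistical assertions sharp while staying
light: $10^4$–$10^5$ cells for Monte-Carlo/efficiency checks, 500 kb–1 Mb
genomes with 5–20 origins for profile and calling checks, three-species
repertoires of ~30 origins for the family oracle, a ten-leaf tree (all 1023
phyletic patterns against all 512 internal labelings) for the parsimony
oracle, and twenty replicate eight-species histories for end-to-end branch
recovery.

## Known limitations

* The kinetics model is the constant-rate special case; time-varying firing
  (increasing activation probability through S), licensing limits and fork
  stalls are out of scope.
* Calling within ~25 kb of chromosome ends is unreliable (derivative
  support), consistent with excluding subtelomeric origins downstream.
* Origin families rely purely on positional synteny; sequence-level origin
  alignment is not attempted, and ortholog/synteny inference itself is an
  input, not a product, of the package.
* Parsimony counts are a proxy for a probabilistic birth–death
  reconstruction; rate estimation across branches is not attempted, and the
  output metadata flags the counts as parsimony-based.
* The weighting of the exponential-culture age distribution in the MFA
  generator is standard asynchronous-culture theory, not a fitted quantity.
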