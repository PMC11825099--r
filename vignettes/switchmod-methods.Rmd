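---
title: "Two-state promoter models and the analysis of bimodal single-cell expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state promoter models and the analysis of bimodal single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`switchmod` studies genes whose single-cell expression distributions are
bimodal: an isogenic population in which some cells express at a low rate and
others at a high rate.  The core object is a reduced stochastic model of
transcription and translation in which the promoter switches between two
transcription states, L (low) and H (high).  In each state, transcription
initiation is a cycle of two rate-limiting steps: an RNAP holoenzyme binds the
free promoter and finds the transcription start site (pseudo-first-order rate
`k_bind_X * n_holo`), and the bound complex then escapes the promoter,
releasing one RNA (`k_esc_X`).  While occupied, the promoter accepts no new
binding.  The long-run transcription rate of a locked state is therefore the
inverse mean cycle time,

    r_X = 1 / ( 1/(k_bind_X * n_holo) + 1/k_esc_X ),

and the locked-state stationary means are exact: `mean RNA = r_X / kd_rna`,
`mean Protein = r_X * k_tr / (kd_rna * kd_prot)`.  Translation (`k_tr` per
RNA) and first-order RNA/protein decay (`kd_rna`, `kd_prot`, covering both
degradation and dilution by growth) are independent of the promoter state.
State switching (`k_H`: L to H; `k_L`: H to L — the subscript names the
destination) is allowed only while the promoter is free; an engaged RNAP
plausibly blocks the change.  The alternative (switching regardless of
occupancy) is available via `build_reduced_model(..., switch_occupied =
TRUE)`.

Holoenzymes are treated as a fixed concentration parameter, not a consumed
species: the pool (`n_rnap70`, `n_rnap38`) is large and shared genome-wide,
so a single promoter does not deplete it measurably.

Bimodality arises when the switching timescale is slow compared with the
protein relaxation time `1/kd_prot`: each cell then spends long stretches
fluctuating around one of the two locked-state means, and a population
snapshot shows two modes.

## Reference parameter values

All units are minutes.  The shipped exponential-phase reference is:

| parameter  | value            | meaning |
|------------|------------------|---------|
| `k_bind_H` | 1e-3 (x 500 holoenzymes = 0.5/min) | H-state binding |
| `k_esc_H`  | 1                | H-state escape |
| `k_bind_L` | 1e-4 (0.05/min)  | L-state binding (H/10) |
| `k_esc_L`  | 0.1              | L-state escape (H/10) |
| `k_H`, `k_L` | 0.001          | state switching |
| `k_tr`     | 1                | translation per RNA |
| `kd_rna`   | 0.5              | 2-min mean RNA lifetime |
| `kd_prot`  | 0.02             | 50-min protein lifetime |

These satisfy the regime that defines the model: both L-state initiation
steps one order of magnitude below the H-state ones; switching slower than
every other rate; protein decay on the tens-of-minutes scale typical of
dilution-dominated bacterial proteins.  The locked-state protein means are
3.3 (L) and 33 (H) copies, and the stationary distribution is bimodal with
the taller peak in the first mode.  Two deliberate choices deserve comment:

* **Burst size.** `k_tr / kd_rna = 2` keeps the protein Fano factor near 3,
  so the two modes are well separated at the reference yet merge (into a
  single mode piled near zero) when translation or the decay rates are
  pushed to their range boundaries — the qualitative collapse pattern this
  model family is meant to exhibit.  Larger burst sizes either destroy the
  reference bimodality or leave the boundary distributions bimodal.
* **Switching at 0.001/min.** The promoter residence time (1000 min) must
  stay well above the protein relaxation time under *every* condition
  studied, including the stationary growth phase where `kd_prot` falls to
  0.0044/min (relaxation 230 min).  Faster switching (e.g. 0.005/min) blurs
  the two states there: the exact master-equation solution becomes unimodal.

## The stationary growth-phase condition

The stationary-phase target is derived from the exponential reference by
documented physiological changes: mean RNA lifetime rises to 7.8 min
(`kd_rna = 1/7.8`); translation activity falls 40-fold; the dilution
component of protein decay (taken as `ln 2 / 40` for a 40-min doubling time)
drops by 91.5% as division stops, while the degradation remainder rises by
8%; and half of the holoenzyme pool shifts from sigma70 to sigma38
(`sigma38_fraction = 0.5`, a configuration value).  Intermediate conditions
interpolate every rate geometrically (`rate(f) = rate_exp^(1-f) *
rate_stat^f`) — rates vary multiplicatively over orders of magnitude and must
stay positive — while holoenzyme counts interpolate linearly and round to
integers.

# Simulation and oracles

Trajectories are sampled with the exact direct-method stochastic simulation
algorithm (no tau-leaping: copy numbers are small and exactness anchors the
test suite).  The inner loop is C++ with a counter-based PCG32 generator:
cell `i` of an ensemble uses a stream derived from `(master seed, i)`, so
ensembles are reproducible and independent of evaluation order.

`sample_snapshot()` emulates a flow-cytometry snapshot of an asynchronous
culture: by default each cell starts with a free promoter whose state is
drawn from the stationary switching distribution (`pi_H = k_H/(k_H + k_L)`),
zero RNA and protein, and runs for 20 protein lifetimes.  Starting every cell
in L instead would bias the mode weights whenever the promoter relaxation
time `1/(k_H + k_L)` is not far below the snapshot time.  `simulate_ssa()`
keeps the deterministic L-free start for single-trajectory work.

Two independent oracles guard the simulator.  Closed-form locked-state means
(above) check one-state models to Monte-Carlo accuracy.  The truncated
chemical master equation (`cme_stationary()`) solves the stationary law
exactly on a finite box: the sparse generator is built with promoter
configuration as the fastest index so the system is banded, one balance
equation is replaced by normalisation, and the box grows by 1.5x per side
until the boundary mass is below tolerance (default 1e-6; pass a tighter
value when sub-ppm mean accuracy is needed, since truncation biases the mean
by roughly the boundary mass times the box width).  Agreement is measured as
the total variation distance between the empirical snapshot pmf and the CME
protein marginal; at n = 10,000 cells the sampling floor of this statistic
is about 0.02–0.03 for distributions on a few hundred support points, which
is why the equivalence checks use a 0.05 bound.

# Classifying modality

`classify_modality()` is the package's fit-like entry point.  It combines two
criteria; the verdict is bimodal if either fires.

**Analysis scale.** Cytometry intensities are right-skewed and positive and
are analysed on log10; simulated protein counts are analysed raw.  This
choice is a `kind` attribute carried by the data containers.

**Kernel density and peaks.** A Gaussian KDE on a 512-point grid spanning the
data range (Silverman bandwidth), renormalised to integrate to 1 on the grid
so a mode piled against zero keeps its weight.  For integer count data the
bandwidth is floored at 0.75 so the unit lattice cannot masquerade as modes.
Peak detection keeps local maxima (grid edges included — a boundary pile is a
mode) with topographic prominence at least 5% of the maximum density and
mutual separation at least 5% of the range; the global mode always
qualifies.  Two retained peaks make the criterion true.

**Mixture/BIC.** One- and two-component Gaussian mixtures are fitted by EM
(C++ inner loop, 10 deterministic restarts from data-quantile pairs chosen to
also straddle minority components; a private linear-congruential stream keeps
the global RNG untouched and the fits affine-equivariant).  The criterion is
true when all of the following hold, each exposed in configuration:

* `BIC2 <= BIC1 - 10` (strong-evidence convention, BIC on the
  `-2 logLik + p log n` scale);
* minor component weight >= 0.05;
* `|mu2 - mu1| >= 2 min(sd1, sd2)`;
* Ashman separation `D = sqrt(2)|mu2 - mu1| / sqrt(sd1^2 + sd2^2) >= 2.2`.

The Ashman guard is this package's calibration for skewed and discrete data:
two Gaussian components can win the BIC merely by absorbing skewness, while
`D >= 2` is the textbook minimum for a two-Gaussian mixture to show two
modes.  The 2.2 default was set by checking candidate parameter sets against
the exact CME pmf: sets whose true stationary law is unimodal (merged modes,
or a monotone zero-piled pmf) fit with `D` close to 2.0, genuinely bimodal
sets fit well above it.  For integer counts the component SDs are floored at
0.5 (half the lattice) so a point mass on one count value cannot pose as an
infinitely well-separated component.

On 100 seeded datasets of n = 10,000, the classifier's false-positive rate on
single Gaussians and its power on 4-SD-separated equal mixtures are exercised
by the test suite at the 5%/95% levels.

**Weight of the high mode.** `high_mode_weight()` reports, when the sample is
supplied, the fraction of cells above the KDE antimode between the two peaks
rather than the raw EM weight: a two-Gaussian fit on right-skewed components
carries a small (~0.04) systematic weight bias that the antimode cut does
not, which matters when comparing against the stationary promoter occupancy
`pi_H` in the slow-switching limit.

# Shape statistics

For a bimodal call with peaks `pk1 < pk2` of heights `PDF1`, `PDF2`:

* `d = (pk2 - pk1) / (max(v) - min(v))` — relative peak distance, normalised
  by the empirical range of the merged sample (not the density grid span);
* `h = (PDF1 - PDF2) / max(PDF)` — relative height difference.  `PDF1` is
  the height at the lower peak, so `h > 0` means the low mode is taller.
  The opposite sign convention appears in some descriptions of this
  statistic; the convention used is recorded in the output
  (`h_convention`);
* `o = n_overlap / n_total`, with `n_overlap` the number of observations
  strictly between the peak positions (values exactly at a peak are not
  counted).

All three are undefined for unimodal verdicts and error if requested.  They
are invariant under positive affine rescaling of continuous data (the KDE
grid, Silverman bandwidth and quantile-based EM initialisation are all
scale-covariant); the integer-lattice bandwidth and SD floors intentionally
break this for discrete counts, where rescaling has no physical meaning.

# Perturbation experiments

`run_sweep()` multiplies one rate (or a coupled set) across a log-spaced grid
(default 0.1x–10x, seven points), rebuilds the model, snapshots 5,000 cells
per point at 20 protein lifetimes, classifies, and computes shape parameters.
At the shipped defaults the characteristic collapse pattern is: lowering
`k_bind_H`, `k_esc_H` or `k_tr` to 0.1x, or raising `kd_rna` or `kd_prot` to
10x, flips the verdict to unimodal, and the surviving mode sits nearer the
L-state closed-form mean than the H-state one.  One caveat the exact CME
makes visible: with switching gated to the free promoter, lowering `k_esc_L`
10x also destroys bimodality — the promoter must escape before it can leave
L, so slow L-escape traps the state.  Ungated switching removes this
exception.

`run_extended_L_sweep()` raises both L-state steps together toward the
H-state values; at the endpoint the two states coincide and the distribution
is unimodal around the H-locked mean.  `run_stationary_transition()` scans
the growth-phase interpolation; at the shipped defaults bimodality survives
the whole path while both mode means fall several-fold.
`run_unimodal_shift()` starts from the two-state stationary ensemble,
switches the reactions to a one-state variant (L-rate, averaged-rate, or
H-rate; the averaged variant rescales both H steps by a common factor so the
effective rate is `(r_L + r_H)/2`, preserving two-step occupancy noise), and
records when the verdict first becomes (and stays) unimodal.  With
`k_H = k_L` only the averaged variant preserves the parent's stationary mean.

# Synthetic cytometry data

`generate_population()` draws flow-cytometry-like tables: the intensity
channel is a log10-normal mixture times a multiplicative log-normal
extrinsic-noise factor, plus an additive log-normal autofluorescence floor
present in every cell (the wild-type background); replicate-level mean
shifts emulate day-to-day variation across the three biological replicates
that are merged before fitting; SSC-H/FSC-H/Width are unimodal log-normals
tied to log-intensity through a Gaussian copula at a requested correlation.
Log-normal components were chosen because real cytometry intensities are
positive and right-skewed.  Seven named fixtures (`cytometry_fixtures()`)
span distant/close and symmetric/asymmetric mode arrangements; they are
synthetic constructions and claim no correspondence to any real gene's
numbers.  What these data do not emulate: instrument compensation and gating
artefacts, cell-cycle structure, or the detailed shapes of real empirical
distributions — so passing tests show the analysis stages work on data with
this statistical structure, not that they reproduce any particular
measured gene.

`model_to_intensity()` bridges simulation and analysis:
`intensity = autofluorescence + gain x count x lognormal extrinsic factor`.
The reaction model alone has far less cell-to-cell variability than measured
distributions, which also reflect shared-component differences and
measurement noise; the overlay adds exactly those terms.

# Calibration between fluorophore scales

To compare a reporter measured on one fluorophore's scale with the same
construct on another's, four anchors are matched: lowest cell signal, weak-
mode mean, high-mode mean, highest cell signal.  Mode means are taken from
the 2-component mixture fit on the analysis scale and back-transformed
(empirical sub-population means would serve similarly; the mixture means are
less sensitive to the cut point).  The map is the piecewise-linear
interpolant through the four anchor pairs, continued linearly beyond the
span with the terminal segments' slopes — the only monotone choice without
data out there.  Strict monotonicity preserves order statistics, and in
practice modality, under the map.  `linear_fit_stats()` provides the
ordinary least-squares summary (slope, R², slope t-test, 95% bounds) used
when regressing paired per-condition summary levels of two libraries.

# Hysteresis

`track_path()` follows `d` and `o` (not `h`, which depends on the sampled
cell fraction and hence on procedure) along an ordered sequence of
conditions, leaving gaps where the verdict is not bimodal.  `loop_gap()`
quantifies loop non-closure as the mean Euclidean distance in the `(d, o)`
plane over direction-matched conditions — a deliberate operationalisation of
what is otherwise a visual judgement, and exposed as such.  Whether a gap is
meaningful is decided against a resampling null: gaps between pairs of
independent *equilibrated* cycles at the same conditions (`loop_gap_null()`).

`run_ramp_cycle()` provides the simulated experiment: a rate is ramped up
and back down while the cell ensemble is carried from step to step, dwelling
a fixed time after each change.  The default ramp lowers `kd_prot`
(1x, 0.46x, 0.215x, 0.1x) because the decay rates have the strongest
stationary effect on `d`; the slowest protein relaxation along it is about
500 min.  A dwell well above that (default 2500 min) equilibrates each step
and the loop closes to within the null; a dwell near 100 min leaves the
ensemble lagging its conditions and the forward and backward paths separate.
The turning-point snapshot is shared by both directions (the cycle visits it
once), which makes the gap estimate slightly conservative.  Ensemble sizes
of ~12,000 cells keep the sampling null below the lag signal.

# Positive-feedback variant

`build_feedback_model()` implements the alternative bimodality source: the
expressed protein itself activates the promoter (activation propensity
`k_act x Protein`, the protein acting catalytically rather than being
sequestered), deactivation restores the basal configuration, and each
configuration transcribes through the same two-step scheme (basal = L rates,
active = H rates).  At the shipped `feedback_params()` defaults the exact
CME stationary pmf is bimodal (modes near 1 and 29 protein copies), and
classifier verdicts on simulated snapshots agree.

# Problem sizes and numerical choices

The shipped defaults keep every experiment at desk scale: snapshots use
5,000–10,000 cells; oracle comparisons n = 10,000 against CME boxes of a few
thousand states; classifier calibration 100 seeded datasets of n = 10,000;
sweeps 5,000 cells per grid point; hysteresis cycles 12,000 cells with a
6–8 pair null.  Degenerate inputs are errors, not guesses: constant samples,
fewer than 50 values, non-increasing anchors, unimodal calls passed to
`shape_params()` or `compute_anchors()`.  EM non-convergence after all
restarts sets the BIC criterion false with a warning rather than failing the
classification.  Ties in EM restarts resolve by log-likelihood; equal-mean
initialisations fall back to the interquartile pair.

# Known limitations

* The reduced model omits the mechanistic detail of supercoiling locking,
  reversible initiation steps and non-functional protein production;
  perturbations act only through rate-constant changes.
* Cell division is folded into first-order dilution; there is no lineage or
  partitioning noise.
* The classifier's discrete-data calibration (bandwidth and SD floors,
  Ashman guard) is tuned for unit-lattice counts in the tens-to-hundreds
  range; counts in the thousands behave as continuous data.
* The hysteresis machinery detects lagging ensembles; it cannot by itself
  attribute a measured lag to any molecular memory mechanism.
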