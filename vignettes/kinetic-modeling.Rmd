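---
title: "Kinetic modeling of RNA polymerase multi-nucleotide addition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of RNA polymerase multi-nucleotide addition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polkin)
```

## The experiment being modeled

In a chemical quench-flow multi-nucleotide addition assay, elongation
complexes (ECs) of a purified RNA polymerase are assembled on a nucleic-acid
scaffold bearing a radiolabeled 10-mer RNA, rapidly mixed with saturating
NTPs and Mg^2+^, and quenched at times between 5 ms and 10 s. The template
permits nine successive incorporations, so the 10-mer is extended to a
19-mer through nine resolvable intermediates. Each quenched time point is
run on a sequencing gel; the fraction of lane signal in each RNA-length band
(10–19 nucleotides) versus time is the observable. Because NTPs are
saturating, each addition step is summarized by a single observed
pseudo-first-order rate constant; the package deliberately does not resolve
binding, catalysis, and translocation as separate elementary steps.

`polkin` implements the four linear first-order schemes used to describe
Pols I, II, and III with and without the Pol I inhibitor BMH-21:

* **S1** (Pol I, vehicle): an irreversible chain
  $EC_{10} \xrightarrow{k_1} EC_{11} \to \cdots \xrightarrow{k_9} EC_{19}$,
  plus intrinsic nuclease cleavage of the starting RNA,
  $EC_{10} \xrightarrow{k_{10}} \text{sink}$.
* **S2** (Pol I + BMH-21): S1 plus off-pathway paused states at the 11- and
  12-mer, $EC_{11} \rightleftharpoons EC_{11}^{*}$
  ($k_{on,1}$/$k_{off,1}$) and likewise at 12. Paused complexes cannot
  elongate; they must revert before the next addition. Active and paused
  complexes of the same length co-migrate as one gel band.
* **S3** (Pol II): a fully reversible chain with per-step forward and
  reverse constants $k_{F,i}$/$k_{R,i}$ — slow pyrophosphate release makes
  pyrophosphorolysis competitive — and no nuclease path.
* **S4** (Pol III): S1 plus activation of an initially inactive
  subpopulation, $EC_{10}^{*} \xrightarrow{k_{act}} EC_{10}$, with the
  initial mass split $(1 - f_{inactive}, f_{inactive})$.

All schemes conserve mass by construction: the cleavage product is an
explicit sink species, not a leak, and every generator matrix has zero
column sums (asserted to 1e-12). By default the sink maps to no band — the
fate of the radiolabel after cleavage is not modeled — but
`build_scheme(..., cleaved_band =)` can expose it as a short product band
if a user's chemistry warrants it.

## Solving the kinetics

The model is the linear system $\dot{x} = Kx$. The default solver
diagonalizes $K$ once and evaluates
$x(t) = V e^{\Lambda t} V^{-1} x(0)$, which is exact for linear systems and
fast enough to sit inside a global fit (~0.2 ms per 20-point solve). Fitted
rates can span four orders of magnitude and crossover can make rate pairs
nearly confluent, where the eigenbasis degenerates; the solver verifies its
own output (initial-derivative residual, per-time mass conservation,
negativity below −1e-10) and redoes failing solves with a scaled-and-squared
matrix exponential. An adaptive stiff integrator (`deSolve::lsoda`) is kept
as an independent cross-check and agrees with the primary path to better
than 1e-6 on every scheme in the test suite. Round-off negativity is clamped
to zero only at output; anything beyond 1e-9 raises an error instead of
being hidden.

For irreversible chains with pairwise-distinct rates the package also ships
the Bateman closed form (`bateman_chain()`), used purely as an analytic
oracle: the test suite requires agreement with the matrix solver to 1e-7
across randomly drawn chains. The closed form refuses near-confluent rates
(relative separation ≤ 1e-6) rather than evaluating its singular
denominators.

### A note on the pausing signature

With strong pausing (entry ≫ exit, e.g. 20 vs 0.5 s^-1^), the 11-mer band
rises on the elongation timescale but decays in two well-separated phases,
the terminal phase limited by pause exit — the band persists two orders of
magnitude longer than without pausing. It is worth recording that the
co-migrated band of this scheme family is provably *unimodal* in time: its
derivative is a combination of three real exponential modes and can change
sign only once. A double-peaked 11-mer trace, as raw gels can suggest, is
therefore a feature such a model can approach only as a biphasic shoulder,
never as two genuine local maxima; the package's qualitative tests assert
the attainable biphasic/persistence signature.

## Synthetic data

The study's raw quench-flow data are not publicly deposited, so
`default_scenarios()` defines six synthetic arms that stand in for them:
Pol I vehicle (S1), Pol I + BMH-21 (S2), Pol II vehicle and drug (S3, one
shared parameter set — the drug leaves Pol II unaffected), and Pol III
vehicle and drug (S4). Each uses 20 log-spaced time points spanning
0.005–10 s, three replicates, and additive Gaussian band-fraction noise of
SD 0.02. The scenario rate constants are **regimes, not reproductions**:
only the printed summary relationships are anchored exactly — the Pol III
mean addition rate of 49 s^-1^ (vehicle) versus 39 s^-1^ (drug), the
greater-than-2-fold Pol I reductions at the 13-/14-mer steps under drug,
and the fastest-to-slowest ordering Pol I > Pol III > Pol II. The remaining
values were chosen once as magnitudes typical of these enzymes and are not
revisited.

The noise model is additive truncated-Gaussian on band fractions, reflecting
approximately signal-independent phosphorimager quantification error;
SD 0.02 gives scatter resembling published gel quantifications. Noise is
independent per band with no per-lane renormalization (renormalization is an
option, off by default, since the original normalization procedure is
unstated). Two consequences are worth knowing. First, truncation at zero
biases near-zero bands upward by up to $\sigma\varphi(0) \approx 0.008$; the
test suite checks the generator against the analytic clipped-Gaussian mean
rather than pretending the bias away. Second, independent noise lets a
lane's band total stray slightly above 1, which real per-lane-normalized
fractions cannot do; the loaders accordingly tolerate noisy totals. What
passing tests on these data demonstrate is recoverability under the stated
noise structure — not robustness to gel artifacts (band overlap, smearing,
quench-timing error), which are out of scope.

A master seed is split into independent per-replicate streams, so replicate
*i* of a 3-replicate dataset is identical to replicate *i* of a larger one
with the same seed, and every dataset is reproducible from
`(scenario, seed)`.

## Global fitting

Each replicate's nine product time courses (bands 11–19 by default; the
10-mer can be added via `fit_config(fitted_bands =)`) are fit simultaneously
with one shared parameter set by unweighted least squares — no weighting
scheme is assumed because none is stated for the assay. Rates are optimized
as log10 values inside box bounds of [1e-3, 1e4] s^-1^: positivity is
structural, observed rates span roughly 0.1–100 s^-1^, and the log scale
makes the Gaussian mutation and blend crossover scale-free. The inactive
fraction $f_{inactive}$ is bounded on its natural [0, 1] scale.

`hybrid_optimize()` follows the multi-start evolutionary strategy used in
transient-state kinetics (the cited optimizer's exact hyperparameters live
in its own repository, so this module defines an equivalent contract rather
than a clone): a genetic algorithm — tournament selection (k = 3), BLX-0.5
blend crossover, Gaussian mutation, elitism, and a few fresh random
immigrants per generation to keep exploring — alternates with a
Levenberg–Marquardt polish (`minpack.lm::nls.lm`) whose result is
re-injected into the population. After the final GA round the incumbent plus
well-separated alternatives (minimum distance 0.5 in transformed space) are
polished — together with two fresh random starts — making the last stage a
true multi-start. Defaults (population 48, 60 generations over 3 phases, 5
polish candidates) were chosen for desk-scale runtime — a 10-parameter
replicate fits in about 1 s, an 18-parameter reversible-chain fit in about
3 s — and are all exposed in `fit_config()`. Because the reversible chain's
larger parameter space multiplies the number of spurious basins, any GA
settings left at their defaults are scaled with the parameter count p
(population max(48, 4p), max(60, 5p) generations, 4 phases beyond 14
parameters); with this budget the 18-parameter noiseless round trip reaches
the global optimum on every tested seed.

Two details matter in practice:

* **Bound release.** Least-squares polishes of chain models are attracted
  to spurious optima in which a forward/reverse pair runs to the upper
  bound, mimicking a fast equilibrium. A polish that ends with parameters
  pinned to the box boundary is therefore re-centered at the box midpoint
  and re-polished (up to three rounds, continuing through transiently worse
  objectives); only the final best is adopted. This step is what makes the
  18-parameter reversible fit reliably reach the global optimum on
  noiseless data.
* **Determinism and ties.** The whole search is a pure function of
  `config$seed`; ties between equal-objective optima are broken by the
  smaller transformed-parameter norm.

Replicates are fit individually and `aggregate_replicates()` reports each
parameter's mean and sample SD (n−1) across fits, the convention used for
tabulating kinetic constants from independent reactions. Degenerate input —
all fitted bands zero — is rejected before optimization rather than
"converging" silently.

## Model comparison and summaries

Competing schemes on the same data are adjudicated by AICc,
$n\ln(\mathrm{SSR}/n) + 2p + 2p(p+1)/(n-p-1)$. AICc was chosen over a
nested F-test because the null hypothesis pins rates at the boundary of the
parameter space (pause rates = 0), violating the F-test's regularity
conditions; with n = 180 observations and 10–14 parameters the
small-sample correction still matters. One replicate's 180 points carry
only marginal evidence against a 4-parameter elaboration — noise
occasionally buys the paused-state scheme a just-under-the-penalty SSR
improvement — so `compare_schemes_replicates()` adjudicates a whole
experiment by summing AICc over its independent replicate comparisons,
which decides reliably. The comparison also reports the
qualitative failure signature that motivates the paused-state scheme —
systematic positive late-time residuals on the 11-/12-mer bands when the
simple chain is forced onto pausing data — plus a per-band
Wald–Wolfowitz-style runs diagnostic of residual structure.

`summarize_kinetics()` computes the tabulated conventions: the arithmetic
mean of the nine addition-step constants (excluding the nuclease and
activation parameters, which are not nucleotide-addition steps), per-step
fold changes against a reference fit, and per-step forward/reverse ratios
for the reversible scheme (undefined, not infinite, where a reverse rate
is zero).

## EC stability analysis

In the RNase-protection assay, ECs are challenged at t = 0 with RNase A,
1 M KCl, and drug or vehicle. An intact EC protects its 10-mer; a collapsed
EC exposes it, yielding a 7-mer, so collapse is quantified as
signal(7-mer)/(signal(7-mer)+signal(10-mer)) — invariant to lane exposure.
`analyze_stability()` averages replicate collapse fractions per condition
and contrasts two conditions by the maximum absolute difference of the
means; the "unaffected" verdict requires the difference to stay within 2
replicate SDs at every shared time point (multiplier exposed as `sd_mult`).
An optional single-exponential rise-to-plateau fit
$f(t) = f_0 + A(1 - e^{-kt})$ reuses the hybrid optimizer; it is a
descriptive convenience, off by default, because no mechanistic decay model
is claimed for these curves. The synthetic stability generator uses a
log-spaced 0–10 min grid as a stand-in, since the assay's exact sampling
times are not printed.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the sizes the analyses
are designed for: 20-point, 3-replicate datasets; 10 independent seeds per
scenario for recovery and model selection; 10^4^-point log grids for
qualitative curve-shape checks; 100 random chains for the solver-vs-oracle
bound (max-abs error < 1e-7). Scheme-limit equivalences (S2 with pause
rates 0, S3 with reverse rates 0, S4 with no inactive pool, each against
the corresponding simpler scheme) hold to 1e-9. Parameter recovery on the
default scenarios achieves median relative errors of a few percent for the
addition-step constants — comfortably inside the 15% working tolerance —
with pause entry/exit rates typically within 1.3-fold.

## Limitations

* Observed rate constants are composites at one saturating NTP
  concentration; nothing here models concentration dependence.
* The synthetic noise model is a stand-in; the original gels' true noise
  magnitude and correlation are unknown.
* Individual reverse rates of the reversible scheme are weakly constrained
  by band data alone; forward/reverse *ratios* are the robust summary.
* No bootstrap or profile-likelihood intervals: uncertainty is reported as
  replicate SD, matching the assay's own convention.
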