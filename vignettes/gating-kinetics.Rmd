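---
title: "Inferring multi-state gating kinetics from single-channel recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring multi-state gating kinetics from single-channel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatingmcmc)
```

## The model

A single ion channel is modeled as a continuous-time Markov chain on a
small set of hidden conformational states $S_1, \dots, S_n$.  The chain is
not observed directly: each state belongs to one of three *conductance
classes* — fully open ($O$), sub-conductance / half-open ($O_S$), closed
($C$) — and the recording only reveals the class.  This is the classical
aggregated Markov model of single-channel analysis.  The transition rates
$q_{ij} \ge 0$ (ms$^{-1}$) live on the edges of a state graph and are
collected in the infinitesimal generator $Q$ with
$q_{ii} = -\sum_{j \ne i} q_{ij}$, so rows of $Q$ sum to zero.  We use the
row convention throughout: probability row vectors multiply $Q$ from the
left, $\pi Q = 0$ defines the stationary distribution, and the transition
matrix over one sampling interval $\tau$ is $A_\tau = e^{Q\tau}$, computed
by the scaling-and-squaring Padé approximation.  (Some texts write the
transposed column convention; the two descriptions are equivalent, and we
standardize on rows because the forward filter below naturally propagates
row vectors.)

The package ships a five-state open-loop topology for VDAC, the
mitochondrial outer-membrane anion channel, whose gating at $-10$ mV shows
all three classes:

$$S_5 \;\overset{q_{51}}{\underset{q_{15}}{\rightleftharpoons}}\; S_1
  \;\overset{q_{13}}{\underset{q_{31}}{\rightleftharpoons}}\; S_3
  \;\overset{q_{34}}{\underset{q_{43}}{\rightleftharpoons}}\; S_4
  \;\overset{q_{42}}{\underset{q_{24}}{\rightleftharpoons}}\; S_2$$

with $S_3$ fully open, $S_2$ closed, and $S_1, S_4, S_5$ sharing the
sub-conductance level.  The topology is a tree (acyclic), so detailed
balance $\pi_i q_{ij} = \pi_j q_{ji}$ holds automatically for any positive
rates and all $2(n-1)$ directed rates are free parameters.  Published rate
estimates for five experimental conditions (wild-type, two nitrosation
levels, recombinant un-phosphorylated, and an S137E phosphomimetic) are
available through `vdac_model()` and serve as defaults and as ground truth
for the synthetic-data generator.  Cyclic topologies, which would require
constrained sampling to maintain detailed balance, are out of scope.

## From current trace to event sequence

Recordings are sampled currents $I_k$ (pA) at fixed $\tau$ (0.2 ms at the
5 kHz digitization rate used for the packaged conditions).  Idealization is
plain two-threshold classification of magnitudes: a sample is $O$ when
$|I_k| \ge |I_O|$, $C$ when $|I_k| \le |I_C|$, and $O_S$ otherwise, with
$|I_O| > |I_C|$.  Because only magnitudes enter, the classification is
invariant to the sign of the recording.  We adopt the inclusive
comparisons ($\ge$, $\le$); boundary samples carry no probability under
noise, so the choice is immaterial in practice but is fixed for
reproducibility.  Published threshold tables sometimes label the pair in
the opposite order; we resolve the labels semantically — the larger
magnitude always separates the fully open level, since the open channel
conducts more — and store magnitudes only.  No filtering is applied before
thresholding (an optional median prefilter exists but is off by default).
The idealized sequence is run-length encoded: maximal runs of a class with
their lengths in samples.

## The likelihood

States within a class are hidden, so the likelihood of an event sequence
sums over all hidden state paths.  With the diagonal 0/1 projection
$\theta_c$ selecting the states of class $c$
($\theta_O + \theta_{O_S} + \theta_C = I$), the forward filter is

$$v_k = v_{k-1}\, A_\tau\, \theta_{E_k},$$

and the likelihood is the total mass left after the last step.  The filter
is initialized by restricting the starting distribution to the first
event's class and renormalizing, i.e. we condition on the first event (a
one-event sequence has log-likelihood 0).  The default starting
distribution is the stationary distribution of the candidate $Q$ — the
natural choice for long equilibrium recordings; a uniform-over-class
alternative is selectable.  Scaling (renormalizing $v$ and accumulating
log factors) keeps half-million-sample recordings in range.

Two implementation notes matter for speed and correctness:

* **Run compression.** A run of $m$ identical classes contributes
  $(A_\tau \theta_c)^m$, which we evaluate by binary exponentiation with
  cached squarings (each squaring rescaled by its largest entry, with the
  log factors accumulated, so extremely long runs cannot underflow).  This
  turns a 500,000-sample recording with a few hundred runs into a few
  hundred small matrix products per likelihood evaluation and is what
  makes full-scale fits take seconds.  The per-sample recursion is
  retained (`method = "sample"`) and the two agree to $10^{-9}$ relative;
  the test suite additionally pins both against an exhaustive
  path-enumeration oracle on all short sequences.
* **Marginal likelihood, not path sampling.** We compute the marginal
  probability of the observed classes with hidden states summed out,
  rather than augmenting the sampler with hidden-path updates.  The
  acceptance ratio below therefore uses $P(E \mid Q)$ directly.

Multiple recordings of one condition are treated as independent and fitted
simultaneously by summing their log-likelihoods.

## The sampler

Inference is random-walk Metropolis–Hastings over the free rates.  Each
iteration perturbs every directed rate by an independent
$U[-\delta, \delta]$ draw (a one-rate-at-a-time mode exists for
diagnostics and tuning).  A proposal with any negative rate is
auto-rejected — not reflected — which together with the symmetric proposal
leaves the invariant distribution intact.  The prior is independent
exponential with mean $\lambda$ on every rate, i.e.
$\log P(Q) = \sum_i q_{ii} / \lambda$ up to a constant; the default
$\lambda = 30$ ms$^{-1}$ is deliberately weak and only penalizes rates far
above the gating scale.  A candidate is accepted with probability
$\min\{1, \exp[\Delta(\log L + \log P)]\}$.

Defaults follow the published protocol: 20,000 iterations with the first
10,000 discarded as burn-in, and $\delta$ in the tuning range
$[0.0005, 0.05]$ ms$^{-1}$ (default 0.005).  Because the posterior scales
of the eight rates span four orders of magnitude (slow exits from the
dominant sub-conductance state sit near $10^{-4}$ ms$^{-1}$), a fixed
scalar $\delta$ mixes poorly.  `tune_proposal()` therefore runs short
adaptive pilots — one-rate-at-a-time updates, doubling or halving each
rate's $\delta$ every 25 sweeps toward a 20–50% acceptance window — and
the production chain then uses the tuned per-rate widths divided by
$\sqrt{d}$ (the standard dimension scaling for joint random-walk
updates), held fixed so the production chain is a valid MH sampler.  The
pilot is multi-start: three uniform rate levels plus several random
log-uniform rate vectors, keeping the run that ends at the best
log-posterior.  This matters because the aggregated likelihood has
permuted local modes — e.g. a fast-cycling peripheral pair of
sub-conductance states can impersonate the slow dominant one — and every
uniform start can fall into the same wrong basin; diverse relative rate
structures among the starts break that tie.  Production chains can also
be replicated from independent seeds and their post-burn-in samples
pooled, which is how the package's own recovery experiment stabilizes
posterior means.  Chains are reproducible bit for
bit from a single integer seed, which is stored on the chain object.

Posterior summaries (means, batch-means Monte-Carlo standard errors,
central credible intervals, histograms) are computed on post-burn-in
samples only.  Rates are reported externally in s$^{-1}$, the conventional
unit of the published tables; everything internal is ms$^{-1}$ (converting
by $10^3$ at the I/O boundary avoids overflow in $e^{Q\tau}$ at
$\tau = 0.2$ ms).

Model comparison across candidate topologies is by maximum post-burn-in
log-posterior, supplemented by a qualitative burst diagnostic (the
distribution of open runs between successive closures), because
closely-nested candidates can be statistically indistinguishable while
still failing to reproduce burst patterns.  A candidate whose class map
cannot produce an observed class at all scores $-\infty$.

## Dwell times and stationary analysis

The dwell time of class $A$ has the Colquhoun–Hawkes density

$$f(t) = \Phi_0\, e^{Q_{AA}t}\, (-Q_{AA})\, u_A, \qquad
  \Phi_0 = \pi_B Q_{BA} / (\pi_B Q_{BA} u_A),$$

a (possibly signed-weight) mixture of exponentials obtained from the
eigendecomposition of the class sub-generator $Q_{AA}$; when the class has
a single state this collapses to an exponential with the state's total
exit rate.  The eigenroute is used when the eigenvector matrix is
well-conditioned (condition number below $10^8$); otherwise evaluation
falls back to the Padé exponential of $Q_{AA}t$.  Empirical dwell
histograms use 0.5 ms bins and store raw counts; the square-root frequency
ordinate conventional in this field is applied only at plotting.
Theoretical overlays multiply exact bin integrals (differences of the
survival function) by $\eta$, the observed event count of the class.  We
default $\eta$ to the raw count rather than fitting it; sub-$\tau$ events
escape detection, so $\eta$ silently absorbs missed brief events and the
densities are reported untruncated — exact missed-event corrections are
out of scope.

Stationary distributions solve $\pi Q = 0$ by replacing one equation of
the transposed system with the normalization constraint (with an SVD
null-space fallback when that system is ill-conditioned); for acyclic
models the independent closed form chained from detailed balance agrees to
$10^{-10}$ and is used as a cross-check throughout the tests.  Occupancies
are often easier to read after excluding a dominant dwell state and
renormalizing (`restricted_stationary()`), e.g. comparing the four minor
states of the five-state model across conditions.

## The synthetic-data generator

`gillespie_path()` simulates the chain exactly (exponential holding times,
categorical jumps, stationary initial state by default);
`discretize()` samples the instantaneous state on the $\tau$ grid — no
within-interval averaging, matching the per-sample thresholding model — so
sojourns shorter than $\tau$ can vanish exactly as brief events escape a
real digitizer; `render_trace()` maps classes to fixed current levels and
adds Gaussian noise of 0.5 pA standard deviation by default, the
background noise level of the recordings the packaged conditions describe.
Current levels are configuration, not a reproduction claim: the published
simulations assigned amplitudes ad hoc, and we place the sub-conductance
level midway between the two thresholds, the open level 5 pA beyond the
open threshold, and the closed level below the closed threshold, on the
negative branch (open events deflect downward at negative holding
potentials).  For the wild-type condition this puts every level at least
five noise standard deviations from the nearest threshold, so
re-idealization of a rendered trace recovers the generating event sequence
essentially always; with zero noise the round trip is exact, which the
tests exploit.

What the generator does *not* emulate: amplitude variability within a
class, baseline drift, the 1 kHz anti-aliasing filter's correlated noise,
and voltage dependence.  Passing tests therefore demonstrate correctness
of the inference machinery under the model's own assumptions, not
robustness to these real-data artifacts.

## Problem sizes and what the checks compute

The package's end-to-end recovery experiment emulates the full wild-type
condition: four recordings of 100 s each (500,000 samples apiece at
$\tau = 0.2$ ms — the recording length of the published convergence
analysis, times the published $n = 4$), rendered with 0.5 pA noise,
idealized and fitted simultaneously with the pilot-then-production
protocol above.  At the wild-type rates this yields on the order of a
hundred open and closed events per 400 s of data, so the exit rates of the
open and closed states (notably $q_{34}$ and $q_{24}$) and the slow exits
from the dominant sub-conductance state ($q_{43}$, $q_{42}$) are well
identified.  The rates of the peripheral sub-conductance states $S_1$ and
$S_5$ ($q_{13}$, $q_{15}$, $q_{51}$) are a known limitation: they are
informed only by brief open–gap–open "flicker" excursions whose stationary
frequency at the wild-type parameters is roughly one per 100 s, so their
posteriors remain broad and ridge-like at any realistic recording length,
and point estimates of $q_{13}$ should not be trusted even when the
credible interval covers the generating value.  The test suite computes
exactly this: posterior-mean recovery and credible-interval coverage for
$q_{13}$ and $q_{34}$ over replicated synthetic experiments, a
path-enumeration oracle for the likelihood on all sequences of up to 8
events, chi-squared agreement between $10^6$-event Monte-Carlo dwell
samples and the closed-form densities, conservation properties, and prior
recovery of the sampler under a flat likelihood.

## Numerical choices, in one place

* Matrix exponential: scaling-and-squaring Padé (Armadillo `expmat`);
  eigendecomposition is never the primary path since $Q$ may in principle
  be defective.
* Stationary solve: replaced-equation linear solve, SVD null space as
  fallback, negative round-off clipped and renormalized; failures raise a
  singular-system error naming the likely zero-rate edge cause.
* Forward filter: per-run rescaling with accumulated logs; cached matrix
  powers rescaled by their maximum entry.
* Degenerate inputs: absorbing classes, empty class restrictions,
  mixed-$\tau$ joint fits, non-monotone or irregular time columns, and
  negative rates are rejected with specific errors rather than propagated.
* Ties at thresholds resolve toward the extreme classes ($\ge$ open,
  $\le$ closed).
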