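---
title: "Multi-parameter photon-by-photon HMM: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parameter photon-by-photon HMM: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Confocal smFRET measurements of freely diffusing molecules produce bursts of
photons, each photon tagged with an arrival time (integer clock ticks, e.g.
50 ns for 20 MHz nsALEX or 12.5 ns for μsALEX) and a detection stream. With
alternating excitation there are three informative streams: donor excitation
with donor emission (DD, index 0), donor excitation with acceptor emission
(DA, 1), and acceptor excitation with acceptor emission (AA, 2). The raw
FRET efficiency `E_raw = n_DA / (n_DD + n_DA)` reports on inter-dye
distance; the raw stoichiometry `S_raw = (n_DD + n_DA) / (n_DD + n_DA +
n_AA)` reports on dye photophysics (about 0.5 for a doubly labelled,
doubly emitting molecule, near 1 when the acceptor is dark, low when the
donor is dark). Molecules interconvert between conformational states on
timescales from microseconds to seconds, and the dyes also blink — so the
photon stream mixes FRET-relevant and FRET-irrelevant dynamics.

`mph2mm` fits a hidden Markov model directly to photon arrivals, without
binning. Using all three streams as the emission alphabet (the
multi-parameter analysis, r = 3) lets the model separate, say, a dark
acceptor (E ≈ low, S ≈ 1) from a genuine low-FRET conformation (E ≈ low,
S ≈ 0.5) — states that are indistinguishable in the donor-excitation
streams alone (the single-parameter analysis, r = 2).

## The model

A `q`-state model has an initial distribution π, a per-clock-tick
transition matrix **A** and a q × r emission matrix **B** (row i is the
stream distribution of photons emitted in state i). The hidden chain steps
once per clock tick; photons are observed only at their arrival ticks. For
two photons separated by `Δt` ticks the effective transition kernel is the
exact matrix power **A**^Δt, computed by binary exponentiation and cached
per distinct gap. A gap of zero ticks (simultaneous photons on different
detectors) propagates with the identity: no time elapses.

Likelihoods use a per-step scaled forward–backward recursion (scale factors
accumulate the log-likelihood), which is exact and underflow-free for
bursts up to millions of photons; emission and transition entries at desk
scale are far from denormals, so log-space arithmetic is unnecessary in
the forward pass. Viterbi decoding runs in log space.

Baum–Welch estimation must count expected transitions *including those in
the unobserved ticks inside each gap*. For a gap of length d with endpoint
weights accumulated in a matrix U, the expected k→l transition count is
`A_kl * S_d[k,l]` with `S_d = Σ_{τ=0}^{d-1} (Aᵀ)^τ U (Aᵀ)^{d-1-τ}`,
evaluated in O(q³ log d) by the doubling identity
`S(d1+d2) = S(d1) P^{d2} + P^{d1} S(d2)`. The test suite verifies both the
likelihood and these expectations against an explicit "silent-tick"
construction (inserting Δt−1 null-emission ticks and running plain
Baum–Welch) to 1e−9, and the likelihood against exhaustive path sums.

## Model selection

The number of free parameters is `K = q² + (r−1)q − 1`. Two criteria are
computed for every fitted model:

* `BIC  = −2 ln p(y | λ̂) + K ln n`, with the marginal likelihood;
* `ICL  = −2 ln p(y, ŝ | m, λ̂) + K ln n`, with the *joint* posterior of
  the data and the most likely (Viterbi) state path ŝ; n is the total
  photon count. Because the joint never exceeds the marginal, ICL ≥ BIC
  always.

The ICL is the primary, extremum-based criterion: the preferred model
minimizes it. `h2mm_scan()` optimizes q = 1, 2, … and stops once the ICL
has risen for two consecutive q past a local minimum (guarding against
shallow ripples) or at `q_max` (default 6, which covers published use).
A modified BIC (BIC′) is reported alongside as a threshold-based second
opinion: this package normalizes it as the relative BIC improvement still
available from adding one state, `BIC′(q) = (BIC(q) − BIC(q+1))/BIC(q)`,
flagging the first q below 0.005. `bic_prime()` is deliberately the single
place this formula lives, so the normalization can be revised against the
original literature without touching callers. When the criteria disagree
the scan selects the ICL minimum and emits a prominent advisory — the
working policy is ICL first, BIC′ second, prior knowledge of the system
last.

### Initialization and local optima

The default initializer (`default_init_model()`) is deterministic given
(q, r, seed): uniform prior; off-diagonal per-tick transition
probabilities log-spaced over [1e−7, 1e−3]; emission rows spread along the
E axis at S ≈ 0.5, plus one high-S and one low-S row for q ≥ 3 with r = 3
so dark-dye candidates are represented from the start; the seed applies a
small multiplicative jitter. A complementary `"s-split"` pattern (half the
rows at high S, half at low S) covers solutions organized along the
stoichiometry axis — jitter restarts never cross between the two basins,
so structurally diverse multi-starts fit both patterns and keep the higher
likelihood (this is how the unshifted-μsALEX artifact fit below is
obtained).

EM likelihood surfaces for multi-stream photon data can hold well-separated
local optima — on shifted μsALEX data a merged-state solution is locally
stable and sits thousands of nats below the global optimum. The scan
therefore also warm-starts each q from the previous state count's best fit
grown by one flat, weakly coupled state (`grow_model()`), keeping
whichever candidate ends higher (`init_strategy = "both"`). The warm route
is in practice the more reliable and the cheaper; `"warm"` runs only it
(after a cold start at the smallest q) and is what the package's own
validation studies use.

Convergence is declared when the absolute log-likelihood gain drops below
`tol` (default 1e−3 nats), with `max_iter` 1000 by default. In the
validation studies the scans cap EM at 300 iterations per candidate: the
selected models converge in under 40 iterations, and the cap only curtails
the slow terminal crawl of over-fitted candidates whose ICL is already far
from the minimum.

## Burst processing

Background is estimated per 30 s slice as the maximum-likelihood
exponential rate of inter-photon delays above a threshold (initial 0.5 ms,
re-fit as 2/rate until stable within 5%) — bursts contribute the short
delays, the memoryless background tail the long ones. Bursts are photons
covered by any "hot" window: the rate `m/(t_{i+m−1} − t_i)` of a sliding
window of m = 10 consecutive photons at least F = 6 times the local
background rate (ties count as hot). The dual-channel search (DCBS) runs
the same search independently on the donor-excitation (streams 0+1) and
acceptor-excitation (stream 2) photon subsets and keeps time-intersections
of overlapping bursts, suppressing single-dye species. Bursts with at
least 30 photons over all streams are retained. All intervals are
half-open with 0-based photon indices.

Burst variance analysis (BVA) cuts each burst's donor-excitation photons
into consecutive non-overlapping windows of 5, takes the standard
deviation of the window-wise E, and compares it with the shot-noise
expectation `sqrt(E(1−E)/5)`; bursts above that semicircle indicate
within-burst dynamics. It is the model-free qualitative check run before
any HMM fitting.

## μsALEX and the alternation artifact

In μsALEX the lasers alternate slowly enough that donor- and
acceptor-excitation photons segregate in time within each alternation
period. Fitted on such raw times, the HMM locks onto the laser: all states
drift to S ≈ 0 or 1 and the fitted "rates" track the alternation
timescale rather than the molecule. `shift_acceptor_photons()` cures this
by remapping each AA photon so that its fractional position inside the
acceptor window becomes the same fraction of the *donor* window of the
same period (for equal-length windows this is an exact integer
subtraction). The mapping preserves intra-window spacing, is period-local,
and is idempotent; photons are re-sorted stably.

One quantitative note from this package's validation: on unshifted
simulated data the q = 2 maximum-likelihood solution reproduces the
artifact exactly (S fitted to 1 and 0), and its rate constants settle at
roughly *twice* the excitation-switching event rate (2/period) when
photons are sparse (~1 photon per window), approaching 1/half-period from
above as photons densify. The artifact rates are thus pinned to the
alternation timescale — two orders of magnitude above the simulated
molecular rates — but their precise multiple of the alternation frequency
depends on the photon rate per window. The shift also assumes dynamics
slow compared with the alternation period; transitions approaching that
timescale bias S toward window averages.

## The simulator

`sim_scenario()`/`make_dataset()` generate ground-truth data: an exact
Gillespie continuous-time Markov trajectory per burst (initialized from
the stationary distribution), photons as a Poisson process at the current
state's total rate with streams drawn from the state's
`(p_DD, p_DA, p_AA) = (S(1−E), S·E, 1−S)`, per-stream background photons
superposed over bursts and quiet stretches alike, timestamps quantized to
clock ticks, and — in μsALEX mode — photons thinned by the alternation
gating (with equal half-period windows each class retains half its
photons, so target S values hold post-thinning). Dark-dye photophysics is
modelled as ordinary states with extreme S. A single global seed fans out
to per-segment substreams, so datasets are bitwise reproducible and early
bursts are unchanged when the burst count grows. The true per-tick model
uses `I + Q·τ`; at the rates and clocks simulated the linearization error
is below 1e−8 per entry.

What the simulator deliberately does *not* emulate: diffusion through the
Gaussian excitation volume (bursts have constant brightness and sharp
edges), detector dead time and afterpulsing, and TCSPC nanotime
(lifetime) structure. Passing recovery tests therefore demonstrate the
correctness of the inference given the model's assumptions — not
robustness to brightness envelopes or detector artifacts in real data.

### Study conditions used in the validation suite

* **Three-state nsALEX system** (`scenario_3state_dark_acceptor()`): FRET states
  at E 0.2 and 0.65, both S 0.5, interconverting at 300 s⁻¹ each way; a
  dark-acceptor state at E 0.2 (raw E of a dark acceptor comes from donor
  leakage, and is chosen to coincide with the low-FRET state — exactly the
  regime where the AA stream is decisive and the donor-excitation streams
  alone cannot separate the states), S 0.95, entered at 100 s⁻¹ and left
  at 1000 s⁻¹; burst photon rate 1e5 s⁻¹, 500 exponential bursts of mean
  4.5 ms (≈2.2×10⁵ photons), background (700, 500, 600) counts/s, 50 ns
  clock. Across 20 seeds the ICL selects q = 3 and the aligned states
  recover E/S within 0.03 and rates within 20% (seed-averaged); on the
  same data restricted to streams {0, 1} the ICL selects q = 2 with the
  dark acceptor merged into the low-FRET state.
* **Two-state μsALEX system** (`scenario_usalex_2state()`): E 0.2/0.65 at
  S 0.5, 300 s⁻¹ each way, 12.5 ns clock, 4000-tick (50 μs, 20 kHz)
  alternation with equal windows — the artifact/shift demonstration.
* **BVA calibration**: a static E = 0.5 state (500 bursts) lies on the
  semicircle within Monte-Carlo error; the millisecond two-state system
  lies above it in the intermediate-E bins.

## Error estimates

Two complementary error proxies are provided. Weighted dwell statistics
(`weighted_dwell_stats()`) compute photon-count-weighted mean, SD and SE
of the Viterbi dwells' E and S per state; weights match the ratio
denominators (donor-excitation photons for E, all photons for S), and the
SE uses the effective sample size `(Σw)²/Σw²`. The weighting scheme is a
documented package choice. `variance_of_subsets()` re-optimizes seeded
round-robin subsets of bursts from the full-data model and reports the
spread of each parameter across subsets, with subset states matched to the
full model by greedy nearest-neighbour assignment in (E, S), ties to the
lower index.

Rate constants are reported as `k_ij = A_ij / clock_period` (valid for
per-tick probabilities ≪ 1; a warning fires above 0.01 per tick and a
matrix-logarithm alternative is available). Dwell durations are measured
photon-to-photon with no extrapolation to burst edges; edge dwells are
tagged `initial`/`terminal` so duration analyses can exclude them.

## Degenerate inputs and numerical choices

Row-stochasticity is validated to 1e−12. A stream with zero emission
probability in every state produces an explicit −∞ likelihood flag and an
abort naming the first offending burst. EM keeps the previous row for a
state starved of expected occupancy (< 1e−12) and warns. Ratios with zero
denominators carry NA "undefined" flags rather than errors. Ties in
timestamp sorting preserve input order (stable radix sort). The EM
monotonicity guarantee is asserted in tests at 1e−8 relative.

## Known limitations

* Constant-brightness bursts mean burst-search boundary behaviour on real,
  diffusion-shaped bursts is not exercised by the validation suite.
* BIC′'s normalization is this package's reading of a threshold-style
  criterion; it is isolated in one function for future correction.
* The Viterbi-based dwell statistics inherit Viterbi's bias against very
  short dwells; the subset-variance route does not, at higher cost.
* Fluorescence-lifetime (nanotime) information is ignored beyond nsALEX
  stream gating.
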