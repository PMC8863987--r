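# mph2mm — multi-parameter photon-by-photon hidden Markov modeling for smFRET

`mph2mm` infers the conformational and photophysical states of single
biomolecules from confocal smFRET photon streams — directly from photon
arrival times, without binning. It is aimed at single-molecule
spectroscopists analysing diffusing-molecule ALEX/PIE measurements (nsALEX
or μsALEX) who need to know *how many* states interconvert within bursts,
what each state's raw FRET efficiency `E_raw = n_DA/(n_DD+n_DA)` and
stoichiometry `S_raw = (n_DD+n_DA)/(n_DD+n_DA+n_AA)` are, and the
transition rate constants between them — including sub-millisecond
dynamics invisible in burst-wise histograms.

## The method

A `q`-state hidden Markov model runs on the acquisition clock: initial
distribution π, per-tick transition matrix **A**, and a q × r emission
matrix **B** whose rows give each state's photon-stream probabilities over
the r detection streams (DD, DA and — the "multi-parameter" part — the
acceptor-excitation AA stream). Between photons separated by Δt ticks the
transition kernel is the exact matrix power **A**^Δt; Baum–Welch EM
maximizes the likelihood with transition expectations accumulated exactly
over the unobserved ticks inside every gap. Using the AA stream (r = 3)
separates dye-dark states from genuine FRET states that look identical in
the donor-excitation streams alone (r = 2).

The number of states is selected by the integrated complete likelihood,

    ICL = −2 ln p(y, ŝ | m, λ̂) + K ln n,    K = q² + (r−1)q − 1,

where ŝ is the Viterbi path and n the photon count; the preferred model
minimizes the ICL, with a modified-BIC threshold criterion (BIC′, 0.005)
reported as a second opinion. Around the HMM the package provides the full
workflow: background estimation, sliding-window and dual-channel (DCBS)
burst search, burst selection, burst variance analysis (BVA), the μsALEX
acceptor-photon shift that removes the laser-alternation artifact, Viterbi
dwell segmentation and classification, weighted dwell statistics and
subset-variance error estimates, photon-HDF5 and plain-text I/O, and a
ground-truth photon simulator used by the validation suite.

## Worked example

```r
library(mph2mm)

# simulate a two-state system (E_raw 0.2 / 0.65, 300 s^-1 each way) with
# background, then run the standard workflow
scenario <- sim_scenario(
  states = data.frame(E = c(0.2, 0.65), S = c(0.5, 0.5), rate = c(1e5, 1e5)),
  rate_matrix = matrix(c(0, 300, 300, 0), 2, byrow = TRUE),
  n_bursts = 150, burst_duration_mean = 4.5e-3, inter_burst_mean = 20e-3,
  background = c(DD = 700, DA = 500, AA = 600), clock_period = 50e-9)
ds <- make_dataset(scenario, seed = 42)

bg     <- estimate_background(ds$series)
bursts <- select_bursts(sliding_burst_search(ds$series, bg), min_photons = 30)
data   <- as_obs_set(ds$series, bursts)
scan   <- h2mm_scan(data, q_max = 4)
print(scan)
summary(scan_fit(scan))
```

```
Model scan over state counts (r = 3 streams)
 q    loglik viterbi_logpost  K     n      ICL      BIC converged BIC_prime selected
 1 -63366.96       -63366.96  2 61364 126756.0 126756.0      TRUE  0.039600
 2 -60832.03       -61115.91  7 61364 122309.0 121741.2      TRUE -0.000469        *
 3 -60821.98       -61146.78 14 61364 122447.9 121798.3      TRUE -0.000734
 4 -60817.08       -61143.01 23 61364 122539.6 121887.7      TRUE        NA
Selected q = 2 ( ICL-minimum ); BIC' flags q = 2

Photon-by-photon HMM fit: q = 2 states, r = 3 streams
  61364 photons in 130 bursts; loglik -60832.026 (converged after 13 EM iterations)
  ICL 122308.984  BIC 121741.225  (K = 7)
<state_model> q = 2 states, r = 3 streams
 state  prior  E_raw  S_raw
     0 0.4428 0.2008 0.5004
     1 0.5572 0.6433 0.5042

Transition rate constants (s^-1, row -> column):
       [,1]   [,2]
[1,] -308.0  308.0
[2,]  339.2 -339.2
```

The ICL is minimized at q = 2 — additional states raise it, so they are
over-fits. The recovered states sit at `E_raw` 0.20 and 0.64 with `S_raw`
≈ 0.5 (both dyes emitting), and the fitted rate constants (308 and
339 s⁻¹) recover the simulated 300 s⁻¹ interconversion to within sampling
error. Downstream, `predict(fit, data, type = "dwells")` segments each
burst's Viterbi path into dwells with per-dwell E/S, and
`weighted_dwell_stats()` summarizes their spread per state.

For a μsALEX measurement, apply `shift_acceptor_photons()` before fitting:
unshifted acceptor-excitation photon times make the HMM lock onto the
laser alternation (all states at S ≈ 0 or 1 with rates at the alternation
timescale) instead of the molecule.

A full scripted pipeline (search → BVA → scan → dwells → report, with CSV
and JSON artifacts and a run manifest) is available as `run_pipeline()` /
`inst/scripts/h2mm-pipeline.R`.

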