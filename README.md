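# gestaltsync

Spike synchrony as a readout of Gestalt structure in a V1-like spiking
network.

## The problem

Neurons in primary visual cortex are linked by excitatory *horizontal
connections* whose strength decreases with retinotopic distance and with
the difference in preferred orientation — a wiring pattern shaped by the
statistics of natural images, which in turn follow the Gestalt grouping
principles (proximity, similarity, good continuation). If the wiring
encodes those statistics, then the degree of zero-lag spike synchrony
among stimulus-driven neurons can act as an estimate of how well a
stimulus matches the prior stored in the connectivity — a readout that
needs no oscillations, only noise-induced coherence through the coupling.

`gestaltsync` implements the full simulation pipeline for testing this
idea: parametric Gestalt stimuli, orientation-channel decomposition and
Poisson encoding, a pulse-coupled fully excitatory Izhikevich network with
receptor/transmitter synapse kinetics, the Rsync synchrony statistic, and
the nonparametric statistics and controls around it.

## The model in brief

One neuron per (pixel, orientation channel) on a 20 × 20 grid with 5
channels (N = 2000). Membrane dynamics are the regular-spiking Izhikevich
equations

v' = 0.04 v² + 5v + 140 − u − I + ε,  u' = a(bv − u),

with reset v ← c, u ← u + d at v ≥ 30 mV. Input is conductance-based,
I = (v − E)[Σⱼ Wˡᵃᵗᵢⱼ rⱼ + rᵉˣᵗ Sᵉˣᵗ], where each spike opens receptors
through r' = α[T](1 − r) − βr with a transmitter pulse [T] of duration τ.
The fixed lateral weights combine spatial proximity and orientation
similarity,

Wˡᵃᵗᵢⱼ = (Sᵈ/(L∞(i,j) + 1) + Sᵃ/(Δ(i,j) + 1)) · Sˡᵃᵗ,

with L∞ the Chebyshev pixel distance and Δ the folded orientation
difference (0–90°). Synchrony of a neuron set S over window T is

Rsync(S, T) = Var̂ₜ[⟨Aᵢ(t)⟩ᵢ] / ⟨Var̂ₜ[Aᵢ(t)]⟩ᵢ ∈ [0, 1],

where Aᵢ is the spike train convolved with a causal exponential kernel
(3 ms timescale). Independent neurons give ≈ 1/|S|; identical firing
gives 1.

## Worked example

```r
library(gestaltsync)

stim <- generateProximityStimulus(gapPx = 0)   # one unbroken line, 2 halves
conn <- buildConnectivity(20)                  # calibrated defaults
rec  <- simulateStimulusTrial(stim, conn, seedR = 1, seedCpp = 2)
g    <- groupRsync(rec, stim, segmentIds = c(1, 2), kPerSegment = 4, seed = 3)
g$value
#> [1] 0.2201826
```

The value is the group synchrony of 8 randomly chosen driven neurons (4
per segment) in one trial: well above the 1/8 = 0.125 independence
baseline, because the lateral coupling correlates the stimulus-driven
subnetwork. Running `experimentConfig("proximity")` through
`runGestaltExperiment()` repeats this over the gap series 0–4 with 100
trials each and attaches the Kruskal–Wallis / Dunn / rank-sum statistics;
synchrony declines as the gap grows.

A compact end-to-end run of the extreme conditions of all three
experiments (with jitter and ablation controls and the
connectivity–synchrony correlation):

```r
rep <- runReplication(seed = 20, nTrials = 20)
replicationHeadline(rep)[c("proximity_median_gap0", "proximity_median_gap4")]
#> $proximity_median_gap0
#> [1] 0.2256842
#>
#> $proximity_median_gap4
#> [1] 0.2046248
```

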