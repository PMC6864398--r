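# erknet

Candidate network models, Bayesian model selection and single-cell
trajectory analytics for growth-factor-driven ERK dynamics.

## The problem

In PC-12 cells, the temporal pattern of ERK/MAPK activity — transient,
sustained, pulsatile in phase with a stimulus, or anti-phasic — encodes
cell-fate information. For FGF2 the receptor layer involves a competition
between heparan-sulfate proteoglycan (HSPG) co-receptors and FGF receptors
(FGFR): the ternary HSPG·FGF2·FGFR complex (`HFR`) signals, the binary
FGF2·FGFR complex (`FR`) may titrate receptors away or signal weakly, and
the wiring of intracellular negative feedback further shapes the dynamics.
`erknet` is a desk-scale pipeline for asking *which network architecture
explains observed ERK dynamics*:

* **Model family** — 12 candidate ODE models crossing three receptor
  schemes (simple / competitive / competitive joint activation) with four
  feedback wirings (none / ERK-driven negative feedback / receptor-driven
  incoherent feed-forward / both), plus optional positive-feedback
  variants; 24–36 free parameters each, Michaelis–Menten cascade tiers,
  Hill-type feedback, and an explicit nonlinear FRET-sensor readout
  `r(t) = 1 + rho * EKARp(t)`.
* **Simulation** — piecewise-constant pulse schedules (sustained, single
  pulse, 3'/20' multi-pulse, mixed 3'/30'/20'/60'/5'), integrated with a
  compiled L-stable Rosenbrock scheme with exact restarts at pulse edges.
* **Inference** — nested sampling with log-uniform priors, a Gaussian
  likelihood on population-average curves, evidence `Z = ∫ L dX` with
  deterministic shrinkage `X_i = exp(-i/n_live)`, joint termination rules,
  posterior resampling and maximum-likelihood extraction.
* **Selection** — evidence ranking (`Δ log Z`), posterior-predictive
  benchmarking on held-out stimulation schemes, and an in-silico HSPG
  knockout (`HSPG_tot = 0`).
* **Trajectory analytics** — baseline normalization, DTW + hierarchical
  clustering, cluster composition summaries, PCA projection, in/anti-phase
  classification, and the Jeffries–Matusita population separability
  `d_JM(p, q) = Σ_i (√p_i − √q_i)²` with its normalized area-under-curve
  summary `d_popul = mean_k d_JM(k) / 2 ∈ [0, 1]`.
* **Synthetic data** — seeded generators for heterogeneous single-cell
  populations, the training/validation/knockout condition suite, a
  two-population separability benchmark and planted-cluster fixtures,
  driven by a committed synthetic ground-truth parameter set for model B3.

See the methods vignette (`vignettes/erknet-methods.Rmd`) for the model
equations, numerical choices, and the design rationale.

## Worked example

```r
library(erknet)

truth <- b3_reference_params()          # committed synthetic ground truth
m     <- get_model("B3")

# multi-pulse stimulation: four 3-minute 250 ng/ml pulses, 20-minute pauses
sched <- make_schedule("multi_pulse", dose = 250, width_min = 3,
                       pause_min = 20, n_pulses = 4)
sim <- simulate_model(m, truth, sched)
classify_phase(sim$readout, sched)
#> [1] "anti_phase"

# the same stimulus after knocking out the HSPG co-receptor pool
ko <- simulate_model(m, hspg_knockout(truth), sched)
classify_phase(ko$readout, sched)
#> [1] "in_phase"
round(c(max(sim$readout), max(ko$readout)), 3)
#> [1] 1.317 1.228
```

At high dose the ligand titrates FGFR into the binary complex during each
pulse while loading a large HSPG-bound reservoir; after washout the
reservoir re-forms signaling ternary complexes, so ERK activity peaks in
the *pauses* (anti-phase, peak ratio 1.317). Without HSPG only the weak
direct route remains and the response follows the pulses at reduced
amplitude (in-phase, 1.228).

```r
# population separability of two synthetic single-cell populations
fx <- generate_ev2b_fixture(mean_separation = 1, seed = 1)
population_distance(fx$a, fx$b)$d_popul
#> [1] 0.5657494
```

A command-line interface wraps the pipeline:

```sh
exec/erknet simulate --model B3 --schedule multi_pulse:250:3:20:4 --out sim.csv
exec/erknet synth --what suite --seed 1 --out data/
exec/erknet cluster --input data/train_pulse_250.csv --metric dtw \
    --linkage ward --k 6 --out labels.csv
```

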