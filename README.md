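# engramnet

Spiking-network simulation of memory-engram formation through homeostatic
structural plasticity, with the accompanying analysis battery and an
analytic memory-capacity model.

## The science

Most network models of learning change synaptic *weights*. Here the wiring
itself is the memory: neurons grow and prune synaptic *elements* (axonal
boutons and dendritic spines) so that their intracellular calcium — a leaky
integrator of their own spikes, `dCa/dt = -Ca/τ + β·[fired]` — holds a
set-point ε. Element growth follows a Gaussian rule

    dz/dt = ν ( 2 exp( -((Ca - ξ)/ζ)² ) - 1 ),   ξ = (η+ε)/2,
    ζ = (η-ε) / (2 √(-ln 0.5)),

zero at the minimum calcium η and at ε, maximal (+ν) at their midpoint.
Vacant elements decay (`dvac/dt = -vac/τ_vac`); surplus synapses are pruned
uniformly at random; vacant axons find vacant dendrites with probability
proportional to vacancy times a Gaussian kernel of distance,
`exp(-‖x_j-x_i‖²/2σ²)`, sampled exactly or through a Barnes–Hut octree
(acceptance criterion θ). Neurons are Izhikevich units
(`dv/dt = k₂v² + k₁v + k₀ - u + I`, spike-and-reset at 30 mV) driven by
normal background noise, spikes of presynaptic partners (conductance k,
weights ±1 by source type), and scheduled stimulation currents.

A network of spatial boxes, each holding disjoint excitatory ensembles
(US, C1, C2) and a static readout neuron fan-in connected from US,
undergoes a conditioned-learning protocol: baseline stimulation of each
ensemble forms strongly within-connected engrams; co-stimulation of US and
C1 wires the two engrams together; in the retrieval phase (plasticity
frozen) stimulating C1 alone re-activates US and its readout. The package
also implements pattern completion (cumulative partial stimulation of C1),
long-distance association under an enlarged kernel scale, lesion/recovery
experiments, 3-σ classification of readout rates with a KS normality
check, ensemble connectivity matrices, and the closed-form
signal-to-noise capacity model `snr(t) = snr_init (1-q)^t` with
`q = (n_engram/n_total)(s_engram/s_neuron)`.

## Worked example

Grow a 1,000-neuron box from the fully disconnected state to homeostatic
equilibrium and stimulate its US ensemble:

```r
library(engramnet)

fx  <- make_fixture("onebox-small", seed = 1)
net <- grow_network(fx$net, seed = 2, max_steps = 80000,
                    check_every = 10000, verbose = TRUE)
#> step 10000: 64.4 Hz, Ca 0.658, 6.12 syn/neuron
#> step 20000: 68.7 Hz, Ca 0.692, 8.43 syn/neuron
#> step 30000: 69.5 Hz, Ca 0.696, 8.71 syn/neuron
#> step 40000: 69.7 Hz, Ca 0.698, 8.57 syn/neuron
#> step 50000: 69.7 Hz, Ca 0.698, 8.36 syn/neuron
#> step 60000: 69.6 Hz, Ca 0.695, 8.28 syn/neuron
synapses_per_neuron(net)
#> [1] 8.282
```

Starting fully disconnected, the neurons wire themselves up until firing
settles at the set-point rate ε/(βτ) = 70 Hz and connectivity at ~8–9
synapses per neuron — the homeostatic equilibrium. Now stimulate the
50-neuron US ensemble with 20 mV for 2,000 steps and watch its readout:

```r
sch <- stim_schedule(
    stims = data.frame(start = 1000L, duration = 2000L, amplitude = 20,
                       target = "US@0", phase = "baseline"),
    end = 4000)
run <- run_simulation(net, sch, record = "readouts", seed = 3)
ro  <- net$pop$id[net$pop$kind == "readout"]
run$bins[ro, ] * 1000 / run$bin_steps     # readout rate per 1,000-step bin
#> [1] 125 203 212 117
```

The readout fires at ~120 Hz unstimulated (driven by its 50 US inputs at
70 Hz plus background) and jumps well above that while its ensemble is
stimulated — the "unconditioned reaction". How far above depends directly
on the readout's static fan-in; see the vignette for why desk-scale
readouts sit far from the 1 kHz saturation a 333-wide fan-in produces.
The full conditioning experiment is
`conditioning_schedule()` + `run_simulation()` + `classify_readouts()`;
see the methods vignette (`vignettes/homeostatic-engrams.Rmd`) for the
model, the desk-scaling rules and their limits.

The capacity model is pure arithmetic:

```r
cp <- capacity_params(n_total = 12500, n_engram = 333,
                      s_neuron = 9, s_engram = 4)
overwrite_probability(cp)
#> [1] 0.01184
memories_until(list(q = overwrite_probability(cp), snr_init = 1), 0.1)
#> [1] 194
```

A thin command-line surface over the same functions lives in
`inst/cli/engramnet.R` (subcommands `grow`, `condition`,
`pattern-complete`, `lesion`, `long-distance`, `analyze`, `capacity`).

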