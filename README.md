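# spikeye

Classification of eye movements — saccades versus fixations — from
event-camera (neuromorphic vision sensor) streams with a spiking
convolutional network, in R.

Event cameras report asynchronous per-pixel events
`e_i = (x_i, y_i, t_i, p_i)` whenever log brightness changes by more than
a contrast threshold θ, with polarity `p ∈ {−1, +1}`. Saccades (rapid
ballistic gaze shifts, ~20–300 ms) produce dense event bursts; fixations
(gaze-holding, ~50–600 ms) produce only sparse drift-driven events. The
package implements the full analysis chain:

* **events_core** — an `EventStream` S4 data model with CSV and Arrow
  container I/O, half-open time slicing, label-interval alignment, seeded
  class balancing and user-wise train/test splits;
* **eye_sim** — a synthetic near-eye scene (pupil/iris/sclera discs) with
  physiological gaze kinematics and a contrast-threshold event-camera
  emulator (`L(x,y,t) = log I`, one event per crossed θ-multiple,
  reference advanced by the crossed multiple), the fixture generator for
  everything else;
* **spike_encoding** — binary spike tensors
  `S ∈ {0,1}^{2×H×W×T}` with `S[p, y, x, ⌊t′/Δt⌋] = 1` and spike-rate
  maps `r = (1/T) Σ_t S`;
* **snn_core / spiking_convnet** — discrete CUBA-LIF dynamics
  (`u[t] = (1−α_u)u[t−1] + x[t]`, `v[t] = (1−α_v)v[t−1] + u[t] + b`,
  `s = Θ(v − ϑ)`, `v ← v(1−s)`), surrogate-gradient spike function, and
  the geometry-parameterized architecture
  Conv(2→8,3×3,s2) → Pool → Conv(8→8,3×3,s1) → Pool → Flatten →
  Dense(→103) → Dense(→117) → Output(→2), decoded by output spike rate
  `ŷ = argmax_i (1/T) Σ_t s_i[t]`;
* **train_eval** — spike-rate loss
  `L = ½‖(1/T)Σ_t s(t) − r̂‖²` with `r̂ = r_true·1[l] + r_false(1−1[l])`,
  hand-authored backpropagation through time with surrogate gradients,
  Adam, classification metrics and a temporal-resolution sweep
  (effective FPS = 1000/window);
* **complexity** — SNN-vs-ANN operation accounting (events, synops,
  activations, MACs) under the uniform fan-out convention, sparsity
  ratios, and the energy estimate
  `E(F) = T·(f_r·E_AC·O_AC + E_MAC·O_MAC)`.

At the native 360×260 sensor geometry the architecture's arithmetic comes
out exactly: flatten size 11,264; trainable parameters
144 + 576 + 1,160,192 + 12,051 + 234 = 1,173,197; equivalent-ANN MAC
total 4,771,157; activation total 287,366.

## Worked example

A desk-scale end-to-end run: simulate a labelled synthetic dataset at
64×64, split by synthetic participant, train the spiking classifier for
20 epochs at a 33-ms accumulation window (1-ms bins), and evaluate on the
held-out users:

```r
library(spikeye)

scene <- sceneModel(width = 64, height = 64)
kin   <- kinematicsParams(sacAmplitudePx = c(8, 25))
segs  <- generateDataset(scene, kin, emulatorParams(),
                         nPerClass = 150, seed = 101)
split <- splitByUser(segs, trainUsers = 1:7, testUsers = 8:10)

net <- buildSpikingConvNet(width = 64, height = 64)
fit <- trainNetwork(net, split$train,
                    trainConfig(epochs = 20, seed = 42,
                                learningRate = 0.001, rTrue = 0.5),
                    windowMs = 33)
m <- evaluateNetwork(fit$net, split$test, windowMs = 33)
unlist(m[c("accuracy", "precision", "recall", "f1")])
```

```
 accuracy precision    recall        f1
        1         1         1         1
```

(210 training / 90 held-out segments; the training loss falls from 0.082
to 0.012 over the 20 epochs.)

Accuracy is the fraction of held-out windows classified correctly;
precision/recall treat saccade as the positive class. The complexity
report mirrors the operation-accounting table:

```r
ann <- countAnnMacs(buildSpikingConvNet())   # full geometry
ann[, c("node", "stage", "units", "macs")]
attr(ann, "total")                           # 4771157
```

A thin CLI over the same functions lives at `inst/cli/spikeye-cli.R`
(subcommands `simulate`, `encode`, `train`, `eval`, `sweep`, `profile`,
`run`).

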