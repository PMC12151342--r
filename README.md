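# thermoplaid

Simulation and analysis of closed-loop "thermal plaid" behavior experiments
in larval zebrafish.

## The problem

Larval zebrafish swim in discrete bouts (100–200 ms of tail beating
separated by 0.5–1.8 s rests) and navigate temperature gradients to
thermoregulate. In a closed-loop assay, an infrared laser steered by online
tracking couples the water temperature to the fish's position through a
doubly periodic power landscape,

    P(x, y) = 750 mW · (0.5 sin(2πx/15) + 0.5 sin(2πy/15)) + 1250 mW,

spanning 25–28 °C, so every swim changes the temperature the fish
experiences (sensorimotor feedback). A yoked *replay* fish passively
receives the identical temperature sequence, decoupled from its own
movement. Comparing the two conditions asks whether the fish processes
thermal stimuli differently when it causes them.

`thermoplaid` provides, for simulated data with known ground truth:

- a bout-based virtual fish whose swim initiation follows a logistic policy
  on one-second temperature and bout histories, plus yoked replay pairing
  (`simulate_fish()`, `make_replay_pair()`);
- swim-bout detection from tail-angle traces via sliding-window vigor
  (`swim_vigor()`, `detect_bouts()`, `bout_kinematics()`, `edge_filter()`);
- a convolutional-network encoder of swim probability per 40 ms bin,
  trained with binary cross-entropy (`build_inputs()`, `train_encoder()`),
  with a circular-permutation null control;
- receptive fields extracted by differentiating the trained network —
  the change in swim log-odds per °C at each of 25 history lags — and
  their transformation into bout-frequency modulation,
  Δp(t) = logistic(k·s(t) + logit(p̄)) − p̄, Δbf = Δp · 25 s⁻¹
  (`extract_rf()`, `rf_effect()`, `rf_modulation_summary()`);
- a linear decoding comparison: mixed-selectivity (coincidence-detector)
  neuron activity → 10 principal components → ridge logistic classification
  of closed-loop vs replay, benchmarked against classifiers on the raw
  inputs over 0–10 s integration windows (`decode_feedback_condition()`);
- fish-level bootstrap statistics for clustered behavioral data
  (`bootstrap_ks()`, `binned_density_with_se()`).

The simulator is first-class, tested code: its generative kernels are the
ground truth against which receptive-field recovery is measured.

## Worked example

```r
library(thermoplaid)

field <- plaid_field()
power_at(field, 3.75, 3.75)            # warmest point
#> [1] 2000
plaid_repeat_distance(field, "diagonal")
#> [1] 21.2132

# simulate a yoked pair and detect bouts
pol  <- generative_policy()
plaid <- simulate_fish(pol, field = field, duration_s = 300, seed = 42)
pair  <- make_replay_pair(plaid, policy = pol, seed = 43)
bouts <- extract_bouts(plaid)
nrow(bouts)
#> [1] 156

# temperature change during bouts vs matched random intervals
dT <- per_bout_delta_t(bouts, plaid$temp_c, seed = 1)
tapply(dT$delta_t, dT$interval, median)
#>      bout   control 
#> 0.3613872 0.0000000

# fit the swim-probability encoder and extract the receptive field
inp <- build_inputs(list(plaid, pair$replay))
m   <- train_encoder(inp, epochs = 30, batch = 256, lr = 2e-3, seed = 1)
evaluate_roc_auc(m, inp)               # held-out classification
#> [1] 0.6889507
rf  <- extract_rf(m, inp, seed = 1)
cor(rf$temp_coeffs, pol$temp_kernel)   # recovery of the generative kernel
#> [1] 0.7296467
autoplot(rf)                           # coefficients vs time before a bout
```

The per-bout temperature change (median ≈ 0.36 °C here) exceeds the
stationary-interval control (exactly 0 between bouts, since a simulated
closed-loop fish only changes temperature by moving); in replay the two are
indistinguishable. Held-out ROC-AUC of 0.69 means the network ranks a
random bout bin above a random non-bout bin 69% of the time. Kernel
recovery improves with data: at the study scale used in the acceptance
suite (20 experiments × 10 min, 10 fits), the median correlation between
extracted and generative temperature kernels exceeds 0.8.

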