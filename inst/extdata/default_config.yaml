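# Default model configuration.
# Intrinsic parameters (time constants, alpha, sigma, gains) are the
# baseline values of the model; kernel widths, pool gain and noise
# amplitudes are the package calibration (see the methods vignette).
circuit:
  n_neurons: 72
  gamma: 1.0          # feedback gain (per edge in three-area topologies)
  beta: 1.0           # input gain
  tau_y: 1.0          # ms
  tau_u: 1.0
  tau_a: 1.0
  tau_q: 1.0
  alpha: 10.0         # derivative coupling in the gain dynamics
  sigma: 0.07         # semisaturation constant
  half_width: 30      # tuning-curve half width, degrees
  excit_width: 3      # recurrent kernel, excitatory center SD, degrees
  inhib_width: 30     # recurrent kernel, inhibitory surround SD, degrees
  inhib_strength: 0.003
  feedback_width: 15  # feedback kernel SD, degrees
  diag_boost: 2.0     # diagonal / off-diagonal row mass of the feedback
  pool_gain: 1.3      # normalization-pool strength
  identity_recurrent: false
noise:
  synaptic_amp: 1.0   # low-pass synaptic noise amplitude
  tau_noise: 1.0      # ms
  mult_amp: 0.1       # multiplicative rate-noise coefficient
  extrinsic_amp: 0.05 # extrinsic LFP noise amplitude
  extrinsic_corr: 0.5 # extrinsic noise correlation across areas
experiment:
  contrast_grid: [0, 1, 3, 6, 10, 12, 25, 40, 50, 75, 100]
  gamma_low: [0.1, 0.25, 0.5]
  gamma_high: [1.0, 1.1]
  freq_step_hz: 1.0
  subset_size: 30
  n_repeats: 25
  seed: 1
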