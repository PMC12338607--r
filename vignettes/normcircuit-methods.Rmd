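---
title: "Hierarchical normalization circuits: model, analytics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical normalization circuits: model, analytics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(normcircuit)
```

## The model

`normcircuit` implements a hierarchy of recurrently connected cortical
areas, each a ring of orientation-tuned columns with four cell types per
column: principal excitatory cells $y$, modulatory excitatory cells $u$,
and two modulatory inhibitory populations $a$ and $q$. The circuit
implements *divisive normalization dynamically*: instead of imposing the
normalization equation as a static input-output rule, the modulator cells
compute the normalization signal on the fly and feed it back as a recurrent
gain, so that normalization is the stable fixed point of the dynamics.

Writing $\lfloor v \rfloor$ for (smoothed) rectification and
$y^+ = \lfloor y \rfloor^2$ for firing rates, each area obeys

$$
\begin{aligned}
\tau_y \dot y &= -y + \tfrac{\beta}{2} z
  + \frac{1}{1+\lfloor a \rfloor}\odot
  \Big(W_r \lfloor y \rfloor + G \odot \lfloor q \rfloor\Big),\\
\tau_u \dot u &= -u + \tfrac{\sigma^2}{2} + N\,(y^+ \odot \lfloor u\rfloor),\\
\tau_a \dot a &= -a + H + \hat u + a \odot \hat u + \alpha\,
  \frac{d\hat u}{dt},\qquad \hat u = \sqrt{\lfloor u \rfloor / 2},\\
\tau_q \dot q &= -q + \lfloor y \rfloor,
\end{aligned}
$$

where $z$ is the feedforward drive (the stimulus convolved with the tuning
curves for the input area, $W_{ff}\,y^+_{\mathrm{lower}}$ above it),
$G = \sum_e \tfrac{\gamma_e}{2} W_{fb,e}\, y^+_{\mathrm{higher}}$ is the
gain-scaled feedback drive onto the principal cells (gated by the
$q$-interneuron signal), and $H = \sum_e \tfrac12 W_{fb,e}\,
y^+_{\mathrm{higher}}$ is the fixed half-strength feedback onto the
inhibitory gain population. The factors of $\tfrac12$ reflect the model's
two fixed routing fractions: half of the input drive targets the
modulatory pathway, and the feedback to the inhibitory population is fixed
at one half. $N$ is the all-ones normalization pool, scaled as described
below.

### Why the fixed point is exactly the normalization equation

Let $s = \sigma^2 + \mathbf{1}^\top\kappa\, z^2$ be the normalization
denominator ($\kappa$ the pool scale) and suppose $\beta=\gamma=1$ and
$W_r = I$. Substituting the candidate solution $y = z/\sqrt{s}$, i.e.
$y^+ = z^2/s$:

* the $u$-equation has the uniform solution $u^\ast = s/2$, because the
  pool term satisfies $\kappa\sum_j y_j^{+}u = u\,(s - \sigma^2)/s$ and
  therefore $u = \sigma^2/2 + u\,(1 - \sigma^2/s)$, giving
  $\hat u^\ast = \sqrt{s}/2 \equiv x$;
* the $q$-equation gives $q^\ast = \lfloor y \rfloor$, so the feedback
  gating equals the rectified membrane potential;
* the $a$-equation then gives $a^\ast = (x + H)/(1 - x)$, which is finite
  for all neurons (including undriven flank neurons) provided $s < 4$;
* substituting into the $y$-equation, the recurrent gain becomes
  $1/(1+a^\ast) = (1-x)/(1 + P/2)$ with $P = W_{fb}\,y^+_2$, and the drive
  $\lfloor y\rfloor (1 + P/2)$ cancels the feedback factor exactly, leaving
  $y = z/2 + (1-x)\,y$, i.e. $y = z/\sqrt{s}$.

Two structural choices make this work for *every* neuron. First, the
recurrent and feedback drives act on rectified membrane potentials
$\lfloor y \rfloor$ (the square root of the firing rate), as in earlier
single-area formulations of this circuit family; if they acted on the
squared rates, undriven neurons that receive spread-out feedback would
need unbounded gain to stay silent, and no exact normalization solution
would exist. Second, the feedback onto principal cells is gated by the
$q$-signal, which tracks $\lfloor y \rfloor$; at balanced gains the
feedback excitation of $y$ and the feedback drive onto $a$ then cancel
exactly, so the lower area's fixed point is *feedback-invariant* at
$\gamma = 1$ — the property that lets a hierarchy of areas all satisfy the
normalization equation simultaneously. For $\gamma \ne 1$ the fixed point
shifts (computed by damped Newton iteration seeded with the analytic
solution); $\gamma < 1$ tilts the feedback toward inhibition, $\gamma > 1$
toward excitation.

The derivative coupling $\alpha\, d\hat u/dt$ makes the gain population
respond to the *rate of change* of the normalization signal. It does not
move the fixed point, but it shapes the linearized dynamics strongly; with
the default $\alpha = 10$ it is the main source of the fast resonances.

### Normalization pool scale

The normalization matrix is all ones — every neuron contributes equally —
scaled by `pool_gain` divided by the squared norm of the population
response to a full-contrast stimulus (a rotation-invariant constant of
the geometry, about 9 for the default 72-neuron ring with 30-degree
raised-cosine tuning). With this scale the normalization denominator at
contrast $c \in [0,1]$ is exactly $\sigma^2 + \texttt{pool\_gain}\cdot
c^2$, the peak firing rate follows a hyperbolic ratio in $c^2$, and the
semisaturation constant is $\sigma/\sqrt{\texttt{pool\_gain}}$. An
unscaled all-ones pool would make the denominator reach $\approx 9$ at
full contrast, for which the principal-cell equation has no feasible gain
(the balanced solution requires $s < 4$). The default `pool_gain = 1.3`
was calibrated once, together with the kernel widths below, so that the
high-contrast resonance falls in the gamma band (see *Calibration*).

## Geometry and connectivity

* **Tuning curves** are raised cosines
  $\cos^2\!\big(\pi d / (2 w)\big)$ of the circular orientation distance
  $d$ (180-degree wrap), with half-width $w = 30°$ and unit peak.
  The input drive is `contrast/100` times the tuning curve — an idealized
  thalamic stage.
* **Recurrent kernels** are circulant differences of circular Gaussians,
  rescaled to unit spectral radius. The defaults (excitatory SD 3°,
  inhibitory SD 30°, surround strength 0.003) give a narrow self-excitation
  with a weak, broad inhibitory surround: near connections excitatory,
  the most distant connections inhibitory. The narrowness is deliberate —
  it keeps the kernel's eigenvalue spectrum flat across the spatial modes
  that carry the activity bump, so the fixed point stays close to the
  normalization solution and the low-contrast (alpha-band) resonances
  survive. Strong broad surrounds damp the slow spatial modes and abolish
  the low-frequency phenomenology.
* **Feedback kernels** are circular Gaussians (SD 15°) whose diagonal is
  set to `diag_boost` (default 2) times the off-diagonal row mass, then
  row-normalized; this makes them symmetric, nonnegative and row-wise
  diagonally dominant, and the feedforward matrix is their transpose
  (hence identical).

## Noise model and linear response

Around the operating point, fluctuations obey
$dx = J\,(x - x^\ast)\,dt + L\,dW$. Three noise sources:

1. **Low-pass synaptic noise**: one Ornstein-Uhlenbeck state per membrane
   equation (time constant `tau_noise`), entering that equation scaled by
   its membrane time constant. Its low-frequency spectral density is
   `synaptic_amp`$^2$ per channel.
2. **Multiplicative rate noise**: white forcing on the principal-cell
   equations with frozen-coefficient amplitude `mult_amp` times the
   fixed-point firing rate (the standard small-noise linearization of
   state-multiplicative noise).
3. **Extrinsic noise**: a white component added to the *LFP observation
   only* (amplitude `extrinsic_amp`, inter-areal correlation
   `extrinsic_corr`); it never enters the dynamics.

The cross-spectral density follows the resolvent formula
$S(\omega) = A(i\omega I + J)^{-1} Q(\omega)(-i\omega I + J)^{-\top}
A^\top$ with the auxiliary noise states folded in analytically (the
forcing spectrum $Q(\omega)$ is diagonal: white multiplicative terms plus
the OU Lorentzian). It is evaluated once per frequency from a complex
Schur decomposition of the circuit Jacobian. Spectra are two-sided
densities per Hz, so $\int_0^\infty 2\,\mathrm{Re}\,S\,df = C(0)$; the
stationary covariance $C(0)$ itself solves the Lyapunov equation
$JC + CJ^\top = -LDL^\top$ (block Bartels-Schur solver). A compiled
Euler-Maruyama simulator provides the empirical oracle for both.

### Operating point and spontaneous activity

Fixed points are solved with the hard rectification (the normalization
identity is then exact to machine precision). For linear-response
analyses the operating point is re-solved under the Gaussian-rectification
smoothing (width $10^{-3}$): with a smooth rectifier the resting state
sits slightly above threshold, which gives spontaneous activity a slow,
lively baseline spectrum. Driven fixed points are essentially unaffected
(the membrane potentials are far from threshold), but the baseline
spectrum — and therefore the normalized power
$(P - P_0)/(P + P_0)$ — depends on this choice.

## Communication subspaces

From the covariance $C(0)$ of the principal-cell rate fluctuations
($\delta r = 2\lfloor y^\ast\rfloor\,\delta y$), source and target
populations give $C_1, C_2, C_3$; the optimal linear readout is
$B = C_1^{-1} C_3$, the predicted target covariance
$\hat C_2 = C_3^\top C_1^{-1} C_3$, and the prediction performance at rank
$i$ is the cumulative eigenvalue sum of $\hat C_2$ over the total target
variance. Two dimensionality criteria are reported: the 95%-of-full-
performance rank (default) and the numerical rank of $\hat C_2$ (equal to
the rank of $C_3$ when $C_1$ is full rank). Subset-averaged curves draw
30-neuron source/target subsets (disjoint within an area) 25 times under
a fixed seed and report mean ± SEM (unbiased standard deviation over
$\sqrt{n}$).

The frequency decomposition replaces $C(0)$ with the narrow-band
covariance $\mathrm{Re}\,S(f)$ (the band-width prefactor drops out of the
performance, which is invariant to global scaling) and repeats the same
subset protocol at every frequency with identical subset draws.

## Calibration

The intrinsic parameters are fixed at their baseline values ($\tau = 1$
ms for all four cell types, $\alpha = 10$, $\sigma = 0.07$,
$\beta = \gamma = 1$). The free structural knobs — kernel widths, pool
gain, rectification smoothing and the noise amplitudes — were calibrated
*once*, against the qualitative spectral targets (a gamma-band resonance
at 40–60 Hz at high contrast whose normalized peak is largest near 40%
contrast; an alpha-band peak near 10 Hz at low contrast and low feedback
gain that vanishes at high feedback gain; a $1/f^4$ high-frequency tail;
beta-band inter-areal coherence at low contrast), and then frozen in
`inst/extdata/default_config.yaml`. Probing these targets uses
band-restricted peak extraction with the conventional band edges (alpha
3–20 Hz as implemented for low-frequency peaks, gamma 30–80 Hz, a broad
8–90 Hz window for peak-shift monotonicity).

Problem sizes used throughout the shipped analyses: 72 neurons per cell
type per area (576 circuit states for two areas), 1 Hz frequency grids to
1 kHz for spectral features, a 0.05–5000 Hz composite grid for the
spectral-integral consistency check, and 10-second stochastic simulations
at dt = 0.01 ms for the empirical oracle.

## What the synthetic conditions do and do not show

All inputs are idealized gratings (a contrast and an orientation); the
generator produces no naturalistic images, no trial structure, and no
spiking variability — fluctuations are Gaussian by construction, so the
subspace analytics are exact population quantities rather than estimates
from finite trials. Passing tests therefore demonstrate internal
consistency of the analytics and the stated emergent phenomena of this
reconstruction, not goodness-of-fit to any recorded dataset.

## Known limitations

* The modulator equations were reconstructed from the printed structure
  plus the exact-normalization requirement; other closures exist (the
  `u_input_mix` option implements one alternative, in which part of the
  modulatory drive comes from the squared feedforward input rather than
  the recurrent rate pool; both close the same fixed point). Three
  consequences of the closure used here that differ from the
  phenomenology reported for this circuit family: the relative rate
  increase from raising the feedback gain is larger in the lower area
  than in the higher area; inter-areal prediction performance is largest
  at low frequencies at every contrast (the slow shared
  normalization-pool fluctuations dominate the band-limited covariances,
  so the frequency-resolved communication profile does not mirror the
  coherence resonances, which do peak in the beta/gamma range); and the
  gamma-band normalized-power peak height is maximal near 25% rather than
  40% contrast (normalized power saturates near 1 at low contrast because
  the driven resonances dwarf the spontaneous baseline).
* Freezing the recurrent gain at its operating point (the
  normalization-removed control) leaves an unstable linear system at
  driven operating points: the dynamic normalization loop is also the
  stabilizer, so without it no stationary spectrum - and a fortiori no
  gamma resonance - exists.
* The higher area's contrast-response function can supersaturate by a few
  percent past its peak.
* Interior coherence peaks are extracted in a 10-120 Hz window (beta +
  gamma); sub-10 Hz local maxima of coherence are treated as part of the
  low-frequency regime, not as "the" coherence peak (alpha-band activity
  appears as a coherence dip).
* Feedback is instantaneous (no conduction delays), weights are fixed (no
  plasticity), and the LFP proxy is a plain sum of principal-cell
  membrane potentials.

## A worked example

```{r example, eval = FALSE}
circ <- two_area_circuit()
crf <- run_crf(circ)
crf$fits$V1$c50; crf$fits$V2$c50   # semisaturation contrasts, V2 < V1

lin <- linearize_circuit(circ, stimulus(50, 0))
sys <- build_stochastic_system(lin, noise_spec())
i <- principal_index(circ, "V1")[which.max(lin$rates$V1)]
sp <- psd(sys, freqs = seq(1, 1000, by = 1), channels = i)
highfreq_slope(sp$freqs, auto_spectrum(sp), c(300, 1000))  # ~ -4
```
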