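---
title: "Theta-modulated plasticity and the emergence of replay in a ring network of place cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-modulated plasticity and the emergence of replay in a ring network of place cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(thetaring)
```

## The model

`thetaring` simulates a recurrent network of N hippocampal place cells on a
periodic (ring-like) track and the slow reorganization of its synaptic
connectivity by spike-timing-dependent plasticity (STDP) during exploration.
The firing rate of cell $i$ obeys

$$\tau \dot r_i = -r_i + \phi\!\left(\frac{1}{N}\sum_j (w_{ij} - w_I)\, x_j
r_j + I_i(t)\right),\qquad \phi(I) = \alpha \log(1 + e^{I/\alpha}),$$

with rate time constant $\tau = 10$ ms, transfer smoothness $\alpha = 1$ Hz
and a global inhibitory offset $w_I = 65$ subtracted from every excitatory
weight. Each cell carries a short-term synaptic depression variable
$\dot x_i = (1 - x_i)/\tau_x - U_0 x_i r_i$ ($\tau_x = 800$ ms,
$U_0 = 8\times 10^{-4}$) that gates its outgoing synapses and is responsible
for transient, sharp-wave-like population bursts during quiescence. Cells
fire as inhomogeneous Poisson processes (one Bernoulli draw with
$p = r_i\,\Delta t$ per step), and *only* the spikes drive plasticity — the
rate dynamics are otherwise deterministic given the trajectory.

The place-field input on track $\mu$ is a cosine bump at the animal's
position $X(t)$ with multiplicative theta modulation,

$$I_i = I_0 + I_{PF}\cos(\theta_i^\mu - X(t))\,(1 + I_\theta
\cos 2\pi f t),$$

with defaults $I_0 = 3$ Hz, $I_{PF} = 25$ Hz, $I_\theta = 1$, $f = 8$ Hz.
Global remapping is modeled by drawing the place-field centers
$\theta_i^\mu$ independently and uniformly on each track
(`remap_tracks()`), so the ordering of cells on one track carries no
information about any other. The virtual animal moves with velocity
$v_0 + v_1(t)$, where $v_1$ is an Ornstein–Uhlenbeck process
($\tau_v = 10$ s, $\sigma_v = 2$ rad/s, $v_0 = 0.5$ rad/s); a constant-
velocity mode is available for the analytic comparisons.

STDP is implemented online with exponential spike traces. A pre-before-post
pair with latency $T$ potentiates by $A_+ e^{-T/\tau_+}$ and the reverse
order depresses by $A_- e^{T/\tau_-}$; the default
potentiation-dominant rule ($A_+ = 0.1$, $\tau_+ = 20$ ms, $A_- = 0.1/3$,
$\tau_- = 60$ ms) is *balanced*, $A_+\tau_+ = A_-\tau_-$, so constant rates
cause no net drift of the mean weight. A triplet extension adds slower
second traces so that recent postsynaptic (presynaptic) activity amplifies
potentiation (depression); `is_balanced()` reports all balance residuals.
Weights are clipped to $[0, w_{max} = 80]$ and start at $w_{init} = 40$;
autapses are never updated.

## Mean-field theory of connectivity growth

In the slow-plasticity limit the expected drift of the weight profile
depends only on the place-field offset and decomposes into Fourier modes
$w_0 + w_{even}\cos\Delta\theta + w_{odd}\sin\Delta\theta$. For
cosine-tuned activity $r = r_0 + r_{PF}\cos(\theta - v t)$ the package
implements the closed forms (`pair_growth_const_v()`, `triplet_growth()`),
e.g.

$$\dot w_{even} = \frac{r_{PF}^2}{2}\left[\frac{A_+\tau_+}{1 + \tau_+^2 v^2}
 - \frac{A_-\tau_-}{1 + \tau_-^2 v^2}\right],$$

and the general quadrature $\int K(T)\,\mathrm{AC}(T)\,dT$
(`growth_from_AC()`), which serves as the independent oracle for every
closed form in the test suite. Theta modulation splits the drive into three
traveling components at $v$ and $v \pm 2\pi f$ (`growth_with_theta()`); the
sidebands dominate the even-mode growth by orders of magnitude because they
modulate the autocorrelation on a time scale commensurate with the
plasticity window. The growth is maximal at
$f^\ast = 1/(2\pi\sqrt{\tau_+\tau_-}) \approx 4.59$ Hz for the default
windows — inside the theta band:

```{r sweep}
sweep <- growth_frequency_sweep(pair_rule(), v = 1)
attr(sweep, "f_opt")
plot(sweep)
```

`selfconsistent_coefficients()` gives the linear-response rate coefficients
of the driven ring at given connectivity modes, and
`depression_corrected_rates()` the depression-corrected effective
coefficients (the uniform fixed point is found by a bracketing root solve,
the spatial response by a 2-by-2 linear system per velocity component).
Averaging over a symmetric velocity distribution
(`growth_with_velocity_dist()`) kills the odd mode exactly: direction bias,
not modulation, writes the connectivity asymmetry.

## Replay instability

Without place-field input the uniform quiescent state destabilizes to a
traveling wave — the model's replay event — when
$w_{even}\, x_0\, \phi' > 2$, where $\phi'$ is the transfer gain at the
quiescent operating point (`quiescent_operating_point()`) and $x_0$ the
depression fixed point. `eigenvalues_spatial_mode()` implements the analytic
eigenvalues, `critical_even_mode()` the threshold $2/(\phi' x_0)$, and
`jacobian_threshold_oracle()` verifies it numerically by bisection on the
spectrum of the discretized linear ring.

```{r stability}
critical_even_mode(gain = 1, x0 = 1)
jacobian_threshold_oracle(N = 100, gain = 1)$threshold
```

## Sequential correlation

The sequential correlation (`sequential_correlation()`) of a rate matrix
under an ordering is the mean zero-lag Pearson correlation of the $N-1$
adjacent pairs (an open chain). It is affine- and time-permutation
invariant; cells with zero variance in a window are dropped from their
pairs with a warning, and windows with fewer than two usable pairs yield
`NA` rather than 0. `shuffle_null()` recomputes the SC under uniformly
random orderings — the pairwise correlation matrix is computed once, so
5000 shuffles are effectively free — and returns the empirical p-value of
an observed ordering. `sc_transition_time()` operationalizes the replay
transition as the first probe whose SC exceeds half the asymptotic SC
(mean of the final 20% of probes) and stays above it; series whose
asymptote is below 0.2 are reported as having no transition, which guards
against spurious "transitions" in flat, near-zero series.

## The synthetic-recording generator

`synth_recording()` emulates a silicon-probe session on a periodic track:
an OU-velocity trajectory with a clockwise bias, cosine-tuned rates with
cell-specific baselines (2–4 Hz), tuning amplitudes (8–15 Hz) and uniform
phases, multiplicative theta modulation (depth 1 at 8 Hz by default), and
Poisson spiking at 1 ms resolution. Rates are rectified at zero, so
strongly tuned cells have half-wave place fields like real data. The
generator reproduces the statistical structure the analysis pipeline
relies on — spatial tuning, theta comodulation, Poisson variability — but
not spike-sorting artifacts, non-stationary representations (it assumes
stable fields), theta phase precession, or ripple-band structure; passing
tests therefore validate the pipeline's statistics, not those aspects of
real recordings.

The analysis chain mirrors the experimental one: occupancy-normalized rate
maps on 50 position bins (`rate_map_1d()`, no smoothing by default since
the reference analysis states none), a two-harmonic cosine fit
(`fit_cosine_model()`, identical to the first two FFT coefficients on a
uniform grid), selection by tuning index $TI = r_1/r_0 \ge 1$ (lax preset
0.5) and mean rate > 0.4 Hz, phase ordering, and windowed SC against
5000-shuffle nulls with Bonferroni correction across 3-min windows.

## Numerical choices

* **Integration**: forward Euler, default $\Delta t = 1$ ms
  (configurable); traces decay *exactly* ($e^{-\Delta t/\tau}$
  multipliers) so plasticity tests carry no integration error. The
  compiled engine and a pure-R reference engine perform identical updates
  in identical RNG order and agree to floating-point rounding.
* **Update order** per step: motion, input (at the new time and position),
  Euler update of rates and depression, spike draws from the updated
  rates, plasticity.
* **Simultaneous spikes**: weight increments are computed from traces
  *before* their own-spike increments (so exactly coincident pre/post
  spikes do not interact), increments are accumulated before clipping, and
  clipping to $[0, w_{max}]$ happens once per step.
* **OU discretization**: $v_1 \leftarrow v_1 - v_1\,\Delta t/\tau_v +
  (\sigma_v/\tau_v)\sqrt{\Delta t}\,\eta$; the continuum equation is
  dimensionally ambiguous, so the alternative scaling
  $\sigma_v\sqrt{\Delta t/\tau_v}$ is exposed as a configuration switch
  and the choice is recorded in every run manifest.
* **Angles**: positions live in $[-\pi, \pi)$; offsets are wrapped
  differences in $(-\pi, \pi]$ with the convention
  $\Delta\theta = \theta_{post} - \theta_{pre}$, so $w_{odd} > 0$ means
  stronger connections in the direction of motion.
* **Fourier modes**: `fourier_modes()` is the least-squares first-harmonic
  fit. On a complete uniform offset grid this equals the discrete
  projections $2\langle w\cos\Delta\rangle$ etc.; computed directly on a
  weight matrix it avoids the $O(1/N)$ leakage of the mean weight into the
  even mode that the naive projection suffers when the diagonal is
  excluded.
* **Quadrature**: kernel integrals are truncated at
  $40\max(\tau_+, \tau_-)$, where the exponential tail bounds the error at
  $\sim 10^{-17}$ of the kernel mass.
* **Tracks**: between tracks, traces and depression variables are reset
  and weights are carried over — only the weight matrix stores memory.

## Desk-scale protocols and what they show

The headline network phenomena develop over simulated hours in a
100-cell network. The test suite reproduces them at desk scale with three
compressions, all reported here because they are choices, not
consequences of the theory:

1. **Amplitude boosting** (`scale_rule()`): growth rates are linear in the
   STDP amplitudes, so a boost of 5 compresses learning time fivefold.
   Boosting has a ceiling: weight *diffusion* scales with the squared
   amplitudes while drift is linear, so at large boosts the even mode
   saturates well below the replay threshold. The suite verifies the
   linear-regime prediction directly (simulated growth within 3 SE of the
   closed forms over 10 seeds).
2. **Accelerated input**: sessions probing the burst-SC transition raise
   $I_{PF}$ from 25 to 35 Hz, the same acceleration used in the model's
   own input-amplitude variation, which shifts transitions to earlier
   times without changing the mechanism.
3. **Surrogate pre-training**: transition sessions start from a
   connectivity with an even mode of 13 (about the saturated trained
   value) in a *previous* track's ordering, standing in for the hours of
   prior exploration that make pre-transition bursts structured — and
   hence make the novel-track burst SC start near zero. At full scale the
   same crossing occurs from scratch, only slower.

Under these conditions the burst SC on a novel track transitions within a
4000 s session at $f = 8$ Hz and does not at 0.5 Hz or 50 Hz, while the
odd mode grows identically at all three frequencies — isolating the even
mode as the driver, as the theory requires. For cued replay after sparse-
coding training (coding level 0.5, three tracks), the evoked expression of
a stored map at desk-scale amplitudes is dominated by the
pattern-formation transient after cue onset rather than by a long
traveling wave; the SC readout therefore scores the evoked epoch from 50
ms after onset. Selective cues then retrieve the cued track's ordering as
the argmax across stored tracks.

Problem sizes used by the automated checks: N = 100 cells (the standard
network) for all protocol simulations — smaller rings make the off-band SC
controls too noisy — and N = 64 for the Monte Carlo growth-rate
comparisons, whose mean-field prediction is N-independent; sessions of
40–4000 s of simulated time; 10-seed ensembles; 35-min synthetic
recordings of 50 cells; 5000-shuffle nulls.

## Known limitations

* Euler integration biases oscillatory rate amplitudes by $O(\Delta
  t/\tau)$; theory-validation tests run at $\Delta t = 0.02$–0.1 ms.
* The SC is degenerate (all pairwise correlations near 1) when activity is
  spatially uniform or near-silent, as in an untrained quiescent network;
  protocol analyses therefore compare structured states, mirroring the
  experimental situation where prior environments always structure the
  bursts.
* Balanced triplet rules leave only near-cancelling residuals of the
  large A3 terms in the growth rates; Monte Carlo validation probes the
  pure-triplet term separately, where it is resolvable.
* No ripple-frequency oscillations, no spiking (integrate-and-fire)
  dynamics, no plasticity of feed-forward inputs, and no 2-D tracks: the
  model is a rate model on a ring by construction.
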