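# thetaring

Simulation and theory of how theta-rhythm-modulated synaptic plasticity
sculpts the recurrent connectivity of a hippocampal place-cell network and
thereby gives rise to spontaneous replay.

## Who this is for

Computational neuroscientists studying hippocampal sequence learning: the
package provides (i) a stochastic firing-rate simulator of N place cells on
periodic tracks with online STDP, short-term synaptic depression,
theta-modulated place-field input and a virtual animal; (ii) the closed-form
mean-field theory for the slow growth of the connectivity's spatial Fourier
modes; (iii) the linear stability analysis of the quiescent state (the
traveling-wave replay instability); and (iv) the sequential-correlation (SC)
statistic with shuffle nulls, plus a place-field characterization pipeline
and a synthetic-recording generator for end-to-end validation.

## The model in brief

Rates follow a ring network with global inhibition and depression-gated
recurrence,

    tau r_i' = -r_i + phi( (1/N) sum_j (w_ij - w_I) x_j r_j + I_i(t) ),
    phi(I) = alpha log(1 + exp(I/alpha)),

driven by a theta-modulated cosine place field,
`I_i = I0 + IPF cos(theta_i - X(t)) (1 + Itheta cos(2 pi f t))`. Spikes are
Poisson from the rates and drive pairwise (or triplet) trace STDP with kernel
`K(T) = A+ exp(-T/tau+)` for `T >= 0`, `-A- exp(T/tau-)` for `T < 0`. In the
slow-plasticity limit the mean weight profile `w(Δθ)` drifts as

    d/dt w_even = ∫ K(T) AC(T) dT,

the integral of the plasticity window against the autocorrelation of
place-cell activity. Theta modulation at frequency `f` folds the
autocorrelation to the time scale of the window, and the even-mode growth
peaks at `f* = 1/(2 pi sqrt(tau+ tau-)) ≈ 4.6 Hz` for the default 20/60 ms
windows. Replay emerges as a traveling-wave instability of the quiescent
state once `w_even * x0 * phi' > 2`.

## Worked example

```r
library(thetaring)

## 1. where in frequency does connectivity learning peak?
sweep <- growth_frequency_sweep(pair_rule(), v = 1)
attr(sweep, "f_opt")
#> [1] 4.552935

## 2. how strong must the even mode get before replay appears?
op <- quiescent_operating_point(40, network_params(), I0 = 3,
                                dep = depression_params())
critical_even_mode(op$gain, op$x0)
#> [1] 11.90171

## 3. does a synthetic recording show sequential structure?
rec  <- synth_recording(n_cells = 50, duration = 600, seed = 8)
maps <- rate_map_1d(rec$events, rec$trajectory)
fits <- lapply(1:50, function(i)
  fit_cosine_model(maps$rate[i, ], maps$positions, maps$mean_rate[i]))
ordv <- phase_ordering(fits, select_cells(fits))
R    <- bin_spikes(rec$events, 600, 0.5, n_cells = 50)
set.seed(9)
shuffle_null(R, 5000, ordering = ordv)
#> SC shuffle null: mean = 0.0052, sd = 0.0648 (5000 shuffles)
#> observed SC = 0.7085 (empirical p = 0.0002)
```

The first number is the modulation frequency (Hz) that maximizes the growth
of the even (cosine) connectivity mode — inside the theta band. The second is
the critical even-mode amplitude at the quiescent operating point of the
standard network (gain 0.168): connectivity must reach this value before
spontaneous bursts replay the learned track. The third block runs the full
recording pipeline — rate maps, cosine tuning fits, tuning-index selection,
phase ordering — and shows that the place-field ordering's SC (0.71) sits far
outside the shuffle null (mean ~0).

A full simulation with plasticity is one call:

```r
sim <- simulate_ring(duration = 60, seed = 1)   # N = 100, 8 Hz theta, STDP on
fourier_modes(sim$W, sim$centers)
plot(sim, "rates")
```

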