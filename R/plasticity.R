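#' Pairwise STDP rule
#'
#' Temporally asymmetric spike-timing-dependent plasticity: a pre-before-post
#' pair with latency `T >= 0` potentiates by `A_plus * exp(-T/tau_plus)`; a
#' post-before-pre pair depresses by `A_minus * exp(T/tau_minus)` (for
#' `T < 0`). Defaults are the potentiation-dominant rule
#' `A+ = 0.1, tau+ = 20 ms, A- = 0.1/3, tau- = 60 ms`, which is *balanced*:
#' `A+ tau+ = A- tau-`, so constant firing rates produce no net drift of the
#' mean synaptic weight.
#'
#' @param A_plus potentiation amplitude (weight increment per unit trace), >= 0.
#' @param tau_plus potentiation window, seconds, > 0.
#' @param A_minus depression amplitude, >= 0.
#' @param tau_minus depression window, seconds, > 0.
#' @return an object of class `pair_rule`.
#' @seealso [plasticity_preset()], [triplet_rule()], [stdp_kernel()]
#' @export
pair_rule <- function(A_plus = 0.1, tau_plus = 0.020,
                      A_minus = 0.1 / 3, tau_minus = 0.060) {
  check_that(
    "A_plus must be >= 0" = is_num(A_plus) && A_plus >= 0,
    "A_minus must be >= 0" = is_num(A_minus) && A_minus >= 0,
    "tau_plus must be > 0" = is_num(tau_plus) && tau_plus > 0,
    "tau_minus must be > 0" = is_num(tau_minus) && tau_minus > 0
  )
  structure(list(A_plus = A_plus, tau_plus = tau_plus,
                 A_minus = A_minus, tau_minus = tau_minus),
            class = c("pair_rule", "plasticity_rule"))
}

#' Triplet STDP rule
#'
#' Extends the pairwise rule with second (slower) traces: a post spike of cell
#' i potentiates `w_ij` by `r1_j * (A2_plus + A3_plus * o2_i)` where `o2_i` is
#' the slow postsynaptic trace (time constant `tau_y`) evaluated *before* its
#' own increment; a pre spike of cell j depresses by
#' `o1_i * (A2_minus + A3_minus * r2_j)` with the slow presynaptic trace `r2`
#' (time constant `tau_x3`, named to avoid collision with the depression
#' constant tau_x). The rule is fully balanced when `A2+ tau+ = A2- tau-`,
#' `tau_x3 = tau_y` and `A3+ tau+ tau_y = A3- tau- tau_x3`.
#'
#' @param A2_plus,A2_minus pairwise amplitudes.
#' @param A3_plus,A3_minus triplet amplitudes.
#' @param tau_plus,tau_minus first-trace time constants, seconds.
#' @param tau_y post slow-trace time constant, seconds.
#' @param tau_x3 pre slow-trace time constant, seconds.
#' @return an object of class `triplet_rule`.
#' @export
triplet_rule <- function(A2_plus = 0.1, tau_plus = 0.020,
                         A2_minus = 0.1 / 3, tau_minus = 0.060,
                         A3_plus = 0.1, tau_y = 0.100,
                         A3_minus = A3_plus * tau_plus * tau_y /
                           (tau_minus * tau_x3),
                         tau_x3 = 0.100) {
  check_that(
    "amplitudes must be >= 0" = all(c(A2_plus, A2_minus, A3_plus, A3_minus) >= 0),
    "time constants must be > 0" = all(c(tau_plus, tau_minus, tau_y, tau_x3) > 0)
  )
  structure(list(A_plus = A2_plus, tau_plus = tau_plus,
                 A_minus = A2_minus, tau_minus = tau_minus,
                 A3_plus = A3_plus, tau_y = tau_y,
                 A3_minus = A3_minus, tau_x3 = tau_x3),
            class = c("triplet_rule", "plasticity_rule"))
}

#' Named plasticity-rule presets
#'
#' * `"pair"`: potentiation-dominant balanced pairwise rule
#'   (A+ = 0.1, tau+ = 20 ms, A- = 0.1/3, tau- = 60 ms).
#' * `"antisymmetric"`: A+ = A- = 0.1, tau+ = tau- = 40 ms. Produces no growth
#'   of the even connectivity mode (and hence no replay transition).
#' * `"depression_dominant"`: amplitudes swapped relative to `"pair"`
#'   (A+ = 0.1/3, tau+ = 20 ms, A- = 0.1, tau- = 60 ms) so that depression
#'   dominates at short latencies; the even mode *decays*.
#' * `"triplet"`: balanced triplet rule on top of the pairwise defaults.
#'
#' @param name preset name.
#' @return a [pair_rule()] or [triplet_rule()] object.
#' @export
plasticity_preset <- function(name = c("pair", "antisymmetric",
                                       "depression_dominant", "triplet")) {
  name <- match.arg(name)
  switch(name,
    pair = pair_rule(),
    antisymmetric = pair_rule(A_plus = 0.1, tau_plus = 0.040,
                              A_minus = 0.1, tau_minus = 0.040),
    depression_dominant = pair_rule(A_plus = 0.1 / 3, tau_plus = 0.020,
                                    A_minus = 0.1, tau_minus = 0.060),
    triplet = triplet_rule()
  )
}

#' Scale the amplitudes of a plasticity rule
#'
#' Multiplies every amplitude (A+, A-, and the triplet A3 terms if present) by
#' a common factor. The mean-field growth rates are linear in the amplitudes,
#' so a scaled rule compresses learning time by the same factor; used for
#' desk-scale protocol runs.
#'
#' @param rule a `pair_rule` or `triplet_rule`.
#' @param factor positive multiplier.
#' @return a rule of the same class with scaled amplitudes.
#' @export
scale_rule <- function(rule, factor) {
  stopifnot(inherits(rule, "plasticity_rule"), is_num(factor), factor >= 0)
  rule$A_plus <- rule$A_plus * factor
  rule$A_minus <- rule$A_minus * factor
  if (inherits(rule, "triplet_rule")) {
    rule$A3_plus <- rule$A3_plus * factor
    rule$A3_minus <- rule$A3_minus * factor
  }
  rule
}

#' STDP kernel K(T)
#'
#' Evaluates the plasticity window: `K(T) = A+ exp(-T/tau+)` for `T >= 0`
#' (pre-before-post, potentiation) and `K(T) = -A- exp(T/tau-)` for `T < 0`
#' (post-before-pre, depression). The kernel is discontinuous at `T = 0`, with
#' `K(0) = A+` by convention (zero latency counted as potentiation).
#'
#' @param rule a [pair_rule()] (for a triplet rule, the pairwise part is used).
#' @param T latency pre-to-post, seconds; vectorized.
#' @return weight change per unit rate-product, same length as `T`.
#' @export
stdp_kernel <- function(rule, T) {
  stopifnot(inherits(rule, "plasticity_rule"))
  ifelse(T >= 0,
         rule$A_plus * exp(-T / rule$tau_plus),
         -rule$A_minus * exp(T / rule$tau_minus))
}

#' Check the balance conditions of a plasticity rule
#'
#' A rule is balanced when constant firing rates induce no net drift of the
#' mean weight: `A+ tau+ = A- tau-`, and for triplet rules additionally
#' `tau_x3 = tau_y` and `A3+ tau+ tau_y = A3- tau- tau_x3`.
#'
#' @param rule a plasticity rule.
#' @param tol absolute tolerance on the residuals.
#' @return list with `balanced` (logical) and named `residuals`.
#' @export
is_balanced <- function(rule, tol = 1e-12) {
  stopifnot(inherits(rule, "plasticity_rule"))
  res <- c(pair = rule$A_plus * rule$tau_plus - rule$A_minus * rule$tau_minus)
  if (inherits(rule, "triplet_rule")) {
    res <- c(res,
             triplet_tau = rule$tau_x3 - rule$tau_y,
             triplet_amp = rule$A3_plus * rule$tau_plus * rule$tau_y -
               rule$A3_minus * rule$tau_minus * rule$tau_x3)
  }
  list(balanced = all(abs(res) < tol), residuals = res)
}

#' Fresh plasticity trace state
#'
#' Per-neuron exponential traces: `r1` (presynaptic, tau+), `o1`
#' (postsynaptic, tau-), and for triplet rules the slow traces `r2` (tau_x3)
#' and `o2` (tau_y). Traces decay exponentially between spikes and are
#' incremented by 1 at the neuron's own spikes.
#'
#' @param N number of neurons.
#' @param triplet logical; allocate the slow traces.
#' @return list of trace vectors (class `trace_state`).
#' @export
new_trace_state <- function(N, triplet = FALSE) {
  z <- numeric(N)
  st <- list(r1 = z, o1 = z)
  if (triplet) {
    st$r2 <- z
    st$o2 <- z
  }
  structure(st, class = "trace_state")
}

## internal: shared trace/weight update machinery.
## Order within a step (matched exactly by the C++ engine):
##   1. all traces decay by exp(-dt/tau)
##   2. weight increments are computed from the decayed traces *before* the
##      increments due to this step's own spikes (so simultaneous pre/post
##      spikes do not interact at zero latency)
##   3. spiking neurons' traces increment by 1
##   4. accumulated increments are applied and W is clipped to [0, wmax];
##      the diagonal (autapses) is never updated
stdp_step <- function(W, traces, spikes, rule, wmax, dt, triplet) {
  N <- nrow(W)
  ep <- exp(-dt / rule$tau_plus)
  em <- exp(-dt / rule$tau_minus)
  traces$r1 <- traces$r1 * ep
  traces$o1 <- traces$o1 * em
  if (triplet) {
    traces$r2 <- traces$r2 * exp(-dt / rule$tau_x3)
    traces$o2 <- traces$o2 * exp(-dt / rule$tau_y)
  }
  sp <- which(spikes != 0)
  if (length(sp)) {
    dW <- matrix(0, N, N)
    ## post spike i: w_ij += r1_j * (A2+ + A3+ * o2_i)
    amp_post <- if (triplet) rule$A_plus + rule$A3_plus * traces$o2[sp] else
      rep(rule$A_plus, length(sp))
    dW[sp, ] <- dW[sp, , drop = FALSE] + outer(amp_post, traces$r1)
    ## pre spike j: w_ij -= o1_i * (A2- + A3- * r2_j)
    amp_pre <- if (triplet) rule$A_minus + rule$A3_minus * traces$r2[sp] else
      rep(rule$A_minus, length(sp))
    dW[, sp] <- dW[, sp, drop = FALSE] - outer(traces$o1, amp_pre)
    diag(dW) <- 0
    W <- W + dW
    W[W < 0] <- 0
    W[W > wmax] <- wmax
    traces$r1[sp] <- traces$r1[sp] + 1
    traces$o1[sp] <- traces$o1[sp] + 1
    if (triplet) {
      traces$r2[sp] <- traces$r2[sp] + 1
      traces$o2[sp] <- traces$o2[sp] + 1
    }
  }
  list(W = W, traces = traces)
}

#' Apply one step of pairwise STDP updates
#'
#' Performs, in order: exponential trace decay over `dt`; weight increments for
#' every spike this step (post spike of i adds `A+ * r1_j` to all `w_ij`, pre
#' spike of j subtracts `A- * o1_i` from all `w_ij`), computed from the traces
#' *before* their own-spike increments; trace increments (+1) for spiking
#' neurons; clipping of W to `[0, wmax]`. Increments are accumulated before
#' clipping, so the result is independent of the order of simultaneous spikes.
#' Autapses (the diagonal) are never updated.
#'
#' @param W weight matrix (post-by-pre).
#' @param traces a [new_trace_state()] list.
#' @param spikes integer/logical vector marking this step's spikes.
#' @param rule a [pair_rule()].
#' @param wmax upper weight bound.
#' @param dt time step, seconds.
#' @return list with updated `W` and `traces`.
#' @export
apply_pair_updates <- function(W, traces, spikes, rule, wmax, dt) {
  stopifnot(inherits(rule, "pair_rule"))
  stdp_step(W, traces, spikes, rule, wmax, dt, triplet = FALSE)
}

#' Apply one step of triplet STDP updates
#'
#' As [apply_pair_updates()], with the triplet amplification: potentiation uses
#' `A2+ + A3+ * o2_i` and depression `A2- + A3- * r2_j`, with the slow traces
#' evaluated before their own increments. With `A3+ = A3- = 0` the trajectory
#' is identical to the pairwise rule.
#'
#' @inheritParams apply_pair_updates
#' @param rule a [triplet_rule()].
#' @return list with updated `W` and `traces`.
#' @export
apply_triplet_updates <- function(W, traces, spikes, rule, wmax, dt) {
  stopifnot(inherits(rule, "triplet_rule"))
  stdp_step(W, traces, spikes, rule, wmax, dt, triplet = TRUE)
}
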