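## Independent numeric oracles used across the suite. These deliberately
## avoid the package's closed forms: everything is brute-force quadrature of
## the kernel against trigonometric correlation functions.

uniform_centers <- function(N) seq(-pi, pi, length.out = N + 1)[1:N]

## kernel x cos / kernel x sin integrals by quadrature
quad_kernel_trig <- function(rule, v, trig = c("cos", "sin")) {
  trig <- match.arg(trig)
  Tmax <- 40 * max(rule$tau_plus, rule$tau_minus)
  f <- function(T) {
    k <- ifelse(T >= 0, rule$A_plus * exp(-T / rule$tau_plus),
                -rule$A_minus * exp(T / rule$tau_minus))
    k * (if (trig == "cos") cos(v * T) else sin(v * T))
  }
  ## integrate in period-sized panels so the adaptive rule resolves fast
  ## oscillations without roundoff failures
  panel <- if (abs(v) > 2 * pi / Tmax) 2 * pi / abs(v) else Tmax
  ## always split at the kernel discontinuity T = 0
  cuts <- sort(unique(c(-Tmax, 0, seq(-Tmax, Tmax, by = panel), Tmax)))
  sum(vapply(seq_len(length(cuts) - 1), function(i) {
    integrate(f, cuts[i], cuts[i + 1], rel.tol = 1e-11, abs.tol = 1e-16,
              subdivisions = 500L)$value
  }, numeric(1)))
}

## even/odd growth by quadrature for a sum of traveling cosine components
## with amplitudes amps at angular velocities vels
quad_growth <- function(rule, amps, vels) {
  even <- 0
  odd <- 0
  for (k in seq_along(amps)) {
    even <- even + amps[k]^2 / 2 * quad_kernel_trig(rule, vels[k], "cos")
    odd <- odd + amps[k]^2 / 2 * quad_kernel_trig(rule, vels[k], "sin")
  }
  list(even = even, odd = odd)
}

## natural magnitude scale of a growth rate for relative comparisons
kernel_mass <- function(rule, amps) {
  sum(amps^2) / 2 *
    (rule$A_plus * rule$tau_plus + rule$A_minus * rule$tau_minus)
}

## factorized quadrature oracle for the triplet growth rates (pre at t, post
## at t + T convention); independent of the package's closed forms
triplet_quad_oracle <- function(rule, r0, a, v) {
  Tm <- 60 * max(rule$tau_plus, rule$tau_minus, rule$tau_y, rule$tau_x3)
  C <- function(tauk) integrate(function(u) exp(-u / tauk) * cos(v * u),
                                0, Tm, rel.tol = 1e-12,
                                subdivisions = 4000L)$value
  S <- function(tauk) integrate(function(u) exp(-u / tauk) * sin(v * u),
                                0, Tm, rel.tol = 1e-12,
                                subdivisions = 4000L)$value
  Cp <- C(rule$tau_plus); Sp <- S(rule$tau_plus)
  Cm <- C(rule$tau_minus); Sm <- S(rule$tau_minus)
  Cy <- C(rule$tau_y); Sy <- S(rule$tau_y)
  Cx <- C(rule$tau_x3); Sx <- S(rule$tau_x3)
  a2 <- a^2 / 2
  dw0_pair <- (rule$A_plus * rule$tau_plus -
                 rule$A_minus * rule$tau_minus) * r0^2
  dwe_pair <- a2 * (rule$A_plus * Cp - rule$A_minus * Cm)
  dwo_pair <- a2 * (rule$A_plus * Sp + rule$A_minus * Sm)
  Z1 <- complex(real = Cp, imaginary = -Sp) * complex(real = Cy, imaginary = Sy)
  Z2 <- complex(real = Cm, imaginary = Sm) * complex(real = Cx, imaginary = -Sx)
  A3p <- rule$A3_plus; A3m <- rule$A3_minus
  ty <- rule$tau_y; tx <- rule$tau_x3
  tp <- rule$tau_plus; tm <- rule$tau_minus
  list(
    dw0 = dw0_pair + A3p * (r0^3 * tp * ty + r0 * a2 * tp * Cy) -
      A3m * (r0^3 * tm * tx + r0 * a2 * tm * Cx),
    dweven = dwe_pair + A3p * r0 * a2 * (ty * Cp + Re(Z1)) -
      A3m * r0 * a2 * (tx * Cm + Re(Z2)),
    dwodd = dwo_pair + A3p * r0 * a2 * (ty * Sp - Im(Z1)) -
      A3m * r0 * a2 * (-tx * Sm - Im(Z2))
  )
}
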