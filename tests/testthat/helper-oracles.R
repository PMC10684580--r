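# Independent oracles used across the suite. These deliberately avoid the
# package's eigen-decomposition propagation path: explicit Runge-Kutta
# stepping, closed-form 2x2 partial fractions, and brute-force root scans.

# Explicit fixed-step RK4 integration of dM/dt = K M over t_end.
rk4_propagate <- function(K, M0, t_end, n_steps) {
  dt <- t_end / n_steps
  M <- as.complex(M0)
  for (i in seq_len(n_steps)) {
    k1 <- K %*% M
    k2 <- K %*% (M + (dt / 2) * k1)
    k3 <- K %*% (M + (dt / 2) * k2)
    k4 <- K %*% (M + dt * k3)
    M <- M + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(M)
}

# FID by fine-step explicit integration, sampled at dwell multiples.
rk4_fid <- function(K, M0, acq, substeps) {
  dwell <- 1 / acq$spectral_width
  s <- complex(acq$n_points)
  M <- as.complex(M0)
  s[1] <- sum(M)
  for (n in seq_len(acq$n_points - 1)) {
    M <- rk4_propagate(K, M, dwell, substeps)
    s[n + 1] <- sum(M)
  }
  s
}

# Ideal spin echo by fine-step integration: evolve tau/2, conjugate
# (180-degree pulse), evolve tau/2.
rk4_echo <- function(K, M0, tau, n_steps) {
  M <- rk4_propagate(K, M0, tau / 2, n_steps)
  rk4_propagate(K, Conj(M), tau / 2, n_steps)
}

# Closed-form two-site McConnell FID (states P and PL) via the 2x2 partial
# fraction form of exp(At): no numeric eigen-decomposition involved.
two_site_fid <- function(k_PtoPL, k_off, omega_P, omega_PL, R2, M0, acq) {
  a11 <- -2i * pi * omega_P - R2 - k_PtoPL
  a12 <- k_off
  a21 <- k_PtoPL
  a22 <- -2i * pi * omega_PL - R2 - k_off
  tr <- a11 + a22
  dt <- a11 * a22 - a12 * a21
  rt <- sqrt(tr^2 - 4 * dt)
  lp <- (tr + rt) / 2
  lm <- (tr - rt) / 2
  # s(t) = sum_pm exp(l t) * 1'(A - l_other I) M0 / (l - l_other)
  wp <- ((a11 - lm) * M0[1] + a12 * M0[2] +
         a21 * M0[1] + (a22 - lm) * M0[2]) / (lp - lm)
  wm <- ((a11 - lp) * M0[1] + a12 * M0[2] +
         a21 * M0[1] + (a22 - lp) * M0[2]) / (lm - lp)
  tvec <- (seq_len(acq$n_points) - 1) / acq$spectral_width
  wp * exp(lp * tvec) + wm * exp(lm * tvec)
}

# Brute-force root of the binding quadratic as literally written:
# f(x) = k1_off x - (L0 - A x)(P0 - A x) k1_on, scanned for a sign change on
# [0, min(P0, L0)/A] and refined by bisection inside the bracket.
bruteforce_PL <- function(scheme, P0, L0, n_grid = 1e5) {
  A <- scheme_A(scheme)
  f <- function(x) scheme$k1_off * x -
    (L0 - A * x) * (P0 - A * x) * scheme$k1_on
  hi <- min(P0, L0) / A
  if (hi == 0) return(0)
  xs <- seq(0, hi, length.out = n_grid)
  fx <- f(xs)
  i <- which(fx[-1] * fx[-length(fx)] <= 0)[1]
  if (is.na(i)) return(hi)  # saturated: root at the boundary
  lo <- xs[i]; up <- xs[i + 1]
  for (k in 1:200) {
    mid <- (lo + up) / 2
    if (f(lo) * f(mid) <= 0) up <- mid else lo <- mid
  }
  (lo + up) / 2
}

# Standard two-state binding quadratic (A = 1), closed form with the stable
# root expression.
two_state_PL <- function(Kd, P0, L0) {
  b <- Kd + P0 + L0
  2 * P0 * L0 / (b + sqrt(b^2 - 4 * P0 * L0))
}

# Acquisition small enough for RK4 oracles at desk scale.
oracle_acq <- function(n_points = 256, zf = 2, apod = "none", sw = 4000)
  acquisition_settings(sw, n_points, zf, apod)

# Random valid three-state parameter draw with rates bounded so that the
# RK4 oracle meets its accuracy target at the chosen substep count.
random_draw <- function() {
  list(
    kon_L = stats::runif(1, 0, 500),        # pseudo-first-order P -> PL
    k_off = stats::runif(1, 10, 500),
    k2 = stats::runif(1, 0, 200),
    k2p = stats::runif(1, 20, 500),
    omega_P = stats::runif(1, -400, 400),
    omega_PL = stats::runif(1, -400, 400),
    R2 = stats::runif(1, 10, 80)
  )
}

draw_generator <- function(d) {
  # build the generator through the public API with L_free chosen to give
  # the drawn pseudo-first-order rate
  scheme <- exchange_scheme(1e6, d$k_off, d$k2, d$k2p)
  spin <- spin_parameters(d$omega_P, d$omega_PL, d$R2)
  list(K = evolution_matrix(scheme, spin, d$kon_L / 1e6),
       scheme = scheme, spin = spin)
}
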