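#' Spin parameters of the observed amide
#'
#' Resonance offsets and relaxation of the observed nucleus in the three
#' protein states. The transiently unbound conformer PL* resonates at the
#' free-protein offset (its contacts are broken, so the local environment is
#' free-like), and a single transverse relaxation rate R2 is shared by all
#' states; both are model assumptions, not fields.
#'
#' @param omega_P resonance offset of the free protein (Hz, relative to the
#'   carrier)
#' @param omega_PL resonance offset of the bound state (Hz); the exchange
#'   shift difference is `delta_omega = omega_PL - omega_P`
#' @param R2 transverse relaxation rate shared by all states (s^-1), > 0
#' @param echo_time duration of the pre-acquisition spin echo (s);
#'   default 0.011 s emulates the INEPT transfer periods of the HSQC
#' @return an object of class `spin_parameters`
#' @export
spin_parameters <- function(omega_P, omega_PL, R2, echo_time = 0.011) {
  if (!is.finite(R2) || R2 <= 0) stop("R2 must be > 0")
  if (!is.finite(echo_time) || echo_time < 0) stop("echo_time must be >= 0")
  if (!is.finite(omega_P) || !is.finite(omega_PL))
    stop("offsets must be finite")
  structure(list(omega_P = omega_P, omega_PL = omega_PL, R2 = R2,
                 echo_time = echo_time),
            class = "spin_parameters")
}

#' @export
print.spin_parameters <- function(x, ...) {
  cat(sprintf(
    "Spin parameters: omega_P = %g Hz, omega_PL = %g Hz (dw = %g Hz), R2 = %g s^-1, echo = %g ms\n",
    x$omega_P, x$omega_PL, x$omega_PL - x$omega_P, x$R2, 1e3 * x$echo_time))
  invisible(x)
}

#' Acquisition and processing settings
#'
#' @param spectral_width spectral width (Hz); the dwell time is its inverse
#' @param n_points number of complex time-domain points (power of two >= 256)
#' @param zero_fill_factor integer >= 1; the FID is zero-filled to
#'   `n_points * zero_fill_factor` before the Fourier transform
#' @param apodization `"cosine"` (shifted cosine bell over the acquisition
#'   time, the default) or `"none"`
#' @return an object of class `acquisition_settings`
#' @export
acquisition_settings <- function(spectral_width = 4000, n_points = 2048,
                                 zero_fill_factor = 2,
                                 apodization = c("cosine", "none")) {
  apodization <- match.arg(apodization)
  if (!is.finite(spectral_width) || spectral_width <= 0)
    stop("spectral_width must be > 0")
  n_points <- as.integer(n_points)
  if (n_points < 256 || bitwAnd(n_points, n_points - 1L) != 0L)
    stop("n_points must be a power of two >= 256")
  zero_fill_factor <- as.integer(zero_fill_factor)
  if (zero_fill_factor < 1) stop("zero_fill_factor must be >= 1")
  structure(list(spectral_width = spectral_width, n_points = n_points,
                 zero_fill_factor = zero_fill_factor,
                 apodization = apodization),
            class = "acquisition_settings")
}

# Peaks must sit well inside the spectral window; checked when a slice is
# actually simulated (the settings object alone does not know the offsets).
check_window <- function(acq, spin) {
  lim <- 2 * max(abs(spin$omega_P), abs(spin$omega_PL)) + 10 * spin$R2 / pi
  if (acq$spectral_width <= lim)
    stop(sprintf(
      "spectral_width = %g Hz too small for offsets/linewidth (need > %g Hz)",
      acq$spectral_width, lim))
  invisible(TRUE)
}

#' Bloch-McConnell evolution generator
#'
#' Assembles the 3x3 complex generator K of the coupled transverse
#' magnetization equations dM/dt = K M for the state vector
#' M = (M_P, M_PL, M_PL*) (column vector; K acts from the left). Each
#' diagonal entry is `-i 2 pi Omega - R2 - (total outflow rate)`; the
#' off-diagonals carry the exchange inflows: P -> PL at `k1_on * L_free`,
#' PL -> P at `k1_off`, PL -> PL* at `k2`, PL* -> PL at `k2_prime`. Exchange
#' conserves magnetization, so the real parts of all column sums equal -R2.
#'
#' @param scheme an [exchange_scheme()]
#' @param spin a [spin_parameters()]
#' @param L_free equilibrium free-ligand concentration (M); the bimolecular
#'   step is treated as pseudo-first-order at this fixed concentration
#' @return a 3x3 complex matrix
#' @export
evolution_matrix <- function(scheme, spin, L_free) {
  if (!is.finite(L_free) || L_free < 0) stop("L_free must be >= 0")
  wP <- -2i * pi * spin$omega_P
  wPL <- -2i * pi * spin$omega_PL
  kPL <- scheme$k1_on * L_free   # P -> PL pseudo-first-order rate
  K <- matrix(0 + 0i, 3, 3)
  K[1, 1] <- wP - spin$R2 - kPL
  K[1, 2] <- scheme$k1_off
  K[2, 1] <- kPL
  K[2, 2] <- wPL - spin$R2 - scheme$k1_off - scheme$k2
  K[2, 3] <- scheme$k2_prime
  K[3, 2] <- scheme$k2
  K[3, 3] <- wP - spin$R2 - scheme$k2_prime   # PL* resonates at omega_P
  K
}

#' Initial transverse magnetization from equilibrium populations
#'
#' The detected amide is carried equally by all three protein states, so the
#' starting transverse magnetization is proportional to the equilibrium
#' concentrations, normalized to unit total amplitude.
#'
#' @param eq an `equilibrium_state` from [solve_equilibrium()]
#' @return complex vector (M_P, M_PL, M_PLstar) summing to 1
#' @export
initial_magnetization <- function(eq) {
  pops <- c(eq$P, eq$PL, eq$PLstar)
  tot <- sum(pops)
  if (tot <= 0) stop("all protein species concentrations are zero")
  as.complex(pops / tot)
}

# Exact propagator exp(K * t) by eigen-decomposition of the (generically
# diagonalizable) complex generator.
propagator <- function(K, t) {
  if (t == 0) return(diag(3) + 0i)
  ed <- eigen(K)
  V <- ed$vectors
  V %*% (exp(ed$values * t) * solve(V))
}

#' Apply an ideal spin echo
#'
#' Propagates the magnetization through a tau/2 - 180deg - tau/2 echo:
#' `M = U conj(U M0)` with `U = exp(K tau/2)` and element-wise complex
#' conjugation standing in for an ideal, instantaneous 180deg pulse. Chemical
#' shift evolution is refocused; relaxation, and exchange between states of
#' unequal shift, attenuate the signal — this reproduces the losses during
#' the INEPT periods preceding acquisition.
#'
#' @param K generator from [evolution_matrix()]
#' @param M0 starting magnetization (complex length-3)
#' @param tau total echo time (s), >= 0
#' @return complex length-3 magnetization after the echo
#' @export
apply_spin_echo <- function(K, M0, tau) {
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(as.complex(M0))
  U <- propagator(K, tau / 2)
  as.vector(U %*% Conj(U %*% as.complex(M0)))
}

#' Propagate the free induction decay
#'
#' Samples the detected signal `s(t) = M_P(t) + M_PL(t) + M_PL*(t)` at
#' multiples of the dwell time `1/spectral_width`, using the exact solution
#' of the linear system (eigen-decomposition of the generator) rather than
#' generic ODE stepping: `s(n) = sum_j w_j exp(lambda_j n dt)` with
#' `w_j = (1' V)_j (V^-1 M0)_j`.
#'
#' @param K generator from [evolution_matrix()]
#' @param M_start magnetization at the start of acquisition
#' @param acq an [acquisition_settings()]
#' @return complex vector of length `n_points`
#' @export
propagate_fid <- function(K, M_start, acq) {
  if (any(!is.finite(Re(K))) || any(!is.finite(Im(K))))
    stop("non-finite entries in evolution generator")
  ed <- eigen(K)
  coef <- solve(ed$vectors, as.complex(M_start))
  w <- colSums(ed$vectors) * coef
  dwell <- 1 / acq$spectral_width
  tvec <- (seq_len(acq$n_points) - 1) * dwell
  s <- complex(acq$n_points)
  for (j in 1:3) s <- s + w[j] * exp(ed$values[j] * tvec)
  s
}

apodization_window <- function(n, type) {
  switch(type,
    none = rep(1, n),
    # shifted cosine bell: unity at the first point, zero at the end of the
    # acquired data (90deg-shifted sine bell, TOPSPIN-style)
    cosine = cos(pi / 2 * (seq_len(n) - 1) / (n - 1)),
    stop("unknown apodization: ", type)
  )
}

#' One-dimensional spectrum container
#'
#' @param frequency strictly increasing, uniformly spaced axis (Hz)
#' @param intensity real intensities, same length
#' @param metadata named list of provenance (equivalents, parameters,
#'   noise sigma for synthetic data, ...)
#' @return an object of class `spectrum1d`
#' @export
spectrum1d <- function(frequency, intensity, metadata = list()) {
  if (length(frequency) != length(intensity))
    stop("frequency and intensity must have the same length")
  if (length(frequency) > 1) {
    d <- diff(frequency)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-6 * abs(d[1]))
      stop("frequency axis must be strictly increasing and uniform")
  }
  structure(list(frequency = frequency, intensity = intensity,
                 metadata = metadata),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("spectrum1d: %d points, %g to %g Hz",
              length(x$frequency), min(x$frequency), max(x$frequency)))
  if (!is.null(x$metadata$equivalents))
    cat(sprintf(", %g equivalents", x$metadata$equivalents))
  cat("\n")
  invisible(x)
}

#' Fourier-transform an FID into a 1D spectrum
#'
#' Apodizes the acquired points, zero-fills, applies the discrete Fourier
#' transform and returns the real part on a frequency axis spanning
#' `[-spectral_width/2, +spectral_width/2)`. The sign convention is fixed so
#' that a species precessing at offset +Omega Hz produces a peak at
#' +Omega Hz. The first FID point is halved before the transform, the
#' standard correction that removes the constant baseline offset of the
#' sampled one-sided transform.
#'
#' @param fid complex vector of length `acq$n_points`
#' @param acq an [acquisition_settings()]
#' @param mode `"real"` (default) or `"magnitude"`
#' @param metadata optional metadata list carried into the spectrum
#' @return a [spectrum1d()]
#' @export
spectrum_from_fid <- function(fid, acq, mode = c("real", "magnitude"),
                              metadata = list()) {
  mode <- match.arg(mode)
  if (length(fid) != acq$n_points)
    stop("fid length must equal acq$n_points")
  if (any(!is.finite(Re(fid))) || any(!is.finite(Im(fid))))
    stop("non-finite FID values")
  w <- apodization_window(acq$n_points, acq$apodization)
  x <- fid * w
  x[1] <- 0.5 * x[1]
  n_tot <- acq$n_points * acq$zero_fill_factor
  x <- c(x, complex(n_tot - acq$n_points))
  # the generator evolves as exp(-i 2 pi Omega t); conjugate so that +Omega
  # lands in the +frequency bins of R's fft (which uses exp(-2 pi i k n / N))
  sp <- stats::fft(Conj(x))
  step <- acq$spectral_width / n_tot
  k <- 0:(n_tot - 1)
  freq <- k * step
  freq[freq >= acq$spectral_width / 2] <-
    freq[freq >= acq$spectral_width / 2] - acq$spectral_width
  ord <- order(freq)
  val <- if (mode == "real") Re(sp)[ord] else Mod(sp)[ord]
  spectrum1d(freq[ord], val, metadata)
}

#' Simulate one titration slice
#'
#' Full pipeline for a single mix: solve the binding/isomerization
#' equilibrium, set the initial magnetization from the equilibrium
#' populations, apply the pre-acquisition spin echo, propagate the FID and
#' Fourier-transform it. Deterministic.
#'
#' @param scheme an [exchange_scheme()]
#' @param spin a [spin_parameters()]
#' @param mix a [mix_composition()]
#' @param acq an [acquisition_settings()]
#' @param mode passed to [spectrum_from_fid()]
#' @return a [spectrum1d()] with equivalents and free-ligand metadata
#' @export
simulate_slice <- function(scheme, spin, mix, acq = acquisition_settings(),
                           mode = "real") {
  check_window(acq, spin)
  eq <- solve_equilibrium(scheme, mix)
  K <- evolution_matrix(scheme, spin, eq$L)
  M0 <- initial_magnetization(eq)
  M1 <- apply_spin_echo(K, M0, spin$echo_time)
  fid <- propagate_fid(K, M1, acq)
  spectrum_from_fid(fid, acq, mode = mode,
                    metadata = list(equivalents = mix$equivalents,
                                    P0 = mix$P0, L0 = mix$L0,
                                    L_free = eq$L))
}

#' Measure a peak in a 1D spectrum
#'
#' Locates the discrete maximum inside a frequency window, refines its
#' position and height by parabolic interpolation through the three
#' surrounding points, and measures the full width at half maximum by linear
#' interpolation of the half-height crossings. Operates on the spectrum as
#' given (no baseline correction): a constant baseline leaves the position
#' unchanged but biases the FWHM, so callers should window appropriately.
#'
#' @param spectrum a [spectrum1d()]
#' @param window length-2 numeric, frequency interval (Hz) to search
#' @return list with `position` (Hz), `fwhm` (Hz), `height`
#' @export
measure_peak <- function(spectrum, window = range(spectrum$frequency)) {
  f <- spectrum$frequency
  y <- spectrum$intensity
  sel <- which(f >= window[1] & f <= window[2])
  if (length(sel) < 3) stop("window contains fewer than 3 points")
  yi <- y[sel]
  imax <- which.max(yi)
  if (imax == 1 || imax == length(sel) ||
      yi[imax] <= max(yi[1], yi[length(sel)]))
    stop("no peak: no interior maximum above the window edges")
  i <- sel[imax]
  step <- f[2] - f[1]
  ym <- y[i - 1]; y0 <- y[i]; yp <- y[i + 1]
  denom <- ym - 2 * y0 + yp
  dx <- if (denom == 0) 0 else 0.5 * (ym - yp) / denom
  position <- f[i] + dx * step
  height <- y0 - 0.25 * (ym - yp) * dx
  half <- height / 2
  # walk outwards from the maximum to the half-height crossings
  jl <- i
  while (jl > 1 && y[jl] > half) jl <- jl - 1
  jr <- i
  while (jr < length(y) && y[jr] > half) jr <- jr + 1
  if (y[jl] > half || y[jr] > half)
    stop("no peak: half-height crossing outside the spectrum")
  xl <- f[jl] + (half - y[jl]) / (y[jl + 1] - y[jl]) * step
  xr <- f[jr - 1] + (y[jr - 1] - half) / (y[jr - 1] - y[jr]) * step
  list(position = position, fwhm = xr - xl, height = height)
}
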