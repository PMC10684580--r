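test_that("evolution generator matches the coupled equations term by term", {
  sc <- exchange_scheme(1e9, 300, 30, 700)
  sp <- spin_parameters(0, 294, 50)
  # equilibrium free ligand at 1.3 equivalents, P0 = 250 uM
  eq <- solve_equilibrium(sc, mix_composition(250e-6, 1.3 * 250e-6))
  K <- evolution_matrix(sc, sp, eq$L)
  kPL <- 1e9 * eq$L
  # hand-assembled generator, term by term
  ref <- matrix(c(
    -2i * pi * 0 - 50 - kPL, 300, 0,
    kPL, -2i * pi * 294 - 50 - 300 - 30, 700,
    0, 30, -2i * pi * 0 - 50 - 700), 3, 3, byrow = TRUE)
  expect_equal(K, ref, tolerance = 1e-14)
  # exchange conserves magnetization: real column sums are -R2
  expect_equal(Re(colSums(K)), rep(-50, 3), tolerance = 1e-10)
})

test_that("no-exchange generator is diagonal", {
  sc <- exchange_scheme(0, 0, 0, 0)
  sp <- spin_parameters(120, 310, 40)
  K <- evolution_matrix(sc, sp, 0)
  expect_equal(K, diag(c(-2i * pi * 120 - 40, -2i * pi * 310 - 40,
                         -2i * pi * 120 - 40)), tolerance = 1e-14)
})

test_that("initial magnetization follows equilibrium populations", {
  sc <- exchange_scheme(1e9, 300, 30, 700)
  eq <- solve_equilibrium(sc, mix_composition(250e-6, 0))
  expect_equal(initial_magnetization(eq), as.complex(c(1, 0, 0)))
  eq2 <- solve_equilibrium(sc, mix_composition(250e-6, 325e-6))
  M <- initial_magnetization(eq2)
  expect_equal(sum(M), 1 + 0i)
  expect_equal(Re(M[3] / M[2]), 30 / 700, tolerance = 1e-12)
  bad <- eq2; bad$P <- bad$PL <- bad$PLstar <- 0
  expect_error(initial_magnetization(bad), "zero")
})

test_that("spin echo: closed-form attenuation, identity at tau 0, oracle", {
  # no exchange: amplitude attenuated by exp(-R2 tau), zero net phase
  K <- evolution_matrix(exchange_scheme(0, 0, 0, 0),
                        spin_parameters(150, 150, 50), 0)
  M <- apply_spin_echo(K, c(1, 0, 0), 0.011)
  expect_equal(Mod(M[1]), exp(-0.55), tolerance = 1e-12)
  expect_equal(Arg(M[1]), 0, tolerance = 1e-12)
  # tau = 0 is the identity
  expect_equal(apply_spin_echo(K, c(0.3, 0.5, 0.2), 0), as.complex(c(0.3, 0.5, 0.2)))
  # full three-state echo against fine-step explicit integration
  sc <- exchange_scheme(1e9, 300, 30, 700)
  sp <- spin_parameters(0, 294, 50)
  eq <- solve_equilibrium(sc, mix_composition(250e-6, 1.3 * 250e-6))
  K3 <- evolution_matrix(sc, sp, eq$L)
  M0 <- initial_magnetization(eq)
  got <- apply_spin_echo(K3, M0, 0.011)
  ref <- rk4_echo(K3, M0, 0.011, 20000)
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("single-species FID is a pure damped oscillation", {
  sp <- spin_parameters(294, 294, 60)
  K <- evolution_matrix(exchange_scheme(0, 0, 0, 0), sp, 0)
  acq <- oracle_acq(256)
  fid <- propagate_fid(K, c(1, 0, 0), acq)
  tvec <- (0:255) / acq$spectral_width
  expect_equal(fid, exp((-2i * pi * 294 - 60) * tvec), tolerance = 1e-12)
})

test_that("matrix propagation matches fine-step explicit integration", {
  set.seed(31)
  acq <- oracle_acq(256)
  for (i in 1:8) {
    d <- random_draw()
    g <- draw_generator(d)
    M0 <- as.complex(c(0.5, 0.35, 0.15))
    got <- propagate_fid(g$K, M0, acq)
    ref <- rk4_fid(g$K, M0, acq, substeps = 128)
    expect_lt(max(Mod(got - ref)) / max(Mod(got)), 1e-8)
  }
})

test_that("fast-exchange two-state limit collapses to the mean shift", {
  # k_ex >> 2 pi dw: mono-exponential at the population-weighted shift
  kon_L <- 8e4; koff <- 4e4
  sp <- spin_parameters(0, 200, 30)
  K <- evolution_matrix(exchange_scheme(1e9, koff, 0, 0), sp, kon_L / 1e9)
  pP <- koff / (koff + kon_L)
  M0 <- as.complex(c(pP, 1 - pP, 0))
  acq <- oracle_acq(512)
  fid <- propagate_fid(K, M0, acq)
  sl <- spectrum_from_fid(fid, acq)
  pk <- measure_peak(sl, c(50, 350))
  expect_equal(pk$position, (1 - pP) * 200, tolerance = 2)
  # and the exact closed-form two-site solution agrees pointwise
  ref <- two_site_fid(kon_L, koff, 0, 200, 30, M0[1:2], acq)
  expect_lt(max(Mod(fid - ref)) / max(Mod(fid)), 1e-10)
})

test_that("spectrum sign convention and Lorentzian line width", {
  sp <- spin_parameters(294, 294, 60)
  K <- evolution_matrix(exchange_scheme(0, 0, 0, 0), sp, 0)
  acq <- oracle_acq(2048, zf = 4)
  fid <- propagate_fid(K, c(1, 0, 0), acq)
  sl <- spectrum_from_fid(fid, acq)
  step <- sl$frequency[2] - sl$frequency[1]
  pk <- measure_peak(sl, c(200, 400))
  expect_equal(pk$position, 294, tolerance = step)       # peak at +Omega
  expect_equal(pk$fwhm, 60 / pi, tolerance = 0.05 * 60 / pi)
  # axis spans [-sw/2, sw/2)
  expect_equal(sl$frequency[1], -acq$spectral_width / 2)
  expect_lt(max(sl$frequency), acq$spectral_width / 2)
})

test_that("all-zero FID gives an all-zero spectrum", {
  acq <- oracle_acq(256)
  sl <- spectrum_from_fid(complex(256), acq)
  expect_true(all(sl$intensity == 0))
  expect_error(spectrum_from_fid(complex(100), acq), "length")
})

test_that("real-spectrum integral is independent of exchange rates", {
  # no apodization, no echo: the spectrum integral equals the first FID
  # point (total starting magnetization), whatever the exchange rates
  acq <- oracle_acq(512)
  sp <- spin_parameters(-80, 150, 40, echo_time = 0)
  M0 <- as.complex(c(0.4, 0.45, 0.15))
  ints <- vapply(list(c(0, 0), c(50, 300), c(2000, 4000)), function(k) {
    K <- evolution_matrix(exchange_scheme(1e8, k[1], k[2], max(k[2], 1)),
                          sp, k[1] / 1e8)
    sl <- spectrum_from_fid(propagate_fid(K, M0, acq), acq)
    sum(sl$intensity) * (sl$frequency[2] - sl$frequency[1])
  }, numeric(1))
  expect_equal(ints[2] / ints[1], 1, tolerance = 1e-3)
  expect_equal(ints[3] / ints[1], 1, tolerance = 1e-3)
})

test_that("two-state pipeline matches the closed-form two-site solution", {
  set.seed(41)
  P0 <- 250e-6
  acq <- oracle_acq(512)
  for (i in 1:50) {
    k_on <- 10^stats::runif(1, 6, 8)
    k_off <- stats::runif(1, 10, 2000)
    sp <- spin_parameters(stats::runif(1, -300, 300),
                          stats::runif(1, -300, 300),
                          stats::runif(1, 15, 80), echo_time = 0)
    sc <- exchange_scheme(k_on, k_off, 0, 0)
    mix <- mix_composition(P0, stats::runif(1, 0.2, 4) * P0)
    got <- simulate_slice(sc, sp, mix, acq)
    eq <- solve_equilibrium(sc, mix)
    M0 <- as.complex(c(eq$P, eq$PL) / (eq$P + eq$PL))
    fid <- two_site_fid(k_on * eq$L, k_off, sp$omega_P, sp$omega_PL,
                        sp$R2, M0, acq)
    ref <- spectrum_from_fid(fid, acq)
    expect_lt(max(abs(got$intensity - ref$intensity)) /
                max(ref$intensity), 1e-6)
  }
})

test_that("slice limits: apo Lorentzian and slow-exchange linewidth", {
  # no ligand: Lorentzian at omega_P whatever the scheme
  sc <- exchange_scheme(1e9, 300, 30, 700)
  sp <- spin_parameters(-120, 174, 45, echo_time = 0)
  acq <- oracle_acq(1024, zf = 4)
  sl <- simulate_slice(sc, sp, mix_composition(250e-6, 0), acq)
  pk <- measure_peak(sl, c(-250, 0))
  expect_equal(pk$position, -120, tolerance = 0.5)
  expect_equal(pk$fwhm, 45 / pi, tolerance = 0.05 * 45 / pi)
  # slow exchange, saturating ligand, k2 = 0: bound-peak width gains
  # k1_off / pi over the relaxation width
  sc2 <- exchange_scheme(1e5, 20, 0, 0)
  sp2 <- spin_parameters(0, 3000, 40, echo_time = 0)
  acq2 <- acquisition_settings(8192, 4096, 4, "none")
  sl2 <- simulate_slice(sc2, sp2, mix_composition(250e-6, 5 * 250e-6), acq2)
  pk2 <- measure_peak(sl2, c(2800, 3200))
  expect_equal(pk2$position, 3000, tolerance = 1)
  expect_equal(pk2$fwhm - 40 / pi, 20 / pi, tolerance = 0.05 * 20 / pi)
})

test_that("isomerization broadens the saturated bound-state peak", {
  sp <- spin_parameters(0, 294, 50)
  acq <- acquisition_settings(4000, 2048, 4)
  mix <- mix_composition(250e-6, 3 * 250e-6)
  with_iso <- simulate_slice(exchange_scheme(1e9, 300, 30, 700), sp, mix, acq)
  without <- simulate_slice(exchange_scheme(1e9, 300, 0, 0), sp, mix, acq)
  w1 <- measure_peak(with_iso, c(150, 450))$fwhm
  w0 <- measure_peak(without, c(150, 450))$fwhm
  expect_gt(w1, w0 + 1)
})

test_that("peak measurement: interpolation, baseline, windows", {
  f <- seq(-100, 100, by = 0.5)
  y <- 1 / (1 + ((f - 10.2) / 5)^2)   # Lorentzian HWHM 5 at 10.2 Hz
  sl <- spectrum1d(f, y)
  pk <- measure_peak(sl, c(-50, 60))
  expect_equal(pk$position, 10.2, tolerance = 0.25)
  expect_equal(pk$fwhm, 10, tolerance = 0.1)
  # constant baseline: position unchanged (FWHM is baseline-sensitive)
  pk_b <- measure_peak(spectrum1d(f, y + 0.2), c(-50, 60))
  expect_equal(pk_b$position, pk$position, tolerance = 1e-6)
  # monotone window content -> no interior maximum
  expect_error(measure_peak(spectrum1d(f, f), c(-50, 50)), "no peak")
})

test_that("spectral window guard rejects too-small widths", {
  sp <- spin_parameters(0, 2500, 50)
  expect_error(
    simulate_slice(exchange_scheme(1e9, 300, 0, 0), sp,
                   mix_composition(250e-6, 0), acquisition_settings(4000)),
    "spectral_width")
})
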