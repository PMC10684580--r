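#' Ground truth for a synthetic titration series
#'
#' Bundles everything needed to generate (and later score against) a
#' synthetic titration: the exchange scheme, spin parameters, protein
#' concentration, equivalents grid, acquisition settings, the noise level
#' and the seed.
#'
#' @param scheme an [exchange_scheme()]
#' @param spin a [spin_parameters()]
#' @param P0 total protein concentration (M)
#' @param grid equivalents grid
#' @param acq an [acquisition_settings()]
#' @param noise_sigma additive Gaussian noise s.d. as a fraction of the
#'   global maximum peak height, >= 0
#' @param seed integer seed recorded with the truth
#' @return an object of class `ground_truth`
#' @export
ground_truth <- function(scheme, spin, P0 = 250e-6,
                         grid = default_equivalents_grid(),
                         acq = acquisition_settings(),
                         noise_sigma = 0.01, seed = 1L) {
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be >= 0")
  structure(list(scheme = scheme, spin = spin, P0 = P0, grid = grid,
                 acq = acq, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: Kd = %.3g M, dw = %g Hz, P0 = %g M, %d grid points, noise %g, seed %d\n",
    scheme_kd(x$scheme), x$spin$omega_PL - x$spin$omega_P, x$P0,
    length(x$grid), x$noise_sigma, x$seed))
  invisible(x)
}

#' Published titration parameter presets
#'
#' Two ground-truth templates matching the published simulation parameter
#' sets for designed Armadillo-repeat-protein/peptide titrations:
#'
#' * `fast_intermediate` — the four-module protein with its matching
#'   four-repeat peptide (Kd = 300 nM): `k1_on = 1e9 M^-1 s^-1`,
#'   `k1_off = 300 s^-1`, `k2 = 30 s^-1`, `k2_prime = 700 s^-1`,
#'   shift difference 294 Hz. Fast-to-intermediate exchange: a single peak
#'   walks from the free to the bound position during the titration.
#' * `slow_femtomolar` — the seven-module protein with the seven-repeat
#'   peptide (Kd = 484 fM): `k1_on = 6.2e8 M^-1 s^-1`,
#'   `k1_off = 3e-4 s^-1`, `k2 = 30 s^-1`, `k2_prime = 100 s^-1`, shift
#'   difference 246 Hz. Slow exchange: a second peak builds up in
#'   proportion to the added peptide, yet is broadened by the bound-state
#'   isomerization far beyond what the minuscule off-rate could cause.
#'
#' The free-protein offset is anchored at 0 Hz (only the shift difference is
#' physically constrained), P0 = 250 uM and the echo time is 11 ms.
#'
#' @param R2 shared transverse relaxation rate (s^-1); the published traces
#'   do not state it, so a typical amide value for proteins of this size is
#'   the default
#' @param noise_sigma noise level stored in the presets (fraction of max
#'   height)
#' @return named list of two [ground_truth()] objects
#' @export
#' @examples
#' pr <- titration_presets()
#' scheme_kd(pr$slow_femtomolar$scheme)  # 4.84e-13 M
titration_presets <- function(R2 = 50, noise_sigma = 0.01) {
  list(
    fast_intermediate = ground_truth(
      scheme = exchange_scheme(1e9, 300, 30, 700),
      spin = spin_parameters(0, 294, R2, echo_time = 0.011),
      noise_sigma = noise_sigma),
    slow_femtomolar = ground_truth(
      scheme = exchange_scheme(6.2e8, 3e-4, 30, 100),
      spin = spin_parameters(0, 246, R2, echo_time = 0.011),
      noise_sigma = noise_sigma)
  )
}

#' Generate a noisy synthetic titration series
#'
#' Simulates the noiseless series at the ground-truth parameters and adds
#' Gaussian noise of standard deviation `noise_sigma * (global maximum
#' height)` independently to every frequency point of every slice, in the
#' frequency domain (observed traces are processed frequency-domain data).
#' Seeded and reproducible: the same truth yields bitwise-identical output.
#'
#' @param truth a [ground_truth()]
#' @return list with `series` (a [titration_series()]) and `truth`
#' @export
generate_series <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  series <- simulate_titration(truth$scheme, truth$spin, truth$P0,
                               truth$grid, truth$acq)
  if (truth$noise_sigma > 0) {
    gmax <- max(vapply(series$slices, function(s) max(s$intensity),
                       numeric(1)))
    sd <- truth$noise_sigma * gmax
    rng_state <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(rng_state))
      assign(".Random.seed", rng_state, .GlobalEnv))
    set.seed(truth$seed)
    for (k in seq_along(series$slices)) {
      s <- series$slices[[k]]
      s$intensity <- s$intensity + stats::rnorm(length(s$intensity), 0, sd)
      s$metadata$noise_sigma <- truth$noise_sigma
      series$slices[[k]] <- s
    }
  }
  series$provenance$noise_sigma <- truth$noise_sigma
  series$provenance$seed <- truth$seed
  list(series = series, truth = truth)
}

#' Generate synthetic chemical-shift tables with a known bin design
#'
#' Draws per-residue amide shift perturbations landing strictly inside
#' requested CSP bins, and returns matching free/bound shift tables together
#' with the expected classification. The combined perturbation of magnitude
#' v is split between the two dimensions by a random angle, so
#' `dH = v cos(a)` and `dN = 4 v sin(a)` reproduce v exactly under the CSP
#' formula.
#'
#' @param n_residues total number of residues; must be at least the sum of
#'   the design counts (extras get zero perturbation, bin `"none"`)
#' @param bin_design named integer vector mapping bin labels (see
#'   [csp_bins()]) to counts
#' @param seed integer seed
#' @return list with `free`, `bound` (data.frames `residue,dH,dN,assigned`)
#'   and `expected` (data.frame `residue,csp_ppm,bin`)
#' @export
generate_shift_tables <- function(n_residues, bin_design, seed = 1L) {
  bins <- csp_bins()
  if (length(bin_design) > 0 &&
      (!all(names(bin_design) %in% names(bins))))
    stop("unknown bin label(s): ",
         paste(setdiff(names(bin_design), names(bins)), collapse = ", "))
  if (any(bin_design < 0)) stop("bin counts must be >= 0")
  if (sum(bin_design) > n_residues)
    stop("bin design asks for more residues than n_residues")
  rng_state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(seed)
  uppers <- c(2, bins[1:4])        # cap the open-ended top bin at 2 ppm
  names(uppers) <- names(bins)
  target_bin <- rep("none", n_residues)
  i <- 1
  for (nm in names(bin_design)) {
    cnt <- bin_design[[nm]]
    if (cnt > 0) {
      target_bin[i:(i + cnt - 1)] <- nm
      i <- i + cnt
    }
  }
  dH <- dN <- numeric(n_residues)
  v <- numeric(n_residues)
  for (k in seq_len(n_residues)) {
    nm <- target_bin[k]
    lo <- bins[[nm]]
    hi <- uppers[[nm]]
    # strictly inside the half-open bin, clear of both edges; the "none"
    # bin means no perturbation at all
    vk <- if (nm == "none") 0
          else stats::runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
    a <- stats::runif(1, 0, pi / 2)
    v[k] <- vk
    dH[k] <- vk * cos(a)
    dN[k] <- 4 * vk * sin(a)
  }
  ids <- seq_len(n_residues)
  free <- data.frame(residue = ids,
                     dH = round(stats::rnorm(n_residues, 8.3, 0.5), 3),
                     dN = round(stats::rnorm(n_residues, 118, 4), 3),
                     assigned = TRUE)
  sgnH <- sample(c(-1, 1), n_residues, replace = TRUE)
  sgnN <- sample(c(-1, 1), n_residues, replace = TRUE)
  bound <- data.frame(residue = ids,
                      dH = free$dH + sgnH * dH,
                      dN = free$dN + sgnN * dN,
                      assigned = TRUE)
  csp_vals <- sqrt((free$dH - bound$dH)^2 + ((free$dN - bound$dN) / 4)^2)
  expected <- data.frame(residue = ids, csp_ppm = csp_vals,
                         bin = classify_csp(csp_vals),
                         stringsAsFactors = FALSE)
  list(free = free, bound = bound, expected = expected)
}
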