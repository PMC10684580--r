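#' Default molar-equivalents grid of the titration protocol
#'
#' Ligand-to-protein molar ratios of the standard titration: 0.1-equivalent
#' steps from 0 up to 1.5 (dense sampling through the binding transition),
#' then 0.5-equivalent steps up to 5.5 (24 points in total).
#'
#' @return numeric vector of 24 equivalents values
#' @export
default_equivalents_grid <- function() {
  c(seq(0, 1.5, by = 0.1), seq(2, 5.5, by = 0.5))
}

#' Titration series container
#'
#' @param equivalents strictly increasing non-negative molar ratios
#' @param slices list of [spectrum1d()], one per equivalents value, sharing
#'   one frequency axis
#' @param P0 total protein concentration (M)
#' @param provenance named list (scheme, spin, acquisition, ...)
#' @return an object of class `titration_series`
#' @export
titration_series <- function(equivalents, slices, P0, provenance = list()) {
  if (length(equivalents) != length(slices))
    stop("one slice per equivalents value required")
  if (any(equivalents < 0) || any(diff(equivalents) <= 0))
    stop("equivalents must be strictly increasing and >= 0")
  if (length(slices) > 1) {
    ax <- slices[[1]]$frequency
    same <- vapply(slices, function(s)
      length(s$frequency) == length(ax) &&
        max(abs(s$frequency - ax)) < 1e-9 * max(1, max(abs(ax))),
      logical(1))
    if (!all(same)) stop("all slices must share one frequency axis")
  }
  structure(list(equivalents = equivalents, slices = slices, P0 = P0,
                 provenance = provenance),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "titration_series: %d slices, %g to %g equivalents, P0 = %g M\n",
    length(x$slices), min(x$equivalents), max(x$equivalents), x$P0))
  invisible(x)
}

#' Simulate a full titration series
#'
#' One [simulate_slice()] per equivalents value, with total ligand
#' `L0 = equivalents * P0`. Deterministic.
#'
#' @param scheme an [exchange_scheme()]
#' @param spin a [spin_parameters()]
#' @param P0 total protein concentration (M)
#' @param grid equivalents grid, default [default_equivalents_grid()]
#' @param acq an [acquisition_settings()]
#' @return a [titration_series()]
#' @export
simulate_titration <- function(scheme, spin, P0,
                               grid = default_equivalents_grid(),
                               acq = acquisition_settings()) {
  slices <- lapply(grid, function(eqv)
    simulate_slice(scheme, spin, mix_composition(P0, eqv * P0), acq))
  titration_series(grid, slices, P0,
                   provenance = list(scheme = scheme, spin = spin,
                                     acquisition = acq))
}

#' Subset a titration series by equivalents
#'
#' Selects the slices at the given equivalents values (matched within a
#' tolerance), e.g. to restrict a fit to the informative titration points.
#'
#' @param series a [titration_series()]
#' @param equivalents values to keep
#' @param tol matching tolerance
#' @return a [titration_series()] with the selected slices
#' @export
subset_titration <- function(series, equivalents, tol = 1e-6) {
  idx <- vapply(equivalents, function(e) {
    i <- which(abs(series$equivalents - e) <= tol)
    if (length(i) != 1) stop("no unique slice at ", e, " equivalents")
    i
  }, integer(1))
  titration_series(series$equivalents[idx], series$slices[idx], series$P0,
                   series$provenance)
}
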