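#' Three-state exchange scheme
#'
#' Container for the four rate constants of the binding/isomerization scheme
#' P + L <-> PL <-> PL*: bimolecular association (`k1_on`), dissociation
#' (`k1_off`), and the unimolecular isomerization of the bound state into a
#' transiently (partially) unbound conformer (`k2` forward, `k2_prime`
#' reverse).
#'
#' @param k1_on bimolecular association rate constant (M^-1 s^-1)
#' @param k1_off dissociation rate constant (s^-1)
#' @param k2 forward isomerization rate PL -> PL* (s^-1)
#' @param k2_prime reverse isomerization rate PL* -> PL (s^-1)
#' @return an object of class `exchange_scheme`
#' @details All rates must be non-negative. If `k2 > 0` then `k2_prime`
#'   must be strictly positive, otherwise PL* would be an absorbing state and
#'   the equilibrium ratio \[PL*\]/\[PL\] = k2/k2' is undefined. The derived
#'   stoichiometric factor A = 1 + k2/k2' (>= 1) accounts for the ligand
#'   sequestered in both bound species.
#' @export
#' @examples
#' sc <- exchange_scheme(1e9, 300, 30, 700)
#' scheme_kd(sc)  # 3e-7 M
exchange_scheme <- function(k1_on, k1_off, k2 = 0, k2_prime = 0) {
  rates <- c(k1_on = k1_on, k1_off = k1_off, k2 = k2, k2_prime = k2_prime)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (k2 > 0 && k2_prime <= 0)
    stop("k2 > 0 requires k2_prime > 0 (PL* would be absorbing)")
  structure(
    list(k1_on = k1_on, k1_off = k1_off, k2 = k2, k2_prime = k2_prime),
    class = "exchange_scheme"
  )
}

#' @export
print.exchange_scheme <- function(x, ...) {
  cat("Three-state exchange scheme  P + L <-> PL <-> PL*\n")
  cat(sprintf("  k1_on    = %.4g M^-1 s^-1\n", x$k1_on))
  cat(sprintf("  k1_off   = %.4g s^-1\n", x$k1_off))
  cat(sprintf("  k2       = %.4g s^-1\n", x$k2))
  cat(sprintf("  k2_prime = %.4g s^-1\n", x$k2_prime))
  if (x$k1_on > 0)
    cat(sprintf("  Kd = k1_off/k1_on = %.4g M\n", x$k1_off / x$k1_on))
  invisible(x)
}

#' Stoichiometric factor A = 1 + k2/k2'
#'
#' @param scheme an [exchange_scheme()]
#' @return A >= 1; equals 1 when the isomerization branch is absent
#' @export
scheme_A <- function(scheme) {
  if (scheme$k2 == 0) 1 else 1 + scheme$k2 / scheme$k2_prime
}

#' Titration mix composition
#'
#' Total protein and ligand concentrations for a single titration point.
#' Molar equivalents are defined as `L0/P0`.
#'
#' @param P0 total protein concentration (M), > 0
#' @param L0 total ligand (peptide) concentration (M), >= 0
#' @return an object of class `mix_composition`
#' @export
mix_composition <- function(P0, L0) {
  if (!is.finite(P0) || P0 <= 0) stop("P0 must be > 0")
  if (!is.finite(L0) || L0 < 0) stop("L0 must be >= 0")
  structure(list(P0 = P0, L0 = L0, equivalents = L0 / P0),
            class = "mix_composition")
}

#' @export
print.mix_composition <- function(x, ...) {
  cat(sprintf("Mix: P0 = %.4g M, L0 = %.4g M (%.3g equivalents)\n",
              x$P0, x$L0, x$equivalents))
  invisible(x)
}

#' Solve the three-state binding equilibrium
#'
#' Computes the equilibrium concentrations of free protein P, bound complex
#' PL, transiently unbound conformer PL* and free ligand L at fixed totals.
#' \[PL\] is the physical root of the mass-action quadratic
#' `k1_on A^2 x^2 - (k1_off + k1_on A (P0 + L0)) x + k1_on P0 L0 = 0`
#' with A = 1 + k2/k2'; the remaining species follow from
#' \[PL*\] = (k2/k2') \[PL\], \[P\] = P0 - A \[PL\], \[L\] = L0 - A \[PL\].
#'
#' @param scheme an [exchange_scheme()]
#' @param mix a [mix_composition()]
#' @return an object of class `equilibrium_state` with fields `P`, `PL`,
#'   `PLstar`, `L` (M) plus the totals
#' @details The smaller quadratic root is always the physical one
#'   (the larger violates `A*PL <= min(P0, L0)`). It is evaluated in the
#'   Citardauq form `2c / (-b + sqrt(b^2 - 4ac))`, which is free of
#'   cancellation when `k1_off << k1_on * P0` — the femtomolar-Kd regime where
#'   the naive formula loses all precision. Negative round-off no larger than
#'   `1e-15 * P0` in magnitude is clamped to zero.
#' @export
#' @examples
#' eq <- solve_equilibrium(exchange_scheme(1e9, 300, 30, 700),
#'                         mix_composition(250e-6, 325e-6))
#' eq$PLstar / eq$PL  # = k2/k2' = 30/700
solve_equilibrium <- function(scheme, mix) {
  stopifnot(inherits(scheme, "exchange_scheme"),
            inherits(mix, "mix_composition"))
  A <- scheme_A(scheme)
  P0 <- mix$P0
  L0 <- mix$L0
  if (L0 == 0 || scheme$k1_on == 0) {
    PL <- 0
  } else {
    a <- scheme$k1_on * A^2
    b <- -(scheme$k1_off + scheme$k1_on * A * (P0 + L0))
    cc <- scheme$k1_on * P0 * L0
    disc <- b^2 - 4 * a * cc
    # disc >= 0 always for physical inputs; guard round-off
    disc <- max(disc, 0)
    PL <- 2 * cc / (-b + sqrt(disc))
  }
  clamp0 <- function(x) {
    if (x < 0 && x > -1e-15 * P0) 0 else x
  }
  PLstar <- if (scheme$k2 == 0) 0 else (scheme$k2 / scheme$k2_prime) * PL
  out <- list(
    P = clamp0(P0 - A * PL),
    PL = clamp0(PL),
    PLstar = clamp0(PLstar),
    L = clamp0(L0 - A * PL),
    P0 = P0, L0 = L0
  )
  if (any(unlist(out[c("P", "PL", "PLstar", "L")]) < 0))
    stop("equilibrium solution produced a negative concentration")
  structure(out, class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Equilibrium state (M):\n")
  cat(sprintf("  P = %.6g  PL = %.6g  PL* = %.6g  L = %.6g\n",
              x$P, x$PL, x$PLstar, x$L))
  invisible(x)
}

#' Dissociation constant from rate constants
#'
#' `Kd = k_off / k_on`, the equilibrium dissociation constant of a
#' bimolecular binding step.
#'
#' @param k_on association rate constant (M^-1 s^-1), > 0
#' @param k_off dissociation rate constant (s^-1), >= 0
#' @return Kd in molar
#' @export
#' @examples
#' kd_from_rates(6.2e8, 3.0e-4)  # 4.84e-13 M: femtomolar binding
kd_from_rates <- function(k_on, k_off) {
  if (!is.finite(k_on) || k_on <= 0) stop("k_on must be > 0")
  if (!is.finite(k_off) || k_off < 0) stop("k_off must be >= 0")
  k_off / k_on
}

#' Dissociation constant of an exchange scheme
#'
#' Convenience wrapper: Kd of the binding step of a three-state scheme,
#' `k1_off / k1_on`.
#'
#' @param scheme an [exchange_scheme()]
#' @return Kd in molar
#' @export
scheme_kd <- function(scheme) {
  kd_from_rates(scheme$k1_on, scheme$k1_off)
}

#' Read a kinetic parameter table
#'
#' Reads a delimited text table of per-peptide kinetic constants with header
#' `peptide,k_on,k_off` (uncertainty columns `k_on_sd`, `k_off_sd` are kept
#' if present) and appends the derived `Kd = k_off/k_on` column.
#'
#' @param path path to a comma-separated file
#' @return a data.frame with a `Kd` column appended
#' @export
read_kinetic_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("peptide", "k_on", "k_off")
  if (!all(need %in% names(tab)))
    stop("kinetic table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$k_on <= 0)) stop("k_on must be > 0")
  if (any(tab$k_off < 0)) stop("k_off must be >= 0")
  tab$Kd <- tab$k_off / tab$k_on
  tab
}
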