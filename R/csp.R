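#' Chemical shift perturbation of one residue
#'
#' Weighted Euclidean combination of the amide 1H and 15N shift changes
#' between free and bound states,
#' `sqrt((dHf - dHb)^2 + ((dNf - dNb)/4)^2)` (ppm), the nitrogen axis being
#' compressed by its larger shift range. Residues unassigned in either state
#' are set to zero CSP.
#'
#' @param rs a list or one-row data.frame with fields `dH_free`, `dN_free`,
#'   `dH_bound`, `dN_bound` (ppm) and logical `assigned_free`,
#'   `assigned_bound`
#' @param nitrogen_weighting `"quarter"` (default): the nitrogen difference
#'   is divided by 4 before squaring; `"quarter_squared"`: the squared
#'   difference is divided by 4 (i.e. scaling by 1/2) — provided because the
#'   two readings differ only in the weighting
#' @return CSP in ppm (>= 0)
#' @export
#' @examples
#' csp(list(dH_free = 8, dN_free = 120, dH_bound = 8, dN_bound = 120.4,
#'          assigned_free = TRUE, assigned_bound = TRUE))  # 0.1
csp <- function(rs, nitrogen_weighting = c("quarter", "quarter_squared")) {
  nitrogen_weighting <- match.arg(nitrogen_weighting)
  af <- if (is.null(rs$assigned_free)) TRUE else isTRUE(rs$assigned_free)
  ab <- if (is.null(rs$assigned_bound)) TRUE else isTRUE(rs$assigned_bound)
  if (!af || !ab) return(0)
  dH <- rs$dH_free - rs$dH_bound
  dN <- rs$dN_free - rs$dN_bound
  if (nitrogen_weighting == "quarter") sqrt(dH^2 + (dN / 4)^2)
  else sqrt(dH^2 + dN^2 / 4)
}

#' CSP bin boundaries
#'
#' The five perturbation classes and their lower bounds (ppm). Bins are
#' half-open `[lower, upper)`: boundary values belong to the stronger bin.
#'
#' @return named numeric vector of lower bounds, strongest first
#' @export
csp_bins <- function() {
  c("very strong" = 1, strong = 0.5, moderate = 0.25, weak = 0.11, none = 0)
}

#' Classify a CSP value into a perturbation bin
#'
#' @param value CSP in ppm, >= 0 (vectorized)
#' @return character vector of bin labels among
#'   `"very strong"`, `"strong"`, `"moderate"`, `"weak"`, `"none"`
#' @export
#' @examples
#' classify_csp(c(1.2, 0.25, 0.05))
classify_csp <- function(value) {
  if (any(!is.finite(value)) || any(value < 0))
    stop("CSP values must be finite and >= 0")
  bins <- csp_bins()
  labs <- names(bins)
  vapply(value, function(v) labs[which(v >= bins)[1]], character(1))
}

#' Per-residue CSP table
#'
#' Joins free- and bound-state shift tables by residue id, computes the CSP
#' and its bin for every residue present in either table. A residue missing
#' from one table is flagged unassigned in that state and gets CSP 0; the
#' flags are kept so downstream users can distinguish "zero" from "unknown".
#'
#' @param free_table,bound_table data.frames with columns `residue`, `dH`,
#'   `dN` and optionally logical `assigned` (default TRUE); residue ids must
#'   be unique within each table
#' @param nitrogen_weighting passed to [csp()]
#' @return data.frame with columns `residue`, `csp_ppm`, `bin`,
#'   `assigned_free`, `assigned_bound`
#' @export
csp_table <- function(free_table, bound_table,
                      nitrogen_weighting = "quarter") {
  norm <- function(tab, side) {
    need <- c("residue", "dH", "dN")
    if (!all(need %in% names(tab)))
      stop(side, " table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$residue))
      stop("duplicate residue ids in ", side, " table")
    if (is.null(tab$assigned)) tab$assigned <- TRUE
    tab
  }
  ft <- norm(free_table, "free")
  bt <- norm(bound_table, "bound")
  ids <- sort(union(ft$residue, bt$residue))
  fi <- match(ids, ft$residue)
  bi <- match(ids, bt$residue)
  out <- data.frame(residue = ids, csp_ppm = NA_real_, bin = NA_character_,
                    assigned_free = !is.na(fi) & ft$assigned[pmax(fi, 1)],
                    assigned_bound = !is.na(bi) & bt$assigned[pmax(bi, 1)],
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    rs <- list(
      dH_free = if (is.na(fi[k])) NA_real_ else ft$dH[fi[k]],
      dN_free = if (is.na(fi[k])) NA_real_ else ft$dN[fi[k]],
      dH_bound = if (is.na(bi[k])) NA_real_ else bt$dH[bi[k]],
      dN_bound = if (is.na(bi[k])) NA_real_ else bt$dN[bi[k]],
      assigned_free = out$assigned_free[k],
      assigned_bound = out$assigned_bound[k]
    )
    out$csp_ppm[k] <- csp(rs, nitrogen_weighting)
  }
  out$bin <- classify_csp(out$csp_ppm)
  out
}

#' Read a chemical-shift table
#'
#' Comma-separated text with header `residue,dH,dN` and an optional
#' `assigned` column (logical/0-1); `#` comment lines and blank lines are
#' ignored.
#'
#' @param path file path
#' @return data.frame
#' @export
read_shift_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         blank.lines.skip = TRUE)
  if (!is.null(tab$assigned)) tab$assigned <- as.logical(tab$assigned)
  tab
}

#' Write a CSP table
#'
#' Comma-separated text with columns `residue,csp_ppm,bin`.
#'
#' @param tab data.frame from [csp_table()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_csp_table <- function(tab, path) {
  utils::write.csv(tab[, c("residue", "csp_ppm", "bin")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
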