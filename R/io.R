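#' Write a 1D spectrum as two-column text
#'
#' Comma-separated `frequency_hz,intensity` records preceded by `# key=value`
#' metadata header lines (scalar metadata entries only).
#'
#' @param spectrum a [spectrum1d()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  md <- spectrum$metadata
  for (nm in names(md)) {
    v <- md[[nm]]
    if (is.atomic(v) && length(v) == 1 && !is.na(v))
      writeLines(sprintf("# %s=%s", nm,
                         if (is.numeric(v)) format(v, digits = 17)
                         else as.character(v)), con)
  }
  writeLines("frequency_hz,intensity", con)
  writeLines(sprintf("%.10g,%.10g", spectrum$frequency,
                     spectrum$intensity), con)
  invisible(path)
}

#' Read a 1D spectrum from two-column text
#'
#' Tolerates blank lines and `#` comments; `# key=value` comments are parsed
#' back into metadata (numeric where possible).
#'
#' @param path file path
#' @return a [spectrum1d()]
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- list()
  hdr <- grep("^\\s*#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^[ \t]*#[ \t]*([^=[:space:]]+)[ \t]*=[ \t]*(.*)$",
                               h))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) trimws(m[3]) else val
    }
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data records in ", path)
  if (!grepl("^frequency_hz\\s*,\\s*intensity", body[1]))
    stop("missing 'frequency_hz,intensity' header in ", path)
  dat <- utils::read.csv(text = body)
  spectrum1d(dat$frequency_hz, dat$intensity, metadata = meta)
}

#' Write a titration series to a directory
#'
#' One spectrum file per slice, named `slice_<equivalents>.csv`, plus a
#' `ground_truth.txt` key=value sidecar when a [ground_truth()] is supplied.
#'
#' @param series a [titration_series()]
#' @param dir output directory (created if needed)
#' @param truth optional [ground_truth()] written alongside
#' @return character vector of written slice paths, invisibly
#' @export
write_titration_dir <- function(series, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series$slices))
  for (k in seq_along(series$slices)) {
    s <- series$slices[[k]]
    s$metadata$equivalents <- series$equivalents[k]
    s$metadata$P0 <- series$P0
    paths[k] <- file.path(dir, sprintf("slice_%07.3f.csv",
                                       series$equivalents[k]))
    write_spectrum(s, paths[k])
  }
  if (!is.null(truth)) write_ground_truth(truth, file.path(dir, "ground_truth.txt"))
  invisible(paths)
}

#' Read a titration series from a directory
#'
#' Reads every `slice_*.csv` file written by [write_titration_dir()],
#' ordered by the equivalents recorded in each file's metadata.
#'
#' @param dir directory path
#' @return a [titration_series()]
#' @export
read_titration_dir <- function(dir) {
  files <- list.files(dir, pattern = "^slice_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no slice_*.csv files in ", dir)
  slices <- lapply(files, read_spectrum)
  eqv <- vapply(slices, function(s) {
    if (is.null(s$metadata$equivalents))
      stop("slice file without equivalents metadata")
    s$metadata$equivalents
  }, numeric(1))
  ord <- order(eqv)
  P0 <- slices[[1]]$metadata$P0
  if (is.null(P0)) stop("slice files lack P0 metadata")
  titration_series(eqv[ord], slices[ord], P0)
}

write_ground_truth <- function(truth, path) {
  sc <- truth$scheme; sp <- truth$spin; acq <- truth$acq
  lines <- c(
    sprintf("scheme.k1_on_per_M_s = %.17g", sc$k1_on),
    sprintf("scheme.k1_off_per_s = %.17g", sc$k1_off),
    sprintf("scheme.k2_per_s = %.17g", sc$k2),
    sprintf("scheme.k2_prime_per_s = %.17g", sc$k2_prime),
    sprintf("spin.omega_P_hz = %.17g", sp$omega_P),
    sprintf("spin.omega_PL_hz = %.17g", sp$omega_PL),
    sprintf("spin.R2_per_s = %.17g", sp$R2),
    sprintf("spin.echo_time_s = %.17g", sp$echo_time),
    sprintf("mix.P0_M = %.17g", truth$P0),
    sprintf("titration.grid = %s",
            paste(format(truth$grid, digits = 17), collapse = ",")),
    sprintf("acq.spectral_width_hz = %.17g", acq$spectral_width),
    sprintf("acq.n_points = %d", acq$n_points),
    sprintf("acq.zero_fill_factor = %d", acq$zero_fill_factor),
    sprintf("acq.apodization = %s", acq$apodization),
    sprintf("synth.noise_sigma = %.17g", truth$noise_sigma),
    sprintf("synth.seed = %d", truth$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a structured run configuration
#'
#' Parses a flat `section.key = value` text file (blank lines and `#`
#' comments ignored) into a nested list. Every physical quantity carries an
#' explicit unit suffix in its key (`_per_s`, `_per_M_s`, `_hz`, `_s`, `_M`)
#' to keep units unambiguous; the suffix is kept in the returned names.
#' Values are numeric where possible; comma-separated values become numeric
#' vectors; `grid = default` expands to [default_equivalents_grid()].
#'
#' @param path config file path
#' @return nested named list, one element per section
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^[ \t]*([^=[:space:]]+)[ \t]*=[ \t]*(.*)$",
                                ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    m[3] <- trimws(m[3])
    key <- strsplit(m[2], ".", fixed = TRUE)[[1]]
    if (length(key) != 2)
      stop("config keys must be section.key: ", m[2])
    raw <- m[3]
    val <- if (identical(raw, "default") &&
               key[2] == "grid") default_equivalents_grid()
    else if (grepl(",", raw, fixed = TRUE)) {
      v <- suppressWarnings(as.numeric(strsplit(raw, ",")[[1]]))
      if (any(is.na(v))) strsplit(raw, ",")[[1]] else v
    } else {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) raw else v
    }
    if (is.null(cfg[[key[1]]])) cfg[[key[1]]] <- list()
    cfg[[key[1]]][[key[2]]] <- val
  }
  cfg
}

config_scheme <- function(cfg) {
  s <- cfg$scheme
  if (is.null(s)) stop("config lacks a [scheme] section")
  exchange_scheme(s$k1_on_per_M_s, s$k1_off_per_s,
                  if (is.null(s$k2_per_s)) 0 else s$k2_per_s,
                  if (is.null(s$k2_prime_per_s)) 0 else s$k2_prime_per_s)
}

config_spin <- function(cfg) {
  s <- cfg$spin
  if (is.null(s)) stop("config lacks a [spin] section")
  spin_parameters(s$omega_P_hz, s$omega_PL_hz, s$R2_per_s,
                  if (is.null(s$echo_time_s)) 0.011 else s$echo_time_s)
}

config_acq <- function(cfg) {
  a <- cfg$acq
  if (is.null(a)) return(acquisition_settings())
  acquisition_settings(
    spectral_width = if (is.null(a$spectral_width_hz)) 4000
                     else a$spectral_width_hz,
    n_points = if (is.null(a$n_points)) 2048 else a$n_points,
    zero_fill_factor = if (is.null(a$zero_fill_factor)) 2
                       else a$zero_fill_factor,
    apodization = if (is.null(a$apodization)) "cosine" else a$apodization)
}
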