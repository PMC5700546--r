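#' A circular-dichroism spectrum
#'
#' @param wavelengths wavelength grid, nm; strictly monotone (ascending or
#'   descending).
#' @param signal CD signal, one value per wavelength (millidegrees unless
#'   stated otherwise at conversion time).
#' @param meta optional metadata list (concentration, path length, residue
#'   count, condition, ...).
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, signal, meta = list()) {
  stopifnot(is.numeric(wavelengths), is.numeric(signal))
  if (length(wavelengths) != length(signal)) {
    stop("wavelengths and signal must have equal length")
  }
  d <- diff(wavelengths)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("wavelength grid must be strictly monotone")
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 signal = as.numeric(signal), meta = meta),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d points, %g-%g nm\n", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Average repeated scans and subtract a blank
#'
#' Pointwise mean of the scans minus the blank. All spectra must share an
#' identical wavelength grid; no interpolation is attempted.
#'
#' @param scans list of [cd_spectrum()] objects.
#' @param blank a [cd_spectrum()] on the same grid, or `NULL` for no
#'   subtraction.
#' @return A [cd_spectrum()].
#' @export
average_scans <- function(scans, blank = NULL) {
  stopifnot(is.list(scans), length(scans) >= 1L)
  grid <- scans[[1]]$wavelengths
  for (s in scans) {
    stopifnot(inherits(s, "cd_spectrum"))
    if (!identical(s$wavelengths, grid)) {
      stop("all scans must share an identical wavelength grid")
    }
  }
  avg <- rowMeans(do.call(cbind, lapply(scans, `[[`, "signal")))
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "cd_spectrum"))
    if (!identical(blank$wavelengths, grid)) {
      stop("blank wavelength grid does not match the scans")
    }
    avg <- avg - blank$signal
  }
  cd_spectrum(grid, avg, meta = scans[[1]]$meta)
}

#' Convert a CD signal to mean molar ellipticity
#'
#' \deqn{MME(\lambda) = \frac{signal(\lambda)}{c \cdot 10 \cdot L \cdot N_{res}}}
#' with the signal in degrees, `c` the molar protein concentration (M), `L`
#' the path length (cm) and `N_res` the number of residues in the construct.
#' Instruments export millidegrees; by default the signal is divided by 1000
#' before the formula is applied (`signal_unit = "mdeg"`); pass
#' `signal_unit = "deg"` if the spectrum is already in degrees.
#'
#' @param spec a [cd_spectrum()].
#' @param c_molar protein concentration, M (> 0).
#' @param path_cm cuvette path length, cm (> 0).
#' @param n_res residue count (>= 1); 95 for the S100A5 construct the
#'   defaults emulate.
#' @param signal_unit `"mdeg"` (default) or `"deg"`.
#' @return A [cd_spectrum()] whose signal is the mean molar ellipticity
#'   (deg cm2 dmol-1).
#' @export
mean_molar_ellipticity <- function(spec, c_molar, path_cm, n_res = 95,
                                   signal_unit = c("mdeg", "deg")) {
  stopifnot(inherits(spec, "cd_spectrum"))
  signal_unit <- match.arg(signal_unit)
  if (!is.numeric(c_molar) || c_molar <= 0) stop("c_molar must be > 0")
  if (!is.numeric(path_cm) || path_cm <= 0) stop("path_cm must be > 0")
  if (!is.numeric(n_res) || n_res < 1) stop("n_res must be >= 1")
  deg <- if (signal_unit == "mdeg") spec$signal * 1e-3 else spec$signal
  mme <- deg / (c_molar * 10 * path_cm * n_res)
  cd_spectrum(spec$wavelengths, mme,
              meta = c(spec$meta, list(converted = "mean molar ellipticity")))
}

#' Denaturation-corrected extinction coefficient
#'
#' Corrects a sequence-predicted extinction coefficient (valid for the
#' unfolded protein in concentrated denaturant) to the native state using
#' absorbances of the same sample in both buffers:
#' \deqn{\varepsilon_{native} = \varepsilon_{denat} \cdot A_{native} / A_{denat}}
#'
#' @param eps_denat predicted extinction coefficient in denaturant,
#'   1/(M cm).
#' @param A_native absorbance of the native sample.
#' @param A_denat absorbance of the denatured sample (> 0).
#' @return Native-state extinction coefficient, 1/(M cm).
#' @examples
#' corrected_extinction(5500, 0.91, 1.00) # 5005
#' @export
corrected_extinction <- function(eps_denat, A_native, A_denat) {
  stopifnot(is.numeric(eps_denat), is.numeric(A_native), is.numeric(A_denat))
  if (any(eps_denat <= 0) || any(A_native <= 0)) {
    stop("eps_denat and A_native must be > 0")
  }
  if (any(A_denat <= 0)) stop("A_denat must be > 0")
  eps_denat * A_native / A_denat
}

#' Read / write two-column CD spectra
#'
#' Plain-text format: comment header with a unit declaration, then
#' `wavelength_nm<TAB>signal_mdeg` rows.
#'
#' @param spec a [cd_spectrum()].
#' @param path file path.
#' @return `write_cd_spectrum` invisibly returns `path`;
#'   `read_cd_spectrum` returns a [cd_spectrum()].
#' @export
write_cd_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "cd_spectrum"))
  writeLines(c("# itcfit cd spectrum v1",
               "# units: wavelength=nm signal=mdeg",
               "wavelength\tsignal",
               paste(.fmt9(spec$wavelengths), .fmt9(spec$signal), sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cd_spectrum
#' @export
read_cd_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("empty CD spectrum: ", path)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  if (any(lengths(rows) != 2L)) {
    stop("malformed CD spectrum row in ", path)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 2L,
              byrow = TRUE)
  if (any(is.na(m))) stop("non-numeric CD spectrum value in ", path)
  cd_spectrum(m[, 1], m[, 2])
}
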