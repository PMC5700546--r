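#' Plain-text heat-table dialect
#'
#' The package's canonical integrated-heat format is a plain-text table with
#' commented header lines carrying the experiment metadata and unit
#' declarations, followed by one row per shot. The column layout, delimiter
#' and units are configurable to ingest close variants of integrated-heat
#' exports. All numeric output uses 9 significant digits with a
#' locale-independent decimal point.
#'
#' @param delimiter field separator (default tab).
#' @param columns column layout; a permutation of `c("shot", "dV", "heat")`
#'   or just `c("dV", "heat")`.
#' @param vol_unit injection-volume unit in the file: `"uL"`, `"mL"` or `"L"`.
#' @param heat_unit heat unit in the file: `"ucal"`, `"mcal"`, `"cal"` or
#'   `"kcal"`.
#' @return An object of class `heat_dialect`.
#' @export
heat_dialect <- function(delimiter = "\t", columns = c("shot", "dV", "heat"),
                         vol_unit = c("uL", "mL", "L"),
                         heat_unit = c("ucal", "mcal", "cal", "kcal")) {
  vol_unit <- match.arg(vol_unit)
  heat_unit <- match.arg(heat_unit)
  if (!all(columns %in% c("shot", "dV", "heat")) || anyDuplicated(columns) ||
      !all(c("dV", "heat") %in% columns)) {
    stop("columns must be a permutation of c('shot','dV','heat') or c('dV','heat')")
  }
  structure(list(delimiter = delimiter, columns = columns,
                 vol_unit = vol_unit, heat_unit = heat_unit),
            class = "heat_dialect")
}

# unit factors to internal units (L and kcal)
.vol_to_L <- c(uL = 1e-6, mL = 1e-3, L = 1)
.heat_to_kcal <- c(ucal = 1e-9, mcal = 1e-6, cal = 1e-3, kcal = 1)

.fmt9 <- function(x) sprintf("%.9g", x)

#' Write a titration experiment as a plain-text heat table
#'
#' Output is deterministic: the same experiment and dialect always produce
#' identical bytes.
#'
#' @param exp a [titration_experiment()].
#' @param path output file path.
#' @param dialect a [heat_dialect()].
#' @return Invisibly, `path`.
#' @export
write_integrated_heats <- function(exp, path, dialect = heat_dialect()) {
  stopifnot(inherits(exp, "titration_experiment"),
            inherits(dialect, "heat_dialect"))
  s <- exp$schedule
  n <- length(s$dV)
  header <- c(
    "# itcfit integrated heats v1",
    sprintf("# units: volume=%s heat=%s", dialect$vol_unit, dialect$heat_unit),
    sprintf("# V0_L: %s", .fmt9(s$V0)),
    sprintf("# syringe_conc_uM: %s", .fmt9(s$syringe_conc)),
    sprintf("# cell_conc_uM: %s", .fmt9(s$cell_conc)),
    sprintf("# temperature_C: %s", .fmt9(s$temperature)),
    sprintf("# condition: %s", exp$condition_label))
  cols <- list(shot = as.character(seq_len(n)),
               dV = .fmt9(s$dV / .vol_to_L[[dialect$vol_unit]]),
               heat = .fmt9(exp$heats / .heat_to_kcal[[dialect$heat_unit]]))
  body <- do.call(paste, c(cols[dialect$columns], sep = dialect$delimiter))
  head_row <- paste(dialect$columns, collapse = dialect$delimiter)
  writeLines(c(header, head_row, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a plain-text heat table as a titration experiment
#'
#' Malformed rows (ragged fields, non-numeric values, a non-monotone shot
#' index) are hard errors naming the offending line; nothing is silently
#' skipped. Heats are converted to internal kcal and volumes to litres
#' according to the dialect's declared units.
#'
#' @param path input file path.
#' @param dialect a [heat_dialect()].
#' @return A [titration_experiment()] (without truth).
#' @export
read_integrated_heats <- function(path, dialect = heat_dialect()) {
  stopifnot(inherits(dialect, "heat_dialect"))
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty heat table: ", path)
  is_comment <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  if (!is.null(meta$units)) {
    declared <- regmatches(meta$units,
                           regexec("volume=(\\S+)\\s+heat=(\\S+)", meta$units))[[1]]
    if (length(declared) == 3L &&
        (declared[2] != dialect$vol_unit || declared[3] != dialect$heat_unit)) {
      stop(sprintf("unit mismatch: file declares volume=%s heat=%s, dialect expects volume=%s heat=%s",
                   declared[2], declared[3], dialect$vol_unit, dialect$heat_unit))
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("heat table has no data rows: ", path)
  # first non-comment line is the column header
  hdr <- strsplit(lines[body_idx[1]], dialect$delimiter, fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), dialect$columns)) {
    stop(sprintf("line %d: column header '%s' does not match dialect columns '%s'",
                 body_idx[1], lines[body_idx[1]],
                 paste(dialect$columns, collapse = dialect$delimiter)))
  }
  data_idx <- body_idx[-1]
  if (length(data_idx) == 0L) stop("heat table has a header but no data: ", path)
  ncol <- length(dialect$columns)
  vals <- matrix(NA_real_, nrow = length(data_idx), ncol = ncol,
                 dimnames = list(NULL, dialect$columns))
  for (r in seq_along(data_idx)) {
    i <- data_idx[r]
    fields <- strsplit(lines[i], dialect$delimiter, fixed = TRUE)[[1]]
    if (length(fields) != ncol) {
      stop(sprintf("line %d: expected %d fields, found %d", i, ncol,
                   length(fields)))
    }
    num <- suppressWarnings(as.numeric(fields))
    if (any(is.na(num))) {
      stop(sprintf("line %d: non-numeric field in '%s'", i, lines[i]))
    }
    vals[r, ] <- num
  }
  if ("shot" %in% dialect$columns) {
    shot <- vals[, "shot"]
    if (any(diff(shot) <= 0)) {
      bad <- which(diff(shot) <= 0)[1] + 1L
      stop(sprintf("line %d: shot index is not strictly increasing",
                   data_idx[bad]))
    }
  }
  getm <- function(key, default) {
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  }
  sched <- injection_schedule(
    V0 = getm("V0_L", 1.4e-3),
    dV = vals[, "dV"] * .vol_to_L[[dialect$vol_unit]],
    syringe_conc = getm("syringe_conc_uM", 0),
    cell_conc = getm("cell_conc_uM", 0),
    temperature = getm("temperature_C", 25))
  titration_experiment(
    sched, vals[, "heat"] * .heat_to_kcal[[dialect$heat_unit]],
    condition_label = if (!is.null(meta$condition)) meta$condition else "")
}

#' Write a simulated study: one heat table per experiment plus a manifest
#'
#' The JSON manifest records the file names, condition labels and, for
#' synthetic experiments, the generating truth.
#'
#' @param experiments list of [titration_experiment()] objects.
#' @param dir output directory (created if needed).
#' @param dialect a [heat_dialect()].
#' @return Invisibly, the manifest list.
#' @export
write_study <- function(experiments, dir, dialect = heat_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(experiments), function(e) {
    ex <- experiments[[e]]
    fn <- sprintf("experiment_%02d.tsv", e)
    write_integrated_heats(ex, file.path(dir, fn), dialect)
    entry <- list(file = fn, condition = ex$condition_label)
    if (!is.null(ex$truth)) {
      entry$truth <- list(
        thermo = unclass(ex$truth$thermo),
        nuisance = unclass(ex$truth$nuisance))
    }
    entry
  })
  manifest <- list(format = "itcfit study manifest v1",
                   n_experiments = length(experiments),
                   experiments = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a study directory written by [write_study()]
#'
#' @param dir study directory containing `manifest.json`.
#' @param dialect a [heat_dialect()].
#' @return List of [titration_experiment()] objects.
#' @export
read_study <- function(dir, dialect = heat_dialect()) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path)
  lapply(manifest$experiments, function(entry) {
    read_integrated_heats(file.path(dir, entry$file), dialect)
  })
}
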