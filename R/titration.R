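#' Injection schedule of a titration
#'
#' Instrument geometry and injection program for a finite-volume calorimeter
#' cell: active cell volume, ordered per-shot injection volumes, syringe and
#' nominal cell concentrations, and the experiment temperature. The
#' temperature is recorded as metadata only; the equilibrium model is
#' isothermal.
#'
#' @param V0 active cell volume, litres.
#' @param dV ordered injection volumes, litres (one per shot, all > 0).
#' @param syringe_conc titrant concentration in the syringe, uM.
#' @param cell_conc nominal macromolecule concentration in the cell, uM.
#' @param temperature experiment temperature, degrees C (metadata).
#' @return An object of class `injection_schedule`.
#' @examples
#' injection_schedule(V0 = 1.4e-3, dV = rep(10e-6, 25),
#'                    syringe_conc = 900, cell_conc = 60)
#' @export
injection_schedule <- function(V0, dV, syringe_conc, cell_conc,
                               temperature = 25) {
  stopifnot(is.numeric(V0), length(V0) == 1L, V0 > 0,
            is.numeric(dV), is.numeric(syringe_conc), is.numeric(cell_conc),
            length(syringe_conc) == 1L, length(cell_conc) == 1L,
            syringe_conc >= 0, cell_conc >= 0)
  if (length(dV) > 0 && any(dV <= 0)) stop("all injection volumes must be > 0")
  if (any(dV >= V0)) stop("an injection volume must be smaller than the cell volume")
  if (sum(dV) > 0.3 * V0) {
    warning("total injected volume exceeds 30% of the cell volume; ",
            "the displacement model is a poor approximation")
  }
  structure(list(V0 = V0, dV = as.numeric(dV),
                 syringe_conc = syringe_conc, cell_conc = cell_conc,
                 temperature = temperature),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf("<injection_schedule> %d shots, V0 = %g mL\n",
              length(x$dV), x$V0 * 1e3))
  cat(sprintf("  syringe %g uM -> cell %g uM at %g C\n",
              x$syringe_conc, x$cell_conc, x$temperature))
  invisible(x)
}

#' Per-experiment nuisance parameters
#'
#' Parameters specific to one titration: the fraction-competent factor
#' `f_comp` multiplying the nominal cell concentration (absorbs concentration
#' measurement error in both components; values above 1 mean the protein
#' concentration was under-estimated or the titrant over-estimated, so the
#' admissible range is \[0, 2\], not \[0, 1\]), a dilution heat per mole of
#' injected titrant, a constant per-shot intercept heat, and the per-shot
#' Gaussian noise scale.
#'
#' @param f_comp fraction competent, dimensionless, in \[0, 2\].
#' @param dH_dil dilution heat per mole of injected titrant, kcal/mol.
#' @param q_int constant per-shot intercept heat, kcal/shot.
#' @param sigma per-shot Gaussian heat noise scale, kcal (> 0).
#' @return An object of class `nuisance_params`.
#' @export
nuisance_params <- function(f_comp = 1, dH_dil = 0, q_int = 0,
                            sigma = 2.5e-10) {
  stopifnot(is.numeric(f_comp), length(f_comp) == 1L,
            is.numeric(dH_dil), length(dH_dil) == 1L,
            is.numeric(q_int), length(q_int) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (f_comp < 0 || f_comp > 2) stop("f_comp must lie in [0, 2]")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(f_comp = f_comp, dH_dil = dH_dil, q_int = q_int,
                 sigma = sigma),
            class = "nuisance_params")
}

#' A titration experiment: schedule plus observed heats
#'
#' @param schedule an [injection_schedule()].
#' @param heats observed integrated heat per shot, kcal; one value per
#'   injection in the schedule.
#' @param condition_label free-text condition tag (e.g. "apo", "+Ca").
#' @param truth optional list with elements `thermo` ([thermo_params()]) and
#'   `nuisance` ([nuisance_params()]) recording the generating parameters of
#'   synthetic data.
#' @return An object of class `titration_experiment`.
#' @export
titration_experiment <- function(schedule, heats, condition_label = "",
                                 truth = NULL) {
  stopifnot(inherits(schedule, "injection_schedule"), is.numeric(heats))
  if (length(heats) != length(schedule$dV)) {
    stop("length(heats) must equal the number of injections")
  }
  if (!is.null(truth)) {
    stopifnot(inherits(truth$thermo, "thermo_params"),
              inherits(truth$nuisance, "nuisance_params"))
  }
  structure(list(schedule = schedule, heats = as.numeric(heats),
                 condition_label = condition_label, truth = truth),
            class = "titration_experiment")
}

#' @export
print.titration_experiment <- function(x, ...) {
  cat(sprintf("<titration_experiment> '%s', %d shots%s\n",
              x$condition_label, length(x$heats),
              if (is.null(x$truth)) "" else " (synthetic, truth attached)"))
  invisible(x)
}

#' Total concentrations in the cell after each injection
#'
#' Discrete displacement bookkeeping for an overfilled cell: each shot pushes
#' a volume `dV_i` of the current cell contents out of the active volume and
#' replaces it with syringe solution. After shot i,
#' \deqn{M_i = M_0 \prod_{j \le i} (1 - dV_j/V_0)}
#' \deqn{L_i = L_{i-1} (1 - dV_i/V_0) + C_{syr}\, dV_i/V_0}
#' This is exact arithmetic, not an exponential approximation.
#'
#' @param schedule an [injection_schedule()].
#' @return A data.frame with one row per shot: `M_tot` and `L_tot`, uM.
#' @export
evolve_concentrations <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  n <- length(schedule$dV)
  if (n == 0L) return(data.frame(M_tot = numeric(0), L_tot = numeric(0)))
  f <- 1 - schedule$dV / schedule$V0
  M_tot <- schedule$cell_conc * cumprod(f)
  L_tot <- numeric(n)
  L <- 0
  for (i in seq_len(n)) {
    L <- L * f[i] + schedule$syringe_conc * schedule$dV[i] / schedule$V0
    L_tot[i] <- L
  }
  data.frame(M_tot = M_tot, L_tot = L_tot)
}

#' Noise-free per-injection heats of a titration
#'
#' The observable model: with competent macromolecule
#' \eqn{M_{comp,i} = f_{comp} M_i} and cumulative heat content
#' \eqn{Q_i} = [total_heat_content()] at the post-shot-i equilibrium
#' (with the free ligand from [free_ligand()]), the heat of shot i is
#' \deqn{q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}
#'       + \Delta H_{dil}\, C_{syr} dV_i + q_{int}}
#' with \eqn{Q_0 = 0}. The middle term corrects for heat-carrying material
#' displaced from the active volume during the shot; the last two terms are
#' the linear dilution background (per-mole dilution heat of the injected
#' titrant plus a constant per-shot intercept). The noise scale in `nuisance`
#' plays no role here; it applies only when generating synthetic data.
#'
#' @param thermo a [thermo_params()] object.
#' @param nuisance a [nuisance_params()] object.
#' @param schedule an [injection_schedule()].
#' @param engine `"cpp"` (default) or `"R"` forward-model engine.
#' @return Numeric vector of per-shot heats, kcal.
#' @export
injection_heats <- function(thermo, nuisance, schedule,
                            engine = c("cpp", "R")) {
  stopifnot(inherits(thermo, "thermo_params"),
            inherits(nuisance, "nuisance_params"),
            inherits(schedule, "injection_schedule"))
  engine <- match.arg(engine)
  conc <- evolve_concentrations(schedule)
  dH2 <- if (thermo$model == "two_site") thermo$dH2 else 0
  K <- .assoc_constants(thermo)
  if (engine == "cpp") {
    return(cpp_injection_heats(K[["K1"]], K[["K2"]], thermo$dH1, dH2,
                               nuisance$f_comp, nuisance$dH_dil,
                               nuisance$q_int, conc$M_tot, conc$L_tot,
                               schedule$dV, schedule$V0,
                               schedule$syringe_conc))
  }
  .injection_heats_r(thermo, nuisance, schedule, conc)
}

.injection_heats_r <- function(thermo, nuisance, schedule, conc) {
  n <- length(schedule$dV)
  if (n == 0L) return(numeric(0))
  M_comp <- nuisance$f_comp * conc$M_tot
  Lf <- free_ligand(thermo, M_comp, conc$L_tot, engine = "R")
  Q <- total_heat_content(thermo, M_comp, Lf, schedule$V0)
  Qprev <- c(0, Q[-n])
  dVfrac <- schedule$dV / schedule$V0
  Q - Qprev + dVfrac * (Q + Qprev) / 2 +
    nuisance$dH_dil * (schedule$syringe_conc * 1e-6 * schedule$dV) +
    nuisance$q_int
}
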