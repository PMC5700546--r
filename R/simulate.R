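#' Reference parameter sets for the S100A5 metal-binding presets
#'
#' Central fitted values used as ground truth by the study presets: Cu2+
#' binds the Cys-free S100A5 variant at a single site, Ca2+ at two sites
#' described by a stepwise binding polynomial, each measured with and
#' without a saturating concentration of the other metal. The
#' `wildtype_aggregated` preset reuses the Cu2+ parameters but with a
#' competent fraction of 0.2 and five-fold noise, mimicking a
#' metal-driven-aggregation-degraded measurement.
#'
#' @param condition one of `"cu_apo"`, `"cu_plus_ca"`, `"ca_apo"`,
#'   `"ca_plus_cu"`, `"wildtype_aggregated"`.
#' @return List with elements `thermo` ([thermo_params()]), `f_comp`,
#'   `model`, `sigma_ucal` (per-shot noise, microcalories) and
#'   `label`.
#' @export
reference_params <- function(condition = c("cu_apo", "cu_plus_ca", "ca_apo",
                                           "ca_plus_cu",
                                           "wildtype_aggregated")) {
  condition <- match.arg(condition)
  switch(condition,
    cu_apo = list(
      thermo = thermo_params("single_site", Kd1 = 1.81, dH1 = -3.4),
      f_comp = 1.43, model = "single_site", sigma_ucal = 0.75,
      label = "Cu2+ into apo protein"),
    cu_plus_ca = list(
      thermo = thermo_params("single_site", Kd1 = 0.96, dH1 = -3.6),
      f_comp = 1.17, model = "single_site", sigma_ucal = 0.75,
      label = "Cu2+ into Ca2+-saturated protein"),
    ca_apo = list(
      thermo = thermo_params("two_site", Kd1 = 0.46, dH1 = -1.4,
                             Kd2 = 6.33, dH2 = -4.6),
      f_comp = 0.66, model = "two_site", sigma_ucal = 1.0,
      label = "Ca2+ into apo protein"),
    ca_plus_cu = list(
      thermo = thermo_params("two_site", Kd1 = 0.18, dH1 = -1.2,
                             Kd2 = 10.46, dH2 = -4.1),
      f_comp = 0.58, model = "two_site", sigma_ucal = 1.0,
      label = "Ca2+ into Cu2+-saturated protein"),
    wildtype_aggregated = list(
      thermo = thermo_params("single_site", Kd1 = 1.81, dH1 = -3.4),
      f_comp = 0.20, model = "single_site", sigma_ucal = 3.75,
      label = "Cu2+ into aggregating wildtype protein"))
}

#' Study preset: a fully specified simulated experimental design
#'
#' Resolves a named condition into the replicate structure of the emulated
#' study: Cu2+ titrations as two technical replicates each at its own
#' protein concentration drawn from 50-80 uM; Ca2+ titrations as four
#' experiments at one fixed protein concentration with titrant/titrate
#' ratios 8x, 10x, 15x and 18x; the aggregated-wildtype pathology as a
#' single noisy, low-competence titration.
#'
#' @inheritParams reference_params
#' @param seed integer seed controlling concentration draws and shot noise.
#' @param V0 active cell volume, litres.
#' @param dV injection volumes, litres (default 25 shots of 10 uL).
#' @param cu_syringe_ratio syringe/cell concentration ratio for the
#'   single-site (Cu2+) designs; the titration then reaches about 2.4
#'   equivalents of the competent protein.
#' @param sigma_ucal per-shot Gaussian noise, microcalories; defaults to
#'   the condition's calibrated value.
#' @param dH_dil true per-mole dilution heat, kcal/mol.
#' @param q_int true per-shot intercept heat, kcal.
#' @return An object of class `study_preset`.
#' @export
study_preset <- function(condition, seed = 1, V0 = 1.4e-3,
                         dV = rep(10e-6, 25), cu_syringe_ratio = 15,
                         sigma_ucal = NULL, dH_dil = -0.5, q_int = 1e-9) {
  ref <- reference_params(condition)
  if (is.null(sigma_ucal)) sigma_ucal <- ref$sigma_ucal
  if (ref$model == "two_site") {
    ratios <- c(8, 10, 15, 18)
    n_rep <- length(ratios)
  } else {
    ratios <- rep(cu_syringe_ratio, if (condition == "wildtype_aggregated") 1 else 2)
    n_rep <- length(ratios)
  }
  structure(list(condition = condition, ref = ref, seed = as.integer(seed),
                 V0 = V0, dV = dV, ratios = ratios, n_rep = n_rep,
                 sigma_ucal = sigma_ucal, dH_dil = dH_dil, q_int = q_int),
            class = "study_preset")
}

#' Generate one synthetic titration
#'
#' Observed heats are the noise-free [injection_heats()] plus iid Gaussian
#' noise of scale `nuisance$sigma`, drawn from the seeded stream. The
#' generating parameters are attached as `truth`.
#'
#' @param thermo a [thermo_params()].
#' @param nuisance a [nuisance_params()] (its `sigma` is the noise scale).
#' @param schedule an [injection_schedule()].
#' @param seed integer seed.
#' @param condition_label free-text tag stored on the experiment.
#' @return A [titration_experiment()] with `truth` attached.
#' @export
generate_experiment <- function(thermo, nuisance, schedule, seed = 1,
                                condition_label = "synthetic") {
  q <- injection_heats(thermo, nuisance, schedule)
  set.seed(as.integer(seed))
  heats <- q + stats::rnorm(length(q), 0, nuisance$sigma)
  titration_experiment(schedule, heats, condition_label = condition_label,
                       truth = list(thermo = thermo, nuisance = nuisance))
}

#' Generate a full synthetic study from a preset
#'
#' @param preset a [study_preset()] or a condition name understood by it.
#' @param seed seed override (defaults to the preset's).
#' @return List of [titration_experiment()] objects with truths attached.
#' @examples
#' study <- generate_study("cu_apo", seed = 7)
#' length(study) # 2 technical replicates
#' @export
generate_study <- function(preset, seed = NULL) {
  if (is.character(preset)) preset <- study_preset(preset)
  stopifnot(inherits(preset, "study_preset"))
  seed <- if (is.null(seed)) preset$seed else as.integer(seed)
  ref <- preset$ref
  sigma <- preset$sigma_ucal * 1e-9 # ucal -> kcal
  set.seed(seed)
  if (ref$model == "two_site") {
    cell <- stats::runif(1, 50, 80) # one fixed protein concentration
    cell_conc <- rep(cell, preset$n_rep)
  } else {
    cell_conc <- stats::runif(preset$n_rep, 50, 80)
  }
  nuis <- nuisance_params(f_comp = ref$f_comp, dH_dil = preset$dH_dil,
                          q_int = preset$q_int, sigma = sigma)
  lapply(seq_len(preset$n_rep), function(e) {
    sched <- injection_schedule(
      V0 = preset$V0, dV = preset$dV,
      syringe_conc = preset$ratios[e] * cell_conc[e],
      cell_conc = cell_conc[e])
    lab <- sprintf("%s [%gx, rep %d]", ref$label, preset$ratios[e], e)
    sub_seed <- as.integer((as.numeric(seed) * 1000 + e) %% 2147483647)
    generate_experiment(ref$thermo, nuis, sched,
                        seed = sub_seed, condition_label = lab)
  })
}
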