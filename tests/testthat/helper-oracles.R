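# Independent oracles and fixture builders shared across the suite.

# Plain bisection solve of the free-ligand mass balance, independent of the
# package's closed-form/Newton solvers. K1, K2 are association constants
# (1/uM); returns L in [0, L_tot] with |residual| <= tol * max(L_tot, 1).
bisect_free_ligand <- function(K1, K2, M, L_tot, tol = 1e-13) {
  if (L_tot == 0) return(0)
  resid <- function(L) {
    P <- 1 + K1 * L + K1 * K2 * L^2
    L + M * (K1 * L + 2 * K1 * K2 * L^2) / P - L_tot
  }
  lo <- 0; hi <- L_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= tol * max(L_tot, 1)) break
  }
  (lo + hi) / 2
}

# Small default geometry used by most tests: 25 x 10 uL shots into a 1.4 mL
# cell, matching the generator's defaults.
test_schedule <- function(syringe_conc = 900, cell_conc = 60, n_shots = 25,
                          dV = 10e-6, V0 = 1.4e-3) {
  injection_schedule(V0 = V0, dV = rep(dV, n_shots),
                     syringe_conc = syringe_conc, cell_conc = cell_conc)
}

# Cumulative heat content after each shot, recomputed from the public
# pieces (mass balance + heat content); used for the telescoping identity.
cumulative_Q <- function(thermo, nuisance, schedule) {
  conc <- evolve_concentrations(schedule)
  M_comp <- nuisance$f_comp * conc$M_tot
  Lf <- free_ligand(thermo, M_comp, conc$L_tot)
  total_heat_content(thermo, M_comp, Lf, schedule$V0)
}
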