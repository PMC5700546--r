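#' Thermodynamic parameters of a binding model
#'
#' Construct the shared thermodynamic parameter set of a calorimetric binding
#' model: a single-site model (one dissociation constant, one enthalpy) or a
#' two-site stepwise binding polynomial (two macroscopic dissociation
#' constants, two stepwise enthalpies).
#'
#' Package-wide unit conventions: concentrations and dissociation constants in
#' \eqn{\mu M}, molar enthalpies in kcal/mol, volumes in litres, heats in kcal.
#'
#' For the two-site model the parameters are *stepwise macroscopic* constants:
#' \eqn{K_1 = 1/K_{d,1}} governs the first ligation step and
#' \eqn{K_2 = 1/K_{d,2}} the second. The likelihood of any titration is
#' invariant under relabelling the two steps, so the parameters are kept in
#' the canonical order \eqn{K_{d,1} \le K_{d,2}} (site 1 is the
#' higher-affinity step); if the arguments arrive in the opposite order the
#' constructor swaps the (Kd, dH) pairs together.
#'
#' @param model `"single_site"` or `"two_site"`.
#' @param Kd1 dissociation constant of the first (higher-affinity) step, uM.
#' @param dH1 molar enthalpy of the first step, kcal/mol.
#' @param Kd2 dissociation constant of the second step, uM (two-site only).
#' @param dH2 molar enthalpy of the second step, kcal/mol (two-site only).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params("single_site", Kd1 = 1.8, dH1 = -3.4)
#' thermo_params("two_site", Kd1 = 6.3, dH1 = -4.6, Kd2 = 0.46, dH2 = -1.4)
#' @export
thermo_params <- function(model = c("single_site", "two_site"),
                          Kd1, dH1, Kd2 = NULL, dH2 = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(Kd1), length(Kd1) == 1L, is.finite(Kd1),
            is.numeric(dH1), length(dH1) == 1L, is.finite(dH1))
  if (Kd1 <= 0) stop("Kd1 must be > 0")
  if (model == "single_site") {
    if (!is.null(Kd2) || !is.null(dH2)) {
      stop("Kd2/dH2 are not meaningful for the single-site model")
    }
    obj <- list(model = model, Kd1 = Kd1, dH1 = dH1)
  } else {
    stopifnot(is.numeric(Kd2), length(Kd2) == 1L, is.finite(Kd2),
              is.numeric(dH2), length(dH2) == 1L, is.finite(dH2))
    if (Kd2 <= 0) stop("Kd2 must be > 0")
    if (Kd1 > Kd2) { # canonical order: step 1 is the tighter site
      tmp <- Kd1; Kd1 <- Kd2; Kd2 <- tmp
      tmp <- dH1; dH1 <- dH2; dH2 <- tmp
    }
    obj <- list(model = model, Kd1 = Kd1, dH1 = dH1, Kd2 = Kd2, dH2 = dH2)
  }
  class(obj) <- "thermo_params"
  obj
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>", x$model, "\n")
  cat(sprintf("  Kd1 = %g uM, dH1 = %g kcal/mol\n", x$Kd1, x$dH1))
  if (x$model == "two_site") {
    cat(sprintf("  Kd2 = %g uM, dH2 = %g kcal/mol\n", x$Kd2, x$dH2))
  }
  invisible(x)
}

# stepwise macroscopic association constants (1/uM); K2 = 0 collapses the
# two-site polynomial to the single-site model
.assoc_constants <- function(params) {
  K1 <- 1 / params$Kd1
  K2 <- if (params$model == "two_site") 1 / params$Kd2 else 0
  c(K1 = K1, K2 = K2)
}

#' Binding polynomial and species fractions at a known free-ligand activity
#'
#' Evaluate the stepwise binding polynomial
#' \eqn{P = 1 + K_1 L + K_1 K_2 L^2} at a free titrant concentration `L_free`
#' and return the equilibrium ligation-state fractions. `F1` is the fraction
#' of macromolecule with exactly one ligand bound (\eqn{K_1 L / P}), `F2`
#' the fraction with two (\eqn{K_1 K_2 L^2 / P}), and
#' \eqn{\bar n = F_1 + 2 F_2} the mean number of ligands bound. For the
#' single-site model \eqn{K_2 = 0} identically, so `F2 = 0`.
#'
#' @param params a [thermo_params()] object.
#' @param L_free free titrant concentration(s), uM; vectorised.
#' @return A data.frame with columns `L_free`, `P`, `F1`, `F2`, `n_avg`.
#' @examples
#' p <- thermo_params("two_site", Kd1 = 1, dH1 = -4, Kd2 = 1, dH2 = -4)
#' binding_polynomial(p, L_free = 1) # P = 3, F1 = F2 = 1/3, n_avg = 1
#' @export
binding_polynomial <- function(params, L_free) {
  stopifnot(inherits(params, "thermo_params"), is.numeric(L_free))
  if (any(!is.finite(L_free)) || any(L_free < 0)) {
    stop("L_free must be finite and >= 0")
  }
  K <- .assoc_constants(params)
  P <- 1 + K[["K1"]] * L_free + K[["K1"]] * K[["K2"]] * L_free^2
  F1 <- K[["K1"]] * L_free / P
  F2 <- K[["K1"]] * K[["K2"]] * L_free^2 / P
  data.frame(L_free = L_free, P = P, F1 = F1, F2 = F2, n_avg = F1 + 2 * F2)
}

#' Solve the free-ligand mass balance
#'
#' Given a total titrant concentration `L_tot` and a competent macromolecule
#' concentration `M_comp`, find the unique free titrant concentration
#' \eqn{L \in [0, L_{tot}]} satisfying
#' \eqn{L_{tot} = L + M_{comp}\,\bar n(L)}. For the single-site model the
#' quadratic mass balance is solved in closed form (numerically stable root);
#' for the two-site model a safeguarded Newton iteration on the bracketed,
#' monotone residual is used. The relative mass-balance residual of the
#' returned root is below 1e-10.
#'
#' @param params a [thermo_params()] object.
#' @param M_comp competent macromolecule concentration(s), uM.
#' @param L_tot total titrant concentration(s), uM.
#' @param engine `"cpp"` (default) or `"R"`; both implement the same
#'   contract and agree to near machine precision.
#' @return Free ligand concentration(s), uM, recycled to the common length.
#' @examples
#' p <- thermo_params("single_site", Kd1 = 1, dH1 = -4)
#' free_ligand(p, M_comp = 50, L_tot = 25) # ~0.93 uM
#' @export
free_ligand <- function(params, M_comp, L_tot, engine = c("cpp", "R")) {
  stopifnot(inherits(params, "thermo_params"),
            is.numeric(M_comp), is.numeric(L_tot))
  engine <- match.arg(engine)
  if (any(!is.finite(M_comp)) || any(M_comp < 0)) stop("M_comp must be >= 0")
  if (any(!is.finite(L_tot)) || any(L_tot < 0)) stop("L_tot must be >= 0")
  n <- max(length(M_comp), length(L_tot))
  M_comp <- rep_len(M_comp, n)
  L_tot <- rep_len(L_tot, n)
  K <- .assoc_constants(params)
  if (engine == "cpp") {
    return(cpp_free_ligand(K[["K1"]], K[["K2"]], M_comp, L_tot))
  }
  .free_ligand_r(K[["K1"]], K[["K2"]], M_comp, L_tot)
}

# pure-R reference solver; vectorised safeguarded Newton on the bracket
# [0, L_tot] for the two-site cubic, closed-form root for single-site
.free_ligand_r <- function(K1, K2, M, Ltot) {
  if (K2 == 0) {
    # K1 L^2 + (1 + K1 (M - Ltot)) L - Ltot = 0, positive root, stable form
    b <- 1 + K1 * (M - Ltot)
    disc <- sqrt(b^2 + 4 * K1 * Ltot)
    L <- ifelse(b >= 0, 2 * Ltot / (b + disc), (disc - b) / (2 * K1))
    return(pmin(L, Ltot))
  }
  # residual g(L) = L + M * n_avg(L) - Ltot, strictly increasing on [0, Ltot]
  g <- function(L) {
    P <- 1 + K1 * L + K1 * K2 * L^2
    L + M * (K1 * L + 2 * K1 * K2 * L^2) / P - Ltot
  }
  gprime <- function(L) {
    P <- 1 + K1 * L + K1 * K2 * L^2
    dP <- K1 + 2 * K1 * K2 * L
    num <- K1 * L + 2 * K1 * K2 * L^2
    dnum <- K1 + 4 * K1 * K2 * L
    1 + M * (dnum * P - num * dP) / P^2
  }
  lo <- numeric(length(Ltot))
  hi <- Ltot
  L <- Ltot / 2
  for (iter in seq_len(100L)) {
    gv <- g(L)
    hi <- ifelse(gv > 0, L, hi)
    lo <- ifelse(gv <= 0, L, lo)
    step <- gv / gprime(L)
    Lnew <- L - step
    bad <- !is.finite(Lnew) | Lnew <= lo | Lnew >= hi
    Lnew[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(Lnew - L) <= 1e-14 * pmax(Lnew, 1e-300)
    L <- Lnew
    if (all(done | Ltot == 0)) break
  }
  L[Ltot == 0] <- 0
  L
}

#' Total heat content of the cell at equilibrium
#'
#' Cumulative heat (kcal) evolved by forming the equilibrium ligation-state
#' distribution from the free components:
#' \deqn{Q = V_0 \, [M_{comp}] \, (\Delta H_1 F_1 + (\Delta H_1 + \Delta H_2) F_2)}
#' with the concentration converted from uM to mol/L. The single-site model
#' reduces to \eqn{Q = V_0 [M_{comp}] \Delta H_1 F_1}.
#'
#' @param params a [thermo_params()] object.
#' @param M_comp competent macromolecule concentration, uM.
#' @param L_free free titrant concentration, uM; vectorised with `M_comp`.
#' @param V0 active cell volume, litres.
#' @return Heat content in kcal.
#' @export
total_heat_content <- function(params, M_comp, L_free, V0) {
  stopifnot(is.numeric(V0), length(V0) == 1L, V0 > 0)
  if (any(M_comp < 0)) stop("M_comp must be >= 0")
  st <- binding_polynomial(params, L_free)
  dH2 <- if (params$model == "two_site") params$dH2 else 0
  V0 * (M_comp * 1e-6) * (params$dH1 * st$F1 + (params$dH1 + dH2) * st$F2)
}
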