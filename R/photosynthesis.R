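#' @title Leaf photosynthesis models
#' @description
#' Standard steady-state leaf models used both to fit measured response
#' curves and as forward models inside the mechanistic simulator: the
#' Farquhar-von Caemmerer-Berry (FvCB) biochemical model for C3 leaves, a
#' simplified enzyme-limited C4 form, and the non-rectangular hyperbola for
#' light-response curves. Rubisco kinetic constants default to the
#' published 25 degC values and are held fixed (no Arrhenius scaling by
#' default): curves here are measured at a single controlled cuvette
#' temperature, so temperature machinery would only add unidentifiable
#' freedom.
#' @name photosynthesis_models
NULL

#' FvCB C3 net assimilation
#'
#' `Ac = Vcmax (Ci - G*) / (Ci + Kc (1 + O/Ko))`,
#' `Aj = J (Ci - G*) / (4 Ci + 8 G*)`, `A = min(Ac, Aj) - Rd`.
#' At `Ci = G*` (the photorespiratory compensation point of the gross
#' terms) both gross rates vanish and `A = -Rd` exactly.
#'
#' @param Ci intercellular CO2, umol mol-1 (> 0, vectorized).
#' @param Vcmax maximum Rubisco carboxylation rate, umol m-2 s-1.
#' @param J electron transport rate available for RuBP regeneration,
#'   umol m-2 s-1.
#' @param Rd dark respiration, umol m-2 s-1.
#' @param Kc,Ko Michaelis constants for CO2 (umol mol-1) and O2
#'   (mmol mol-1); defaults 404.9 and 278.4.
#' @param gamma_star photorespiratory CO2 compensation point G*,
#'   umol mol-1; default 42.75.
#' @param O oxygen concentration, mmol mol-1; default 210.
#' @param smooth use a hyperbolic-minimum transition between `Ac` and `Aj`
#'   instead of the hard `min()`; default `FALSE` (simplest published
#'   form; smoothing shifts fitted `Vcmax` slightly).
#' @param theta_smooth convexity of the smoothed transition.
#' @return Net assimilation A, umol CO2 m-2 s-1.
#' @export
fvcb_c3 <- function(Ci, Vcmax, J, Rd, Kc = 404.9, Ko = 278.4,
                    gamma_star = 42.75, O = 210,
                    smooth = FALSE, theta_smooth = 0.995) {
  if (any(Ci <= 0)) abort("Ci must be > 0")
  stopifnot(Vcmax > 0, J > 0, Rd >= 0)
  Ac <- Vcmax * (Ci - gamma_star) / (Ci + Kc * (1 + O / Ko))
  Aj <- J * (Ci - gamma_star) / (4 * Ci + 8 * gamma_star)
  gross <- if (smooth) {
    hyperbolic_min(Ac, Aj, theta_smooth)
  } else {
    pmin(Ac, Aj)
  }
  gross - Rd
}

# smaller root of theta x^2 - (a + b) x + a b = 0: smooth minimum of a, b
hyperbolic_min <- function(a, b, theta) {
  ((a + b) - sqrt((a + b)^2 - 4 * theta * a * b)) / (2 * theta)
}

#' Simplified C4 net assimilation
#'
#' Enzyme-limited C4 form: assimilation is the minimum of the
#' PEP-carboxylation-limited rate `Vpmax Ci / (Ci + Kp)` and the Rubisco
#' plateau `Vcmax` (the CO2-concentrating mechanism keeps the bundle
#' sheath near CO2 saturation), minus `Rd`. It saturates at far lower Ci
#' than the C3 model: the half-saturation constant `Kp` (default 80
#' umol mol-1) is an order of magnitude below the effective C3 Michaelis
#' term (~1000 umol mol-1).
#'
#' @param Ci intercellular CO2, umol mol-1 (> 0, vectorized).
#' @param Vcmax Rubisco-limited plateau, umol m-2 s-1.
#' @param Vpmax maximum PEP carboxylation rate, umol m-2 s-1.
#' @param Rd dark respiration, umol m-2 s-1.
#' @param Kp Michaelis constant of PEP carboxylase for CO2, umol mol-1.
#' @return Net assimilation, umol CO2 m-2 s-1.
#' @export
c4_assim <- function(Ci, Vcmax, Vpmax, Rd, Kp = 80) {
  if (any(Ci <= 0)) abort("Ci must be > 0")
  stopifnot(Vcmax > 0, Vpmax > 0, Rd >= 0)
  pmin(Vpmax * Ci / (Ci + Kp), Vcmax) - Rd
}

#' Non-rectangular hyperbola light response
#'
#' `A(Q) = [phi Q + Amax - sqrt((phi Q + Amax)^2 - 4 theta phi Q Amax)] /
#' (2 theta) - Rd`. `Amax` is the light-saturated gross plateau, so
#' `A(0) = -Rd` exactly. As `theta -> 0` the form reduces to the
#' rectangular hyperbola `phi Q Amax / (phi Q + Amax) - Rd`, which is used
#' directly for `theta < 1e-8`.
#'
#' @param Q photosynthetic photon flux density, umol m-2 s-1 (>= 0).
#' @param Amax gross light-saturated assimilation, umol m-2 s-1.
#' @param Rd dark respiration, umol m-2 s-1.
#' @param phi apparent quantum yield, mol CO2 mol-1 photons.
#' @param theta convexity in `[0, 1)`.
#' @return Net assimilation, umol CO2 m-2 s-1.
#' @export
light_response <- function(Q, Amax, Rd, phi, theta) {
  if (any(Q < 0)) abort("Q must be >= 0")
  stopifnot(Amax > 0, Rd >= 0, phi > 0, theta >= 0, theta < 1)
  if (theta < 1e-8) {
    return(phi * Q * Amax / (phi * Q + Amax) - Rd)
  }
  hyperbolic_min(phi * Q, Amax, theta) - Rd
}

#' Photorespiration from the FvCB oxygenation ratio
#'
#' Under the FvCB model the oxygenation:carboxylation ratio is
#' `Vo/Vc = 2 G*/Ci`, and half the oxygenation flux releases CO2, so
#' `Pr = 0.5 Vo = Vc G*/Ci` with `Vc = Vcmax Ci / (Ci + Kc (1 + O/Ko))`.
#' For the C4 pathway the effective compensation point at the bundle
#' sheath is near zero (default `gamma_star = 2`), giving the observed
#' near-zero photorespiration.
#'
#' @inheritParams fvcb_c3
#' @return Photorespiration rate, umol CO2 m-2 s-1.
#' @export
photorespiration <- function(Ci, Vcmax, Kc = 404.9, Ko = 278.4,
                             gamma_star = 42.75, O = 210) {
  if (any(Ci <= 0)) abort("Ci must be > 0")
  Vc <- Vcmax * Ci / (Ci + Kc * (1 + O / Ko))
  Vc * gamma_star / Ci
}

## ---- curve fitting --------------------------------------------------------

#' Fit an A/Ci curve
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the C3 FvCB model or the simplified C4 model
#' to measured `(Ci, A)` points. Starting values are deterministic:
#' `Vcmax` from inverting the Rubisco-limited limb on the low-Ci points,
#' `J` (or `Vpmax`) from the observed maximum. The CO2-saturated
#' photosynthetic potential `AmaxCO2` is reported as the model prediction
#' at `Ci = 2000` umol mol-1.
#'
#' @param curve data.frame with columns `Ci` and `A` (>= 5 points).
#' @param pathway `"C3"` or `"C4"`.
#' @param Kc,Ko,gamma_star,O kinetic constants for the C3 model.
#' @param Kp PEP carboxylase constant for the C4 model.
#' @return list: `Vcmax`, `J` (C3) or `Vpmax` (C4), `Rd`, `AmaxCO2`,
#'   `converged`, `rmse`, `fit` (the `nls` object).
#' @export
fit_aci <- function(curve, pathway = c("C3", "C4"),
                    Kc = 404.9, Ko = 278.4, gamma_star = 42.75, O = 210,
                    Kp = 80) {
  pathway <- match.arg(pathway)
  curve <- validate_curve(curve, "Ci")
  if (max(curve$A) - min(curve$A) < 1e-10) {
    abort("degenerate curve: all A values identical")
  }

  low <- curve[curve$Ci <= stats::quantile(curve$Ci, 0.4), , drop = FALSE]
  rd0 <- max(0.1, -min(curve$A), 0.5)
  if (pathway == "C3") {
    km <- Kc * (1 + O / Ko)
    v0 <- stats::median((low$A + rd0) * (low$Ci + km) /
                          pmax(low$Ci - gamma_star, 1))
    v0 <- max(v0, 5)
    j0 <- 4 * (max(curve$A) + rd0) * 1.1
    fit <- tryCatch(
      minpack.lm::nlsLM(
        A ~ fvcb_c3(Ci, Vcmax, J, Rd, Kc = Kc, Ko = Ko,
                    gamma_star = gamma_star, O = O),
        data = curve,
        start = list(Vcmax = v0, J = j0, Rd = rd0),
        lower = c(Vcmax = 1, J = 1, Rd = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  } else {
    v0 <- max(curve$A) + rd0
    vp0 <- stats::median((low$A + rd0) * (low$Ci + Kp) / pmax(low$Ci, 1))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        A ~ c4_assim(Ci, Vcmax, Vpmax, Rd, Kp = Kp),
        data = curve,
        start = list(Vcmax = v0, Vpmax = max(vp0, 2), Rd = rd0),
        lower = c(Vcmax = 0.5, Vpmax = 0.5, Rd = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  if (inherits(fit, "error")) {
    abort("A/Ci fit did not converge: %s", conditionMessage(fit))
  }
  cf <- as.list(stats::coef(fit))
  pred2000 <- stats::predict(fit, newdata = data.frame(Ci = 2000))
  out <- c(cf, list(
    AmaxCO2 = unname(pred2000),
    converged = fit$convInfo$isConv %||% TRUE,
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    fit = fit))
  out
}

#' Fit an A/PPFD light-response curve
#'
#' Fits the non-rectangular hyperbola by Levenberg-Marquardt least
#' squares. Deterministic initialization: `phi` and `Rd` from a straight
#' line through the three lowest-light points, `Amax` from the maximum
#' observed net rate plus `Rd`, `theta` from 0.7.
#'
#' @param curve data.frame with columns `Q` (PPFD) and `A` (>= 5 points,
#'   including a low-light region).
#' @return list: `Amax`, `Rd`, `phi`, `theta`, `AmaxL` (net
#'   light-saturated capacity `Amax - Rd`), `converged`, `rmse`, `fit`.
#' @export
fit_light <- function(curve) {
  curve <- validate_curve(curve, "Q")
  if (max(curve$A) - min(curve$A) < 1e-10) {
    abort("degenerate curve: all A values identical")
  }
  lowest <- utils::head(curve[order(curve$Q), ], 3)
  lf <- stats::lm(A ~ Q, data = lowest)
  phi0 <- max(stats::coef(lf)[["Q"]], 1e-3)
  rd0 <- max(-stats::coef(lf)[["(Intercept)"]], 0.05)
  amax0 <- max(curve$A) + rd0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A ~ light_response(Q, Amax, Rd, phi, theta),
      data = curve,
      start = list(Amax = amax0, Rd = rd0, phi = phi0, theta = 0.7),
      lower = c(Amax = 0.1, Rd = 0, phi = 1e-4, theta = 0),
      upper = c(Amax = Inf, Rd = Inf, phi = 0.2, theta = 0.999),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    abort("light-response fit did not converge: %s", conditionMessage(fit))
  }
  cf <- as.list(stats::coef(fit))
  c(cf, list(AmaxL = cf$Amax - cf$Rd,
             converged = fit$convInfo$isConv %||% TRUE,
             rmse = sqrt(mean(stats::residuals(fit)^2)),
             fit = fit))
}

validate_curve <- function(curve, xvar) {
  curve <- as.data.frame(curve)
  if (!all(c(xvar, "A") %in% names(curve))) {
    abort("curve needs columns %s and A", xvar)
  }
  curve <- curve[stats::complete.cases(curve[, c(xvar, "A")]), ]
  if (nrow(curve) < 5) abort("need >= 5 curve points, got %d", nrow(curve))
  if (anyDuplicated(curve[[xvar]])) {
    abort("duplicated %s values in curve", xvar)
  }
  curve[order(curve[[xvar]]), ]
}

## ---- derived quantities ---------------------------------------------------

#' Relative stomatal limitation to photosynthesis
#'
#' `Ls = 100 (A(Ci = Ca) - A_operational) / A(Ci = Ca)`: the percentage of
#' assimilation lost to the stomatal CO2 drawdown from ambient `Ca` to the
#' operational `Ci`.
#'
#' @param A_operational assimilation at the operational Ci.
#' @param A_at_Ca assimilation the leaf would achieve at `Ci = Ca` (> 0).
#' @return Percentage in `[0, 100]` when `A_operational <= A_at_Ca`;
#'   a negative value (with a warning) flags apparent supersaturation.
#' @export
stomatal_limitation <- function(A_operational, A_at_Ca) {
  if (any(A_at_Ca <= 0)) abort("A_at_Ca must be > 0")
  ls <- 100 * (A_at_Ca - A_operational) / A_at_Ca
  if (any(ls < 0)) {
    warning("A_operational > A_at_Ca: negative Ls (supersaturation artifact)",
            call. = FALSE)
  }
  ls
}

#' PSII fluorescence parameters from raw signals
#'
#' Standard saturation-pulse derivations: `Fv/Fm = (Fm - Fo)/Fm`,
#' `dF/Fm' = (Fm' - Fs)/Fm'`, `qP = (Fm' - Fs)/(Fm' - Fo')`,
#' `NPQ = Fm/Fm' - 1`, `ETR = dF/Fm' * PPFD * PSII_fraction * absorptance`.
#' All outputs are invariant to rescaling every raw signal by a common
#' positive factor. The PSII excitation fraction (default 0.5) and leaf
#' absorptance (default 0.84) are explicit arguments, not constants —
#' both are species-dependent.
#'
#' @param Fo,Fm dark-adapted minimal and maximal fluorescence (`Fm > Fo > 0`).
#' @param Fs,Fm_prime steady-state and light-adapted maximal fluorescence
#'   (`Fm_prime > Fs > 0`, `Fm >= Fm_prime`).
#' @param Fo_prime light-adapted minimal fluorescence (optional; `qP` is
#'   `NA` without it).
#' @param PPFD actinic light, umol m-2 s-1.
#' @param absorptance leaf absorptance fraction.
#' @param PSII_fraction fraction of absorbed quanta reaching PSII.
#' @return list: `FvFm`, `dF_Fm`, `qP`, `NPQ`, `ETR`.
#' @examples
#' fluorescence_params(Fo = 400, Fm = 2000, Fs = 600, Fm_prime = 800,
#'                     PPFD = 1000)
#' @export
fluorescence_params <- function(Fo, Fm, Fs, Fm_prime, Fo_prime = NULL,
                                PPFD, absorptance = 0.84,
                                PSII_fraction = 0.5) {
  if (!(Fo > 0)) abort("invalid fluorescence record: Fo must be > 0")
  if (!(Fm > Fo)) abort("invalid fluorescence record: need Fm > Fo")
  if (!(Fs > 0)) abort("invalid fluorescence record: Fs must be > 0")
  if (!(Fm_prime > Fs)) {
    abort("invalid fluorescence record: need Fm_prime > Fs")
  }
  if (Fm < Fm_prime) {
    abort("invalid fluorescence record: need Fm >= Fm_prime")
  }
  if (PPFD < 0) abort("PPFD must be >= 0")
  dF <- (Fm_prime - Fs) / Fm_prime
  qP <- if (is.null(Fo_prime)) NA_real_ else {
    if (!(Fo_prime < Fs)) {
      abort("invalid fluorescence record: need Fo_prime < Fs")
    }
    (Fm_prime - Fs) / (Fm_prime - Fo_prime)
  }
  list(FvFm = (Fm - Fo) / Fm,
       dF_Fm = dF,
       qP = qP,
       NPQ = Fm / Fm_prime - 1,
       ETR = dF * PPFD * PSII_fraction * absorptance)
}

#' Alternative electron sink index
#'
#' Ratio of linear electron flow expressed in CO2 equivalents to gross
#' carbon metabolism: `AES = (ETR/4) / (A + Rd)`. Values well above 1
#' indicate electron flow not accounted for by net carbon assimilation
#' plus respiration (photorespiration, Mehler reaction, nitrate
#' reduction). The denominator convention is configurable in spirit —
#' published variants differ — and this ratio is the package default.
#'
#' @param ETR apparent electron transport rate, umol e- m-2 s-1.
#' @param A net assimilation, umol CO2 m-2 s-1.
#' @param Rd dark respiration, umol CO2 m-2 s-1 (`A + Rd > 0`).
#' @return Dimensionless non-negative ratio.
#' @export
alternative_electron_sink <- function(ETR, A, Rd) {
  if (any(A + Rd <= 0)) abort("A + Rd must be > 0")
  if (any(ETR < 0)) abort("ETR must be >= 0")
  (ETR / 4) / (A + Rd)
}
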