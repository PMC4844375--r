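#' @title Synthetic replicate-level data
#' @description
#' Two generator tiers stand in for raw plant data. The direct tier
#' ([simulate_correlated()]) draws multivariate-normal replicates with an
#' exact target correlation matrix — distributional ground truth for
#' testing the connectance statistic. The mechanistic tier
#' ([simulate_leaf_experiment()]) draws leaf parameters from a latent
#' plant-vigor factor, runs the forward photosynthesis and fluorescence
#' models at cuvette conditions and derives the measured variables through
#' the same curve-fitting operations a gas-exchange study would use,
#' emulating 2 x 3 (species x temperature) and 2 x 2 (species x water
#' regime) factorial designs with seven replicate plants per cell.
#' @name synthetic_data
NULL

#' Equicorrelation matrix
#'
#' @param p dimension.
#' @param rho common off-diagonal correlation.
#' @return p x p correlation matrix.
#' @export
equicorr <- function(p, rho) {
  stopifnot(p >= 1, rho > -1 / (p - 1), rho <= 1)
  m <- matrix(rho, p, p)
  diag(m) <- 1
  m
}

#' Repair a nearly-PSD correlation matrix
#'
#' User-entered target matrices are often slightly indefinite. Negative
#' eigenvalues below `-1e-10` trigger a warning; all negative eigenvalues
#' are clipped to zero, the matrix is reconstructed and rescaled back to
#' unit diagonal. A non-unit input diagonal is not repairable and errors.
#'
#' @param R symmetric matrix with unit diagonal.
#' @return positive semi-definite correlation matrix.
#' @export
nearest_psd_corr <- function(R) {
  R <- as.matrix(R)
  if (!isSymmetric(R, tol = 1e-8)) abort("target matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) {
    abort("target matrix diagonal must be 1 (not repairable)")
  }
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= -1e-10) {
    if (min(e$values) < 0) { # numerically trivial negativity: clip silently
      e$values <- pmax(e$values, 0)
      R <- e$vectors %*% diag(e$values, nrow = length(e$values)) %*%
        t(e$vectors)
      R <- stats::cov2cor(R)
    }
    return(R)
  }
  warning(sprintf("target matrix indefinite (min eigenvalue %.3g); %s",
                  min(e$values), "clipped to nearest PSD correlation"),
          call. = FALSE)
  e$values <- pmax(e$values, 0)
  R2 <- e$vectors %*% diag(e$values, nrow = length(e$values)) %*%
    t(e$vectors)
  stats::cov2cor(R2)
}

#' Multivariate-normal replicate table with a target correlation
#'
#' Draws `n` replicates from `N(means, diag(sds) R diag(sds))` using the
#' Cholesky square root of the (PSD-repaired) target correlation matrix.
#' A pure function of its arguments and `seed`.
#'
#' @param n number of replicate rows.
#' @param corr target correlation matrix (unit diagonal; repaired to the
#'   nearest PSD matrix with a warning if slightly indefinite).
#' @param variables column names; defaults to `colnames(corr)` or `V1..Vp`.
#' @param means,sds per-variable location and scale (recycled).
#' @param species,treatment labels for the identifying columns.
#' @param seed integer seed.
#' @return replicate table data.frame (`species`, `treatment`,
#'   `replicate`, then one column per variable).
#' @export
simulate_correlated <- function(n, corr, variables = NULL, means = 0,
                                sds = 1, species = "synthetic",
                                treatment = "synthetic", seed = NULL) {
  stopifnot(n >= 1)
  R <- nearest_psd_corr(corr)
  p <- nrow(R)
  variables <- variables %||% colnames(corr) %||% paste0("V", seq_len(p))
  if (length(variables) != p) abort("need %d variable names", p)
  means <- rep_len(means, p)
  sds <- rep_len(sds, p)
  if (any(sds <= 0)) abort("sds must be > 0")

  # pivoted Cholesky handles rank deficiency from PSD clipping
  ch <- suppressWarnings(chol(R, pivot = TRUE))
  piv <- attr(ch, "pivot")
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * p), n, p)
    (z %*% ch)[, order(piv), drop = FALSE]
  })
  x <- sweep(sweep(x, 2, sds, `*`), 2, means, `+`)
  colnames(x) <- variables
  data.frame(species = species, treatment = treatment,
             replicate = seq_len(n), x, stringsAsFactors = FALSE,
             check.names = FALSE)
}

## ---- mechanistic leaf simulator -------------------------------------------

#' Define a leaf simulation scenario
#'
#' One scenario describes one species x treatment cell: mean leaf
#' parameters, their coefficients of variation across replicate plants,
#' and a latent-factor `coupling` in `[0, 1]` that sets how strongly the
#' replicate-to-replicate parameter deviations share a common plant-vigor
#' axis. Every coupled parameter loads on the single latent factor with
#' loading `coupling`, so the correlation induced between any two coupled
#' parameters is about `coupling^2`; stressed treatment cells are modelled
#' with higher coupling (tighter networks) than benign ones.
#'
#' @param species species label.
#' @param pathway `"C3"` or `"C4"`.
#' @param treatment treatment label.
#' @param n_replicates replicate plants per cell (>= 3; default 7, the
#'   usual size of a growth-chamber factorial cell).
#' @param vcmax_mean,vcmax_cv Rubisco capacity mean (umol m-2 s-1) and CV.
#' @param jv_ratio J:Vcmax ratio (C3) / Vpmax:Vcmax ratio (C4).
#' @param gs_mean,gs_cv stomatal conductance mean (mol m-2 s-1) and CV.
#' @param rd_mean,rd_cv dark respiration mean (umol m-2 s-1) and CV.
#' @param fvfm_mean,fvfm_cv dark-adapted PSII efficiency mean and CV.
#' @param dF_mean,dF_cv effective PSII efficiency mean and CV.
#' @param npq_mean,npq_cv non-photochemical quenching mean and CV.
#' @param coupling latent-factor loading in `[0, 1]`.
#' @param noise_sd additive measurement noise on assimilation readings,
#'   umol m-2 s-1 (the cuvette-level repeatability).
#' @param Ca ambient CO2, umol mol-1.
#' @param ppfd actinic light for the fluorescence readings, umol m-2 s-1.
#' @param seed integer seed for this cell.
#' @return `leaf_scenario` list.
#' @export
leaf_scenario <- function(species, pathway = c("C3", "C4"), treatment,
                          n_replicates = 7,
                          vcmax_mean = 70, vcmax_cv = 0.18,
                          jv_ratio = 1.7,
                          gs_mean = 0.25, gs_cv = 0.25,
                          rd_mean = 2, rd_cv = 0.2,
                          fvfm_mean = 0.78, fvfm_cv = 0.015,
                          dF_mean = 0.22, dF_cv = 0.12,
                          npq_mean = 2.2, npq_cv = 0.15,
                          coupling = 0.6, noise_sd = 0.3,
                          Ca = 380, ppfd = 1200, seed = NULL) {
  pathway <- match.arg(pathway)
  if (n_replicates < 3) abort("n_replicates must be >= 3")
  if (coupling < -1 || coupling > 1) abort("coupling must be in [-1, 1]")
  if (any(c(vcmax_cv, gs_cv, rd_cv, fvfm_cv, dF_cv, npq_cv) < 0)) {
    abort("CVs must be >= 0")
  }
  structure(as.list(environment()), class = "leaf_scenario")
}

# multiplicative deviation: mean * (1 + cv * u), u standard normal with
# loading `lam` on the shared factor f; floored away from zero
dev_par <- function(mean, cv, lam, f, lo = 0.05) {
  u <- lam * f + sqrt(1 - lam^2) * stats::rnorm(length(f))
  pmax(mean * (1 + cv * u), lo * mean)
}

#' Simulate one treatment cell of a leaf experiment
#'
#' Per replicate plant: draw leaf parameters around the scenario means
#' with a shared latent vigor factor; solve the operational Ci from the
#' supply-demand balance `A(Ci) = gs (Ca - Ci)`; build A/Ci and A/PPFD
#' response curves from the forward models (plus measurement noise) and
#' derive `Vcmax`, `AmaxCO2`, `AmaxL` and `Rd` by refitting them with
#' [fit_aci()] and [fit_light()]; derive `Pr`, `Ls`, `E` and the
#' fluorescence parameters (`FvFm`, `dF_Fm`, `NPQ`, `ETR`) from the same
#' draws. Growth proxies `DMt` and `LA` accumulate from the plant's carbon
#' gain. With `fit_curves = FALSE` the curve-fitting step is replaced by
#' the closed-form forward evaluation — useful for large-n distributional
#' checks where thousands of nonlinear fits would add nothing.
#'
#' @param scenario a [leaf_scenario()].
#' @param fit_curves derive capacities by refitting synthetic response
#'   curves (default) or by direct forward evaluation.
#' @return replicate table data.frame; attribute `n_regenerated` counts
#'   replicates that were redrawn after a forward-model failure.
#' @export
simulate_leaf_cell <- function(scenario, fit_curves = TRUE) {
  stopifnot(inherits(scenario, "leaf_scenario"))
  s <- scenario
  with_seed(s$seed, {
    n <- s$n_replicates
    rows <- vector("list", n)
    n_regen <- 0L
    for (i in seq_len(n)) {
      repeat {
        row <- tryCatch(simulate_one_leaf(s, fit_curves),
                        error = function(e) NULL)
        if (!is.null(row)) break
        n_regen <- n_regen + 1L
        if (n_regen > 50L * n) {
          abort("leaf simulator failing persistently for %s/%s",
                s$species, s$treatment)
        }
      }
      rows[[i]] <- row
    }
    out <- data.frame(species = s$species, treatment = s$treatment,
                      replicate = seq_len(n),
                      do.call(rbind, rows), stringsAsFactors = FALSE)
    attr(out, "n_regenerated") <- n_regen
    out
  })
}

simulate_one_leaf <- function(s, fit_curves) {
  f <- stats::rnorm(1) # latent plant vigor
  lam <- s$coupling
  vcmax <- dev_par(s$vcmax_mean, s$vcmax_cv, lam, f)
  gs <- dev_par(s$gs_mean, s$gs_cv, lam, f)
  rd <- dev_par(s$rd_mean, s$rd_cv, lam, f)
  fvfm <- min(dev_par(s$fvfm_mean, s$fvfm_cv, lam, f), 0.86)
  dF <- min(dev_par(s$dF_mean, s$dF_cv, lam, f), 0.95 * fvfm)
  npq <- dev_par(s$npq_mean, s$npq_cv, -lam, f) # quenching relaxes with vigor

  c3 <- s$pathway == "C3"
  j <- s$jv_ratio * vcmax * (1 + 0.05 * stats::rnorm(1))
  gstar <- if (c3) 42.75 else 2
  forward <- function(Ci) {
    if (c3) fvcb_c3(Ci, vcmax, j, rd, gamma_star = gstar)
    else c4_assim(Ci, vcmax, s$jv_ratio * vcmax, rd)
  }

  # operational Ci from supply = demand: A(Ci) = gs (Ca - Ci)
  bal <- function(Ci) forward(Ci) - gs * (s$Ca - Ci)
  if (bal(s$Ca - 1e-6) < 0) abort("leaf cannot assimilate at ambient CO2")
  ci_op <- stats::uniroot(bal, c(max(gstar, 1) + 1e-3, s$Ca - 1e-6),
                          tol = 1e-8)$root
  a_op <- forward(ci_op)
  if (a_op <= 0.5) abort("non-viable draw: operational A <= 0.5")

  # light response around the operational point
  phi <- 0.06 * (1 + 0.08 * stats::rnorm(1))
  theta <- min(max(0.7 + 0.05 * stats::rnorm(1), 0.3), 0.95)
  amax_gross <- a_op + rd

  if (fit_curves) {
    ci_grid <- c(50, 100, 150, 250, 400, 600, 900, 1200, 1600)
    aci <- data.frame(
      Ci = ci_grid,
      A = forward(ci_grid) + stats::rnorm(length(ci_grid), 0, s$noise_sd))
    fa <- fit_aci(aci, pathway = s$pathway)
    q_grid <- c(0, 25, 50, 100, 200, 400, 700, 1100, 1600, 2000)
    lc <- data.frame(
      Q = q_grid,
      A = light_response(q_grid, amax_gross, rd, phi, theta) +
        stats::rnorm(length(q_grid), 0, s$noise_sd))
    fl <- fit_light(lc)
    amaxl <- fl$AmaxL
    rd_meas <- fl$Rd
    vcmax_meas <- fa$Vcmax
    amaxco2 <- fa$AmaxCO2
  } else {
    amaxl <- a_op + stats::rnorm(1, 0, s$noise_sd)
    rd_meas <- rd * (1 + 0.05 * stats::rnorm(1))
    vcmax_meas <- vcmax * (1 + 0.03 * stats::rnorm(1))
    amaxco2 <- forward(2000) + stats::rnorm(1, 0, s$noise_sd)
  }

  pr <- if (c3) {
    photorespiration(ci_op, vcmax, gamma_star = gstar)
  } else {
    photorespiration(ci_op, vcmax, gamma_star = gstar, Kc = 80, Ko = 278.4)
  }
  ls <- stomatal_limitation(a_op, max(forward(s$Ca), a_op + 1e-6))
  e_tr <- gs * 14.8 * (1 + 0.08 * stats::rnorm(1)) # VPD 1.5 kPa / 101.3 kPa

  # actinic PPFD at the fluorescence reading fluctuates a little around the
  # set point, so ETR is not an exact multiple of dF_Fm across replicates
  etr <- dF * s$ppfd * (1 + 0.03 * stats::rnorm(1)) * 0.5 * 0.84
  dmt <- pmax(0.4 * amaxl * (1 + 0.15 * stats::rnorm(1)), 0.1)
  la <- pmax(0.006 * amaxl * (1 + 0.2 * stats::rnorm(1)), 0.001)

  data.frame(AmaxL = amaxl, gs = gs, E = e_tr, Rd = rd_meas, Pr = pr,
             Ci = ci_op, FvFm = fvfm, dF_Fm = dF, NPQ = npq, ETR = etr,
             Vcmax = vcmax_meas, AmaxCO2 = amaxco2, Ls = ls,
             DMt = dmt, LA = la)
}

#' Simulate a full factorial leaf experiment
#'
#' @param scenarios list of [leaf_scenario()] objects (one per cell).
#' @param fit_curves see [simulate_leaf_cell()].
#' @return named list of replicate tables, one per `species/treatment`.
#' @export
simulate_leaf_experiment <- function(scenarios, fit_curves = TRUE) {
  stopifnot(length(scenarios) >= 1)
  out <- lapply(scenarios, simulate_leaf_cell, fit_curves = fit_curves)
  names(out) <- vapply(scenarios, function(s) {
    paste(s$species, s$treatment, sep = "/")
  }, character(1))
  out
}

#' Preset factorial scenarios
#'
#' Ready-made scenario sets emulating the two study designs: a 2 x 3
#' temperature experiment (a C3 soybean-like species and a C4
#' palisade-grass-like species at 20, 30 and 40 degC) and a 2 x 2
#' water-availability experiment (100% vs 30% refill of transpired
#' water). Parameter means follow the magnitudes typical of the two
#' functional types (C3: high Vcmax and multi-umol photorespiration; C4:
#' low Vcmax, near-zero photorespiration). Couplings rise with stress —
#' higher temperature, stronger water deficit — so the simulated
#' networks tighten in the stressed cells, the qualitative pattern this
#' analysis is designed to detect. Fixed per-cell default seeds make the
#' presets reproducible; pass `seed` to shift the whole family.
#'
#' @param experiment `"temperature"` (6 scenarios) or `"water"`
#'   (4 scenarios).
#' @param n_replicates replicates per cell, default 7.
#' @param seed base seed; per-cell seeds are derived by offset.
#' @return list of [leaf_scenario()] objects.
#' @export
preset_scenarios <- function(experiment = c("temperature", "water"),
                             n_replicates = 7, seed = 20130710) {
  experiment <- match.arg(experiment)
  seed <- seed %% 2e9
  cell <- function(i, ...) {
    leaf_scenario(..., n_replicates = n_replicates, seed = seed + i)
  }
  if (experiment == "temperature") {
    list(
      cell(1, species = "C3_soy", pathway = "C3", treatment = "20C",
           vcmax_mean = 61, gs_mean = 0.18, rd_mean = 2.5, dF_mean = 0.18,
           npq_mean = 2.2, coupling = 0.65),
      cell(2, species = "C3_soy", pathway = "C3", treatment = "30C",
           vcmax_mean = 68, gs_mean = 0.22, rd_mean = 1.2, dF_mean = 0.22,
           npq_mean = 2.2, coupling = 0.75),
      cell(3, species = "C3_soy", pathway = "C3", treatment = "40C",
           vcmax_mean = 78, gs_mean = 0.28, rd_mean = 2.4, dF_mean = 0.25,
           npq_mean = 1.9, coupling = 0.85),
      cell(4, species = "C4_grass", pathway = "C4", treatment = "20C",
           vcmax_mean = 18, jv_ratio = 1.15, gs_mean = 0.12, rd_mean = 2.1,
           dF_mean = 0.10, npq_mean = 2.8, coupling = 0.62),
      cell(5, species = "C4_grass", pathway = "C4", treatment = "30C",
           vcmax_mean = 24, jv_ratio = 1.15, gs_mean = 0.16, rd_mean = 2.2,
           dF_mean = 0.15, npq_mean = 2.5, coupling = 0.58),
      cell(6, species = "C4_grass", pathway = "C4", treatment = "40C",
           vcmax_mean = 27, jv_ratio = 1.15, gs_mean = 0.20, rd_mean = 2.4,
           dF_mean = 0.27, npq_mean = 1.8, coupling = 0.82)
    )
  } else {
    list(
      cell(1, species = "C3_soy", pathway = "C3", treatment = "100pct",
           vcmax_mean = 84, gs_mean = 0.25, rd_mean = 2.3, dF_mean = 0.27,
           npq_mean = 2.1, coupling = 0.60),
      cell(2, species = "C3_soy", pathway = "C3", treatment = "30pct",
           vcmax_mean = 61, gs_mean = 0.12, rd_mean = 2.1, dF_mean = 0.40,
           npq_mean = 1.7, coupling = 0.88),
      cell(3, species = "C4_grass", pathway = "C4", treatment = "100pct",
           vcmax_mean = 21, jv_ratio = 1.15, gs_mean = 0.15, rd_mean = 1.2,
           dF_mean = 0.20, npq_mean = 3.2, coupling = 0.55),
      cell(4, species = "C4_grass", pathway = "C4", treatment = "30pct",
           vcmax_mean = 10, jv_ratio = 1.15, gs_mean = 0.07, rd_mean = 0.9,
           dF_mean = 0.21, npq_mean = 3.1, coupling = 0.88)
    )
  }
}
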