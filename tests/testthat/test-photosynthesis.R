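test_that("C3 model hits the compensation point and the min structure", {
  expect_equal(fvcb_c3(42.75, Vcmax = 80, J = 150, Rd = 2.5), -2.5)
  # with Rubisco unconstrained, only the RuBP-regeneration limb remains
  Ci <- c(100, 300, 800)
  aj <- 150 * (Ci - 42.75) / (4 * Ci + 8 * 42.75) - 2.5
  expect_equal(fvcb_c3(Ci, Vcmax = 1e9, J = 150, Rd = 2.5), aj)
  # hand-evaluated Rubisco-limited limb (J non-limiting)
  km <- 404.9 * (1 + 210 / 278.4)
  ac <- 61 * (300 - 42.75) / (300 + km) - 2.5
  expect_equal(fvcb_c3(300, Vcmax = 61, J = 1e6, Rd = 2.5), ac,
               tolerance = 1e-12)
  expect_error(fvcb_c3(0, 80, 150, 2), "Ci")
})

test_that("C3 response is continuous and non-decreasing above gamma*", {
  ci <- seq(43, 1800, by = 1)
  a <- fvcb_c3(ci, Vcmax = 80, J = 150, Rd = 2)
  expect_true(all(diff(a) >= -1e-12))
  expect_true(all(abs(diff(a)) < 0.5)) # no jumps at the limb transition
  # smoothed variant stays below the hard minimum
  asm <- fvcb_c3(ci, Vcmax = 80, J = 150, Rd = 2, smooth = TRUE)
  expect_true(all(asm <= a + 1e-9))
  expect_equal(asm, a, tolerance = 0.05)
})

test_that("C4 model saturates at low Ci relative to the C3 form", {
  # CO2-saturated plateau is the Rubisco limit
  expect_equal(c4_assim(5000, Vcmax = 25, Vpmax = 28, Rd = 2), 23,
               tolerance = 1e-3)
  # low-Ci/ambient-Ci ratio far above the C3 model at matched Ci
  r_c4 <- c4_assim(50, 25, 40, 0) / c4_assim(400, 25, 40, 0)
  r_c3 <- fvcb_c3(50, 80, 150, 0) / fvcb_c3(400, 80, 150, 0)
  expect_gt(r_c4, r_c3)
  # C4 photorespiration stays near zero, C3 well above it
  pr_c4 <- photorespiration(200, Vcmax = 25, gamma_star = 2, Kc = 80)
  expect_lt(pr_c4, 0.5)
  pr_c3 <- photorespiration(270, Vcmax = 80)
  expect_gt(pr_c3, 2)
})

test_that("light response obeys its intercept and theta -> 0 limit", {
  expect_equal(light_response(0, Amax = 20, Rd = 2, phi = 0.05,
                              theta = 0.7), -2)
  q <- c(0, 50, 200, 1000, 2000)
  rect <- 0.05 * q * 20 / (0.05 * q + 20) - 2
  expect_equal(light_response(q, 20, 2, 0.05, theta = 0), rect)
  expect_equal(light_response(q, 20, 2, 0.05, theta = 1e-6), rect,
               tolerance = 1e-4)
  expect_error(light_response(-5, 20, 2, 0.05, 0.7), ">= 0")
})

test_that("A/Ci fitting recovers parameters from its own forward model", {
  ci <- c(50, 100, 200, 350, 500, 700, 900, 1200, 1500)
  a <- fvcb_c3(ci, Vcmax = 80, J = 150, Rd = 1.5)
  fit <- fit_aci(data.frame(Ci = ci, A = a), pathway = "C3")
  expect_true(fit$converged)
  expect_equal(fit$Vcmax, 80, tolerance = 1e-4)
  expect_equal(fit$J, 150, tolerance = 1e-4)
  expect_equal(fit$Rd, 1.5, tolerance = 1e-3)
  expect_equal(fit$AmaxCO2, fvcb_c3(2000, 80, 150, 1.5), tolerance = 1e-4)

  a4 <- c4_assim(ci, Vcmax = 25, Vpmax = 30, Rd = 1.2)
  fit4 <- fit_aci(data.frame(Ci = ci, A = a4), pathway = "C4")
  expect_equal(fit4$Vcmax, 25, tolerance = 1e-3)
  expect_equal(fit4$Vpmax, 30, tolerance = 1e-3)
})

test_that("A/Ci fitting stays nearly unbiased under measurement noise", {
  ci <- c(50, 100, 200, 350, 500, 700, 900, 1200, 1500)
  a0 <- fvcb_c3(ci, Vcmax = 80, J = 150, Rd = 1.5)
  set.seed(424242)
  est <- replicate(100, {
    fit <- fit_aci(data.frame(Ci = ci, A = a0 + rnorm(length(ci), 0, 0.5)))
    fit$Vcmax
  })
  expect_lt(abs(median(est) - 80) / 80, 0.05)
})

test_that("degenerate curves are explicit failures", {
  flat <- data.frame(Ci = c(50, 100, 200, 400, 800), A = rep(5, 5))
  expect_error(fit_aci(flat), "degenerate")
  expect_error(fit_light(data.frame(Q = c(0, 50, 100, 500, 1000),
                                    A = rep(3, 5))), "degenerate")
  expect_error(fit_aci(data.frame(Ci = c(50, 100, 200), A = 1:3)),
               ">= 5")
})

test_that("light-curve fitting recovers all four parameters", {
  q <- c(0, 25, 50, 100, 200, 400, 800, 1200, 1800)
  a <- light_response(q, Amax = 20, Rd = 2, phi = 0.05, theta = 0.7)
  fit <- fit_light(data.frame(Q = q, A = a))
  expect_equal(fit$Amax, 20, tolerance = 1e-4)
  expect_equal(fit$Rd, 2, tolerance = 1e-4)
  expect_equal(fit$phi, 0.05, tolerance = 1e-4)
  expect_equal(fit$theta, 0.7, tolerance = 1e-3)
  expect_equal(fit$AmaxL, 18, tolerance = 1e-3)
})

test_that("stomatal limitation is a bounded percentage", {
  expect_equal(stomatal_limitation(20, 20), 0)
  expect_equal(stomatal_limitation(16, 20), 20)
  expect_equal(stomatal_limitation(0, 20), 100)
  expect_warning(ls <- stomatal_limitation(22, 20), "supersaturation")
  expect_lt(ls, 0)
  expect_error(stomatal_limitation(5, 0), "> 0")
})

test_that("fluorescence derivations match their defining ratios", {
  fp <- fluorescence_params(Fo = 400, Fm = 2000, Fs = 600, Fm_prime = 800,
                            Fo_prime = 450, PPFD = 1000)
  expect_equal(fp$FvFm, 0.8)
  expect_equal(fp$dF_Fm, 0.25)
  expect_equal(fp$NPQ, 2000 / 800 - 1)
  expect_equal(fp$qP, (800 - 600) / (800 - 450))
  expect_equal(fp$ETR, 0.25 * 1000 * 0.5 * 0.84) # = 105
  expect_equal(fp$ETR, 105)

  # Fm' = Fm means no non-photochemical quenching
  fp0 <- fluorescence_params(Fo = 400, Fm = 2000, Fs = 600,
                             Fm_prime = 2000, PPFD = 500)
  expect_equal(fp0$NPQ, 0)
})

test_that("fluorescence outputs are scale invariant and validated", {
  base <- list(Fo = 400, Fm = 2000, Fs = 600, Fm_prime = 800,
               Fo_prime = 450)
  f1 <- do.call(fluorescence_params, c(base, PPFD = 1000))
  f2 <- do.call(fluorescence_params, c(lapply(base, `*`, 3.21),
                                       PPFD = 1000))
  expect_equal(f1, f2, tolerance = 1e-12)

  expect_error(fluorescence_params(Fo = 2000, Fm = 400, Fs = 600,
                                   Fm_prime = 800, PPFD = 1), "Fm > Fo")
  expect_error(fluorescence_params(Fo = 400, Fm = 2000, Fs = 900,
                                   Fm_prime = 800, PPFD = 1),
               "Fm_prime > Fs")
  expect_error(fluorescence_params(Fo = 400, Fm = 700, Fs = 600,
                                   Fm_prime = 800, PPFD = 1),
               "Fm >= Fm_prime")
})

test_that("alternative electron sink is the documented ratio", {
  expect_equal(alternative_electron_sink(0, 5, 1), 0)
  expect_equal(alternative_electron_sink(84, 2, 1.5), 6)
  expect_equal(alternative_electron_sink(168, 2, 1.5),
               2 * alternative_electron_sink(84, 2, 1.5))
  expect_error(alternative_electron_sink(10, -2, 1), "> 0")
})
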