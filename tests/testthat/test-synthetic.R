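test_that("correlated generator is a pure function of its seed", {
  R <- equicorr(10, 0.4)
  t1 <- simulate_correlated(7, R, variables = net_vars(), seed = 5)
  t2 <- simulate_correlated(7, R, variables = net_vars(), seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_correlated(7, R, variables = net_vars(), seed = 6)
  expect_false(identical(t1, t3))
})

test_that("correlated generator hits its target correlation", {
  # identity target: all pairwise |r| small at n = 10000
  tid <- simulate_correlated(10000, diag(10), variables = net_vars(),
                             seed = 81)
  cm <- cor(as.matrix(tid[, net_vars()]))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)

  # equicorrelated 0.8: every sample pair within 0.02
  teq <- simulate_correlated(10000, equicorr(10, 0.8),
                             variables = net_vars(), seed = 82)
  cm2 <- cor(as.matrix(teq[, net_vars()]))
  expect_lt(max(abs(cm2[upper.tri(cm2)] - 0.8)), 0.02)

  # means and sds are honored
  tm <- simulate_correlated(20000, diag(3), variables = c("a", "b", "c"),
                            means = c(1, 10, 100), sds = c(1, 2, 3),
                            seed = 83)
  expect_equal(unname(colMeans(tm[, c("a", "b", "c")])), c(1, 10, 100),
               tolerance = 0.1)
  expect_equal(unname(apply(tm[, c("a", "b", "c")], 2, sd)), c(1, 2, 3),
               tolerance = 0.1)
})

test_that("indefinite targets are repaired, wrong diagonals refused", {
  bad <- matrix(c(1, 0.9, -0.9,
                  0.9, 1, 0.9,
                  -0.9, 0.9, 1), 3, 3) # indefinite by construction
  expect_warning(R <- nearest_psd_corr(bad), "indefinite")
  expect_gte(min(eigen(R, symmetric = TRUE)$values), -1e-10)
  expect_equal(diag(R), rep(1, 3))
  expect_warning(simulate_correlated(50, bad, seed = 84), "indefinite")

  notcorr <- diag(3) * 2
  expect_error(simulate_correlated(5, notcorr, seed = 85),
               "diagonal")
})

test_that("leaf cells have the designed shape and are reproducible", {
  s <- leaf_scenario("sp", "C3", "ctl", n_replicates = 7, seed = 91)
  tab <- simulate_leaf_cell(s)
  expect_identical(nrow(tab), 7L)
  expect_true(all(net_vars() %in% names(tab)))
  expect_true(all(c("Vcmax", "AmaxCO2", "Ls", "DMt", "LA") %in% names(tab)))
  expect_identical(tab, simulate_leaf_cell(s))
  expect_error(leaf_scenario("sp", "C3", "t", n_replicates = 2),
               ">= 3")
  expect_error(leaf_scenario("sp", "C3", "t", coupling = 1.5), "coupling")
})

test_that("curve-fit and forward derivations agree on the same plants", {
  s <- leaf_scenario("sp", "C3", "ctl", n_replicates = 20, seed = 92,
                     noise_sd = 0.1)
  fit <- simulate_leaf_cell(s, fit_curves = TRUE)
  fwd <- simulate_leaf_cell(s, fit_curves = FALSE)
  # different RNG usage, so compare distributions loosely, not rows
  expect_lt(abs(mean(fit$Vcmax) - mean(fwd$Vcmax)) / mean(fwd$Vcmax), 0.15)
  expect_lt(abs(mean(fit$AmaxL) - mean(fwd$AmaxL)) / mean(fwd$AmaxL), 0.15)
})

test_that("pathways land in their photorespiration regimes", {
  pre <- preset_scenarios("temperature", n_replicates = 60)
  c3 <- simulate_leaf_cell(pre[[2]], fit_curves = FALSE) # C3, 30C
  c4 <- simulate_leaf_cell(pre[[5]], fit_curves = FALSE) # C4, 30C
  expect_gt(mean(c3$Pr), 2)
  expect_lt(mean(c4$Pr), 0.5)
})

test_that("coupling raises the cross-module correlation monotonically", {
  zs <- vapply(c(0, 0.5, 0.95), function(cp) {
    s <- leaf_scenario("sp", "C3", "t", n_replicates = 10000,
                       coupling = cp, seed = 93)
    tab <- simulate_leaf_cell(s, fit_curves = FALSE)
    atanh(abs(cor(tab$ETR, tab$AmaxL)))
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_lt(zs[1], 0.05)  # uncoupled: near-independent modules
  expect_gt(zs[3], 1)     # tight coupling: strong linking pair
})

test_that("presets define the two factorial designs", {
  tp <- preset_scenarios("temperature")
  expect_length(tp, 6)
  expect_setequal(vapply(tp, `[[`, "", "treatment"),
                  c("20C", "30C", "40C"))
  wp <- preset_scenarios("water")
  expect_length(wp, 4)
  expect_setequal(vapply(wp, `[[`, "", "species"),
                  c("C3_soy", "C4_grass"))
  expect_true(all(vapply(wp, `[[`, 1, "n_replicates") == 7))
})

test_that("estimated connectance falls in its bootstrap CI (coverage)", {
  spec <- default_network()
  R <- equicorr(10, 0.5)
  hits <- vapply(1:100, function(i) {
    tab <- simulate_correlated(500, R, variables = net_vars(),
                               seed = 9000 + i)
    b <- bootstrap_cg(tab, spec, n_boot = 300, seed = 100 + i)
    truth <- atanh(0.5)
    b$ci["lower", "cg_total"] <= truth && truth <= b$ci["upper", "cg_total"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
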