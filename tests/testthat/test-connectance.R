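test_that("pearson_r matches the direct-formula oracle and base cases", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 4, 8)
  expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  # incomplete pairs dropped before anything else
  expect_equal(pearson_r(c(x, NA), c(y, 1)), pearson_oracle(x, y))
})

test_that("pearson_r rejects degenerate and insufficient input", {
  expect_error(pearson_r(c(1, 1, 1, 1), c(1, 2, 3, 4)), "degenerate")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "insufficient")
  expect_error(pearson_r(c(1, 2, NA), c(1, 2, 3)), "insufficient")
})

test_that("correlation p-values follow the exact t distribution", {
  expect_equal(correlation_pvalue(0, 10), 1)
  # frozen from the t oracle: t = r sqrt((n-2)/(1-r^2)) = 2.575, df = 5
  t_or <- 0.755 * sqrt(5 / (1 - 0.755^2))
  expect_equal(correlation_pvalue(0.755, 7),
               2 * pt(t_or, df = 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(correlation_pvalue(0.755, 7), 0.0497566, tolerance = 1e-6)
  expect_equal(correlation_pvalue(-0.755, 7), correlation_pvalue(0.755, 7))
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_error(correlation_pvalue(0.5, 2), "insufficient")
})

test_that("fisher_z is atanh of |r| with clamping at the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 1.4722195, tolerance = 1e-7)
  expect_equal(fisher_z(-0.5), fisher_z(0.5))
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-12))
  expect_error(fisher_z(1.01), "> 1")

  # strict monotonicity in |r|
  grid <- seq(0, 0.999, by = 0.001)
  expect_true(all(diff(fisher_z(grid)) > 0))
})

test_that("pair_strength is internally consistent and counts pairwise n", {
  tab <- equicorr_table(12, 0.4, seed = 11)
  ps <- pair_strength(tab, c("AmaxL", "gs"))
  expect_equal(ps$z, fisher_z(ps$r))
  expect_equal(ps$p, correlation_pvalue(ps$r, ps$n))
  expect_identical(ps$n, 12L)

  tab$gs[3] <- NA
  ps2 <- pair_strength(tab, c("AmaxL", "gs"))
  expect_identical(ps2$n, 11L)

  # exact linear dependence flags the clamp, tagged with the pair
  tab$E <- 2 * tab$AmaxL
  expect_warning(ps3 <- pair_strength(tab, c("AmaxL", "E")), "AmaxL-E")
  expect_equal(ps3$r, 1)

  # large-sample null: independent noise gives near-zero strength
  big <- equicorr_table(10000, 0, seed = 12)
  ps4 <- pair_strength(big, c("AmaxL", "NPQ"))
  expect_lt(ps4$z, 0.05)
})

test_that("module connectance is the plain mean of pair strengths", {
  tab <- equicorr_table(15, 0.5, seed = 21)
  spec <- default_network()
  pairs <- spec$modules$gas_exchange
  zs <- vapply(seq_len(nrow(pairs)), function(i) {
    pair_strength(tab, c(pairs$a[i], pairs$b[i]))$z
  }, numeric(1))
  expect_equal(module_connectance(tab, pairs), mean(zs))
  expect_error(module_connectance(tab, pairs[0, ]), "empty")

  # significance filtering is opt-in and zeroes, never drops
  ps <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    pair_strength(tab, c(pairs$a[i], pairs$b[i]))
  }))
  zf <- ps$z
  zf[ps$p > 0.05] <- 0
  expect_equal(module_connectance(tab, pairs, sig_filter = TRUE), mean(zf))

  # a failing pair is reported, not dropped
  tab$Pr <- 1
  expect_error(module_connectance(tab, pairs), "AmaxL-Pr.*degenerate")
})

test_that("global connectance averages the two module values", {
  expect_equal(global_connectance(1.68, 1.22), 1.45)
  expect_equal(global_connectance(2.91, 0.90), 1.905)
  expect_equal(global_connectance(0, 0), 0)
  expect_error(global_connectance(-0.1, 1), ">= 0")
})

test_that("analyze_cell assembles a consistent connectance result", {
  spec <- default_network()
  tab <- equicorr_table(40, 0.5, seed = 31, species = "sp", treatment = "t1")
  res <- analyze_cell(tab, spec)
  expect_s3_class(res, "connectance_result")
  expect_identical(nrow(res$pair_results), 16L)
  expect_equal(res$cg_total, (res$cg_ge + res$cg_pho) / 2)
  expect_equal(res$cg_ge,
               mean(res$pair_results$z[res$pair_results$module ==
                                         "gas_exchange"]))
  expect_identical(res$species, "sp")
  # linking pair is outside both module means
  expect_false("AmaxL-ETR" %in%
                 res$pair_results$pair[res$pair_results$module !=
                                         "linking"])

  # null network at large n: every statistic near zero
  null <- equicorr_table(8000, 0, seed = 32)
  rn <- analyze_cell(null, spec)
  expect_lt(rn$cg_total, 0.05)
  expect_lt(rn$linking_z, 0.05)
})

test_that("connectance is invariant under affine rescaling of variables", {
  spec <- default_network()
  tab <- equicorr_table(25, 0.6, seed = 41)
  res <- analyze_cell(tab, spec)
  tab2 <- tab
  tab2$AmaxL <- 3.7 * tab2$AmaxL - 12
  tab2$NPQ <- -2 * tab2$NPQ + 5 # sign flip: |r| unchanged
  res2 <- analyze_cell(tab2, spec)
  expect_equal(res2$cg_ge, res$cg_ge, tolerance = 1e-12)
  expect_equal(res2$cg_pho, res$cg_pho, tolerance = 1e-12)
  expect_equal(res2$linking_z, res$linking_z, tolerance = 1e-12)
})

test_that("equicorrelated data recovers atanh(rho) at large n", {
  # lighter-n companion to the acceptance check, different rho
  tab <- equicorr_table(6000, 0.5, seed = 51)
  cg <- module_connectance(tab, default_network()$modules$gas_exchange)
  expect_equal(cg, atanh(0.5), tolerance = 0.03)
})
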