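#' Bootstrap confidence intervals for connectance statistics
#'
#' Resamples replicate plants (rows) with replacement and recomputes the
#' module, global and linking connectance statistics for each draw,
#' returning percentile confidence intervals. With only seven replicates
#' per treatment cell the point estimates are noisy; the bootstrap makes
#' that uncertainty visible rather than pretending precision.
#'
#' A resample in which any network variable is constant (so correlations
#' are undefined) is redrawn; the number of redraws is reported. Results
#' are a pure function of `(table, spec, n_boot, seed)`.
#'
#' @param table replicate table for one treatment cell.
#' @param spec network specification.
#' @param n_boot number of bootstrap draws (>= 100).
#' @param seed integer seed (mandatory for reproducibility).
#' @param conf confidence level, default 0.95.
#' @return list with `estimate` (named vector: module connectances,
#'   `cg_total`, `linking_z`), `ci` (matrix with `lower`/`upper` rows),
#'   `n_boot`, `n_redraws`, `conf`, `seed`.
#' @export
bootstrap_cg <- function(table, spec = default_network(), n_boot = 1000,
                         seed, conf = 0.95) {
  if (n_boot < 100) abort("n_boot must be >= 100")
  stopifnot(inherits(spec, "network_spec"))
  vars <- unique(unlist(spec_all_pairs(spec)[, c("a", "b")]))
  m <- rt_matrix(table, vars)
  if (nrow(m) < 3) abort("need >= 3 replicates to bootstrap")
  sx <- spec_index(spec, vars)
  est <- cg_from_matrix(m, sx)

  n <- nrow(m)
  n_redraws <- 0L
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
    for (b in seq_len(n_boot)) {
      repeat {
        mb <- m[sample.int(n, n, replace = TRUE), , drop = FALSE]
        const <- apply(mb, 2, function(col) {
          col <- col[!is.na(col)]
          length(col) < 3 || max(col) == min(col)
        })
        if (!any(const)) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 100 * n_boot) {
          abort("bootstrap stuck: constant columns in nearly every resample")
        }
      }
      out[b, ] <- cg_from_matrix(mb, sx)
    }
    out
  })

  a <- (1 - conf) / 2
  ci <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE,
              na.rm = TRUE)
  rownames(ci) <- c("lower", "upper")
  list(estimate = est, ci = ci, n_boot = n_boot, n_redraws = n_redraws,
       conf = conf, seed = seed)
}

#' Permutation test for a difference in global connectance
#'
#' Tests whether two treatment cells differ in global connectance by
#' randomly reassigning replicate plants to the two groups and recomputing
#' `|Cg_total(a) - Cg_total(b)|` for each reassignment. The p-value uses
#' the add-one estimator `(1 + #{null >= observed}) / (1 + n_perm)`, which
#' is exact-level for permutation nulls. Deterministic given `seed`.
#'
#' @param table_a,table_b replicate tables (same variables).
#' @param spec network specification.
#' @param n_perm number of permutations (>= 199).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` (absolute Cg_total difference),
#'   `n_perm`, `seed`.
#' @export
permutation_test_cg <- function(table_a, table_b, spec = default_network(),
                                n_perm = 999, seed) {
  if (n_perm < 199) abort("n_perm must be >= 199")
  stopifnot(inherits(spec, "network_spec"))
  vars <- unique(unlist(spec_all_pairs(spec)[, c("a", "b")]))
  ma <- rt_matrix(table_a, vars)
  mb <- rt_matrix(table_b, vars)
  na <- nrow(ma); nb <- nrow(mb)
  if (na < 3 || nb < 3) {
    abort("need >= 3 replicates per group (got %d and %d)", na, nb)
  }
  sx <- spec_index(spec, vars)
  stat <- function(g1, g2) {
    abs(cg_from_matrix(g1, sx)[["cg_total"]] -
          cg_from_matrix(g2, sx)[["cg_total"]])
  }
  observed <- stat(ma, mb)

  pool <- rbind(ma, mb)
  ntot <- na + nb
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(ntot, na)
      stat(pool[ia, , drop = FALSE], pool[-ia, , drop = FALSE])
    }, numeric(1))
  })
  # undefined draws (constant columns after permutation cannot occur for
  # continuous data, but guard NA propagation from ties in real data)
  null <- null[is.finite(null)]
  p <- (1 + sum(null >= observed - 1e-15)) / (1 + length(null))
  list(p_value = p, observed = observed, n_perm = n_perm, seed = seed)
}
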