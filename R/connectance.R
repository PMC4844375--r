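#' @title Global connectance of a physiological network
#' @description
#' The connectance statistic measures the mean strength of association
#' among the variables of a predefined network. For every declared pair
#' the Pearson correlation r across replicate plants of one treatment cell
#' is transformed to `z = 0.5 ln[(1 + |r|)/(1 - |r|)] = atanh(|r|)` and the
#' module connectance is the unweighted mean of z over the module's pairs.
#' The global connectance of the photosynthetic network is the mean of the
#' two module connectances (gas exchange and photochemistry); the linking
#' pair is reported separately and enters neither average.
#' @name connectance
NULL

#' Pearson correlation of two replicate vectors
#'
#' Thin, validating front end to [stats::cor()]: incomplete pairs are
#' dropped first; fewer than 3 complete pairs or a constant vector is an
#' error rather than a silent `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    abort("insufficient data: %d complete pairs (need >= 3)", length(x))
  }
  if (max(x) == min(x) || max(y) == min(y)) {
    abort("degenerate input: constant vector has no defined correlation")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' on `n - 2` degrees of freedom. By convention `|r| = 1` returns `p = 0`
#' (the statistic is infinite).
#'
#' @param r correlation in `[-1, 1]`.
#' @param n number of complete pairs, at least 3.
#' @return p-value in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) abort("insufficient data: n = %s (need >= 3)", n)
  if (abs(r) > 1 + 1e-8) abort("|r| > 1")
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Fisher z-transform of an absolute correlation
#'
#' `z = 0.5 ln[(1 + |r|)/(1 - |r|)] = atanh(|r|)`. The sign of r is
#' discarded: connectance measures strength, not direction. Correlations of
#' exactly +/-1 (typical of degenerate small-n data) are clamped to
#' `1 - 1e-12` with a warning so the statistic stays finite while the
#' degeneracy is flagged.
#'
#' @param r numeric vector of correlations, `|r| <= 1`.
#' @return Non-negative z values, monotone increasing in `|r|`.
#' @examples
#' fisher_z(0.9)            # 1.47222...
#' fisher_z(-0.5) == fisher_z(0.5)
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) abort("|r| > 1")
  a <- pmin(abs(r), 1)
  if (any(a >= 1 - 1e-12, na.rm = TRUE)) {
    warning("|r| = 1 clamped to 1 - 1e-12 before z-transform",
            call. = FALSE)
    a <- pmin(a, 1 - 1e-12)
  }
  atanh(a)
}

# clamp without warning, for resampling inner loops where perfect
# correlations under resampled small-n data are expected and benign
z_of_r <- function(r) atanh(pmin(abs(r), 1 - 1e-12))

## ---- replicate tables -----------------------------------------------------

#' Read / validate a replicate table
#'
#' A replicate table holds one row per replicate plant with identifying
#' columns `species`, `treatment`, `replicate` followed by numeric variable
#' columns named as in the network spec. `read_replicate_table()` reads the
#' CSV form (comment lines starting `#` allowed).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_replicate_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# numeric matrix of the requested variables, with checks
rt_matrix <- function(table, vars) {
  missing <- setdiff(vars, names(table))
  if (length(missing)) {
    abort("missing variable column(s): %s", paste(missing, collapse = ", "))
  }
  m <- as.matrix(table[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Correlation strength of one variable pair
#'
#' @param table replicate table (see [read_replicate_table()]).
#' @param pair two variable names (character vector, or one row of a pair
#'   data.frame with columns `a`, `b`).
#' @return data.frame row: `pair`, `a`, `b`, `r`, `n`, `p`, `z`, mutually
#'   consistent (`z = fisher_z(r)`, `p = correlation_pvalue(r, n)`).
#' @details Missing values are handled by pairwise-complete deletion and
#'   the effective n is reported per pair. Errors from degenerate or
#'   insufficient data are tagged with the pair name.
#' @export
pair_strength <- function(table, pair) {
  if (is.data.frame(pair)) pair <- c(pair$a[1], pair$b[1])
  stopifnot(length(pair) == 2L)
  m <- rt_matrix(table, pair)
  ok <- stats::complete.cases(m)
  n <- sum(ok)
  r <- tryCatch(pearson_r(m[, 1], m[, 2]),
                error = function(e) {
                  abort("pair %s-%s: %s", pair[1], pair[2],
                        conditionMessage(e))
                })
  z <- withCallingHandlers(
    fisher_z(r),
    warning = function(w) {
      warning(sprintf("pair %s-%s: %s", pair[1], pair[2],
                      conditionMessage(w)), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  data.frame(pair = paste(sort(pair), collapse = "-"),
             a = pair[1], b = pair[2],
             r = r, n = n, p = correlation_pvalue(r, n), z = z,
             stringsAsFactors = FALSE)
}

#' Connectance of a set of pairs
#'
#' Unweighted arithmetic mean of the Fisher z strengths over `pairs`. All
#' pairs enter the average regardless of significance; setting
#' `sig_filter = TRUE` (non-default) zeroes pairs with `p > alpha` before
#' averaging. A pair that cannot be computed is not dropped silently: the
#' error lists every failing pair.
#'
#' @param table replicate table.
#' @param pairs data.frame of pairs (columns `a`, `b`).
#' @param sig_filter zero non-significant pairs first? Default `FALSE`.
#' @param alpha significance level used when `sig_filter = TRUE`.
#' @return Mean z (non-negative scalar).
#' @export
module_connectance <- function(table, pairs, sig_filter = FALSE,
                               alpha = 0.05) {
  if (nrow(pairs) == 0) abort("empty pair set")
  res <- pairs_strength(table, pairs)
  z <- res$z
  if (sig_filter) z[res$p > alpha] <- 0
  mean(z)
}

# all pairs at once; collects failures into one error
pairs_strength <- function(table, pairs) {
  out <- vector("list", nrow(pairs))
  errs <- character()
  for (i in seq_len(nrow(pairs))) {
    out[[i]] <- tryCatch(pair_strength(table, c(pairs$a[i], pairs$b[i])),
                         error = function(e) conditionMessage(e))
    if (is.character(out[[i]])) errs <- c(errs, out[[i]])
  }
  if (length(errs)) {
    abort("connectance not computable for %d pair(s):\n  %s",
          length(errs), paste(errs, collapse = "\n  "))
  }
  do.call(rbind, out)
}

#' Aggregate module connectances into the global connectance
#'
#' The global photosynthetic connectance is the mean of the photochemical
#' and gas-exchange module connectances — not the pooled mean over all
#' pairs, and without the linking pair.
#'
#' @param cg_pho,cg_ge non-negative module connectances.
#' @return `(cg_pho + cg_ge) / 2`.
#' @examples
#' global_connectance(1.68, 1.22)  # 1.45
#' @export
global_connectance <- function(cg_pho, cg_ge) {
  if (any(cg_pho < 0) || any(cg_ge < 0)) {
    abort("module connectances must be >= 0")
  }
  (cg_pho + cg_ge) / 2
}

#' Full connectance analysis of one treatment cell
#'
#' @param table replicate table for a single species x treatment cell.
#' @param spec network specification; default [default_network()].
#' @param sig_filter,alpha passed to [module_connectance()].
#' @return `connectance_result`: list with `species`, `treatment`,
#'   `cg_ge`, `cg_pho`, `cg_total`, `linking_z` and the per-pair
#'   `pair_results` data.frame (module column included).
#' @export
analyze_cell <- function(table, spec = default_network(),
                         sig_filter = FALSE, alpha = 0.05) {
  stopifnot(inherits(spec, "network_spec"))
  all_pairs <- spec_all_pairs(spec)
  res <- pairs_strength(table, all_pairs)
  res$module <- all_pairs$module

  mod_cg <- vapply(names(spec$modules), function(m) {
    z <- res$z[res$module == m]
    p <- res$p[res$module == m]
    if (sig_filter) z[p > alpha] <- 0
    mean(z)
  }, numeric(1))

  linking_z <- if (any(res$module == "linking")) {
    mean(res$z[res$module == "linking"])
  } else NA_real_

  cg_ge <- unname(mod_cg["gas_exchange"])
  cg_pho <- unname(mod_cg["photochemical"])
  structure(list(
    species = as.character(table$species[1] %||% NA),
    treatment = as.character(table$treatment[1] %||% NA),
    cg_ge = cg_ge,
    cg_pho = cg_pho,
    cg_total = global_connectance(cg_pho, cg_ge),
    linking_z = linking_z,
    module_cg = mod_cg,
    pair_results = res
  ), class = "connectance_result")
}

#' @export
print.connectance_result <- function(x, digits = 3, ...) {
  cat(sprintf("<connectance_result> %s / %s\n", x$species, x$treatment))
  cat(sprintf("  Cg_pho = %.*f  Cg_ge = %.*f  Cg_total = %.*f  link z = %.*f\n",
              digits, x$cg_pho, digits, x$cg_ge, digits, x$cg_total,
              digits, x$linking_z))
  cat(sprintf("  %d pairs, n per pair %d-%d\n", nrow(x$pair_results),
              min(x$pair_results$n), max(x$pair_results$n)))
  invisible(x)
}

## ---- fast internal path ---------------------------------------------------

# Index representation of a network spec against a fixed variable order,
# so resampling loops can get all module statistics from one correlation
# matrix call.
spec_index <- function(spec, vars) {
  idx <- function(pairs) {
    cbind(match(pairs$a, vars), match(pairs$b, vars))
  }
  list(vars = vars,
       modules = lapply(spec$modules, idx),
       linking = idx(spec$linking))
}

# cg statistics from a plain matrix whose columns follow sx$vars
cg_from_matrix <- function(m, sx) {
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  mod <- vapply(sx$modules, function(ix) mean(z_of_r(cm[ix])), numeric(1))
  link <- if (nrow(sx$linking)) mean(z_of_r(cm[sx$linking])) else NA_real_
  c(mod,
    cg_total = unname((mod["photochemical"] + mod["gas_exchange"]) / 2),
    linking_z = link)
}
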