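#' @title Study pipeline: connectance reports and treatment comparisons
#' @description
#' Driver-level operations that string the modules together: per-cell
#' connectance reports mirroring the study-table layout (rows `Cg_pho`,
#' `Cg_ge`, `Cg_total`, `ETR-AmaxL`; one column per treatment cell),
#' one-way ANOVA with Tukey HSD and a compact letter display for the
#' per-variable mean tables, percent-change summaries, and a
#' fully-deterministic synthetic reproduction demo.
#' @name pipeline
NULL

#' Connectance report over grouped data
#'
#' Splits the input by `species` and `treatment`, analyzes every cell
#' with [analyze_cell()] and assembles the wide report table plus the
#' long per-pair table. Missing variable columns are reported before any
#' computation; a constant column is reported with every pair it breaks.
#'
#' @param data replicate table covering one or more cells, or a CSV path.
#' @param spec network specification.
#' @param out_dir optional directory; when given, writes
#'   `connectance_wide.csv` and `connectance_pairs.csv`, each with a
#'   header comment recording the seed and a hash of the configuration.
#' @param n_boot optional bootstrap draws; when > 0, percentile CIs for
#'   `cg_total` are added to the wide table.
#' @param seed seed for the bootstrap (recorded in output headers).
#' @param digits report rounding (half-up), default 2; full precision is
#'   retained in the returned objects.
#' @return list: `wide` (statistics x cells data.frame), `pairs` (long
#'   per-pair data.frame), `cells` (list of `connectance_result`).
#' @export
run_connectance <- function(data, spec = default_network(), out_dir = NULL,
                            n_boot = 0, seed = 1, digits = 2) {
  if (is.character(data)) data <- read_replicate_table(data)
  stopifnot(inherits(spec, "network_spec"))
  need <- unique(unlist(spec_all_pairs(spec)[, c("a", "b")]))
  missing <- setdiff(c("species", "treatment", need), names(data))
  if (length(missing)) {
    abort("missing column(s): %s", paste(missing, collapse = ", "))
  }
  const_cols <- need[vapply(need, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    length(x) > 0 && max(x) == min(x)
  }, logical(1))]
  if (length(const_cols)) {
    ap <- spec_all_pairs(spec)
    hit <- ap[ap$a %in% const_cols | ap$b %in% const_cols, ]
    abort("constant column(s) %s break pair(s): %s",
          paste(const_cols, collapse = ", "),
          paste(pair_labels(hit), collapse = ", "))
  }

  cells <- split(data, list(data$species, data$treatment), drop = TRUE)
  results <- lapply(cells, analyze_cell, spec = spec)
  labels <- vapply(results, function(r) {
    paste(r$species, r$treatment, sep = "/")
  }, character(1))

  wide <- data.frame(
    statistic = c("Cg_pho", "Cg_ge", "Cg_total", "ETR-AmaxL"),
    vapply(results, function(r) {
      c(r$cg_pho, r$cg_ge, r$cg_total, r$linking_z)
    }, numeric(4)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(wide)[-1] <- labels

  if (n_boot > 0) {
    cis <- mapply(function(tab, i) {
      bootstrap_cg(tab, spec, n_boot = n_boot, seed = seed + i)
    }, cells, seq_along(cells), SIMPLIFY = FALSE)
    lo <- vapply(cis, function(ci) ci$ci["lower", "cg_total"], numeric(1))
    hi <- vapply(cis, function(ci) ci$ci["upper", "cg_total"], numeric(1))
    ci_rows <- data.frame(statistic = c("Cg_total_lo", "Cg_total_hi"),
                          rbind(unname(lo), unname(hi)),
                          check.names = FALSE, stringsAsFactors = FALSE)
    names(ci_rows)[-1] <- labels
    wide <- rbind(wide, ci_rows)
  }

  pairs_long <- do.call(rbind, lapply(results, function(r) {
    cbind(species = r$species, treatment = r$treatment, r$pair_results,
          stringsAsFactors = FALSE)
  }))
  rownames(pairs_long) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# photonet connectance report | seed=%s | config=%s",
                     seed, object_hash(list(spec = spec, n_boot = n_boot)))
    wide_out <- wide
    wide_out[-1] <- lapply(wide_out[-1], round_half_up, digits = digits)
    write_stamped_csv(wide_out, file.path(out_dir, "connectance_wide.csv"),
                      stamp)
    write_stamped_csv(pairs_long, file.path(out_dir, "connectance_pairs.csv"),
                      stamp)
  }
  list(wide = wide, pairs = pairs_long, cells = results)
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' One-way ANOVA with Tukey HSD and compact letters
#'
#' Compares group means of one variable across treatment levels within
#' the classical framework: one-way ANOVA, all-pairs Tukey honest
#' significant differences, and a compact letter display in which groups
#' sharing a letter are not significantly different at `alpha`. Letters
#' are assigned by a greedy clique cover of the non-significance graph
#' (groups ordered by decreasing mean), so every non-significant pair
#' shares at least one letter and no letter joins a significant pair.
#'
#' @param data replicate table.
#' @param variable variable column to compare.
#' @param group_col grouping column, default `"treatment"`.
#' @param alpha significance level, default 0.05.
#' @return `group_comparison` list: `variable`, `groups`, `means`, `n`,
#'   `F`, `p`, `tukey` (pairwise p matrix), `letters`, `alpha`.
#' @export
compare_treatments <- function(data, variable, group_col = "treatment",
                               alpha = 0.05) {
  if (!variable %in% names(data)) abort("no column '%s'", variable)
  g <- factor(data[[group_col]])
  y <- data[[variable]]
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (any(table(g) < 2)) abort("need >= 2 replicates per group")
  if (stats::var(y) == 0) abort("response is constant across all groups")
  zerovar <- tapply(y, g, stats::var) == 0
  if (any(zerovar)) {
    warning(sprintf("group(s) with zero variance: %s",
                    paste(names(zerovar)[zerovar], collapse = ", ")),
            call. = FALSE)
  }

  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  lv <- levels(g)
  pm <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lv, lv))
  diag(pm) <- 1
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(cmp)) {
    pm[cmp[[i]][1], cmp[[i]][2]] <- tk[i, "p adj"]
    pm[cmp[[i]][2], cmp[[i]][1]] <- tk[i, "p adj"]
  }

  structure(list(
    variable = variable,
    groups = lv,
    means = tapply(y, g, mean),
    n = as.integer(table(g)),
    F = an$`F value`[1],
    p = an$`Pr(>F)`[1],
    tukey = pm,
    letters = cld_letters(pm, tapply(y, g, mean), alpha),
    alpha = alpha
  ), class = "group_comparison")
}

#' Compact letter display by greedy clique cover
#'
#' Given the matrix of pairwise adjusted p-values, builds letter groups
#' such that (i) all members of a letter are mutually non-significant
#' (each letter is a clique of the non-significance graph) and (ii) every
#' non-significant pair shares at least one letter (the cliques cover the
#' graph's edges). Groups are visited in order of decreasing mean;
#' letters follow `a`, `b`, `c`, ...
#'
#' @param p_matrix symmetric matrix of pairwise p-values.
#' @param means group means (for ordering), same names as the matrix.
#' @param alpha significance level.
#' @return named character vector of letter strings per group.
#' @export
cld_letters <- function(p_matrix, means, alpha = 0.05) {
  gn <- rownames(p_matrix)
  ns <- !is.na(p_matrix) & p_matrix > alpha # non-significance adjacency
  diag(ns) <- TRUE
  ord <- gn[order(-unlist(means)[gn])]

  cliques <- list()
  for (g in ord) {
    placed <- FALSE
    for (k in seq_along(cliques)) {
      if (all(ns[g, cliques[[k]]])) {
        cliques[[k]] <- c(cliques[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1L]] <- g
  }
  # cover any non-significant pair the greedy pass missed
  for (i in seq_along(gn)) {
    for (j in seq_along(gn)) {
      if (j <= i || !ns[gn[i], gn[j]]) next
      covered <- any(vapply(cliques, function(cl) {
        all(c(gn[i], gn[j]) %in% cl)
      }, logical(1)))
      if (!covered) {
        cl <- c(gn[i], gn[j])
        for (g in setdiff(ord, cl)) if (all(ns[g, cl])) cl <- c(cl, g)
        cliques[[length(cliques) + 1L]] <- cl
      }
    }
  }
  # drop cliques fully absorbed by another
  keep <- rep(TRUE, length(cliques))
  for (k in seq_along(cliques)) {
    for (k2 in seq_along(cliques)) {
      if (k != k2 && keep[k2] &&
          all(cliques[[k]] %in% cliques[[k2]]) &&
          (length(cliques[[k]]) < length(cliques[[k2]]) || k > k2)) {
        keep[k] <- FALSE
        break
      }
    }
  }
  cliques <- cliques[keep]

  out <- stats::setNames(rep("", length(gn)), gn)
  for (k in seq_along(cliques)) {
    for (g in cliques[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("<group_comparison> %s: F = %.*g, p = %.*g\n",
              x$variable, digits, x$F, digits, x$p))
  df <- data.frame(mean = round_half_up(as.numeric(x$means), 2),
                   n = x$n, letters = x$letters[x$groups],
                   row.names = x$groups)
  print(df)
  invisible(x)
}

#' Percent change relative to a reference value
#'
#' `100 (value_new - value_ref) / value_ref`. Report tables round the
#' result half-up to the nearest integer; full precision is returned.
#'
#' @param value_ref reference (denominator), non-zero.
#' @param value_new new value.
#' @return Signed percentage.
#' @examples
#' percent_change(1.12, 2.04)   # 82.14...
#' round_half_up(percent_change(32.74, 13.10))  # -60
#' @export
percent_change <- function(value_ref, value_new) {
  if (any(value_ref == 0)) abort("reference value must be non-zero")
  100 * (value_new - value_ref) / value_ref
}

#' Synthetic end-to-end reproduction demo
#'
#' Runs both preset factorial experiments through the whole pipeline —
#' simulation, per-variable ANOVA/Tukey mean tables, connectance tables
#' and percent-change summaries — and renders one markdown report. All
#' numbers are synthetic and fully deterministic per `seed`; per-pair
#' sample sizes are printed for transparency.
#'
#' @param seed integer seed.
#' @param out_dir optional directory for `report.md` and the CSVs.
#' @param n_replicates replicates per cell, default 7.
#' @param fit_curves passed to the simulator; default `TRUE`.
#' @return character vector of report lines (invisibly when written).
#' @export
full_reproduction_demo <- function(seed = 20130710, out_dir = NULL,
                                   n_replicates = 7, fit_curves = TRUE) {
  fmt_tab <- function(df, digits = 2) {
    df[-1] <- lapply(df[-1], function(x) {
      if (is.numeric(x)) round_half_up(x, digits) else x
    })
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  mean_table <- function(tabs, vars, digits = 2) {
    all <- do.call(rbind, lapply(tabs, function(t) {
      t[, c("species", "treatment", vars)]
    }))
    rows <- lapply(vars, function(v) {
      cells <- split(all, list(all$species, all$treatment), drop = TRUE)
      vals <- vapply(cells, function(c) mean(c[[v]]), numeric(1))
      lets <- unlist(lapply(split(all, all$species), function(sp) {
        cmp <- compare_treatments(sp, v)
        stats::setNames(cmp$letters,
                        paste(sp$species[1], names(cmp$letters), sep = "."))
      }))
      cell_names <- names(vals)
      data.frame(variable = v, t(stats::setNames(
        sprintf("%s %s", round_half_up(vals, digits),
                lets[cell_names]), cell_names)),
        check.names = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  lines <- c("# Synthetic photosynthetic-network reproduction demo", "",
             sprintf("Seed: %d | replicates per cell: %d", seed,
                     n_replicates), "")
  tables_written <- 0L
  section <- function(title) c("", paste("##", title), "")

  for (exp in c("temperature", "water")) {
    scen <- preset_scenarios(exp, n_replicates = n_replicates,
                             seed = seed)
    tabs <- simulate_leaf_experiment(scen, fit_curves = fit_curves)
    full <- do.call(rbind, tabs)

    ge_vars <- c("AmaxL", "Rd", "Pr", "AmaxCO2", "Ls", "Vcmax")
    ph_vars <- c("FvFm", "dF_Fm", "NPQ", "ETR")
    gr_vars <- c("DMt", "LA")
    for (blk in list(c("Gas exchange means", "ge"),
                     c("Photochemical means", "ph"),
                     c("Growth means", "gr"))) {
      vars <- switch(blk[2], ge = ge_vars, ph = ph_vars, gr = gr_vars)
      lines <- c(lines, section(sprintf("%s experiment: %s", exp, blk[1])),
                 fmt_tab(mean_table(tabs, vars)))
      tables_written <- tables_written + 1L
    }

    rc <- run_connectance(full, seed = seed)
    lines <- c(lines, section(sprintf("%s experiment: connectance", exp)),
               fmt_tab(rc$wide))
    tables_written <- tables_written + 1L

    npair <- stats::aggregate(n ~ species + treatment, rc$pairs, min)
    lines <- c(lines,
               "", sprintf("Minimum per-pair n by cell: %s",
                           paste(sprintf("%s/%s=%d", npair$species,
                                         npair$treatment, npair$n),
                                 collapse = ", ")))

    # percent change of Cg_total relative to the benign reference cell
    ref_trt <- if (exp == "temperature") "30C" else "100pct"
    chg <- do.call(rbind, lapply(rc$cells, function(r) {
      data.frame(species = r$species, treatment = r$treatment,
                 cg_total = r$cg_total, stringsAsFactors = FALSE)
    }))
    pc <- do.call(rbind, lapply(split(chg, chg$species), function(sp) {
      ref <- sp$cg_total[sp$treatment == ref_trt]
      data.frame(species = sp$species, treatment = sp$treatment,
                 pct_change_vs_ref = round_half_up(
                   percent_change(ref, sp$cg_total)),
                 stringsAsFactors = FALSE)
    }))
    lines <- c(lines,
               section(sprintf("%s experiment: Cg_total %% change vs %s",
                               exp, ref_trt)),
               fmt_tab(pc, digits = 0))
    tables_written <- tables_written + 1L
  }
  lines <- c(lines, "", sprintf("Tables rendered: %d", tables_written))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(out_dir, "report.md"))
    return(invisible(lines))
  }
  lines
}
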