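#!/usr/bin/env Rscript
# Step 3 — classical treatment comparisons and connectance inference.
#
# For each experiment: one-way ANOVA + Tukey letters per physiological
# variable within species (the reporting unit used in the study tables),
# percent changes of Cg_total against the benign reference cell, and a
# permutation test for the water-regime connectance contrast.

library(photonet)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20130710L

variables <- c("AmaxL", "Rd", "Pr", "AmaxCO2", "Ls", "Vcmax",
               "FvFm", "dF_Fm", "NPQ", "ETR", "DMt", "LA")

for (exp in c("temperature", "water")) {
  src <- file.path("results", sprintf("sim_%s.csv", exp))
  if (!file.exists(src)) stop("run analysis/01_simulate.R first: no ", src)
  data <- read_replicate_table(src)
  cat(sprintf("\n== %s experiment ==\n", exp))

  rows <- list()
  for (sp in unique(data$species)) {
    d <- data[data$species == sp, ]
    for (v in variables) {
      cmp <- compare_treatments(d, v)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, variable = v,
        F = round_half_up(cmp$F, 2), p = signif(cmp$p, 3),
        means = paste(sprintf("%s=%s%s", cmp$groups,
                              round_half_up(as.numeric(cmp$means), 2),
                              cmp$letters[cmp$groups]), collapse = " "))
    }
  }
  anova_tab <- do.call(rbind, rows)
  out <- file.path("results", sprintf("anova_%s.csv", exp))
  write.csv(anova_tab, out, row.names = FALSE)
  n_sig <- sum(anova_tab$p < 0.05)
  cat(sprintf("ANOVA tables -> %s (%d of %d variable x species", out,
              n_sig, nrow(anova_tab)),
      "comparisons significant at 0.05)\n")

  ref_trt <- if (exp == "temperature") "30C" else "100pct"
  rc <- run_connectance(data)
  for (r in rc$cells) {
    ref_cell <- Filter(function(x) x$species == r$species &&
                         x$treatment == ref_trt, rc$cells)[[1]]
    cat(sprintf("Cg_total %s/%s vs %s: %+d%%\n", r$species, r$treatment,
                ref_trt,
                round_half_up(percent_change(ref_cell$cg_total,
                                             r$cg_total))))
  }

  if (exp == "water") {
    for (sp in unique(data$species)) {
      a <- data[data$species == sp & data$treatment == "100pct", ]
      b <- data[data$species == sp & data$treatment == "30pct", ]
      pt <- permutation_test_cg(a, b, n_perm = 999, seed = seed)
      cat(sprintf(
        "permutation test, %s 100%% vs 30%%: |dCg_total| = %.2f, p = %.3f\n",
        sp, pt$observed, pt$p_value))
    }
    cat("(n = 7 per group: only large connectance shifts can reach",
        "significance)\n")
  }
}
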