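#!/usr/bin/env Rscript

# Stage 3: differential expression between time points.
#
# Counts are TPM-normalized against the clean-tag totals and every pair is
# tested with the Audic-Claverie exact count test; Benjamini-Hochberg FDR is
# controlled within each comparison. DEG = FDR <= 0.01 and |log2 ratio| >= 1.
# Strategy I anchors every later time point at 0 h; strategy II walks
# consecutive pairs.

source("analysis/00_common.R")

em <- load_expression_matrix()

for (strategy in c("I", "II")) {
  res <- run_strategy(em, strategy, time_order = SAMPLES)
  cat(sprintf("\nstrategy %s:\n", strategy))
  for (nm in names(res)) {
    cc <- res[[nm]]
    fwrite(cc, file.path(OUT, sprintf("dge_%s_%s.tsv", strategy, nm)), sep = "\t")
    cat(sprintf("  %-12s up=%3d down=%3d (tested %d genes)\n", nm,
                sum(cc$status == "up"), sum(cc$status == "down"),
                sum(!is.na(cc$p_value))))
  }
  venn <- overlap_counts(lapply(res, deg_genes))
  fwrite(venn, file.path(OUT, sprintf("venn_strategy_%s.tsv", strategy)), sep = "\t")
  all_region <- venn[region == paste(names(res), collapse = "&")]
  cat(sprintf("  DEGs across all four comparisons: %d\n",
              if (nrow(all_region)) all_region$n else 0L))

  # direction tallies of consecutive pairwise overlaps
  for (i in seq_len(length(res) - 1)) {
    tl <- direction_tallies(res[[i]], res[[i + 1]])
    cat(sprintf("  common DEGs %s / %s: %d (%.2f%% down then, %.2f%% up next)\n",
                names(res)[i], names(res)[i + 1], tl$n_common,
                tl$a$down_pct, tl$b$up_pct))
  }
}

union_I <- unique(unlist(lapply(run_strategy(em, "I", time_order = SAMPLES), deg_genes)))
cat(sprintf("\nstrategy-I DEG union (profiled downstream): %d genes\n", length(union_I)))
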