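#!/usr/bin/env Rscript

# Stage 4: time-course expression patterns.
#
# Every strategy-I DEG keeps its full log2-ratio vector versus 0 h; profiles
# are clustered by average-linkage hierarchical clustering on the Pearson
# correlation distance (d = 1 - r). The presentation cut is 27 clusters
# (capped at the number of profiles); the trend tag of each cluster mean
# identifies the archetype shapes.

source("analysis/00_common.R")

em <- load_expression_matrix()
sI <- run_strategy(em, "I", time_order = SAMPLES)
profiles <- build_profiles(sI)
cat(sprintf("profiled genes (DEG in >= 1 baseline comparison): %d\n", nrow(profiles)))

k <- min(27, nrow(profiles))
asg <- hcluster(pearson_distance_matrix(profiles), k = k)
cs <- cluster_summaries(asg, profiles)

fwrite(merge(asg, profiles, by = "gene_id"), file.path(OUT, "clusters.tsv"), sep = "\t")
fwrite(cs$summary, file.path(OUT, "cluster_summary.tsv"), sep = "\t")
means_dt <- data.table(cluster = rownames(cs$means), cs$means)
fwrite(means_dt, file.path(OUT, "cluster_means.tsv"), sep = "\t")

cat(sprintf("cut to %d clusters; sizes and trends:\n", k))
print(cs$summary[order(-n)], nrows = 30)
top4 <- cs$summary[order(-n)][1:min(4, .N)]
cat(sprintf("\nfour largest clusters carry trends: %s\n",
            paste(top4$trend, collapse = ", ")))

# truth check against the planted archetypes
bundle <- load_bundle()
truth <- bundle$truth[, .(gene_id, archetype)]
merged <- merge(asg, truth, by = "gene_id")
cat("\nplanted archetype by cluster (profiled genes):\n")
print(dcast(merged, cluster ~ archetype, fun.aggregate = length), nrows = 30)
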