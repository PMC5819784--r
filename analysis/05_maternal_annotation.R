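#!/usr/bin/env Rscript

# Stage 5: maternal-ortholog classification, 50-kb genomic gene clusters and
# GO over-representation.
#
# OMGs are the B. mori genes in the ortholog table; OMDEGs the subset in the
# strategy-I DEG union. Genes within < 50 kb of an OMDEG on the same scaffold
# form gene clusters (merged transitively). GO enrichment uses the one-sided
# hypergeometric test over the GO-annotated gene background at P <= 0.01.

source("analysis/00_common.R")

bundle <- load_bundle()
em <- load_expression_matrix()
sI <- run_strategy(em, "I", time_order = SAMPLES)
deg_union <- unique(unlist(lapply(sI, deg_genes)))

mc <- classify_maternal_genes(bundle$ortholog_table, em, deg_union)
fwrite(mc$catalog, file.path(OUT, "maternal_catalog.tsv"), sep = "\t")
fwrite(mc$fractions, file.path(OUT, "maternal_fractions.tsv"), sep = "\t")
cat(sprintf("OMGs: %d; expressed: %d; OMDEGs: %d\n",
            mc$n_omg, sum(mc$catalog$class != "unexpressed"),
            sum(mc$catalog$class == "OMDEG")))
cat("high-expression (> 10 TPM at >= 1 time point) fractions per class:\n")
print(mc$fractions)

omdegs <- mc$catalog[class == "OMDEG", bmor_id]
gc <- find_omdeg_gene_clusters(bundle$genes, omdegs)
fwrite(gc, file.path(OUT, "gene_clusters.tsv"), sep = "\t")
multi <- gc[, .N, by = cluster_id][N > 1]
cat(sprintf("\ngene clusters: %d on %d scaffolds (%d with neighbors), %d genes in total\n",
            length(unique(gc$cluster_id)), length(unique(gc$scaffold_id)),
            nrow(multi), length(unique(gc$gene_id))))

background <- unique(bundle$go_table$gene_id)
er <- go_enrichment(intersect(deg_union, background), background, bundle$go_table)
fwrite(er, file.path(OUT, "enrichment_degs.tsv"), sep = "\t")
cat(sprintf("\nGO terms tested: %d; significant at P <= 0.01: %d\n",
            nrow(er), sum(er$significant)))
print(head(er, 5))
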