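# Shared paths and rebuild helpers for the analysis drivers. Every script can
# be re-run in order; all state lives under results/analysis/.

suppressPackageStartupMessages({
  library(tagdge)
  library(data.table)
})

ANALYSIS_SEED <- 1L
OUT <- "results/analysis"
REF_DIR <- file.path(OUT, "reference")
LIB_DIR <- file.path(OUT, "libs")
SAMPLES <- c("0h", "6h", "12h", "18h", "24h")

dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

analysis_reference_config <- function() reference_config(n_genes = 500)

load_bundle <- function() read_reference_bundle(REF_DIR)

load_raw_libraries <- function() {
  libs <- lapply(SAMPLES, function(sm)
    read_raw_library(file.path(LIB_DIR, paste0("raw_", sm, ".tsv")), sm))
  names(libs) <- SAMPLES
  libs
}

# clean + map all libraries and return everything downstream stages need
map_all_libraries <- function(bundle, libs) {
  parts <- partition_ambiguity(extract_virtual_tags(bundle$genes))
  idx <- build_tag_index(parts$unambiguous, parts$ambiguous)
  genome <- build_genome_index(bundle$scaffolds)
  cleans <- lapply(libs, clean_raw_tags)
  mappings <- lapply(cleans, map_clean_tags, index = idx, genome = genome)
  clean_totals <- vapply(cleans, function(cl) cl$total, numeric(1))
  list(parts = parts, index = idx, genome = genome, cleans = cleans,
       mappings = mappings, clean_totals = clean_totals)
}

load_expression_matrix <- function() {
  counts <- as.matrix(fread(file.path(OUT, "expression_counts.tsv")), rownames = "gene_id")
  storage.mode(counts) <- "integer"
  totals_dt <- fread(file.path(OUT, "clean_totals.tsv"))
  totals <- setNames(totals_dt$clean_total, totals_dt$sample_id)
  structure(list(counts = counts,
                 tpm = sweep(counts, 2, totals[colnames(counts)], "/") * 1e6,
                 clean_totals = totals[colnames(counts)]),
            class = "ExpressionMatrix")
}
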