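#' Clean a raw tag library
#'
#' Applies the quality-control rules in order: (1) a 3' adaptor occurrence is
#' trimmed off (everything from the adaptor's first occurrence onward is
#' removed); (2) tags containing an ambiguous base are dropped as low quality;
#' (3) tags whose length differs from `tag_length` are dropped; (4) counts are
#' re-aggregated and tags below `min_copy` copies (singletons by default) are
#' dropped. Surviving counts are preserved.
#'
#' @param raw a `RawTagLibrary`.
#' @param adaptor_seq 3' adaptor to trim; defaults to the library's own
#'   adaptor; `NULL` disables trimming.
#' @param min_copy minimum copy number kept (default 2).
#' @param tag_length required tag length (default 21).
#' @return list of class `"CleanTagLibrary"`: `sample_id`, `tags` (data.table
#'   sequence/count), `total`, `distinct`.
#' @export
clean_raw_tags <- function(raw, adaptor_seq = raw$adaptor_seq, min_copy = 2, tag_length = 21) {
  stopifnot(inherits(raw, "RawTagLibrary"))
  tags <- copy(raw$tags)
  if (nrow(tags) == 0) {
    warning("empty raw library: returning empty clean library")
    return(structure(list(sample_id = raw$sample_id,
                          tags = data.table(sequence = character(0), count = integer(0)),
                          total = 0L, distinct = 0L),
                     class = "CleanTagLibrary"))
  }
  if (!is.null(adaptor_seq) && nzchar(adaptor_seq)) {
    hit <- regexpr(adaptor_seq, tags$sequence, fixed = TRUE)
    trim <- hit > 0
    tags[trim, sequence := substr(sequence, 1L, hit[trim] - 1L)]
  }
  tags <- tags[!grepl("[^ACGT]", sequence)]
  tags <- tags[nchar(sequence) == tag_length]
  tags <- tags[, .(count = sum(count)), by = sequence]
  tags <- tags[count >= min_copy]
  setorder(tags, sequence)
  structure(list(sample_id = raw$sample_id, tags = tags,
                 total = sum(tags$count), distinct = nrow(tags)),
            class = "CleanTagLibrary")
}

#' Build a genome search index
#'
#' Holds the scaffold sequences (and their reverse complements, covering the
#' minus strand) for multi-pattern tag searches. Queries are answered by
#' exact Aho-Corasick matching of the tag and all of its single-substitution
#' variants, which is equivalent to a <= 1-mismatch search without
#' materializing the genome k-mer set.
#'
#' @param scaffolds data.table with a `seq` column of scaffold sequences.
#' @param k tag width (default 21).
#' @return object of class `"GenomeIndex"`.
#' @export
build_genome_index <- function(scaffolds, k = 21L) {
  subject <- Biostrings::DNAStringSet(scaffolds$seq)
  structure(list(subject = subject,
                 subject_rc = Biostrings::reverseComplement(subject),
                 k = k),
            class = "GenomeIndex")
}

# is each query within Hamming distance <= 1 of a genomic k-mer on either strand?
genome_hit <- function(gindex, seqs, max_mismatch = 1L) {
  if (length(seqs) == 0) return(logical(0))
  vars <- hamming1_variants(seqs, include_self = TRUE)
  if (max_mismatch < 1L) vars <- vars[seq_along(seqs)]  # self rows only
  uv <- unique(vars$variant)
  pd <- Biostrings::PDict(uv)
  n_hit <- Biostrings::vcountPDict(pd, gindex$subject, collapse = 1) +
    Biostrings::vcountPDict(pd, gindex$subject_rc, collapse = 1)
  hit_var <- uv[n_hit > 0]
  hit <- logical(length(seqs))
  hit[unique(vars[variant %chin% hit_var, query_id])] <- TRUE
  hit
}

#' Map clean tags to genes and genome
#'
#' Per distinct clean tag, in order: (1) gene lookup against the virtual tag
#' index (exact then 1-mismatch): a `unique` hit is counted for its gene
#' (category `gene_unambiguous`, also part of `gene_all`); a `multi` hit — or a
#' hit on a reference-level ambiguous tag — enters `gene_all` only; (2) tags
#' not matching any gene are searched against the genome (both strands, up to
#' 1 mismatch) and classed `genome`; (3) the remainder is `unknown`. Per-gene
#' counts accumulate the tag counts of unique hits only.
#'
#' @param clean a `CleanTagLibrary`.
#' @param index a `TagIndex` (built with the ambiguous set attached).
#' @param genome optional `GenomeKmerIndex`; if `NULL` the genome step is
#'   skipped and non-gene tags fall through to `unknown`.
#' @param genome_max_mismatch mismatches allowed in the genome search (0 or 1).
#' @return list of class `"MappingResult"`: `tag_table` (sequence, count,
#'   category, genes_hit), `gene_counts` (gene_id, count), `genes_all_mapped`,
#'   `genes_unambiguous_mapped` (character vectors), `totals` (named list of
#'   total/distinct per category).
#' @export
map_clean_tags <- function(clean, index, genome = NULL, genome_max_mismatch = 1L) {
  stopifnot(inherits(clean, "CleanTagLibrary"))
  tags <- copy(clean$tags)
  if (nrow(tags) > 0 && any(nchar(tags$sequence) != index$tag_length))
    stopf("input error: clean library contains tags of wrong length")
  if (nrow(tags) == 0) {
    tags <- data.table(sequence = character(0), count = integer(0))
  }
  qr <- query_tag_index(index, tags$sequence)
  tags[, `:=`(status = qr$status, genes_hit = qr$genes_hit)]
  tags[, category := "unknown"]
  tags[status == "unique", category := "gene_unambiguous"]
  tags[status == "multi", category := "gene_ambiguous"]
  pending <- which(tags$category == "unknown")
  if (!is.null(genome) && length(pending) > 0) {
    gh <- genome_hit(genome, tags$sequence[pending], genome_max_mismatch)
    tags[pending[gh], category := "genome"]
  }

  gene_counts <- tags[category == "gene_unambiguous",
                      .(count = sum(count)), by = .(gene_id = genes_hit)]
  setorder(gene_counts, gene_id)
  genes_all <- sort(unique(unlist(strsplit(
    tags[category %in% c("gene_unambiguous", "gene_ambiguous"), genes_hit],
    ",", fixed = TRUE))))
  genes_unamb <- gene_counts$gene_id

  tot <- function(cats) list(
    total = sum(tags[category %in% cats, count]),
    distinct = nrow(tags[category %in% cats]))
  totals <- list(
    clean = list(total = sum(tags$count), distinct = nrow(tags)),
    gene_all = tot(c("gene_unambiguous", "gene_ambiguous")),
    gene_unambiguous = tot("gene_unambiguous"),
    genome = tot("genome"),
    unknown = tot("unknown")
  )
  structure(list(tag_table = tags[, .(sequence, count, category, genes_hit)],
                 gene_counts = gene_counts,
                 genes_all_mapped = genes_all,
                 genes_unambiguous_mapped = genes_unamb,
                 totals = totals,
                 sample_id = clean$sample_id),
            class = "MappingResult")
}

#' Assemble a library summary from its component counts
#'
#' Computes every percentage field of the per-sample summary table (the
#' raw/clean totals, the gene-mapped, genome-mapped and unknown fractions of
#' clean tags, and the mapped-gene fractions of the reference annotation),
#' with all percentages rounded half-up to 2 decimals.
#'
#' @param sample_id sample label.
#' @param raw_total,raw_distinct raw tag totals.
#' @param clean_total,clean_distinct clean tag totals.
#' @param gene_all_total,gene_all_distinct tags mapped to genes (any).
#' @param gene_unamb_total,gene_unamb_distinct unambiguously gene-mapped tags.
#' @param genes_all_mapped_n,genes_unamb_mapped_n mapped gene counts.
#' @param genome_total,genome_distinct genome-mapped tags.
#' @param unknown_total,unknown_distinct unmapped tags.
#' @param n_reference_genes denominator for the "% of ref genes" fields: the
#'   full annotated gene count (not only CATG-bearing genes).
#' @return list of class `"LibrarySummary"`.
#' @export
library_summary <- function(sample_id,
                            raw_total, raw_distinct,
                            clean_total, clean_distinct,
                            gene_all_total, gene_all_distinct,
                            gene_unamb_total, gene_unamb_distinct,
                            genes_all_mapped_n, genes_unamb_mapped_n,
                            genome_total, genome_distinct,
                            unknown_total, unknown_distinct,
                            n_reference_genes) {
  if (clean_total == 0)
    warning("zero clean tags: percentages reported as 0.00")
  structure(list(
    sample_id = sample_id,
    raw_total = raw_total, raw_distinct = raw_distinct,
    clean_total = clean_total, clean_distinct = clean_distinct,
    gene_all_total = gene_all_total,
    gene_all_pct = pct(gene_all_total, clean_total),
    gene_all_distinct = gene_all_distinct,
    gene_all_distinct_pct = pct(gene_all_distinct, clean_distinct),
    gene_unamb_total = gene_unamb_total,
    gene_unamb_pct = pct(gene_unamb_total, clean_total),
    gene_unamb_distinct = gene_unamb_distinct,
    gene_unamb_distinct_pct = pct(gene_unamb_distinct, clean_distinct),
    genes_all_mapped_n = genes_all_mapped_n,
    genes_all_mapped_pct = pct(genes_all_mapped_n, n_reference_genes),
    genes_unamb_mapped_n = genes_unamb_mapped_n,
    genes_unamb_mapped_pct = pct(genes_unamb_mapped_n, n_reference_genes),
    genome_total = genome_total,
    genome_pct = pct(genome_total, clean_total),
    genome_distinct = genome_distinct,
    genome_distinct_pct = pct(genome_distinct, clean_distinct),
    unknown_total = unknown_total,
    unknown_pct = pct(unknown_total, clean_total),
    unknown_distinct = unknown_distinct,
    unknown_distinct_pct = pct(unknown_distinct, clean_distinct),
    n_reference_genes = n_reference_genes
  ), class = "LibrarySummary")
}

#' Summarize one sample's library
#'
#' @param raw a `RawTagLibrary`.
#' @param clean the matching `CleanTagLibrary`.
#' @param mapping the matching `MappingResult`.
#' @param n_reference_genes annotated gene count used as the "% of ref genes"
#'   denominator.
#' @return a `LibrarySummary`.
#' @export
summarize_library <- function(raw, clean, mapping, n_reference_genes) {
  stopifnot(identical(raw$sample_id, clean$sample_id),
            identical(clean$sample_id, mapping$sample_id))
  t <- mapping$totals
  library_summary(
    sample_id = raw$sample_id,
    raw_total = sum(raw$tags$count), raw_distinct = nrow(raw$tags),
    clean_total = clean$total, clean_distinct = clean$distinct,
    gene_all_total = t$gene_all$total, gene_all_distinct = t$gene_all$distinct,
    gene_unamb_total = t$gene_unambiguous$total,
    gene_unamb_distinct = t$gene_unambiguous$distinct,
    genes_all_mapped_n = length(mapping$genes_all_mapped),
    genes_unamb_mapped_n = length(mapping$genes_unambiguous_mapped),
    genome_total = t$genome$total, genome_distinct = t$genome$distinct,
    unknown_total = t$unknown$total, unknown_distinct = t$unknown$distinct,
    n_reference_genes = n_reference_genes
  )
}

SUMMARY_ROWS <- c(
  "Raw Data Total", "Raw Data Distinct Tag",
  "Clean Tag Total number", "Clean Tag Distinct Tag number",
  "All Tag-Mapping to Gene Total number", "All Tag-Mapping to Gene Total % of clean tag",
  "All Tag-Mapping to Gene Distinct Tag number", "All Tag-Mapping to Gene Distinct Tag % of clean tag",
  "Unambiguous Tag-Mapping to Gene Total number", "Unambiguous Tag-Mapping to Gene Total % of clean tag",
  "Unambiguous Tag-Mapping to Gene Distinct Tag number", "Unambiguous Tag-Mapping to Gene Distinct Tag % of clean tag",
  "All Tag-mapped Genes number", "All Tag-mapped Genes % of ref genes",
  "Unambiguous Tag-mapped Genes number", "Unambiguous Tag-mapped Genes % of ref genes",
  "Mapping to Genome Total number", "Mapping to Genome Total % of clean tag",
  "Mapping to Genome Distinct Tag number", "Mapping to Genome Distinct Tag % of clean tag",
  "Unknown Tag Total number", "Unknown Tag Total % of clean tag",
  "Unknown Tag Distinct Tag number", "Unknown Tag Distinct Tag % of clean tag"
)

#' Combine per-sample summaries into one table
#'
#' Mirrors the row layout of the study-style library summary (one column per
#' sample), suitable for TSV export.
#'
#' @param summaries list of `LibrarySummary` objects.
#' @return data.table with a `Summary` label column and one column per sample.
#' @export
summary_table <- function(summaries) {
  cols <- lapply(summaries, function(s) {
    c(s$raw_total, s$raw_distinct, s$clean_total, s$clean_distinct,
      s$gene_all_total, s$gene_all_pct, s$gene_all_distinct, s$gene_all_distinct_pct,
      s$gene_unamb_total, s$gene_unamb_pct, s$gene_unamb_distinct, s$gene_unamb_distinct_pct,
      s$genes_all_mapped_n, s$genes_all_mapped_pct,
      s$genes_unamb_mapped_n, s$genes_unamb_mapped_pct,
      s$genome_total, s$genome_pct, s$genome_distinct, s$genome_distinct_pct,
      s$unknown_total, s$unknown_pct, s$unknown_distinct, s$unknown_distinct_pct)
  })
  out <- data.table(Summary = SUMMARY_ROWS)
  for (i in seq_along(summaries)) out[, (summaries[[i]]$sample_id) := cols[[i]]]
  out
}
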