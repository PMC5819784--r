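raw_lib <- function(seqs, counts, sample_id = "0h", adaptor = NULL) {
  structure(list(sample_id = sample_id,
                 tags = data.table::data.table(sequence = seqs, count = counts),
                 adaptor_seq = adaptor),
            class = "RawTagLibrary")
}

test_that("cleaning applies length, quality, copy-number and adaptor rules", {
  a21 <- strrep("A", 21); c20 <- strrep("C", 20); g21 <- strrep("G", 21)
  cl <- clean_raw_tags(raw_lib(c(a21, c20, g21), c(5L, 7L, 1L)))
  expect_identical(cl$tags$sequence, a21)
  expect_identical(cl$tags$count, 5L)
  expect_identical(cl$total, 5L)
  expect_identical(cl$distinct, 1L)

  # identity case: nothing violates any rule
  tags <- paste0("CATG", c(strrep("A", 17), strrep("C", 17)))
  cl <- clean_raw_tags(raw_lib(tags, c(3L, 2L)))
  expect_identical(cl$tags$sequence, sort(tags))
  expect_identical(cl$total, 5L)

  # adaptor read-through is trimmed before the length check
  ad <- "TCGTATGCCGTCTTCTGCTTG"
  frag <- paste0(substr(strrep("A", 21), 1, 10), ad)  # 10 bp + adaptor: too short
  cl <- clean_raw_tags(raw_lib(c(frag, strrep("T", 21)), c(4L, 2L), adaptor = ad))
  expect_identical(cl$tags$sequence, strrep("T", 21))

  # ambiguous-base tags are low quality
  nn <- paste0("CATG", "N", strrep("A", 16))
  cl <- clean_raw_tags(raw_lib(c(nn, strrep("T", 21)), c(9L, 3L)))
  expect_identical(cl$tags$sequence, strrep("T", 21))
})

test_that("cleaning matches a rule-by-rule oracle on a mixed library", {
  withr::with_seed(17, {
    good <- paste0("CATG", vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = ""), character(1)))
  })
  ad <- "TCGTATGCCGTCTTCTGCTTG"
  seqs <- c(good,
            strrep("A", 20),                       # short
            strrep("C", 23),                       # long
            paste0("CATG", "N", strrep("G", 16)),  # ambiguous base
            paste0(substr(good[1], 1, 12), ad),    # adaptor read-through
            paste0("CATG", strrep("T", 17)),       # singleton
            good[1])                               # duplicate of good[1]
  counts <- c(5L, 4L, 3L, 2L, 9L, 6L, 7L, 3L, 1L, 2L)
  cl <- clean_raw_tags(raw_lib(seqs, counts, adaptor = ad))

  # oracle: apply each rule in sequence on a plain data.frame
  df <- data.frame(s = seqs, n = counts)
  hit <- regexpr(ad, df$s, fixed = TRUE)
  df$s[hit > 0] <- substr(df$s[hit > 0], 1, hit[hit > 0] - 1)
  df <- df[!grepl("N", df$s) & nchar(df$s) == 21, ]
  agg <- aggregate(n ~ s, df, sum)
  agg <- agg[agg$n >= 2, ]
  agg <- agg[order(agg$s), ]
  expect_identical(cl$tags$sequence, agg$s)
  expect_identical(cl$tags$count, as.integer(agg$n))
})

test_that("cleaning is idempotent and warns on empty input", {
  b <- generate_reference(tiny_config(n_genes = 30), seed = 61)
  lib <- simulate_raw_library(b, "18h", depth = 8000, seed = 3)
  cl1 <- clean_raw_tags(lib)
  again <- structure(list(sample_id = cl1$sample_id, tags = cl1$tags,
                          adaptor_seq = lib$adaptor_seq), class = "RawTagLibrary")
  cl2 <- clean_raw_tags(again)
  expect_identical(cl1$tags, cl2$tags)
  expect_warning(clean_raw_tags(raw_lib(character(0), integer(0))), "empty")
})

test_that("mapping categorizes tags and the categories partition the total", {
  b <- generate_reference(tiny_config(n_genes = 50), seed = 71)
  vts <- extract_virtual_tags(b$genes)
  parts <- partition_ambiguity(vts)
  idx <- build_tag_index(parts$unambiguous, parts$ambiguous)
  genome <- build_genome_index(b$scaffolds)

  lib <- simulate_raw_library(b, "24h", depth = 20000, seed = 5)
  cl <- clean_raw_tags(lib)
  mp <- map_clean_tags(cl, idx, genome)

  t <- mp$totals
  expect_identical(t$gene_all$total + t$genome$total + t$unknown$total, t$clean$total)
  expect_identical(t$clean$total, cl$total)
  expect_identical(t$gene_all$distinct + t$genome$distinct + t$unknown$distinct,
                   cl$distinct)
  expect_true(t$gene_unambiguous$total <= t$gene_all$total)
  expect_true(all(mp$genes_unambiguous_mapped %in% mp$genes_all_mapped))

  # per-tag categories agree with an independent scan on a subsample;
  # the genome side is cross-checked with Biostrings pattern matching
  scafs <- Biostrings::DNAStringSet(b$scaffolds$seq)
  withr::with_seed(8, sub <- mp$tag_table[sample(.N, 40)])
  for (i in seq_len(nrow(sub))) {
    o <- naive_tag_scan(vts, sub$sequence[i])
    expected <- if (o$status == "unique") "gene_unambiguous"
      else if (o$status == "multi") "gene_ambiguous"
      else {
        fwd <- sum(Biostrings::vcountPattern(sub$sequence[i], scafs, max.mismatch = 1))
        rev <- sum(Biostrings::vcountPattern(revcomp_chr(sub$sequence[i]), scafs,
                                             max.mismatch = 1))
        if (fwd + rev > 0) "genome" else "unknown"
      }
    expect_identical(sub$category[i], expected)
  }
})

test_that("all-exact-unique libraries have no genome or unknown tags", {
  b <- generate_reference(tiny_config(n_genes = 40), seed = 81)
  parts <- partition_ambiguity(extract_virtual_tags(b$genes))
  idx <- build_tag_index(parts$unambiguous, parts$ambiguous)
  lib <- simulate_raw_library(b, "0h", depth = 10000, error_rate = 0,
                              artifact_rates = list(), seed = 2)
  cl <- clean_raw_tags(lib)
  mp <- map_clean_tags(cl, idx, build_genome_index(b$scaffolds))
  expect_identical(mp$totals$genome$total, 0L)
  expect_identical(mp$totals$unknown$total, 0L)
})

test_that("an intergenic 21-mer is traced to the genome category", {
  b <- generate_reference(tiny_config(n_genes = 30), seed = 91)
  parts <- partition_ambiguity(extract_virtual_tags(b$genes))
  idx <- build_tag_index(parts$unambiguous, parts$ambiguous)
  genome <- build_genome_index(b$scaffolds)
  # first 21-mer of scaffold 1 lies in the leading intergenic spacer
  # (generated gene starts are all beyond it)
  planted <- substr(b$scaffolds$seq[1], 1, 21)
  expect_true(min(b$genes[scaffold_id == b$scaffolds$scaffold_id[1], start]) > 50)
  clean <- structure(list(sample_id = "0h",
                          tags = data.table::data.table(sequence = planted, count = 4L),
                          total = 4L, distinct = 1L),
                     class = "CleanTagLibrary")
  mp <- map_clean_tags(clean, idx, genome)
  expect_identical(mp$tag_table$category, "genome")
})

test_that("library summary reproduces printed percentage arithmetic", {
  s <- library_summary("0h",
                       raw_total = 6033953, raw_distinct = 282267,
                       clean_total = 5854282, clean_distinct = 105259,
                       gene_all_total = 769935, gene_all_distinct = 18456,
                       gene_unamb_total = 755083, gene_unamb_distinct = 18217,
                       genes_all_mapped_n = 6374, genes_unamb_mapped_n = 6183,
                       genome_total = 4187834, genome_distinct = 58257,
                       unknown_total = 896513, unknown_distinct = 28546,
                       n_reference_genes = 14623)
  expect_identical(s$gene_all_pct, 13.15)
  expect_identical(s$genes_all_mapped_pct, 43.59)
  expect_identical(s$gene_unamb_pct, 12.90)
  expect_identical(s$unknown_pct, 15.31)
  # the three clean-tag fractions close to 100 within rounding slack
  total_pct <- s$gene_all_pct + s$genome_pct + s$unknown_pct
  expect_true(total_pct >= 99.97 && total_pct <= 100.03)
})

test_that("degenerate summaries report 0.00 percentages", {
  s <- suppressWarnings(library_summary("x", 10, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                                        n_reference_genes = 100))
  expect_identical(s$gene_all_pct, 0)
  expect_identical(s$genome_pct, 0)
  expect_warning(library_summary("x", 10, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 100),
                 "zero clean tags")
  s2 <- library_summary("y", 100, 50, 1000, 100, 0, 0, 0, 0, 0, 0, 0, 0, 1000, 100, 100)
  expect_identical(s2$gene_all_pct, 0)
  expect_identical(s2$unknown_pct, 100)
})
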