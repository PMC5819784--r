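test_that("maternal classification partitions the OMG set", {
  counts <- rbind(m1 = c(0L, 0L), m2 = c(50L, 5L), m3 = c(200L, 10L), other = c(5L, 5L))
  colnames(counts) <- c("0h", "24h")
  em <- structure(list(counts = counts,
                       tpm = sweep(counts, 2, c(1e4, 1e4), "/") * 1e6,
                       clean_totals = c("0h" = 1e4, "24h" = 1e4)),
                  class = "ExpressionMatrix")
  omap <- data.table::data.table(dmel_id = c("d1", "d2", "d3"),
                                 bmor_id = c("m1", "m2", "m3"))
  mc <- classify_maternal_genes(omap, em, deg_union = "m3")
  cat <- mc$catalog
  expect_identical(cat[bmor_id == "m1", class], "unexpressed")
  expect_identical(cat[bmor_id == "m2", class], "expressed_nonDEG")
  expect_identical(cat[bmor_id == "m3", class], "OMDEG")
  expect_identical(sum(mc$fractions$n), mc$n_omg)  # classes partition the set
  # high expression is a strict > 10 TPM rule on the max over time points
  expect_true(cat[bmor_id == "m3", high_expression])
  expect_true(cat[bmor_id == "m2", high_expression])  # 50/1e4*1e6 = 5000 TPM
  expect_false(cat[bmor_id == "m1", high_expression])
  expect_warning(classify_maternal_genes(omap[0], em, character(0)), "empty")
})

test_that("high-expression fractions reproduce the printed ratio arithmetic", {
  # 13 of 23 OMDEGs above threshold -> 56.52%; 6 of 37 non-DEGs -> 16.22%
  expect_identical(pct(13, 23), 56.52)
  expect_identical(pct(6, 37), 16.22)
  counts <- matrix(20L, nrow = 23, ncol = 1,
                   dimnames = list(sprintf("m%02d", 1:23), "0h"))
  counts[14:23, 1] <- 1L  # 10 genes at 1 tag -> low TPM at this depth
  em <- structure(list(counts = counts, tpm = counts / 1e6 * 1e6,
                       clean_totals = c("0h" = 1e6)),
                  class = "ExpressionMatrix")
  omap <- data.table::data.table(dmel_id = paste0("d", 1:23), bmor_id = rownames(counts))
  mc <- classify_maternal_genes(omap, em, deg_union = rownames(counts),
                                thresholds = dge_thresholds(high_expression_tpm = 10))
  fr <- mc$fractions[class == "OMDEG"]
  expect_identical(fr$n, 23L)
  expect_identical(fr$n_high, 13L)
  expect_identical(fr$high_pct, 56.52)
})

test_that("gene clusters follow the 50-kb gap rule", {
  genes <- data.table::data.table(
    gene_id = c("omdeg", "near", "far"),
    scaffold_id = "s1",
    start = c(100000L, 140000L, 161001L),
    end   = c(101000L, 141000L, 162000L))
  gc <- find_omdeg_gene_clusters(genes, "omdeg")
  # gap(omdeg, near) = 140000 - 101000 - 1 = 38999 < 50000; far is 60000 away
  expect_setequal(gc$gene_id, c("omdeg", "near"))
  expect_identical(length(unique(gc$cluster_id)), 1L)

  genes2 <- data.table::data.table(
    gene_id = c("omdeg", "far"),
    scaffold_id = "s1", start = c(1000L, 62001L), end = c(2000L, 63000L))
  gc2 <- find_omdeg_gene_clusters(genes2, "omdeg")
  expect_identical(gc2$gene_id, "omdeg")
})

test_that("neighborhoods sharing a gene merge transitively", {
  genes <- data.table::data.table(
    gene_id = c("om1", "mid", "om2"),
    scaffold_id = "s1",
    start = c(1000L, 45000L, 89000L),
    end   = c(2000L, 46000L, 90000L))
  # om1-mid gap 42999, mid-om2 gap 42999, om1-om2 gap 86999 (> 50 kb)
  gc <- find_omdeg_gene_clusters(genes, c("om1", "om2"))
  expect_identical(length(unique(gc$cluster_id)), 1L)
  expect_setequal(gc$gene_id, c("om1", "mid", "om2"))
})

test_that("gene clustering matches a union-find oracle and ignores input order", {
  withr::with_seed(13, {
    genes <- data.table::data.table(
      gene_id = sprintf("g%03d", 1:60),
      scaffold_id = sample(c("s1", "s2", "s3"), 60, replace = TRUE),
      start = sample.int(500000, 60))
    genes[, end := start + sample(500:3000, 60)]
    omdegs <- sample(genes$gene_id, 8)
  })
  gc <- find_omdeg_gene_clusters(genes, omdegs)
  oracle <- union_find_clusters(genes, omdegs)

  pkg_members <- unname(lapply(split(gc$gene_id, gc$cluster_id), sort))
  orc_members <- unname(lapply(oracle, sort))
  expect_setequal(lapply(pkg_members, paste, collapse = ","),
                  lapply(orc_members, paste, collapse = ","))

  gc_rev <- find_omdeg_gene_clusters(genes, rev(omdegs))
  expect_identical(as.data.frame(gc), as.data.frame(gc_rev))
  expect_warning(find_omdeg_gene_clusters(genes, c(omdegs[1], "missing")), "skipped")
})

test_that("GO enrichment equals hypergeometric enumeration", {
  # member set exactly the 5 term-carriers among 10 genes: p = 1 / C(10, 5)
  genes <- sprintf("g%02d", 1:10)
  go <- data.table::data.table(gene_id = genes[1:5], go_id = "GO:0000001",
                               namespace = "molecular_function")
  er <- go_enrichment(genes[1:5], genes, go)
  expect_equal(er$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_true(er$significant)

  # member set = background: no over-representation possible
  er2 <- go_enrichment(genes, genes, go)
  expect_equal(er2$p_value, 1)

  # terms with no member-gene carrier are not reported
  go3 <- rbind(go, data.table::data.table(gene_id = genes[6], go_id = "GO:0000002",
                                          namespace = "biological_process"))
  er3 <- go_enrichment(genes[1:5], genes, go3)
  expect_identical(er3$go_id, "GO:0000001")

  expect_error(go_enrichment("absent", genes, go), "subset")
})

test_that("GO enrichment matches full enumeration on random small backgrounds", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      N <- sample(15:30, 1)
      genes <- sprintf("g%02d", seq_len(N))
      go <- data.table::data.table(
        gene_id = sample(genes, N * 2, replace = TRUE),
        go_id = sample(sprintf("GO:%07d", 1:6), N * 2, replace = TRUE))
      go <- unique(go)[, namespace := "molecular_function"]
      members <- sample(genes, sample(3:8, 1))
      er <- go_enrichment(members, genes, go)
      for (i in seq_len(nrow(er))) {
        expect_equal(er$p_value[i],
                     fisher_oracle(er$k[i], er$K[i], er$n[i], er$N[i]),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("ddCT relative expression follows the doubling rule", {
  ct <- data.table::data.table(
    sample = rep(c("cal", "s1", "s2"), each = 2),
    gene = rep(c("ref", "tgt"), 3),
    replicate = 1L,
    ct = c(20, 25,   # calibrator: dCT = 5
           20, 24,   # one cycle lower  -> 2x
           20, 26))  # one cycle higher -> 0.5x
  res <- ddct_relative_expression(ct, "ref", "cal")
  expect_equal(res[sample == "cal", relative_level], 1)
  expect_equal(res[sample == "s1", relative_level], 2)
  expect_equal(res[sample == "s2", relative_level], 0.5)

  # equal CT everywhere -> all levels 1
  ct2 <- data.table::data.table(sample = rep(c("a", "b"), each = 2),
                                gene = rep(c("ref", "tgt"), 2),
                                replicate = 1L, ct = 22)
  expect_true(all(ddct_relative_expression(ct2, "ref", "a")$relative_level == 1))

  # replicates are averaged before normalization
  ct3 <- data.table::data.table(sample = "a", gene = c("ref", "tgt", "tgt"),
                                replicate = c(1L, 1L, 2L), ct = c(20, 24, 26))
  res3 <- ddct_relative_expression(ct3, "ref", "a")
  expect_equal(res3$dct, 5)

  bad <- ct[gene != "ref" | sample != "s1"]
  expect_error(ddct_relative_expression(bad, "ref", "cal"), "reference gene")
})

test_that("down-planted maternal genes land in a down-trending modal cluster", {
  b <- generate_reference(tiny_config(n_genes = 80, maternal_fraction = 0.15,
                                      maternal_archetype = "down_monotone"),
                          seed = 111)
  parts <- partition_ambiguity(extract_virtual_tags(b$genes))
  idx <- build_tag_index(parts$unambiguous, parts$ambiguous)
  samples <- names(b$time_points)
  mappings <- lapply(seq_along(samples), function(i) {
    lib <- simulate_raw_library(b, samples[i], depth = 4e4, seed = 300 + i)
    map_clean_tags(clean_raw_tags(lib), idx)
  })
  names(mappings) <- samples
  totals <- vapply(mappings, function(m) m$totals$clean$total, numeric(1))
  em <- build_expression_matrix(mappings, totals, gene_ids = sort(b$genes$gene_id))
  sI <- run_strategy(em, "I")
  pr <- build_profiles(sI)
  asg <- hcluster(pearson_distance_matrix(pr), k = min(8, nrow(pr)))
  mc <- classify_maternal_genes(b$ortholog_table, em, deg_union = pr$gene_id)
  omdegs <- mc$catalog[class == "OMDEG", bmor_id]
  expect_gt(length(omdegs), 0)
  modal <- as.integer(names(which.max(table(asg[gene_id %in% omdegs, cluster]))))
  cs <- cluster_summaries(asg, pr)
  modal_mean <- cs$means[as.character(modal), ]
  expect_true(all(diff(c(0, modal_mean)) <= 1e-8))
})
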