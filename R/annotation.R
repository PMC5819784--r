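#' Classify orthologous maternal genes
#'
#' Every B. mori gene appearing in the ortholog map is an orthologous maternal
#' gene (OMG). An OMG is `expressed` when it carries at least one unambiguous
#' tag in any sample, an `OMDEG` when it belongs to the strategy-I DEG union,
#' and otherwise `expressed_nonDEG` or `unexpressed`. The high-expression flag
#' marks genes exceeding the TPM threshold (strictly) at one or more time
#' points.
#'
#' @param ortholog_map data.table with columns `dmel_id`, `bmor_id`.
#' @param em an `ExpressionMatrix` over the reference gene universe.
#' @param deg_union character vector: union of strategy-I DEG gene ids.
#' @param thresholds a [dge_thresholds()] (uses `high_expression_tpm`).
#' @return list of class `"MaternalCatalog"`: `catalog` (data.table: bmor_id,
#'   class, max_tpm, high_expression), `fractions` (data.table per class:
#'   n, n_high, high_pct), `n_omg`.
#' @export
classify_maternal_genes <- function(ortholog_map, em, deg_union,
                                    thresholds = dge_thresholds()) {
  if (nrow(ortholog_map) == 0) {
    warning("empty ortholog map: empty maternal catalog")
    return(structure(list(catalog = data.table(bmor_id = character(0), class = character(0),
                                               max_tpm = numeric(0), high_expression = logical(0)),
                          fractions = data.table(class = character(0), n = integer(0),
                                                 n_high = integer(0), high_pct = numeric(0)),
                          n_omg = 0L),
                     class = "MaternalCatalog"))
  }
  omg <- sort(unique(ortholog_map$bmor_id))
  known <- omg %in% rownames(em$counts)
  max_count <- rep(0, length(omg))
  max_tpm <- rep(0, length(omg))
  max_count[known] <- apply(em$counts[omg[known], , drop = FALSE], 1, max)
  max_tpm[known] <- apply(em$tpm[omg[known], , drop = FALSE], 1, max)
  expressed <- max_count >= 1
  cls <- ifelse(omg %in% deg_union, "OMDEG",
                ifelse(expressed, "expressed_nonDEG", "unexpressed"))
  catalog <- data.table(bmor_id = omg, class = cls, max_tpm = max_tpm,
                        high_expression = max_tpm > thresholds$high_expression_tpm)
  fractions <- catalog[, .(n = .N, n_high = sum(high_expression),
                           high_pct = pct(sum(high_expression), .N)), by = class]
  setorder(fractions, class)
  structure(list(catalog = catalog, fractions = fractions, n_omg = length(omg)),
            class = "MaternalCatalog")
}

#' Genomic gene clusters around OMDEGs
#'
#' For each OMDEG, collects same-scaffold genes whose interval gap to the
#' OMDEG interval is strictly below `max_distance` (overlapping intervals have
#' gap 0); neighborhoods sharing any gene are merged transitively, so each
#' reported cluster is a connected component of the OMDEG-proximity graph.
#' Cluster membership considers all annotated genes, not only DEGs.
#'
#' @param genes data.table with `gene_id`, `scaffold_id`, `start`, `end`.
#' @param omdeg_ids character vector of OMDEG gene ids.
#' @param max_distance maximum gap in bp (default 50000, strict `<`).
#' @return data.table of class `"GeneClusterSet"`: `cluster_id`,
#'   `scaffold_id`, `gene_id`, `start`, `end`, `is_omdeg`, members sorted by
#'   start within cluster; attribute `n_clusters`.
#' @export
find_omdeg_gene_clusters <- function(genes, omdeg_ids, max_distance = 50000) {
  present <- omdeg_ids %in% genes$gene_id
  if (any(!present))
    warning(sprintf("%d OMDEG(s) without coordinates skipped", sum(!present)))
  omdeg_ids <- omdeg_ids[present]
  empty <- data.table(cluster_id = integer(0), scaffold_id = character(0),
                      gene_id = character(0), start = integer(0), end = integer(0),
                      is_omdeg = logical(0))
  if (length(omdeg_ids) == 0) {
    setattr(empty, "n_clusters", 0L)
    setattr(empty, "class", c("GeneClusterSet", class(empty)))
    return(empty[])
  }
  gr <- GenomicRanges::GRanges(genes$scaffold_id,
                               IRanges::IRanges(genes$start, genes$end),
                               gene_id = genes$gene_id)
  names(gr) <- genes$gene_id
  og <- gr[omdeg_ids]
  # gap between intervals; NA across scaffolds, 0 on overlap
  d <- GenomicRanges::distance(rep(og, each = length(gr)),
                               rep(gr, length(og)))
  near <- which(!is.na(d) & d < max_distance)
  edges <- data.table(
    omdeg = rep(omdeg_ids, each = length(gr))[near],
    gene = rep(genes$gene_id, length(og))[near]
  )
  g <- igraph::graph_from_edgelist(as.matrix(edges[, .(omdeg, gene)]), directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  out <- data.table(gene_id = names(membership), comp = membership)
  out <- unique(out)
  out <- merge(out, genes[, .(gene_id, scaffold_id, start, end)], by = "gene_id")
  out[, is_omdeg := gene_id %in% omdeg_ids]
  # stable cluster ids: by scaffold then leftmost start
  setorder(out, scaffold_id, start, gene_id)
  out[, cluster_id := as.integer(factor(comp, levels = unique(comp)))]
  out <- out[, .(cluster_id, scaffold_id, gene_id, start, end, is_omdeg)]
  setattr(out, "n_clusters", length(unique(out$cluster_id)))
  setattr(out, "class", c("GeneClusterSet", class(out)))
  out[]
}

#' GO term over-representation test
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) per GO term with
#' at least one member-set gene: with `N` background genes of which `n` carry
#' the term, and `K` member genes of which `k` carry it,
#' `p = P(X >= k)` for `X ~ Hypergeom(n, N - n, K)`. Two-sided testing is
#' available behind `two_sided`.
#'
#' @param member_genes character vector, subset of `background_genes`.
#' @param background_genes character vector of background gene ids.
#' @param go_table data.table with `gene_id`, `go_id`, `namespace`.
#' @param alpha significance level on the raw p-value (default 0.01).
#' @param two_sided use the two-sided Fisher test instead.
#' @return data.table of class `"EnrichmentResult"`: `go_id`, `namespace`,
#'   `k`, `K`, `n`, `N`, `p_value`, `significant`, sorted by p-value.
#' @export
go_enrichment <- function(member_genes, background_genes, go_table, alpha = 0.01,
                          two_sided = FALSE) {
  member_genes <- unique(member_genes)
  background_genes <- unique(background_genes)
  if (!all(member_genes %in% background_genes))
    stopf("input error: member genes must be a subset of the background")
  empty <- data.table(go_id = character(0), namespace = character(0),
                      k = integer(0), K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), significant = logical(0))
  if (length(member_genes) == 0) {
    setattr(empty, "class", c("EnrichmentResult", class(empty)))
    return(empty[])
  }
  anno <- unique(go_table[gene_id %in% background_genes, .(gene_id, go_id, namespace)])
  N <- length(background_genes)
  K <- length(member_genes)
  res <- anno[, .(
    k = sum(unique(gene_id) %in% member_genes),
    n = length(unique(gene_id)),
    namespace = namespace[1]
  ), by = go_id][k >= 1]
  if (nrow(res) == 0) {
    setattr(empty, "class", c("EnrichmentResult", class(empty)))
    return(empty[])
  }
  res[, `:=`(K = K, N = N)]
  if (two_sided) {
    res[, p_value := vapply(seq_len(.N), function(i)
      stats::fisher.test(matrix(c(k[i], K - k[i], n[i] - k[i], N - K - n[i] + k[i]),
                                nrow = 2))$p.value, numeric(1))]
  } else {
    res[, p_value := phyper(k - 1, n, N - n, K, lower.tail = FALSE)]
  }
  res[, significant := p_value <= alpha]
  setorder(res, p_value, go_id)
  out <- res[, .(go_id, namespace, k, K, n, N, p_value, significant)]
  setattr(out, "class", c("EnrichmentResult", class(out)))
  out[]
}

#' Relative expression by the 2^-ddCT method
#'
#' Replicate CT values are averaged per (sample, gene); the target's mean CT
#' is normalized to the reference gene within each sample
#' (`dCT = CT_target - CT_reference`) and to the calibrator sample
#' (`ddCT = dCT_sample - dCT_calibrator`); the relative level is `2^-ddCT`,
#' so the calibrator's own level is exactly 1.
#'
#' @param ct_table data.table with columns `sample`, `gene`, `replicate`,
#'   `ct`.
#' @param reference_gene reference (housekeeping) gene id, present in every
#'   sample.
#' @param calibrator_sample the sample whose levels define 1.
#' @return data.table: `sample`, `gene`, `dct`, `ddct`, `relative_level`
#'   (reference gene excluded).
#' @export
ddct_relative_expression <- function(ct_table, reference_gene, calibrator_sample) {
  ct <- as.data.table(ct_table)
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stopf("input error: CT values must be positive")
  mean_ct <- ct[, .(ct = mean(ct)), by = .(sample, gene)]
  ref <- mean_ct[gene == reference_gene]
  if (!all(unique(mean_ct$sample) %in% ref$sample))
    stopf("input error: reference gene '%s' missing in some sample", reference_gene)
  if (!calibrator_sample %in% mean_ct$sample)
    stopf("input error: calibrator sample '%s' not present", calibrator_sample)
  ref_ct <- setNames(ref$ct, ref$sample)
  res <- mean_ct[gene != reference_gene]
  res[, dct := ct - ref_ct[sample]]
  cal <- res[sample == calibrator_sample, setNames(dct, gene)]
  if (!all(unique(res$gene) %in% names(cal)))
    stopf("input error: calibrator sample lacks CT for some target gene")
  res[, ddct := dct - cal[gene]]
  res[, relative_level := 2^(-ddct)]
  res[, .(sample, gene, dct, ddct, relative_level)]
}
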