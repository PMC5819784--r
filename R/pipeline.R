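#' Pipeline configuration
#'
#' Collects the settings of a full end-to-end run. Either a simulation block
#' (a [reference_config()]) or a reference directory written by
#' [write_reference_bundle()] must be supplied.
#'
#' @param out_dir output directory.
#' @param seed master seed; per-sample library seeds are derived as
#'   `seed + sample index`.
#' @param simulation a `reference_config`, or `NULL` to read `reference_dir`.
#' @param reference_dir directory with a written reference bundle.
#' @param depth expected raw tags per simulated library.
#' @param error_rate per-base substitution rate of the simulator.
#' @param artifact_rates artifact rates of the simulator.
#' @param thresholds a [dge_thresholds()].
#' @param cluster_k number of profile clusters (presentation default 27; the
#'   cut is capped at the number of profiled genes).
#' @param cluster_linkage hclust linkage.
#' @param gene_cluster_max_distance genomic clustering distance in bp.
#' @param ct_table optional qPCR CT data.table (`sample`, `gene`, `replicate`,
#'   `ct`).
#' @param ct_reference_gene,ct_calibrator_sample qPCR normalization settings.
#' @param write_reference also write the reference bundle under `out_dir`.
#' @return list of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            simulation = reference_config(),
                            reference_dir = NULL,
                            depth = 1e5,
                            error_rate = 0.005,
                            artifact_rates = list(adaptor = 0.005, off_length = 0.01,
                                                  singleton_boost = 0.005, ambiguous = 0.005,
                                                  genomic = 0.15, foreign = 0.03),
                            thresholds = dge_thresholds(),
                            cluster_k = 27,
                            cluster_linkage = "average",
                            gene_cluster_max_distance = 50000,
                            ct_table = NULL,
                            ct_reference_gene = NULL,
                            ct_calibrator_sample = NULL,
                            write_reference = FALSE) {
  if (is.null(simulation) && is.null(reference_dir))
    stopf("configuration error: need a simulation block or a reference_dir")
  if (!is.null(reference_dir) && !dir.exists(reference_dir))
    stopf("configuration error: reference_dir does not exist")
  stopifnot(inherits(thresholds, "DGEThresholds"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation, reference_dir = reference_dir,
                 depth = depth, error_rate = error_rate, artifact_rates = artifact_rates,
                 thresholds = thresholds, cluster_k = cluster_k,
                 cluster_linkage = cluster_linkage,
                 gene_cluster_max_distance = gene_cluster_max_distance,
                 ct_table = ct_table, ct_reference_gene = ct_reference_gene,
                 ct_calibrator_sample = ct_calibrator_sample,
                 write_reference = isTRUE(write_reference)),
            class = "PipelineConfig")
}

stage <- function(name, expr, verbose = TRUE) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full tag-DGE pipeline
#'
#' Simulate (or load) the reference, build the virtual tag library, simulate,
#' clean and map the five libraries, summarize them, run both DGE strategies,
#' build and cluster profiles, classify maternal orthologs, detect genomic
#' gene clusters, run GO enrichment per major cluster, and (optionally)
#' summarize a qPCR CT table. Every stage writes its TSV under
#' `config$out_dir`; a `manifest.json` records the config hash, seed and the
#' row count of every output, and the row counts are re-checked against the
#' files on disk before returning.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage timings.
#' @return invisible list with the main in-memory objects (`bundle`, `index`,
#'   `summaries`, `em`, `strategy_I`, `strategy_II`, `profiles`, `assignment`,
#'   `cluster_summary`, `maternal`, `gene_clusters`, `enrichment`, `qpcr`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  emit <- function(dt, name) {
    path <- file.path(out, name)
    fwrite(as.data.table(dt), path, sep = "\t")
    written[[name]] <<- nrow(as.data.table(dt))
    path
  }

  bundle <- stage("reference", {
    if (!is.null(config$simulation)) generate_reference(config$simulation, seed = config$seed)
    else read_reference_bundle(config$reference_dir)
  }, verbose)
  if (config$write_reference) write_reference_bundle(bundle, file.path(out, "reference"))
  samples <- names(bundle$time_points)

  index <- stage("virtual_tags", {
    vts <- extract_virtual_tags(bundle$genes)
    parts <- partition_ambiguity(vts)
    write_virtual_tags(vts, file.path(out, "virtual_tags.tsv"))
    # the stage expression evaluates in this frame, so plain assignment
    written[["virtual_tags.tsv"]] <- length(unique(vts$sequence))
    build_tag_index(parts$unambiguous, parts$ambiguous)
  }, verbose)

  genome <- stage("genome_index", build_genome_index(bundle$scaffolds), verbose)

  libs <- stage("simulate", {
    lapply(seq_along(samples), function(i)
      simulate_raw_library(bundle, samples[i], depth = config$depth,
                           error_rate = config$error_rate,
                           artifact_rates = config$artifact_rates,
                           seed = config$seed + i))
  }, verbose)
  names(libs) <- samples

  cleans <- stage("clean", lapply(libs, clean_raw_tags), verbose)
  mappings <- stage("map", lapply(cleans, map_clean_tags, index = index, genome = genome),
                    verbose)

  summaries <- stage("summarize", {
    s <- lapply(samples, function(sm)
      summarize_library(libs[[sm]], cleans[[sm]], mappings[[sm]],
                        n_reference_genes = nrow(bundle$genes)))
    emit(summary_table(s), "library_summary.tsv")
    s
  }, verbose)

  em <- stage("expression_matrix", {
    clean_totals <- vapply(cleans, function(cl) cl$total, numeric(1))
    build_expression_matrix(mappings, clean_totals, gene_ids = sort(bundle$genes$gene_id))
  }, verbose)

  strategy_I <- stage("dge_strategy_I", {
    res <- run_strategy(em, "I", time_order = samples, thresholds = config$thresholds)
    for (nm in names(res)) emit(res[[nm]], paste0("dge_I_", nm, ".tsv"))
    emit(overlap_counts(lapply(res, deg_genes)), "venn_strategy_I.tsv")
    res
  }, verbose)
  strategy_II <- stage("dge_strategy_II", {
    res <- run_strategy(em, "II", time_order = samples, thresholds = config$thresholds)
    for (nm in names(res)) emit(res[[nm]], paste0("dge_II_", nm, ".tsv"))
    emit(overlap_counts(lapply(res, deg_genes)), "venn_strategy_II.tsv")
    res
  }, verbose)

  profiles <- stage("profiles", build_profiles(strategy_I), verbose)
  assignment <- NULL
  cluster_summary <- NULL
  if (nrow(profiles) >= 2) {
    assignment <- stage("cluster", {
      k <- min(config$cluster_k, nrow(profiles))
      a <- hcluster(pearson_distance_matrix(profiles), k = k,
                    linkage = config$cluster_linkage)
      emit(merge(a, profiles, by = "gene_id"), "clusters.tsv")
      a
    }, verbose)
    cluster_summary <- stage("cluster_summary", {
      cs <- cluster_summaries(assignment, profiles)
      emit(cs$summary, "cluster_summary.tsv")
      cs
    }, verbose)
  }

  maternal <- stage("maternal", {
    mc <- classify_maternal_genes(bundle$ortholog_table, em, deg_union = profiles$gene_id,
                                  thresholds = config$thresholds)
    emit(mc$catalog, "maternal_catalog.tsv")
    emit(mc$fractions, "maternal_fractions.tsv")
    mc
  }, verbose)

  gene_clusters <- stage("gene_clusters", {
    omdegs <- maternal$catalog[class == "OMDEG", bmor_id]
    gc <- find_omdeg_gene_clusters(bundle$genes, omdegs,
                                   max_distance = config$gene_cluster_max_distance)
    emit(gc, "gene_clusters.tsv")
    gc
  }, verbose)

  enrichment <- stage("enrichment", {
    background <- unique(bundle$go_table$gene_id)  # genes with >= 1 GO annotation
    degs_annotated <- intersect(profiles$gene_id, background)
    er <- go_enrichment(degs_annotated, background, bundle$go_table,
                        alpha = config$thresholds$fdr_max)
    emit(er, "enrichment_degs.tsv")
    er
  }, verbose)

  qpcr <- NULL
  if (!is.null(config$ct_table)) {
    qpcr <- stage("qpcr", {
      q <- ddct_relative_expression(config$ct_table, config$ct_reference_gene,
                                    config$ct_calibrator_sample)
      emit(q, "qpcr_relative.tsv")
      q
    }, verbose)
  }

  manifest <- stage("manifest", {
    cfg_for_hash <- config
    cfg_for_hash$ct_table <- NULL
    man <- list(config_hash = rlang::hash(cfg_for_hash),
                seed = config$seed,
                n_genes = nrow(bundle$genes),
                samples = samples,
                outputs = written)
    jsonlite::write_json(man, file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
    # self-consistency: recorded row counts must equal the files on disk
    for (nm in setdiff(names(written), "virtual_tags.tsv")) {
      n_disk <- nrow(fread(file.path(out, nm)))
      if (n_disk != written[[nm]])
        stopf("manifest row count mismatch for %s (%d vs %d)", nm, written[[nm]], n_disk)
    }
    man
  }, verbose)

  invisible(list(bundle = bundle, index = index, libs = libs, cleans = cleans,
                 mappings = mappings, summaries = summaries, em = em,
                 strategy_I = strategy_I, strategy_II = strategy_II,
                 profiles = profiles, assignment = assignment,
                 cluster_summary = cluster_summary, maternal = maternal,
                 gene_clusters = gene_clusters, enrichment = enrichment,
                 qpcr = qpcr, manifest = manifest))
}
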