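#' Archetype labels for planted expression profiles
#'
#' The five planted time-course shapes: a sustained monotone decrease, a flat
#' profile with a sharp drop at the final time point, a monotone increase, a
#' pulse peaking at the penultimate time point (18 h on the default grid), and
#' a flat null profile.
#' @export
ARCHETYPES <- c("down_monotone", "flat_then_drop", "up_monotone", "pulse_18h", "flat_null")

DEFAULT_TIME_POINTS <- c("0h" = 0, "6h" = 6, "12h" = 12, "18h" = 18, "24h" = 24)

# 3' adaptor ligated downstream of the tag during library construction
DEFAULT_ADAPTOR <- "TCGTATGCCGTCTTCTGCTTG"

#' Generator configuration
#'
#' Assembles and validates the settings of the synthetic reference generator.
#' Defaults describe a desk-scale silkworm-like world: a few hundred genes on a
#' handful of scaffolds, transcripts of 300-1500 bp, a 10% maternal-ortholog
#' subset, and a mixture of planted expression archetypes in which most genes
#' are flat nulls.
#'
#' @param n_scaffolds number of genomic scaffolds.
#' @param n_genes number of genes (> 0).
#' @param transcript_length length range (min, max) in bp; min must allow a
#'   CATG+17 site (>= 25) when `guarantee_catg` is on.
#' @param maternal_fraction fraction of genes flagged as maternal orthologs;
#'   applied by exact count `round(fraction * n_genes)`.
#' @param n_go_terms size of the GO vocabulary.
#' @param go_annotation_prob probability that a gene carries any GO annotation.
#' @param intergenic_mean mean of the short intergenic gaps in bp
#'   (exponential).
#' @param desert_prob probability that a gap is a long gene desert instead;
#'   deserts break the 50-kb proximity chains that an evenly dense
#'   desk-scale genome would otherwise form, giving the genome a realistic
#'   island structure.
#' @param desert_range length range (bp) of a gene desert.
#' @param guarantee_catg if TRUE every transcript is guaranteed at least one
#'   CATG with >= 17 downstream bases (a site is planted when absent).
#' @param paralog_fraction fraction of genes (exact count) that receive a
#'   copied CATG+17 segment from another gene, so the reference carries
#'   multi-gene (ambiguous) tags the way paralogous families do in real
#'   annotations; i.i.d. random transcripts would otherwise essentially never
#'   share a 21-mer.
#' @param time_points named numeric vector of sampling times (hours).
#' @param archetype_mix named proportions over [ARCHETYPES], summing to 1.
#' @param maternal_archetype archetype forced onto maternal genes (maternal
#'   transcripts are deposited and degrade, so the default is
#'   `"down_monotone"`); `NULL` leaves them under `archetype_mix`.
#' @param base_abundance_meanlog,base_abundance_sdlog log-normal parameters of
#'   per-gene baseline abundance (expected tags at 0 h, arbitrary units).
#' @param adaptor_seq 3' adaptor sequence used for adaptor artifacts.
#' @return a list of settings with class `"reference_config"`.
#' @export
reference_config <- function(n_scaffolds = 6,
                             n_genes = 500,
                             transcript_length = c(300, 1500),
                             maternal_fraction = 0.1,
                             n_go_terms = 40,
                             go_annotation_prob = 0.55,
                             intergenic_mean = 1500,
                             desert_prob = 0.15,
                             desert_range = c(55000, 90000),
                             guarantee_catg = TRUE,
                             paralog_fraction = 0.04,
                             time_points = DEFAULT_TIME_POINTS,
                             archetype_mix = c(down_monotone = 0.08,
                                               flat_then_drop = 0.05,
                                               up_monotone = 0.04,
                                               pulse_18h = 0.03,
                                               flat_null = 0.80),
                             maternal_archetype = "down_monotone",
                             base_abundance_meanlog = log(50),
                             base_abundance_sdlog = 1.2,
                             adaptor_seq = DEFAULT_ADAPTOR) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes <= 0)
    stopf("configuration error: n_genes must be positive")
  if (n_scaffolds <= 0) stopf("configuration error: n_scaffolds must be positive")
  if (length(transcript_length) != 2 || transcript_length[1] > transcript_length[2])
    stopf("configuration error: transcript_length range is inverted")
  if (guarantee_catg && transcript_length[1] < 25)
    stopf("configuration error: transcripts shorter than 25 bp cannot carry a CATG+17 site")
  if (maternal_fraction < 0 || maternal_fraction > 1)
    stopf("configuration error: maternal_fraction must be in [0, 1]")
  if (abs(sum(archetype_mix) - 1) > 1e-9)
    stopf("configuration error: archetype_mix proportions must sum to 1")
  if (!all(names(archetype_mix) %in% ARCHETYPES))
    stopf("configuration error: unknown archetype in archetype_mix")
  if (!is.null(maternal_archetype) && !maternal_archetype %in% ARCHETYPES)
    stopf("configuration error: unknown maternal_archetype")
  if (is.null(names(time_points)) || length(time_points) < 2)
    stopf("configuration error: time_points must be a named vector of >= 2 times")
  structure(
    list(n_scaffolds = as.integer(n_scaffolds),
         n_genes = as.integer(n_genes),
         transcript_length = as.integer(transcript_length),
         maternal_fraction = maternal_fraction,
         n_go_terms = as.integer(n_go_terms),
         go_annotation_prob = go_annotation_prob,
         intergenic_mean = intergenic_mean,
         desert_prob = desert_prob,
         desert_range = desert_range,
         guarantee_catg = isTRUE(guarantee_catg),
         paralog_fraction = paralog_fraction,
         time_points = time_points,
         archetype_mix = archetype_mix,
         maternal_archetype = maternal_archetype,
         base_abundance_meanlog = base_abundance_meanlog,
         base_abundance_sdlog = base_abundance_sdlog,
         adaptor_seq = adaptor_seq),
    class = "reference_config"
  )
}

# canonical fold-change vector of an archetype over m time points
archetype_fold_changes <- function(archetype, m) {
  switch(archetype,
    down_monotone  = 2^(-(seq_len(m) - 1)),
    flat_then_drop = c(rep(1, m - 1), 1 / 8),
    up_monotone    = 2^(seq_len(m) - 1),
    pulse_18h      = { v <- rep(1, m); v[m - 1] <- 4; v },
    flat_null      = rep(1, m),
    stopf("unknown archetype '%s'", archetype)
  )
}

#' Assign planted expression archetypes to genes
#'
#' Each gene receives exactly one archetype; archetype counts follow the
#' requested proportions by exact largest-remainder apportionment (not per-gene
#' Bernoulli draws), so tallies are deterministic. Fold-change vectors are the
#' canonical archetype shapes; baseline abundances are log-normal.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param archetype_mix named proportions over [ARCHETYPES] summing to 1.
#' @param seed integer seed.
#' @param time_points named numeric vector of sampling times.
#' @param base_abundance_meanlog,base_abundance_sdlog log-normal parameters.
#' @return a `data.table` (class `"ProfileAssignment"`) with columns `gene_id`,
#'   `archetype`, `base_abundance` and one `fc_<sample>` column per time point.
#' @export
assign_profiles <- function(gene_ids, archetype_mix, seed = 1,
                            time_points = DEFAULT_TIME_POINTS,
                            base_abundance_meanlog = log(50),
                            base_abundance_sdlog = 1.2) {
  if (abs(sum(archetype_mix) - 1) > 1e-9)
    stopf("configuration error: archetype proportions must sum to 1")
  if (!all(names(archetype_mix) %in% ARCHETYPES))
    stopf("configuration error: unknown archetype name")
  n <- length(gene_ids)
  m <- length(time_points)
  withr::with_seed(seed, {
    # exact apportionment: floor counts, then largest remainders
    target <- archetype_mix * n
    counts <- floor(target)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    labels <- sample(rep(names(archetype_mix), times = counts))
    base <- rlnorm(n, base_abundance_meanlog, base_abundance_sdlog)
    fc <- t(vapply(labels, archetype_fold_changes, numeric(m), m = m))
    out <- data.table(gene_id = gene_ids, archetype = labels, base_abundance = base)
    for (j in seq_len(m)) out[, paste0("fc_", names(time_points)[j]) := fc[, j]]
    setattr(out, "time_points", time_points)
    setattr(out, "class", c("ProfileAssignment", class(out)))
    out[]
  })
}

#' Generate a synthetic reference bundle
#'
#' Builds a multi-scaffold genome whose genes carry CATG-bearing transcripts,
#' together with an ortholog table (maternal subset, applied by exact count), a
#' GO annotation table, and a planted expression truth. Gene sequences are
#' embedded verbatim (reverse-complemented on the minus strand) in their
#' scaffolds, separated by random intergenic spacers, so tags can also be
#' traced to the genome.
#'
#' @param config a [reference_config()].
#' @param seed integer seed; output is byte-identical for fixed (config, seed).
#' @return a list of class `"ReferenceBundle"` with elements `scaffolds`
#'   (data.table: scaffold_id, length, seq), `genes` (data.table: gene_id,
#'   scaffold_id, start, end, strand, transcript_seq), `ortholog_table`
#'   (dmel_id, bmor_id), `go_table` (gene_id, go_id, namespace), `truth`
#'   (a `ProfileAssignment`), `time_points`, and `config`.
#' @export
generate_reference <- function(config = reference_config(), seed = 1) {
  stopifnot(inherits(config, "reference_config"))
  withr::with_seed(seed, {
    n <- config$n_genes
    gene_ids <- sprintf("SYNBM%06d", seq_len(n))
    lens <- sample(seq(config$transcript_length[1], config$transcript_length[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    if (config$guarantee_catg) {
      for (i in seq_len(n)) {
        if (!has_catg_site(seqs[i])) {
          p <- sample.int(lens[i] - 24L, 1)
          substr(seqs[i], p, p + 3L) <- "CATG"
        }
      }
    }
    # paralogy: copy a CATG+17 segment between genes so some tags are shared
    n_par <- round((config$paralog_fraction %||% 0) * n)
    if (n_par > 0 && n >= 2) {
      targets <- sample.int(n, n_par)
      for (i in targets) {
        donor <- sample(setdiff(seq_len(n), i), 1)
        dpos <- gregexpr("CATG", seqs[donor], fixed = TRUE)[[1]]
        dpos <- dpos[dpos > 0 & dpos + 20L <= lens[donor]]
        if (length(dpos) == 0) next
        segment <- substr(seqs[donor], dpos[1], dpos[1] + 20L)
        p <- sample.int(lens[i] - 20L, 1)
        substr(seqs[i], p, p + 20L) <- segment
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    scaf_of <- sort(sample.int(config$n_scaffolds, n, replace = TRUE))

    genes <- data.table(gene_id = gene_ids, scaffold_id = sprintf("scaffold%02d", scaf_of),
                        start = 0L, end = 0L, strand = strand, transcript_seq = seqs)
    scaffolds <- data.table(scaffold_id = sprintf("scaffold%02d", seq_len(config$n_scaffolds)),
                            length = 0L, seq = "")
    for (s in seq_len(config$n_scaffolds)) {
      sid <- sprintf("scaffold%02d", s)
      idx <- which(genes$scaffold_id == sid)
      pieces <- list()
      cursor <- 0L
      for (i in idx) {
        gap <- if (runif(1) < config$desert_prob) {
          as.integer(round(runif(1, config$desert_range[1], config$desert_range[2])))
        } else {
          max(50L, as.integer(round(rexp(1, 1 / config$intergenic_mean))))
        }
        pieces[[length(pieces) + 1L]] <- paste(
          sample(c("A", "C", "G", "T"), gap, replace = TRUE), collapse = "")
        cursor <- cursor + gap
        gseq <- if (genes$strand[i] == "+") genes$transcript_seq[i] else revcomp(genes$transcript_seq[i])
        genes[i, `:=`(start = cursor + 1L, end = cursor + nchar(gseq))]
        pieces[[length(pieces) + 1L]] <- gseq
        cursor <- cursor + nchar(gseq)
      }
      tail_gap <- max(50L, as.integer(round(rexp(1, 1 / config$intergenic_mean))))
      pieces[[length(pieces) + 1L]] <- paste(
        sample(c("A", "C", "G", "T"), tail_gap, replace = TRUE), collapse = "")
      full <- paste(unlist(pieces), collapse = "")
      scaffolds[s, `:=`(length = nchar(full), seq = full)]
    }

    # maternal ortholog table: exact count, many-to-many allowed on the dmel side
    n_mat <- round(config$maternal_fraction * n)
    maternal <- sort(sample(gene_ids, n_mat))
    ortholog_table <- if (n_mat > 0) {
      n_dmel <- max(1L, as.integer(round(n_mat * 0.67)))
      dmel_pool <- sprintf("FBgn%07d", seq_len(n_dmel))
      unique(data.table(dmel_id = sample(dmel_pool, n_mat, replace = TRUE),
                        bmor_id = maternal))
    } else data.table(dmel_id = character(0), bmor_id = character(0))

    # GO vocabulary with fixed term -> namespace mapping
    vocab <- data.table(
      go_id = sprintf("GO:%07d", seq_len(config$n_go_terms)),
      namespace = sample(c("molecular_function", "biological_process", "cellular_component"),
                         config$n_go_terms, replace = TRUE)
    )
    annotated <- gene_ids[runif(n) < config$go_annotation_prob]
    go_table <- if (length(annotated) > 0) {
      rbindlist(lapply(annotated, function(g) {
        k <- sample(1:4, 1)
        vocab[sample(.N, min(k, .N))][, .(gene_id = g, go_id, namespace)]
      }))
    } else data.table(gene_id = character(0), go_id = character(0), namespace = character(0))

    truth <- assign_profiles(gene_ids, config$archetype_mix, seed = seed + 1L,
                             time_points = config$time_points,
                             base_abundance_meanlog = config$base_abundance_meanlog,
                             base_abundance_sdlog = config$base_abundance_sdlog)
    if (!is.null(config$maternal_archetype) && n_mat > 0) {
      m <- length(config$time_points)
      fc <- archetype_fold_changes(config$maternal_archetype, m)
      truth[gene_id %in% maternal, archetype := config$maternal_archetype]
      for (j in seq_len(m))
        truth[gene_id %in% maternal, paste0("fc_", names(config$time_points)[j]) := fc[j]]
    }

    bundle <- structure(
      list(scaffolds = scaffolds[, .(scaffold_id, length, seq)],
           genes = genes,
           ortholog_table = ortholog_table,
           go_table = go_table,
           truth = truth,
           time_points = config$time_points,
           config = config),
      class = "ReferenceBundle"
    )
    validate_bundle(bundle)
    bundle
  })
}

has_catg_site <- function(seq) {
  pos <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  any(pos > 0 & pos + 20L <= nchar(seq))
}

validate_bundle <- function(bundle) {
  g <- bundle$genes
  if (anyDuplicated(g$gene_id)) stopf("bundle invariant violated: duplicate gene ids")
  sl <- setNames(bundle$scaffolds$length, bundle$scaffolds$scaffold_id)
  if (any(g$start < 1 | g$end > sl[g$scaffold_id]))
    stopf("bundle invariant violated: gene interval outside scaffold")
  if (any(g$start > g$end)) stopf("bundle invariant violated: start > end")
  if (!all(bundle$ortholog_table$bmor_id %in% g$gene_id))
    stopf("bundle invariant violated: ortholog table references unknown gene")
  if (!all(bundle$go_table$gene_id %in% g$gene_id))
    stopf("bundle invariant violated: GO table references unknown gene")
  invisible(bundle)
}

#' Simulate one raw tag library
#'
#' Draws 21-bp CATG+17 tags for one time point. Per-gene tag counts are Poisson
#' with mean `depth` times the gene's relative planted abundance at that time
#' point (negative-binomial overdispersion behind `overdispersion`). Within a
#' gene, a `prop_3prime` fraction of tags comes from the 3'-most CATG site and
#' the rest is spread uniformly over the other sites. Per-base substitution
#' errors are applied at `error_rate`, and adaptor-containing, off-length,
#' ambiguous-base (N) and spurious singleton tags are injected at the given
#' artifact rates (expected artifact tags per true tag drawn).
#'
#' Two background channels emulate the tag populations real libraries carry
#' beyond the annotated transcriptome: `genomic` emits CATG+17 tags from
#' scaffold positions outside the annotation (unannotated transcription;
#' these map to the genome but not to genes) and `foreign` emits unassignable
#' tags with copy number >= 2 that survive cleaning but match neither the tag
#' library nor the genome.
#'
#' Genes whose transcript lacks a usable CATG site emit nothing.
#'
#' @param bundle a `ReferenceBundle`.
#' @param sample_id one of the bundle's time-point labels.
#' @param depth expected total number of true tags (> 0).
#' @param error_rate per-base substitution probability in [0, 1).
#' @param artifact_rates list with elements `adaptor`, `off_length`,
#'   `singleton_boost`, `ambiguous`, `genomic`, `foreign` (each an expected
#'   fraction of `depth`).
#' @param seed integer seed.
#' @param prop_3prime fraction of a gene's tags drawn from its 3'-most site.
#' @param overdispersion NULL for Poisson counts, or a positive dispersion
#'   parameter for negative-binomial counts (variance mu + od * mu^2).
#' @return a list of class `"RawTagLibrary"`: `sample_id`, `tags` (data.table
#'   sequence/count), `adaptor_seq`; attribute `true_gene_counts` holds the
#'   per-gene emitted tag counts before errors and artifacts.
#' @export
simulate_raw_library <- function(bundle, sample_id, depth = 1e5,
                                 error_rate = 0.005,
                                 artifact_rates = list(adaptor = 0.005, off_length = 0.01,
                                                       singleton_boost = 0.005, ambiguous = 0.005,
                                                       genomic = 0.15, foreign = 0.03),
                                 seed = 1, prop_3prime = 0.9, overdispersion = NULL) {
  stopifnot(inherits(bundle, "ReferenceBundle"))
  if (!sample_id %in% names(bundle$time_points))
    stopf("input error: sample_id '%s' is not on the bundle's time grid", sample_id)
  if (depth <= 0) stopf("depth must be positive")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  ar <- list(adaptor = 0, off_length = 0, singleton_boost = 0, ambiguous = 0,
             genomic = 0, foreign = 0)
  ar[names(artifact_rates)] <- artifact_rates

  sites <- catg_sites(bundle$genes)
  fc_col <- paste0("fc_", sample_id)
  truth <- bundle$truth
  expected <- truth$base_abundance * truth[[fc_col]]
  names(expected) <- truth$gene_id
  # only CATG-bearing genes can emit
  emitting <- intersect(truth$gene_id, unique(sites$gene_id))
  rel <- expected[emitting] / sum(expected[emitting])

  withr::with_seed(seed, {
    mu <- depth * rel
    counts <- if (is.null(overdispersion)) {
      rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / overdispersion)
    }
    names(counts) <- emitting
    true_gene_counts <- counts

    # distribute each gene's count over its sites (3'-most biased)
    pieces <- vector("list", length(emitting))
    for (i in seq_along(emitting)) {
      cnt <- counts[i]
      if (cnt == 0) next
      gs <- sites[gene_id == emitting[i]]
      main <- gs[is_3prime_most == TRUE]
      others <- gs[is_3prime_most == FALSE]
      if (nrow(others) == 0) {
        pieces[[i]] <- data.table(sequence = main$sequence, count = cnt)
      } else {
        n3 <- rbinom(1, cnt, prop_3prime)
        spread <- if (cnt - n3 > 0)
          as.vector(stats::rmultinom(1, cnt - n3, rep(1, nrow(others)))) else
          rep(0L, nrow(others))
        pieces[[i]] <- data.table(sequence = c(main$sequence, others$sequence),
                                  count = c(n3, spread))[count > 0]
      }
    }
    emitted <- rbindlist(pieces)
    if (nrow(emitted) == 0) emitted <- data.table(sequence = character(0), count = integer(0))
    emitted <- emitted[, .(count = sum(count)), by = sequence]

    # per-base substitution errors
    if (error_rate > 0 && nrow(emitted) > 0) {
      p_any <- 1 - (1 - error_rate)^21
      n_err <- rbinom(nrow(emitted), emitted$count, p_any)
      err_seqs <- rep(emitted$sequence, n_err)
      emitted[, count := count - n_err]
      emitted <- emitted[count > 0]
      if (length(err_seqs) > 0) {
        mutated <- mutate_tags(err_seqs, error_rate)
        emitted <- rbindlist(list(emitted, data.table(sequence = mutated, count = 1L)))
      }
    }

    # artifacts
    art <- list()
    n_ad <- rpois(1, depth * ar$adaptor)
    if (n_ad > 0) {
      frag_len <- sample(8:16, n_ad, replace = TRUE)
      base_seq <- sample(sites$sequence, n_ad, replace = TRUE)
      art$adaptor <- data.table(
        sequence = paste0(substr(base_seq, 1, frag_len), bundle$config$adaptor_seq),
        count = sample(1:5, n_ad, replace = TRUE))
    }
    n_off <- rpois(1, depth * ar$off_length)
    if (n_off > 0) {
      L <- sample(c(19L, 20L, 22L, 23L), n_off, replace = TRUE)
      art$off_length <- data.table(
        sequence = paste0("CATG", vapply(L - 4L, function(k)
          paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""), character(1))),
        count = sample(1:5, n_off, replace = TRUE))
    }
    n_amb <- rpois(1, depth * ar$ambiguous)
    if (n_amb > 0) {
      s <- sample(sites$sequence, n_amb, replace = TRUE)
      p <- sample.int(21, n_amb, replace = TRUE)
      for (i in seq_len(n_amb)) substr(s[i], p[i], p[i]) <- "N"
      art$ambiguous <- data.table(sequence = s, count = sample(1:5, n_amb, replace = TRUE))
    }
    n_single <- rpois(1, depth * ar$singleton_boost)
    if (n_single > 0) {
      art$singleton <- data.table(
        sequence = paste0("CATG", random_dna(n_single, 17)), count = 1L)
    }
    n_genomic <- rpois(1, depth * ar$genomic)
    if (n_genomic > 0) {
      gsites <- intergenic_catg_sites(bundle)
      if (length(gsites) > 0) {
        n_sites <- max(1L, min(length(gsites), as.integer(round(n_genomic / 8))))
        chosen <- sample(gsites, n_sites)
        cnt <- as.vector(stats::rmultinom(1, n_genomic, rexp(n_sites)))
        art$genomic <- data.table(sequence = chosen, count = cnt)[count > 0]
      }
    }
    n_foreign <- rpois(1, depth * ar$foreign)
    if (n_foreign > 0) {
      n_seqs <- max(1L, as.integer(round(n_foreign / 5)))
      cnt <- as.vector(stats::rmultinom(1, n_foreign, rep(1, n_seqs)))
      art$foreign <- data.table(sequence = paste0("CATG", random_dna(n_seqs, 17)),
                                count = cnt)[count > 0]
    }

    tags <- rbindlist(c(list(emitted), art))
    tags <- tags[, .(count = sum(count)), by = sequence]
    setorder(tags, sequence)
    lib <- structure(list(sample_id = sample_id, tags = tags,
                          adaptor_seq = bundle$config$adaptor_seq),
                     class = "RawTagLibrary")
    attr(lib, "true_gene_counts") <- true_gene_counts
    lib
  })
}

# CATG+17 21-mers of the scaffolds whose window lies entirely outside every
# annotated gene interval (the template of the unannotated-transcription channel)
intergenic_catg_sites <- function(bundle) {
  out <- lapply(seq_len(nrow(bundle$scaffolds)), function(i) {
    s <- bundle$scaffolds$seq[i]
    sid <- bundle$scaffolds$scaffold_id[i]
    pos <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    pos <- pos[pos > 0 & pos + 20L <= nchar(s)]
    if (length(pos) == 0) return(character(0))
    g <- bundle$genes[scaffold_id == sid]
    if (nrow(g) > 0) {
      in_gene <- vapply(pos, function(p) any(p <= g$end & (p + 20L) >= g$start), logical(1))
      pos <- pos[!in_gene]
    }
    substring(s, pos, pos + 20L)
  })
  unlist(out)
}

# apply >=1 substitution to each sequence, per-base rate `rate` conditioned on >=1
mutate_tags <- function(seqs, rate) {
  n <- length(seqs)
  w <- 21L
  pk <- stats::dbinom(1:w, w, rate)
  k <- sample.int(w, n, replace = TRUE, prob = pk / sum(pk))
  bases <- c("A", "C", "G", "T")
  one <- which(k == 1L)
  if (length(one) > 0) {
    pos <- sample.int(w, length(one), replace = TRUE)
    cur <- substr(seqs[one], pos, pos)
    shift <- sample.int(3, length(one), replace = TRUE)
    newb <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
    for (i in seq_along(one)) substr(seqs[one[i]], pos[i], pos[i]) <- newb[i]
  }
  multi <- which(k > 1L)
  for (i in multi) {
    pos <- sample.int(w, k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  seqs
}
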