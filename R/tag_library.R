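#' Enumerate CATG+17 sites of a gene set
#'
#' Scans each transcript (sense strand) for CATG occurrences with at least 17
#' downstream bases; each such occurrence is one 21-bp tag site. The site whose
#' CATG lies closest to the transcript 3' end is flagged `is_3prime_most` —
#' that is the site the MmeI chemistry captures.
#'
#' @param genes data.table of `GeneRecord`s (needs `gene_id`, `transcript_seq`).
#' @return data.table with columns `gene_id`, `pos` (1-based CATG position),
#'   `sequence` (21-mer starting with CATG), `is_3prime_most`.
#' @export
catg_sites <- function(genes) {
  if (nrow(genes) == 0) {
    return(data.table(gene_id = character(0), pos = integer(0),
                      sequence = character(0), is_3prime_most = logical(0)))
  }
  if (any(grepl("[^ACGT]", genes$transcript_seq)))
    stopf("input error: transcript sequences must be over {A,C,G,T}")
  hits <- gregexpr("CATG", genes$transcript_seq, fixed = TRUE)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    pos <- hits[[i]]
    pos <- pos[pos > 0 & pos + 20L <= nchar(genes$transcript_seq[i])]
    if (length(pos) == 0) next
    out[[i]] <- data.table(
      gene_id = genes$gene_id[i],
      pos = as.integer(pos),
      sequence = substring(genes$transcript_seq[i], pos, pos + 20L),
      is_3prime_most = pos == max(pos)
    )
  }
  res <- rbindlist(out)
  if (nrow(res) == 0) {
    return(data.table(gene_id = character(0), pos = integer(0),
                      sequence = character(0), is_3prime_most = logical(0)))
  }
  res
}

#' Build the virtual reference tag set
#'
#' One row per distinct (sequence, gene) pair. A sequence occurring at several
#' sites of one gene collapses to one row (flagged 3'-most if any of its sites
#' is); a sequence shared by several genes keeps one row per gene, which is
#' what the ambiguity partition operates on.
#'
#' @param genes data.table of gene records with `gene_id`, `transcript_seq`.
#' @return data.table of class `"VirtualTagSet"` with columns `sequence`,
#'   `gene_id`, `is_3prime_most`; attribute `n_genes_with_sites`.
#' @export
extract_virtual_tags <- function(genes) {
  sites <- catg_sites(genes)
  tags <- sites[, .(is_3prime_most = any(is_3prime_most)), by = .(sequence, gene_id)]
  setkey(tags, sequence, gene_id)
  setattr(tags, "n_genes_with_sites", length(unique(sites$gene_id)))
  setattr(tags, "class", c("VirtualTagSet", class(tags)))
  tags[]
}

#' Partition a virtual tag set by reference-level ambiguity
#'
#' A tag sequence present in two or more genes cannot attribute counts and is
#' set aside before indexing; the rest is the unambiguous reference library.
#'
#' @param tagset a `VirtualTagSet`.
#' @return list with elements `unambiguous` and `ambiguous`, both
#'   `VirtualTagSet`s partitioning the input rows.
#' @export
partition_ambiguity <- function(tagset) {
  ng <- tagset[, .(n_genes = length(unique(gene_id))), by = sequence]
  amb_seqs <- ng[n_genes >= 2, sequence]
  amb <- tagset[sequence %in% amb_seqs]
  una <- tagset[!sequence %in% amb_seqs]
  for (x in list(una, amb)) {
    setattr(x, "class", unique(c("VirtualTagSet", class(x))))
  }
  list(unambiguous = una, ambiguous = amb)
}

#' Build a mismatch-tolerant tag index
#'
#' Exact lookup table over the unambiguous reference tags, with 1-mismatch
#' queries answered by enumerating the 63 single-substitution variants of the
#' query. The reference-level ambiguous tag set may be attached so queries
#' landing on (or next to) a multi-gene tag are reported as `multi`.
#'
#' @param unambiguous `VirtualTagSet` of single-gene tags.
#' @param ambiguous optional `VirtualTagSet` of multi-gene tags.
#' @return object of class `"TagIndex"`.
#' @export
build_tag_index <- function(unambiguous, ambiguous = NULL) {
  una <- unambiguous[, .(genes = paste(sort(unique(gene_id)), collapse = ","),
                         n_genes = length(unique(gene_id))), by = sequence]
  if (any(una$n_genes > 1))
    stopf("input error: unambiguous tag set contains multi-gene sequences")
  amb <- if (!is.null(ambiguous) && nrow(ambiguous) > 0) {
    ambiguous[, .(genes = paste(sort(unique(gene_id)), collapse = ",")), by = sequence]
  } else data.table(sequence = character(0), genes = character(0))
  ref <- rbindlist(list(
    una[, .(sequence, genes, ambiguous = FALSE)],
    amb[, .(sequence, genes, ambiguous = TRUE)]
  ))
  setkey(ref, sequence)
  structure(list(ref = ref, tag_length = 21L), class = "TagIndex")
}

#' Query a tag index
#'
#' For each 21-bp query, finds all reference tags within Hamming distance 1,
#' with exact (distance-0) hits taking precedence over distance-1 hits. The
#' hit gene set is the union of gene sets over reference tags at the best
#' distance; status is `unique` when that union is a single gene and no
#' ambiguous reference tag is hit, `multi` when several genes are implicated
#' (directly or through an ambiguous tag), and `none` otherwise.
#'
#' @param index a `TagIndex`.
#' @param seqs character vector of query sequences (each 21 bp).
#' @return data.table with columns `sequence`, `status`
#'   (`unique`/`multi`/`none`), `n_mismatches_best` (0, 1 or NA), `genes_hit`
#'   (comma-separated, empty for `none`).
#' @export
query_tag_index <- function(index, seqs) {
  stopifnot(inherits(index, "TagIndex"))
  if (length(seqs) == 0) {
    return(data.table(sequence = character(0), status = character(0),
                      n_mismatches_best = integer(0), genes_hit = character(0)))
  }
  if (any(nchar(seqs) != index$tag_length))
    stopf("input error: query sequences must be %d bp", index$tag_length)
  ref <- index$ref
  q <- data.table(sequence = seqs, qid = seq_along(seqs))

  # distance-0: direct join
  exact <- ref[q, on = "sequence", nomatch = NULL,
               .(qid, genes, ambiguous, d = 0L)]
  unresolved <- setdiff(q$qid, exact$qid)

  d1 <- data.table(qid = integer(0), genes = character(0), ambiguous = logical(0), d = integer(0))
  if (length(unresolved) > 0) {
    vars <- hamming1_variants(q$sequence[unresolved])
    vars[, qid := q$qid[unresolved][query_id]]
    hit <- ref[vars, on = c(sequence = "variant"), nomatch = NULL,
               .(qid, genes, ambiguous, d = 1L)]
    d1 <- unique(hit)
  }
  hits <- rbindlist(list(exact, d1))

  res <- hits[, {
    gl <- unique(unlist(strsplit(genes, ",", fixed = TRUE)))
    amb_hit <- any(ambiguous)
    list(
      n_mismatches_best = d[1],
      genes_hit = paste(sort(gl), collapse = ","),
      status = if (amb_hit || length(gl) >= 2) "multi" else "unique"
    )
  }, by = qid]

  out <- res[q, on = "qid"]
  out[is.na(status), `:=`(status = "none", genes_hit = "")]
  out[, .(sequence, status, n_mismatches_best, genes_hit)]
}

#' Write / read a virtual tag library as TSV
#'
#' Columns: `sequence`, `gene_ids` (comma-separated), `is_3prime_most`
#' (comma-separated logicals aligned with `gene_ids`).
#' @param tagset a `VirtualTagSet`.
#' @param path output TSV path.
#' @export
write_virtual_tags <- function(tagset, path) {
  wide <- tagset[order(sequence, gene_id),
                 .(gene_ids = paste(gene_id, collapse = ","),
                   is_3prime_most = paste(is_3prime_most, collapse = ",")),
                 by = sequence]
  fwrite(wide, path, sep = "\t")
  invisible(path)
}

#' @rdname write_virtual_tags
#' @param path TSV path written by [write_virtual_tags()].
#' @export
read_virtual_tags <- function(path) {
  wide <- fread(path, sep = "\t", colClasses = list(character = c("sequence", "gene_ids", "is_3prime_most")))
  long <- wide[, {
    g <- strsplit(gene_ids, ",", fixed = TRUE)[[1]]
    f <- as.logical(strsplit(is_3prime_most, ",", fixed = TRUE)[[1]])
    list(gene_id = g, is_3prime_most = f)
  }, by = sequence]
  setkey(long, sequence, gene_id)
  setattr(long, "n_genes_with_sites", length(unique(long$gene_id)))
  setattr(long, "class", c("VirtualTagSet", class(long)))
  long[]
}
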