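#' Write a reference bundle to disk
#'
#' Emits `transcripts.fasta` (transcript sequences), `scaffolds.fasta`,
#' `genes.gff3` (type `gene`, attribute `ID=<gene_id>`, 1-based inclusive
#' coordinates), `orthologs.tsv`, `go.tsv`, `truth.tsv` and
#' `time_points.tsv`. All files round-trip through [read_reference_bundle()].
#'
#' @param bundle a `ReferenceBundle`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tx <- Biostrings::DNAStringSet(setNames(bundle$genes$transcript_seq, bundle$genes$gene_id))
  Biostrings::writeXStringSet(tx, file.path(dir, "transcripts.fasta"))
  sc <- Biostrings::DNAStringSet(setNames(bundle$scaffolds$seq, bundle$scaffolds$scaffold_id))
  Biostrings::writeXStringSet(sc, file.path(dir, "scaffolds.fasta"))
  gr <- GenomicRanges::GRanges(bundle$genes$scaffold_id,
                               IRanges::IRanges(bundle$genes$start, bundle$genes$end),
                               strand = bundle$genes$strand)
  gr$type <- "gene"
  gr$ID <- bundle$genes$gene_id
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "GFF3")
  fwrite(bundle$ortholog_table, file.path(dir, "orthologs.tsv"), sep = "\t")
  fwrite(bundle$go_table, file.path(dir, "go.tsv"), sep = "\t")
  fwrite(as.data.table(bundle$truth), file.path(dir, "truth.tsv"), sep = "\t")
  fwrite(data.table(sample_id = names(bundle$time_points), hours = bundle$time_points),
         file.path(dir, "time_points.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a reference bundle written by [write_reference_bundle()]
#' @param dir directory holding the bundle files.
#' @return a `ReferenceBundle` (with a NULL `config`).
#' @export
read_reference_bundle <- function(dir) {
  tx <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fasta"))
  sc <- Biostrings::readDNAStringSet(file.path(dir, "scaffolds.fasta"))
  gff <- rtracklayer::import(file.path(dir, "genes.gff3"), format = "GFF3")
  gff <- gff[gff$type == "gene"]
  genes <- data.table(
    gene_id = gff$ID,
    scaffold_id = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff))
  )
  genes[, transcript_seq := as.character(tx[gene_id])]
  tp <- fread(file.path(dir, "time_points.tsv"))
  time_points <- setNames(as.numeric(tp$hours), tp$sample_id)
  truth <- fread(file.path(dir, "truth.tsv"))
  setattr(truth, "time_points", time_points)
  setattr(truth, "class", c("ProfileAssignment", class(truth)))
  bundle <- structure(
    list(scaffolds = data.table(scaffold_id = names(sc), length = Biostrings::width(sc),
                                seq = as.character(sc)),
         genes = genes,
         ortholog_table = fread(file.path(dir, "orthologs.tsv"),
                                colClasses = list(character = 1:2)),
         go_table = fread(file.path(dir, "go.tsv"), colClasses = list(character = 1:3)),
         truth = truth,
         time_points = time_points,
         config = NULL),
    class = "ReferenceBundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Write / read a tag-count library TSV
#'
#' Two-column TSV with header `sequence<TAB>count`.
#' @param lib a `RawTagLibrary` or `CleanTagLibrary`.
#' @param path TSV path.
#' @export
write_tag_counts <- function(lib, path) {
  fwrite(lib$tags[, .(sequence, count)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_tag_counts
#' @param sample_id sample label for the reconstructed library.
#' @param adaptor_seq adaptor recorded on the library (for later cleaning).
#' @export
read_raw_library <- function(path, sample_id, adaptor_seq = DEFAULT_ADAPTOR) {
  tags <- fread(path, sep = "\t", colClasses = list(character = "sequence"))
  stopifnot(all(c("sequence", "count") %in% names(tags)))
  structure(list(sample_id = sample_id, tags = tags[, .(sequence, count)],
                 adaptor_seq = adaptor_seq),
            class = "RawTagLibrary")
}

#' Emit a raw library as FASTQ
#'
#' Expands the tag multiset to one read per copy with dummy qualities; mainly
#' for interoperability checks, so the expansion is capped.
#'
#' @param lib a `RawTagLibrary`.
#' @param path FASTQ path.
#' @param max_reads cap on emitted reads.
#' @export
write_raw_fastq <- function(lib, path, max_reads = 1e6) {
  seqs <- rep(lib$tags$sequence, lib$tags$count)
  if (length(seqs) > max_reads) seqs <- seqs[seq_len(max_reads)]
  ids <- sprintf("%s_tag%07d", lib$sample_id, seq_along(seqs))
  x <- Biostrings::BStringSet(setNames(seqs, ids))
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(w) strrep("I", w), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}
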