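#' @importFrom data.table data.table as.data.table setkey setkeyv := .N .SD setorder fwrite fread rbindlist setnames copy setattr %chin%
#' @importFrom stats rpois rbinom rnorm rlnorm rexp runif p.adjust phyper cor hclust cutree as.dist setNames
#' @importFrom utils head tail
NULL

# half-up rounding (R's round() is banker's); used for all printed percentages
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage with half-up rounding
#'
#' Computes `100 * num / den` rounded half-up to `digits` decimals, the
#' convention used throughout the library summary tables. A zero denominator
#' yields 0 (with the caller expected to warn where that matters).
#'
#' @param num numerator.
#' @param den denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @export
pct <- function(num, den, digits = 2) {
  ifelse(den == 0, 0, round_half_up(100 * num / den, digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != floor(x))
    stopf("%s must be a single non-negative integer", name)
}

# reverse complement for plain character vectors of DNA
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)
  )
}

# all Hamming-distance-1 variants of fixed-width sequences; returns a data.table
# (query_id, variant) including the sequence itself (distance 0) when include_self
hamming1_variants <- function(seqs, include_self = FALSE) {
  if (length(seqs) == 0) {
    return(data.table(query_id = integer(0), variant = character(0)))
  }
  w <- nchar(seqs[1])
  bases <- c("A", "C", "G", "T")
  out <- vector("list", 3L * w + include_self)
  j <- 0L
  if (include_self) {
    j <- 1L
    out[[1L]] <- data.table(query_id = seq_along(seqs), variant = seqs)
  }
  for (p in seq_len(w)) {
    cur <- substr(seqs, p, p)
    pre <- substr(seqs, 1L, p - 1L)
    suf <- substr(seqs, p + 1L, w)
    for (b in bases) {
      keep <- cur != b
      if (!any(keep)) next
      j <- j + 1L
      out[[j]] <- data.table(
        query_id = which(keep),
        variant = paste0(pre[keep], b, suf[keep])
      )
    }
  }
  rbindlist(out[seq_len(j)])
}
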