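# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: per-term closed forms with plain summation,
# naive O(n) scans, and hand union-find.

library(data.table)

# ---- Audic-Claverie enumeration oracle -------------------------------------
# term p(k|x) = C(x+k, k) r^k / (1+r)^(x+k), evaluated per k via lchoose;
# lower tail summed ascending from 0, upper tail summed from y until the
# remainder is provably negligible.
ac_oracle <- function(x, y, N1, N2) {
  r <- N2 / N1
  term <- function(k) exp(lchoose(x + k, k) + k * log(r) - (x + k) * log1p(r))
  lower <- sum(term(0:y))
  upper <- 0
  k <- y
  repeat {
    t <- term(k)
    upper <- upper + t
    k <- k + 1
    if (k > x * r + 1 && t < upper * 1e-20) break
    if (k > y + 500000) break
  }
  min(1, 2 * min(lower, upper))
}

# ---- naive Hamming scan over a reference tag table -------------------------
hamming_dist <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

revcomp_chr <- function(x) {
  vapply(x, function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

# ref: data.table(sequence, gene_id) over ALL reference tags (ambiguous incl.)
naive_tag_scan <- function(ref, query) {
  d <- vapply(ref$sequence, hamming_dist, numeric(1), a = query)
  best <- suppressWarnings(min(d))
  if (best > 1) return(list(status = "none", d = NA_integer_, genes = character(0)))
  genes <- sort(unique(ref$gene_id[d == best]))
  list(status = if (length(genes) >= 2) "multi" else "unique",
       d = as.integer(best), genes = genes)
}

# ---- BH step-up oracle ------------------------------------------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# ---- hypergeometric enrichment enumeration ----------------------------------
fisher_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(n, j) * choose(N - n, K - j)) / choose(N, K)
}

# ---- adjusted Rand index -----------------------------------------------------
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  nt <- choose(sum(tab), 2)
  exp_ <- si * sj / nt
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# ---- union-find over OMDEG proximity ----------------------------------------
# genes: data.table(gene_id, scaffold_id, start, end); returns membership list
union_find_clusters <- function(genes, omdeg_ids, max_distance = 50000) {
  parent <- setNames(seq_len(nrow(genes)), genes$gene_id)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) { parent[find(i)] <<- find(j) }
  gap <- function(i, j) {
    if (genes$scaffold_id[i] != genes$scaffold_id[j]) return(Inf)
    g <- max(genes$start[i], genes$start[j]) - min(genes$end[i], genes$end[j]) - 1
    max(0, g)
  }
  keep <- rep(FALSE, nrow(genes))
  for (o in match(omdeg_ids, genes$gene_id)) {
    keep[o] <- TRUE
    for (j in seq_len(nrow(genes))) {
      if (j != o && gap(o, j) < max_distance) {
        union(j, o)
        keep[j] <- TRUE
      }
    }
  }
  roots <- vapply(seq_len(nrow(genes)), find, numeric(1))
  split(genes$gene_id[keep], roots[keep])
}

# ---- shared tiny fixtures ----------------------------------------------------
tiny_config <- function(n_genes = 50, ...) {
  reference_config(n_genes = n_genes, n_scaffolds = 3,
                   transcript_length = c(150, 500), intergenic_mean = 500, ...)
}
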