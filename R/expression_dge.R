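#' DGE thresholds
#'
#' @param fdr_max maximum FDR for a DEG call (inclusive).
#' @param min_abs_log2 minimum |log2 ratio| for a DEG call (inclusive).
#' @param high_expression_tpm TPM above which (strictly) a gene counts as
#'   highly expressed in the maternal catalog.
#' @return list of class `"DGEThresholds"`.
#' @export
dge_thresholds <- function(fdr_max = 0.01, min_abs_log2 = 1.0, high_expression_tpm = 10.0) {
  stopifnot(fdr_max > 0, min_abs_log2 > 0, high_expression_tpm > 0)
  structure(list(fdr_max = fdr_max, min_abs_log2 = min_abs_log2,
                 high_expression_tpm = high_expression_tpm),
            class = "DGEThresholds")
}

#' Transcripts-per-million normalization
#'
#' `TPM = count / clean_total * 1e6`, where `clean_total` is the sample's
#' total clean tags (not the mapped total), so TPM values sum to
#' `1e6 * mapped_fraction`.
#'
#' @param counts numeric vector of per-gene tag counts.
#' @param clean_total total clean tags of the sample (> 0).
#' @return numeric vector of TPM values.
#' @export
tpm_normalize <- function(counts, clean_total) {
  if (length(clean_total) != 1 || clean_total <= 0)
    stopf("clean_total must be a single positive number")
  counts / clean_total * 1e6
}

#' Build an expression matrix from per-sample mapping results
#'
#' @param mappings named list of `MappingResult`s (names = sample ids, in time
#'   order).
#' @param clean_totals named numeric vector of per-sample clean-tag totals.
#' @param gene_ids optional gene universe; defaults to the union of mapped
#'   genes.
#' @return list of class `"ExpressionMatrix"`: `counts` (genes x samples
#'   integer matrix), `tpm` (same shape), `clean_totals`.
#' @export
build_expression_matrix <- function(mappings, clean_totals, gene_ids = NULL) {
  samples <- names(mappings)
  stopifnot(!is.null(samples), all(samples %in% names(clean_totals)))
  if (is.null(gene_ids))
    gene_ids <- sort(unique(unlist(lapply(mappings, function(m) m$gene_counts$gene_id))))
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(samples),
                   dimnames = list(gene_ids, samples))
  for (s in samples) {
    gc <- mappings[[s]]$gene_counts
    gc <- gc[gene_id %in% gene_ids]
    counts[gc$gene_id, s] <- gc$count
  }
  tpm <- sweep(counts, 2, clean_totals[samples], "/") * 1e6
  structure(list(counts = counts, tpm = tpm, clean_totals = clean_totals[samples]),
            class = "ExpressionMatrix")
}

#' Audic-Claverie two-count test
#'
#' Exact test for a difference between tag counts `x` (library 1, size `N1`)
#' and `y` (library 2, size `N2`), based on the conditional weight
#' `p(k|x) = r^k (x+k)! / (x! k! (1+r)^(x+k))` with `r = N2/N1`. The two-sided
#' p-value doubles the smaller of the lower tail (`k <= y`) and the upper tail
#' (`k >= y`) and caps at 1; `one_sided = TRUE` returns the smaller tail
#' uncapped instead. Tails are accumulated in log space from the
#' log-gamma-evaluated mode term with multiplicative recursion, accurate to
#' better than 1e-10 for counts up to at least 50.
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param N1,N2 positive library sizes.
#' @param one_sided return the smaller single tail instead of doubling.
#' @return numeric vector of p-values.
#' @export
audic_claverie_p <- function(x, y, N1, N2, one_sided = FALSE) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)) ||
      any(is.na(x)) || any(is.na(y)))
    stopf("input error: counts must be non-negative integers")
  if (any(N1 <= 0) || any(N2 <= 0)) stopf("input error: library sizes must be positive")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) ac_p_one(x[i], y[i], N1[i], N2[i], one_sided),
         numeric(1))
}

# log p(k|x) = k*log(r) + lgamma(x+k+1) - lgamma(x+1) - lgamma(k+1) - (x+k)*log(1+r).
# Both tails are accumulated fully in log space (terms can span hundreds of
# orders of magnitude for deep libraries), walking outward from k = y with
# multiplicative term recursion and stopping once the remainder is provably
# below 1e-18 of the accumulated mass.
ac_p_one <- function(x, y, N1, N2, one_sided) {
  r <- N2 / N1
  l1r <- log1p(r)
  logadd <- function(a, b) {
    m <- max(a, b)
    if (m == -Inf) return(-Inf)
    m + log1p(exp(min(a, b) - m))
  }
  logp_y <- y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) - (x + y) * l1r
  mode_k <- r * x  # terms decrease below this k going down, above it going up

  # lower tail: k = y, y-1, ..., 0
  lt <- logp_y
  acc_lo <- logp_y
  k <- y
  while (k > 0) {
    lt <- lt + log(k) + l1r - log(r) - log(x + k)
    k <- k - 1
    acc_lo <- logadd(acc_lo, lt)
    # remaining k+1 terms all below exp(lt) once decreasing
    if (k < mode_k && lt + log(k + 1) < acc_lo - 45) break
  }

  # upper tail: k = y, y+1, ...
  lt <- logp_y
  acc_hi <- logp_y
  k <- y
  repeat {
    lt <- lt + log(r) + log(x + k + 1) - log(k + 1) - l1r
    k <- k + 1
    acc_hi <- logadd(acc_hi, lt)
    if (k > mode_k && lt < acc_hi - 50) break  # geometric remainder negligible
    if (k > y + 200000) break
  }

  log_tail <- min(acc_lo, acc_hi)
  p <- exp(log_tail + if (one_sided) 0 else log(2))
  min(1, p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1 and
#' returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of FDR (q) values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("input error: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Compare two libraries gene by gene
#'
#' Genes with zero counts in both samples are untestable and reported `ns`
#' without entering the FDR family. For tested genes the Audic-Claverie
#' p-value is corrected by Benjamini-Hochberg within this comparison. The log2
#' ratio is `log2(tpm_b / tpm_a)`; when exactly one count is zero it is
#' replaced by one tag for the ratio only (the test uses the true counts).
#' A gene is `up` when `log2_ratio >= min_abs_log2` and `fdr <= fdr_max`
#' (expression higher in `b` than in `a`), `down` symmetrically.
#'
#' @param em an `ExpressionMatrix`.
#' @param sample_a,sample_b sample ids (a is the reference side).
#' @param thresholds a [dge_thresholds()].
#' @param one_sided passed to [audic_claverie_p()].
#' @return data.table of class `"DGEComparison"` with columns `gene_id`, `x`,
#'   `y`, `N1`, `N2`, `tpm_a`, `tpm_b`, `log2_ratio`, `p_value`, `fdr`,
#'   `status`; attributes `sample_a`, `sample_b`.
#' @export
compare_libraries <- function(em, sample_a, sample_b, thresholds = dge_thresholds(),
                              one_sided = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (identical(sample_a, sample_b)) stopf("input error: samples of a pair must differ")
  if (!all(c(sample_a, sample_b) %in% colnames(em$counts)))
    stopf("input error: unknown sample id")
  x <- em$counts[, sample_a]
  y <- em$counts[, sample_b]
  N1 <- em$clean_totals[[sample_a]]
  N2 <- em$clean_totals[[sample_b]]
  res <- data.table(gene_id = rownames(em$counts), x = x, y = y, N1 = N1, N2 = N2,
                    tpm_a = em$tpm[, sample_a], tpm_b = em$tpm[, sample_b])
  res[, tested := x > 0 | y > 0]
  # zero-handling for the ratio only
  res[, log2_ratio := {
    xa <- ifelse(x == 0 & y > 0, 1, x)
    yb <- ifelse(y == 0 & x > 0, 1, y)
    ifelse(tested, log2((yb / N2) / (xa / N1)), 0)
  }]
  res[, `:=`(p_value = NA_real_, fdr = NA_real_, status = "ns")]
  if (any(res$tested)) {
    res[tested == TRUE, p_value := audic_claverie_p(x, y, N1, N2, one_sided = one_sided)]
    res[tested == TRUE, fdr := bh_adjust(p_value)]
    res[tested == TRUE & fdr <= thresholds$fdr_max &
          log2_ratio >= thresholds$min_abs_log2, status := "up"]
    res[tested == TRUE & fdr <= thresholds$fdr_max &
          log2_ratio <= -thresholds$min_abs_log2, status := "down"]
  }
  res[, tested := NULL]
  setattr(res, "sample_a", sample_a)
  setattr(res, "sample_b", sample_b)
  setattr(res, "class", c("DGEComparison", class(res)))
  res[]
}

#' Run a pairwise comparison strategy over a time course
#'
#' Strategy `"I"` compares every later time point against the baseline (first)
#' sample; strategy `"II"` compares each sample against the immediately
#' preceding one.
#'
#' @param em an `ExpressionMatrix` with samples in time order (or supply
#'   `time_order`).
#' @param strategy `"I"` or `"II"`.
#' @param time_order character vector of sample ids in time order.
#' @param thresholds a [dge_thresholds()].
#' @return named list of `DGEComparison`s (names like `"0h_vs_6h"`), in time
#'   order.
#' @export
run_strategy <- function(em, strategy = c("I", "II"),
                         time_order = colnames(em$counts),
                         thresholds = dge_thresholds()) {
  strategy <- match.arg(strategy)
  if (length(time_order) < 2) stopf("input error: need at least two time points")
  pairs <- if (strategy == "I") {
    lapply(time_order[-1], function(s) c(time_order[1], s))
  } else {
    lapply(seq_len(length(time_order) - 1),
           function(i) c(time_order[i], time_order[i + 1]))
  }
  out <- lapply(pairs, function(p) compare_libraries(em, p[1], p[2], thresholds))
  names(out) <- vapply(pairs, function(p) paste0(p[1], "_vs_", p[2]), character(1))
  out
}

#' DEG gene set of a comparison
#' @param comparison a `DGEComparison`.
#' @return character vector of gene ids with status `up` or `down`.
#' @export
deg_genes <- function(comparison) comparison[status != "ns", gene_id]

#' Venn region counts of DEG sets
#'
#' For named sets, counts every non-empty region of the membership partition.
#' Region labels join the member set names with `&`.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return data.table with columns `region` and `n`, non-empty regions only.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stopf("input error: need >= 2 named sets")
  universe <- unique(unlist(sets))
  if (length(universe) == 0) return(data.table(region = character(0), n = integer(0)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  out <- data.table(region = names(tab), n = as.integer(tab))
  setorder(out, region)
  out
}

#' Direction tallies within a pairwise DEG overlap
#'
#' For the genes differentially expressed in both comparisons, tallies the
#' up/down direction on each side and the corresponding percentages (half-up,
#' 2 decimals), mirroring statements like "85.96% of the common DEGs were
#' down-regulated from 6 h to 12 h".
#'
#' @param comp_a,comp_b two `DGEComparison`s.
#' @return list: `n_common`, and per side `up`, `down`, `up_pct`, `down_pct`.
#' @export
direction_tallies <- function(comp_a, comp_b) {
  common <- intersect(deg_genes(comp_a), deg_genes(comp_b))
  side <- function(comp) {
    st <- comp[gene_id %in% common, status]
    list(up = sum(st == "up"), down = sum(st == "down"),
         up_pct = pct(sum(st == "up"), length(common)),
         down_pct = pct(sum(st == "down"), length(common)))
  }
  list(n_common = length(common), a = side(comp_a), b = side(comp_b))
}
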