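---
title: "Methods: tag-based DGE profiling of an egg time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based DGE profiling of an egg time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Tag-based digital gene expression (DGE) quantifies transcripts by sequencing
a single 21-bp tag per cDNA molecule: NlaIII cuts at the 3'-most CATG of the
bead-bound cDNA, and MmeI, recognizing the adaptor/CATG junction, cuts 17 bp
downstream, so every read is `CATG` + 17 bases. A gene's expression is the
count of such tags attributable to it, and a library is a multiset of
(sequence, count) pairs. This model has three practical consequences that
shape the whole pipeline:

* only CATG-bearing transcripts are observable;
* a tag is informative only if its 21-mer is unique to one gene;
* counts are library-size-dependent, so comparisons must condition on totals.

`tagdge` implements the full chain from simulated raw libraries to maternal
gene annotation. This vignette records the model assumptions, the parameters
that matter, and the decisions taken where the procedure is genuinely
underdetermined.

# The synthetic world

The generator (`generate_reference()`, `assign_profiles()`,
`simulate_raw_library()`) emulates the *statistical structure* the analysis
assumes, not silkworm biology. Its defaults describe one fixed desk-scale
world:

| parameter | default | rationale |
|---|---|---|
| genes / scaffolds | 500 / 6 | desk scale; enough genes for stable FDR behaviour |
| transcript length | 300–1500 bp | typical mRNA range; every transcript guaranteed one CATG+17 site |
| intergenic gaps | Exp(1500 bp), 15% deserts of 55–90 kb | a uniformly dense mini-genome would chain every gene into one 50-kb cluster; deserts give the island structure real genomes have |
| paralog fraction | 4% (exact count) | i.i.d. random transcripts essentially never share a 21-mer; copied CATG segments make the multi-gene (ambiguous) tag path non-degenerate |
| maternal fraction | 10%, applied by exact count | deterministic tallies for testing |
| maternal archetype | forced `down_monotone` | maternal transcripts are deposited and degrade; this plants the expected biology |
| archetype mix | 8/5/4/3% shaped, 80% flat null | most genes unchanged, as in real libraries |
| baseline abundance | log-normal, meanlog log(50), sdlog 1.2 | strongly skewed abundances (most genes low, few very high) |
| depth | 1e5 expected tags/library | desk scale; the published libraries are ~5.8e6 |
| error rate | 0.005/base | Illumina-era substitution scale |
| artifacts | adaptor 0.5%, off-length 1%, N 0.5%, singletons 0.5% | populations removed by the cleaning rules |
| background | genomic 15%, foreign 3% | unannotated transcription (maps to genome, not genes) and unassignable tags; these populate the genome/unknown categories of the summary table |

Counts are Poisson with mean `depth × relative planted abundance`
(negative-binomial overdispersion behind a knob, off by default — the
procedure being tested makes no overdispersion assumption and single
libraries per time point cannot estimate one). Within a gene, 90% of tags
come from the 3'-most CATG site (the site the chemistry captures) and 10%
leak uniformly over the other sites, which exercises ambiguity handling
because the virtual library indexes every site.

What the generator does *not* emulate: PCR duplication, per-base quality
strings (quality is reduced to the presence of an `N`), bead chemistry,
polymorphism between sample and reference, and any real silkworm sequence.
A green test therefore establishes correctness of the *computations* under
the stated sampling model, not fidelity to any real library.

# Virtual tag library and mapping

`extract_virtual_tags()` enumerates every CATG occurrence with ≥ 17
downstream bases, sense strand only (transcripts are sense sequences; an
antisense option would double the library and is out of scope). Ambiguity is
handled at two levels:

1. *reference level*: a 21-mer present in ≥ 2 genes is removed before
   indexing (`partition_ambiguity()`);
2. *query level*: a clean tag whose ≤ 1-mismatch neighborhood spans ≥ 2
   genes — or touches a reference-ambiguous tag — is reported `multi`.
   This second level is a necessary consequence of mismatch-tolerant
   matching even though only the first is usually described.

Exact hits take precedence over 1-mismatch hits (standard tag-mapping
practice): a tag equal to gene A's reference tag is credited to A even if it
is also one substitution away from gene B. Only `unique` tags contribute to
gene counts; `multi` tags still count as "mapped to gene" in the library
summary, mirroring the all/unambiguous row pair of the published table
layout.

Tags matching no gene are searched against the genome, both strands, ≤ 1
mismatch — implemented as Aho–Corasick exact matching of the 64
single-substitution variants (Biostrings `PDict`) against the scaffolds and
their reverse complements. The remainder is `unknown`. The three categories
partition the clean total exactly; this identity is asserted on every
synthetic run.

# Cleaning rules

In order: 3' adaptor trim (everything from the adaptor's first occurrence),
ambiguous-base (N) removal, exact 21-bp length filter, re-aggregation, and
copy-number ≥ 2. "Low quality" is defined as containing an N because tag
protocols provide no finer signal at this abstraction; cleaning is
idempotent by construction.

# The count test

For counts `x`, `y` with library sizes `N1`, `N2` and `r = N2/N1` the
conditional weight is

$$p(k \mid x) = \frac{r^k \,(x+k)!}{x!\,k!\,(1+r)^{x+k}}$$

and the two-sided p-value is `min(1, 2·min(Σ_{k≤y} p(k|x), Σ_{k≥y} p(k|x)))`
(a one-sided variant sits behind a flag). Note the weights sum to `1 + r`
over all `k`, i.e. the working form is unnormalized; with the doubling and
the cap at 1 this matters only in regimes where the p-value is ~1 anyway,
and the convention is pinned by the hand-derivable case
`x = 5, y = 0, N1 = N2 → p = 2 · C(5,0)/2⁵ = 0.0625`.

Numerically, both tails are accumulated fully in log space, walking outward
from `k = y` with multiplicative term recursion from a single log-gamma
anchor and stopping when the remainder is provably below 1e-18 of the
accumulated mass. This keeps deep-library comparisons (counts in the
thousands, p-values below 1e-300 in magnitude of log) finite and is accurate
to better than 1e-10 against an exact enumeration oracle on the 0–50 count
grid.

Decisions:

* genes with zero counts in both samples are untestable and excluded from
  the FDR family (`ns` status);
* FDR (Benjamini–Hochberg, via `stats::p.adjust`) is controlled per
  comparison, since DEG counts are reported per comparison;
* thresholds are inclusive: FDR ≤ 0.01, |log2 ratio| ≥ 1;
* for the log2 ratio only, a zero count on exactly one side is replaced by
  one tag; the test always uses the true counts.

# Profile clustering

Every gene significant in ≥ 1 strategy-I comparison keeps its full 4-vector
of log2 ratios versus 0 h. The distance is `1 − r` (Pearson), *not*
`1 − |r|`: anti-correlated time courses are opposite biology and must
separate. Zero-variance profiles (possible when a DEG's ratios happen to be
equal) get `r = 1` against identical vectors and `r = 0` otherwise, since
Pearson is undefined there.

Linkage is average (UPGMA); the cut `k` is a presentation parameter
defaulting to 27 to mirror the published figure layout — no claim is made
that any particular `k` is optimal, and the planted-archetype recovery test
uses `k = 4` against ground truth (ARI ≥ 0.9 at noise σ = 0.1). Profiles
are sorted lexicographically by gene id before clustering so results do not
depend on input order; agglomeration ties are then resolved deterministically
by `stats::hclust`.

Cluster trend tags come from the sign pattern of consecutive differences of
the baseline-augmented mean profile with a ±0.25 dead band: `down`
(non-increasing), `up` (non-decreasing), `drop_late` (flat then a final
drop), `pulse` (flat, rise into the penultimate point, fall), else `other`.

# Maternal catalog, gene clusters, enrichment, qPCR

* **OMG/OMDEG**: any gene in the ortholog table is an orthologous maternal
  gene; expressed means ≥ 1 unambiguous tag in ≥ 1 sample; OMDEG means in
  the strategy-I DEG union; the high-expression flag is strict (> 10 TPM at
  ≥ 1 time point). The classes partition the OMG set by construction.
* **Gene clusters**: distance is the interval gap (0 on overlap), the rule
  is strict `< 50 kb`, membership considers all annotated genes (not only
  DEGs), and OMDEG neighborhoods sharing any gene are merged transitively
  (connected components; verified against a union-find oracle). Whether the
  original procedure merged overlapping neighborhoods is unstated; merging
  is the defensible default because unmerged neighborhoods double-report
  shared genes.
* **GO enrichment**: one-sided over-representation via the hypergeometric
  upper tail (two-sided Fisher behind a flag), background = genes with ≥ 1
  GO annotation. Terms are used as annotated — no GO-graph propagation. In
  the synthetic world annotations are independent of expression truth, so
  enrichment acts as a built-in negative control; correctness is
  established against full enumeration on small backgrounds.
* **qPCR**: replicate CTs are averaged; ΔCT against the reference gene, ΔΔCT
  against the calibrator sample, level `2^−ΔΔCT`; the calibrator's own level
  is exactly 1.

# Pipeline and configuration

`run_pipeline()` composes all stages from one `pipeline_config()`, writes
every stage's TSV, and records a manifest (config hash, seed, per-output row
counts) that is re-verified against the files on disk. Stage failures abort
with a stage-named error and retain partial outputs. Configuration is an R
list (serializable as JSON); a YAML front end was deliberately dropped
because the target environment provides no R YAML parser. Per-library seeds
are derived as `seed + sample index`, keeping all derived seeds well below
2³¹.

# Known limitations

* Single library per time point: no replicates, hence no dispersion
  estimation — the exact-test framework is the point, not a GLM.
* The genome search and the 1-mismatch gene mapping share the Hamming
  tolerance but the original pipeline's genome-mapping parameters are
  unknown; both the mismatch allowance and strand handling are config
  flags.
* Published headline counts (thousands of DEGs, 76 OMGs, 27 clusters, 22
  gene clusters) depend on the real 5.8M-tag libraries and external
  ortholog/GO resources and are deliberately not reproduction targets; the
  package reproduces the *arithmetic* of every published percentage and the
  *statistical behaviour* of every published procedure at desk scale.
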