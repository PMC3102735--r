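---
title: "Models and methods behind zgatools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zgatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zgatools)
```

# The scientific setting

At the maternal-to-zygotic transition (MZT) the early embryo switches from
maternally deposited gene products to transcription from its own genome.
Which transcription factors drive that first wave of zygotic transcription
is a question that can be attacked computationally from three directions,
and `zgatools` implements all three as one pipeline:

1. **Binding-site enrichment.** If a factor activates early zygotic genes,
   its consensus binding sites should be over-represented in those genes'
   promoters relative to a compositional null, and depleted or unremarkable
   in control (housekeeping) promoters.
2. **Evidence-weighted activation scoring.** Literature evidence of an
   activator-target relationship can be graded and summed into a cumulative
   score per activator, ranking candidate drivers of the transition.
3. **Expression analysis.** In embryos lacking the maternal contribution of
   a candidate activator, its zygotic targets should drop in expression;
   fold-change calls, the gene-category composition of the regulated sets,
   and a gene-set enrichment statistic quantify this.

# The binomial enrichment model

## Background model

The null model treats genomic sequence as i.i.d. letters with the base
composition of the *D. melanogaster* genome, 57.4% AT and 42.6% GC,
split evenly within each class:

$$p_A = p_T = 0.574/2 = 0.287, \qquad p_C = p_G = 0.426/2 = 0.213.$$

`background_model()` accepts any AT fraction (or a composition estimated
from the data with `base_composition()`); `dmel_composition()` ships the
fly default.

## Site probability and the count null

A degenerate IUPAC consensus of length $L$ with allowed base set $S_j$ at
position $j$ occurs at a fixed position with probability

$$p_\text{site} = \prod_{j=1}^{L} \sum_{b \in S_j} p_b,$$

a fully degenerate position (N) contributing a factor 1. For the 9-bp STAT
consensus `TTCnnnGAA` (six fixed bases, four A/T-class and two G/C-class)
this is $0.287^4 \times 0.213^2 \approx 3.08\times 10^{-4}$.

Counting each of $n$ sequence positions as an independent Bernoulli trial,
the number of motif occurrences is modelled as Binomial$(n, p_\text{site})$
with expectation $np_\text{site}$ and standard deviation
$\sqrt{np_\text{site}(1-p_\text{site})}$; an observed count $x$ is scored by
$Z = (x - np_\text{site})/\sigma$ and the two-tailed normal p-value
$2(1-\Phi(|Z|))$. Depletion is simply a negative $Z$ with the same
two-tailed mapping. An exact binomial two-tailed p (twice the smaller tail
containing $x$, clipped at 1) is also reported.

```{r}
bg <- background_model(dmel_composition())
stat <- parse_motif("STAT", "TTCnnnGAA")
enrichment_test(43, 84000, site_probability(stat, bg))
```

## Trial-count conventions

Two conventions for $n$ are provided in `set_enrichment_report()`:

* `total_bp` (default): every bp of the sequence set is a trial, so 21
  windows of 4,000 bp give $n = 84{,}000$. This ignores the $L-1$ edge
  positions per window where a full motif cannot start.
* `exact_positions`: $n = \sum_i (\ell_i - L + 1)$, the true number of
  start positions (83,832 for the same set and a 9-bp motif).

The difference is a fraction of a percent at promoter scale; `total_bp`
keeps headline numbers on the familiar scale, `exact_positions` is the
corrected null and is what the calibration tests use.

## Numerical behaviour and known limitations

* No continuity correction is applied to $Z$; consequently the normal and
  exact binomial p-values agree closely in the body of the distribution
  (within 20% relative for expected counts $\ge 20$ and $|Z| \le 1.5$) but
  drift apart in the tails — at an expected count of 26 the normal tail can
  be a factor ~2 off the exact tail around $|Z| \approx 3$. Where a
  calibrated p matters, use `p_binomial_exact`; the normal $Z$ remains the
  interpretable effect-size scale.
* The i.i.d. null ignores dinucleotide structure and the mild negative
  correlation between overlapping windows for non-self-overlapping words
  (variance deflation of order $2p_\text{site}(L-1)$, well under the
  Monte-Carlo resolution of the calibration tests at the defaults used).
* Overlapping matches are all counted, consistent with the
  positions-as-trials null.

# Motif scanning and site clusters

`parse_motif()` expands the full IUPAC alphabet into per-position allowed
sets. `scan_sequence()`/`scan_set()` report every (possibly overlapping)
position where each sequence base belongs to the motif's allowed set.
An ambiguous sequence base (N) matches only a fully degenerate motif
position — so N-runs can never fake fixed-position hits. Default scanning
is forward-strand only, matching promoter-scan convention; `strands =
"both"` additionally scans the reverse-complement pattern and reports hits
with strand `-`. The STAT consensus is its own reverse complement, so for
it the two modes contain the same information; for non-palindromic motifs
such as the Zelda TAGteam heptamer `CAGGTAG` both modes are offered and
neither asserted as canonical.

Clusters of sites are maximal single-linkage chains in which consecutive
hit start offsets differ by at most `max_gap` (default 500 bp). For two
sites this reduces to the plain pairwise rule — two sites within 500 bp —
and the chaining extension is deterministic and order-independent. The gap
is measured between start offsets, the simplest testable reading of
"within 500 bp". The test suite checks the caller against an independent
all-pairs adjacency / connected-components oracle.

# Promoter windows

Promoters are defined as the `window_bp` (default 4,000) bp immediately
upstream of the transcription start site (TSS): on the `+` strand the
half-open interval $[\text{tss} - w, \text{tss})$, on the `-` strand
$[\text{tss}+1, \text{tss}+1+w)$ reverse-complemented, so both read
5'→3' towards the gene. Internal coordinates are 0-based half-open;
GFF3 (1-based inclusive) and BED (0-based half-open) are converted in the
readers only. For genes with several transcripts the reader keeps the
5'-most transcript start. Windows running off a contig are truncated and
flagged rather than dropped; the enrichment stage recomputes $n$ from
actual window lengths in `exact_positions` mode, so truncation cannot
silently inflate the null. Whether neighbouring genes overlap a window is
not examined — no overlap exclusion is implemented.

# Activation scores

Evidence records (activator, target gene, evidence category) are converted
to edge weights by a fixed rubric: genetically demonstrated activation in
the early embryo, 10; biochemical/promoter studies in early embryos or
genetic evidence from other stages, 5; unconfirmed genetic screens, 5;
in vitro biochemical assays, 2; bioinformatic evidence, 1. Several records
for one activator-target pair collapse to the **maximum** weight by
default: the rubric grades the single best line of evidence for that
regulatory link, and summing would double-count corroborating citations of
the same interaction. (`combine = "sum"` is available since the opposite
reading is defensible.) Cumulative activator scores sum edge weights over
targets; ranking is by descending score with lexicographic tie-break,
which is arbitrary but deterministic. The map exports as TSV, JSON, or
Graphviz DOT with penwidth increasing in edge weight.

# Expression analysis

Fold change per gene is the ratio of mutant to wild-type replicate means,
with a pseudocount (default 1, on the raw intensity scale) guarding
zeros. Regulation calls use the symmetric threshold: down iff
$\text{fc} \le 1/\theta$, up iff $\text{fc} \ge \theta$, with
$\theta = 1.5$ by default; $\theta$ is a parameter because reasonable
analyses also use 2-fold. Probe-level present/absent filtering of
microarrays is out of scope; a minimum-expression filter can stand in for
it upstream of these functions.

`category_composition()` profiles a called set over the gene categories
(zygotic, maternal, maternal/zygotic, housekeeping, other; unannotated
genes fall into "other"), and `set_overlap()` gives exact intersection
and Jaccard statistics for comparing regulated sets between genotypes.

## The permutation gene-set statistic

`gene_set_enrichment()` implements a weighted Kolmogorov–Smirnov-style
running-sum statistic: genes are ranked by signed score (log2 fold change,
descending), the running sum rises by $|s_i|^w / \sum_{j \in S} |s_j|^w$
at set members and falls by $1/(N - |S|)$ at non-members, and ES is the
signed extremum. The weight exponent defaults to 1. The null is built by
**gene-label permutation** — random same-size gene sets — rather than
phenotype permutation, the appropriate choice when each condition has only
a few replicates. NES is ES over the mean |null ES| of the same sign, and
the nominal p is the smoothed same-sign tail fraction
$(1 + k)/(1 + n_\text{same})$.

One degenerate case needs care: with weighting, a single dominant tail
(e.g. 100 strongly down-regulated genes) can make *every* permuted set's
signed ES negative. An observed positive ES then has no same-sign null,
and the naive smoothed p would call any mid-ranking set maximally
significant. In that case the implementation falls back to a magnitude
comparison against the full null, which correctly reports such sets as
unremarkable. This is an emulation of the classic GSEA procedure, not a
reimplementation of the Broad tool.

# Synthetic data and what the tests demonstrate

The generators produce data with exactly the statistical structure the
analysis assumes:

* `gen_background_sequences()`: i.i.d. letters at a given AT fraction —
  the enrichment null made flesh. Defaults are 21 sequences of 4,000 bp at
  0.574, the promoter-set scale of the enrichment analysis.
* `plant_motifs()`: non-overlapping concrete motif realizations at uniform
  offsets, degenerate positions sampled from the background composition so
  planting barely perturbs overall composition; planted offsets are
  recorded as truth.
* `gen_expression()`: log-normal wild-type means, multiplicative
  per-category fold effects, log-normal replicate noise. Defaults: 1,000
  genes (100 zygotic, 100 maternal, 60 maternal/zygotic, 40 housekeeping,
  700 other), 3 replicates per condition, zygotic effect $1/4.3$ (the
  average down-regulation the mutant analysis centres on), all other
  categories 1, effect spread and replicate noise 0.1 on the log scale —
  small enough that category structure dominates, large enough that calls
  are not trivial. The log-normal form is the simplest positive-valued
  multiplicative-noise model; no distributional claim beyond that is
  intended.
* `gen_evidence_table()`: random evidence records with cumulative-score
  truth recomputed by direct per-pair enumeration.

All generators are pure functions of (parameters, seed): they save and
restore the ambient RNG state, so identical seeds give bit-identical
output regardless of session state.

Because the generators implement the model's own assumptions, green tests
show **internal correctness and calibration** — the scanner equals a
brute-force oracle, the type-I error of the enrichment test matches the
exact size of the discrete test (computed from `dbinom`, about 0.056 at
the sizes used, the deviation from 0.05 being pure count discreteness),
planted effects are recovered — but not robustness to what real data add:
repeats and dinucleotide structure in genomic sequence, probe-level
microarray artifacts, correlated replicates. Conclusions about real
genomes therefore inherit the i.i.d. and log-normal caveats above.

Problem sizes in the shipped tests are chosen to make each property
measurable at Monte-Carlo resolution while keeping the whole suite fast:
2,000 simulated sets of 5 × 1,000 bp with a 4-bp motif for type-I
calibration (expected count ≈ 25), 80 seeds for planted-site recovery,
1,000 permutations for the planted gene-set checks.

# Pipeline and configuration

`run_enrichment_pipeline()` and `run_expression_pipeline()` orchestrate
the stages from a YAML/list config, writing plain-text outputs (FASTA,
6-column BED for hits and clusters, TSV reports, JSON summaries) whose
first lines record an MD5 hash of the config and the seed — identical
configs produce byte-identical outputs. A thin command-line wrapper with
subcommands (`promoters`, `scan`, `enrich`, `activators`, `expression`,
`simulate`, `run-all`) ships in `inst/cli/mzt.R`; it only calls the
exported functions documented here.
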