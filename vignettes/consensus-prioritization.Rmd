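---
title: "Consensus gene prioritization by mega-analysis of odds ratios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gene prioritization by mega-analysis of odds ratios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaor)
```

# The model

`megaor` treats gene prioritization as a combinatorial selection problem
over a binary evidence matrix. Each of *d* evidence dimensions (gene-based
GWAS scores, eQTL–GWAS integration, TWAS, differential expression,
differential methylation, …) contributes a 0/1 label per gene, produced by
that dimension's own domain convention: a strict cut on the
Benjamini–Hochberg adjusted p-value, optionally combined with a strict
fold-change requirement for expression data. The working assumptions are:

* each dimension's false discoveries are already controlled by its own
  threshold, so labels can be treated symmetrically across dimensions;
* the number of genes truly underlying the trait is limited, so a
  *fixed-size* candidate set is a meaningful target;
* no dimension is privileged a priori — a good candidate set should load
  evidence from all dimensions in a balanced way.

For a candidate set $S$ with $|S| = n$, each dimension $j$ gives an odds
ratio $\mathrm{OR}_j$ from the 2×2 table (in $S$ and labelled, in $S$ and
not, outside and labelled, outside and not). With
$\mu = \tfrac1d \sum_j \mathrm{OR}_j$, the objective is

$$\mathrm{cOR}(S) \;=\; \mu \;-\; \sqrt{\tfrac1d \sum_{j=1}^d
  (\mathrm{OR}_j - \mu)^2},$$

the mean of the per-dimension odds ratios minus their population standard
deviation. The subtracted deviation is a penalty: a set whose evidence is
carried by one or two dimensions has a large spread and is punished, so the
optimizer is pushed toward sets supported by *every* dimension. Two
consequences are useful as invariants: $\mathrm{cOR} \le \mu$ always, with
equality exactly when all dimension ORs agree; and the penalty is zero for
one-dimensional matrices, which are therefore rejected ($d \ge 2$ is
required). The divisor of the deviation term is $d$ by default; a
$d - 1$ (sample SD) variant is available via `penalty_divisor` and changes
nothing qualitative.

The published description of this objective gives the penalty only as "a
term controlling the deviation of any dimensional OR"; the concrete
root-mean-square form above is this package's documented choice, selected
as the simplest statistic with exactly that role. It is isolated in one
place (`combined_or()`) and the tests pin its algebra to an independently
coded evaluation.

## Odds ratios and zero cells

An all-or-nothing cell pattern (e.g. every labelled gene of a dimension
inside $S$) makes the raw odds ratio infinite and breaks comparison between
candidate sets. The package therefore defaults to the Haldane correction:
when any of the four cells is zero, 0.5 is added to *all* cells before the
ratio is formed. The correction is applied per dimension, only when needed,
and is configurable (`zero_cell = "none"` reproduces raw arithmetic,
including `Inf`). With Haldane in force the objective is finite for every
proper subset, which the optimizer relies on.

# The optimizer

`megaor_optimize()` performs steepest-ascent hill climbing in the space of
size-$n$ subsets: starting from a seeded uniform random set, all single-gene
swaps (one member out, one non-member in) are evaluated and the best
*strictly* improving swap is accepted, until no swap improves the objective
— the *stable status* — or `max_iters` swaps have been taken (a warning and
`converged = FALSE` result). The cOR trace over accepted swaps is strictly
increasing by construction.

Because cOR depends on $S$ only through the per-dimension counts of
labelled members, genes with identical label rows are exchangeable: the
climb is computed over label-pattern equivalence classes (at most $2^d$),
which is *exactly* the gene-level dynamics at a small fraction of the cost.
Ties between equally improving swaps are broken by the lexicographically
smallest (outgoing gene, incoming gene) pair, making a run a pure function
of (matrix, $n$, seed). A `method = "first"` mode accepts the first
improving swap in a seeded random scan order and is useful on very large
universes.

Hill climbing proves nothing about global optimality, so the package treats
multi-restart behaviour as part of the method: `megaor()` runs `restarts`
independent climbs (restart seeds derived deterministically from the base
seed) and `consensus_genes()` keeps the genes retained in **more than half**
of the stable sets — strictly more, so a gene in exactly 50% of runs is
excluded. On small instances where all $\binom{N}{n}$ subsets can be
enumerated, 50 restarts recover the exhaustive maximum essentially always
(this is one of the package's validation checks, at 100 random instances
with $N \le 12$).

## The size grid and the stable size

The target size $n$ is unknown in practice, so `megaor_grid()` fits a grid
of sizes and studies how the consensus evolves. Two diagnostics are
reported per adjacent size pair: *coverage* (the fraction of the smaller
size's consensus contained in the larger's — consensus sets are typically
nested) and *Jaccard similarity* (the stability measure). The **stable
size** is the smaller size of the first adjacent pair whose Jaccard
similarity reaches 0.9; when no pair qualifies, the most similar pair is
used. This formalizes "the consensus has converged": at sizes beyond the
evidence-rich core the optimizer pads the set with exchangeable low-evidence
genes whose occurrence frequencies stay below the 50% consensus cut, so the
consensus stops changing even as $n$ grows.

# Evidence-matrix construction

* Gene symbols are upper-cased and whitespace-trimmed on ingest. Duplicate
  records for one gene within a table are collapsed to the record with the
  minimum raw p (with a warning) — the same rule used to collapse
  methylation probes to genes (`collapse_probes()` keeps each gene's most
  significant probe).
* When a table carries no adjusted p-values, BH adjustment is computed *per
  table* — per dimension and per tissue — never jointly across dimensions,
  matching how the per-dimension thresholds are quoted in practice.
* All thresholds are strict inequalities (`adj_p < fdr`,
  `|log2FC| > cutoff`). A fold-change column `fc` is accepted on input and
  converted as `log2fc = log2(fc)`; the log2 form is canonical.
* Tissue-resolved dimensions (eQTL integration, TWAS) are labelled per
  tissue and merged by union: a gene significant in any tissue is
  significant for the dimension.
* The evidence-set (ES) matrix keeps genes with at least one positive
  label; the tissue-set (TS) matrix additionally admits all genes expressed
  above a cutoff (default 1, RPKM-like units, strict) in named reference
  tissues, as all-zero rows. The TS matrix probes robustness of the
  selection to diluting the universe with weakly supported genes.
* Pairwise dimension association uses two-sided Fisher tests over the
  matrix universe (association, not direction, is the question); the
  convention follows the published figure in conditioning on the ES
  universe, i.e. on genes with at least one line of evidence.

# Tissue-specific enrichment

The reference tool this stage emulates ships preprocessed tissue panels and
does not restate its scoring math, so the package uses a documented
surrogate: a leave-one-tissue-out z-like score
$(x_{gt} - \bar x_{g,-t}) / (s_{g,-t} + \varepsilon)$, with constant genes
scored 0 by convention, and per-tissue specific sets defined as the top 5%
of genes by score (ties broken by symbol for determinism; the fraction is a
parameter). Enrichment of a query list against each tissue set is a
one-sided (greater) Fisher test over a background universe — enrichment,
not depletion, is the question — with BH adjustment across tissues; both
raw and adjusted p-values are reported since conventions differ between
published analyses. `tsea_threshold_scan()` rebuilds the query at a ladder
of raw-p cutoffs (nested by construction) and emits the tissue × threshold
grid.

# Network characterization

`ppi_resampling_test()` asks whether a gene set carries more internal
interactions than size-matched random sets: the observed count uses the
annotated subset (V genes present in the network), and each null set draws
V nodes uniformly without replacement from the sampling universe. The
universe defaults to the network's node set — not the evidence universe —
so observed and null sets share the annotation rate; an explicit universe
can be supplied. The empirical p-value is $(r + 1)/(N + 1)$ with ties
counted as extreme, which can never be zero and is uniform on its grid
under the null in the absence of ties; the literal exceedance fraction
$r/N$ is available as `correction = "raw"`. Because counts are integers,
ties between null and observed counts bias the p-value conservatively by
about half the tie mass; the package's own calibration checks therefore use
graphs and set sizes with a wide count spread (SD ≈ 23, tie mass ≈ 2%), so
approximate uniformity is actually testable.

Drug-target crosstalk filters a confidence-scored network to edges linking
the candidate set to a target list with confidence strictly above 0.35 (the
usual medium-confidence cut); an edge at exactly the cutoff is excluded,
and genes occurring in both lists are reported separately rather than as
crosstalk. Gene-set enrichment against GMT collections is a one-sided
Fisher test with BH adjustment within the collection.

# The synthetic-study generator

`generate_evidence_study()` draws, per dimension, a 0/1 true-signal
indicator per gene — Bernoulli at `planted_hit_rate` (default 0.6) for the
200 planted disease genes and `background_hit_rate` (default 0.05) for the
rest of the 1,600-gene universe — and emits raw p-values: Beta(0.1, 1) for
signals (sub-uniform, realistically noisy; a single number makes the signal
p constant for degenerate checks) and Uniform(0, 1) otherwise. The
expression dimension adds log2 fold changes at ±`fc_effect` (default 1) for
signals; the methylation dimension emits 1–5 probes per gene with the
signal carried by one probe, plus the probe-to-gene map. Tissue-resolved
dimensions share a per-gene latent indicator with probability 0.9; high
sharing is deliberate — the association between the two genetically
regulated expression dimensions must be strong enough to survive
restriction to the evidence-set universe, which is where pairwise
association is tested, mirroring the dominant eQTL–TWAS dependence seen in
real multi-omics panels. Marginal rates are unchanged by the latent.
`simulate_binary_matrix()` exposes the indicator layer directly and is the
right input for studying the optimizer in isolation.

`generate_tissue_panel()` draws log-normal(meanlog 1, sdlog 1) baseline
expression and up-shifts each tissue's specific genes by a factor of 50,
with planted genes preferentially assigned to the planted tissues. The
large shift reflects genuinely tissue-restricted genes (tens-fold enriched
over other tissues) and keeps them at the top of the specificity ranking
despite the heavy-tailed baseline. `generate_ppi_network()` is an
Erdős–Rényi background with a boosted edge probability inside a planted
module and Uniform(0, 1) edge confidences.

What the generator does *not* emulate: SNP-level GWAS structure and LD,
expression-prediction weights, realistic methylation beta-value
distributions, degree heterogeneity of real PPI networks, and correlated
expression between related tissues in the panel. Passing tests therefore
demonstrate the pipeline's statistical machinery and its recovery behaviour
under a clean planted-signal model, not performance on consortium data.

# Numerical choices and boundary semantics

* Two-sided Fisher p-values use the point-probability ("minlike") rule —
  the sum of probabilities of all tables, at fixed margins, whose point
  probability does not exceed the observed table's (with a $1 + 10^{-7}$
  relative guard against rounding-only ties, the same convention as
  `stats::fisher.test`). Definitions differ across ecosystems, hence the
  explicit statement.
* BH adjustment is the standard step-up via `stats::p.adjust`; capped at 1,
  never below the raw p, rank-preserving.
* Strict boundaries throughout: `adj_p` exactly at an FDR cutoff is not
  significant; occurrence frequency exactly 0.5 is not consensus;
  confidence exactly 0.35 is not crosstalk.
* Degenerate inputs fail loudly: all-zero contingency tables, empty
  evidence, candidate sets that are empty or the whole universe, queries
  disjoint from the background, thresholds yielding empty tissue sets. An
  empty query at one scan threshold is reported as a missing column, not an
  error.
* All randomness flows from explicit integer seeds; a fixed master seed
  reproduces every output byte for byte (the pipeline fans the master seed
  out to stages by fixed offsets and records it, with a config hash, in
  every output header).

# Validation problem sizes

The shipped test suite validates: the cOR algebra against an independent
evaluation on 100 random instances and the optimizer against exhaustive
enumeration of all size-4 subsets (universes of 8–12 genes, 50 restarts);
planted-set recovery on a 1,600-gene, 200-planted, 5-dimension study over
the size grid 120–280 with 100 restarts (recovery ≥ 80% of planted genes,
contamination ≤ 10% of the non-planted universe at the stable size);
Fisher/BH/odds-ratio oracles on 1,000 random tables; null calibration of
the pairwise and resampling tests over 200 replicates each
(Kolmogorov–Smirnov at α = 0.01); planted-tissue recovery in 100 seeded
panel replicates; and end-to-end byte-level determinism of the pipeline.
These sizes were chosen as the smallest at which the properties are
statistically meaningful.

# Limitations

The optimizer is a local search; global optimality is certified only at
enumeration scale, and on real matrices the consensus-over-restarts
construction is the safeguard. The cOR penalty form and the single-swap
move set are this package's documented surrogates for a procedure whose
original description defers detail to prior work; both are pluggable. The
tissue-specificity score is a surrogate for the reference tool's
preprocessing, adequate for recovery of strongly tissue-restricted signal.
Rare-variant and copy-number evidence are out of scope, as is recomputing
gene-level statistics from raw SNP, expression-intensity or methylation
data: the package begins at gene-level association tables.
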