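---
title: "The Link Relevance Index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Link Relevance Index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lriNet)
```

## The model

`lriNet` scores genes by their linking role in a co-expression network
rather than by differential expression. A case/control study enters as a
*microarray experiment situation*: a gene panel, disjoint case and control
sample sets, and their log2 expression matrices
(`MicroarrayExperimentSituation`, a `SummarizedExperiment` whose `colData`
carries the group labels).

From the case/control matrices a co-expression network $(N, g^E)$ is built.
On it, the *microarray network game* assigns each link subset
$g \subseteq g^E$ the worth

$$v(g) \;=\; \frac{1}{n(g^E)} \sum_{i \in N(g^E)} u_{g_i^E}(g),$$

the unanimity game $u_T(g) = \mathbf{1}[T \subseteq g]$ anchored at each
active gene's star $g_i^E$ (the set of its incident links), averaged over
the $n(g^E)$ active genes. So $v$ counts, in normalised form, how many
genes see their entire local link neighbourhood realised inside $g$:
$v(\emptyset) = 0$, $v(g^E) = 1$, and $v$ is monotone under link-set
inclusion.

The **Link Relevance Index** of gene $i$ is the position value of this link
game: half the Shapley value of each of its incident links. For the game
above it collapses to the closed form

$$F_i \;=\; \frac{1}{2\,n(g^E)}\Big(1 + \sum_{j \in N_i(g^E)}
  \frac{1}{n_j(g^E)}\Big),$$

with $N_i$ the neighbours of $i$ and $n_j$ the neighbour count of $j$. The
allocation is efficient ($\sum_i F_i = 1$), anonymous, additive, and
invariant to superfluous links; every linked gene earns at least
$1/(2n(g^E))$ and isolated genes exactly 0 — which is why "salient gene"
(LRI $> 0$, strict) coincides with network membership, and why the score
rewards hubs connected to low-degree partners rather than large fold
changes.

### Three implementations, one answer

The package computes $F$ three independent ways: `lriClosed` (the closed
form above), `lriSum` (the star-sum form of the allocation restricted to
the unanimity decomposition), and `positionValueOracle` (brute-force
Shapley values of all links by factorial-weighted marginal contributions
over all $2^{|g^E|}$ coalitions). The star-sum form needs one reading
choice: the gene set it sums over is taken to be the genes incident to
$i$'s star *including $i$ itself* — with $i$ excluded, the hub of the
4-gene worked example would not receive its printed $18/48$. The three
implementations are asserted equal, as exact rationals, on a battery of
random networks; the oracle is capped at 16 links ($2^{16}$ coalitions,
well under a minute on one CPU) and refuses larger inputs rather than
silently approximating.

### Exact rational arithmetic

LRI values are ratios of small integers, and the method's guarantees
(triple equivalence, $\sum F_i = 1$) are exact statements. All score
computation therefore runs on integer numerator/denominator pairs held in
doubles (exact to $2^{53}$), reduced by gcd at each step with cross-gcd
reduction before products and an explicit overflow stop. Floats are a
derived view, rounded only at output (default 6 decimals in the score TSV,
configurable; full precision is kept internally and in the
fraction column). Ranked output breaks exact ties by sharing a rank and
ordering tied genes lexicographically, so tables are reproducible
byte-for-byte.

Degenerate inputs are contracts, not accidents: an edgeless network yields
an all-zero score table with a warning (strict thresholds legitimately
produce empty networks mid-pipeline), while building a *game* on an
edgeless network is an error, since $v$ is undefined with no active player.
Whether isolated genes appear in score tables with 0 or are dropped is a
flag (`includeIsolated`, default on).

## Building the network

The construction of $g^E$ from expression data is the one stage of the
analysis where a published convention is genuinely absent, so it is
explicit and configurable here (`buildNetwork`), with two deterministic
rules:

* **case-correlation** (default): link $i,j$ when $|r_{ij}| \ge \tau$ over
  the case samples; $\tau$ defaults to 0.9, chosen so that with about a
  hundred samples a null correlation essentially never crosses it while
  tightly co-regulated modules do;
* **differential-correlation**: link when
  $|r^{case}_{ij} - r^{control}_{ij}| \ge \tau$, for rewiring-style
  analyses.

Pearson (default) or Spearman correlation; a per-gene variance floor
(`minVariance`, default 0) plus automatic exclusion of zero-variance genes,
which are left isolated with a warning rather than producing undefined
correlations; at least 3 samples are required per correlated matrix.
Matrices must be finite — missing values are rejected, not imputed.
Edge calling by correlation-test p-values was deliberately left out: a
fixed threshold keeps the rule monotone (raising $\tau$ can only remove
links) and deterministic, both of which are tested properties. Whether a
real study should correlate case samples only, all samples, or a
differential contrast is a judgement call; the default follows the logic
that disease-state co-expression is the structure of interest.

## The comparison stages

**DEG arm** (`computeDeg`): per-gene two-sided Welch $t$-test on log2
values, LFC = mean(case) − mean(control), Benjamini–Hochberg adjustment
(via `stats::p.adjust`), and the dual filter adjusted $p \le \alpha$
(default 0.05) *and* $|LFC| \ge$ `lfcMin` (default 2). The filter is on the
absolute fold change: both directions of dysregulation count. A moderated
(empirical-Bayes) test was intentionally not used — this arm exists to
contrast salient genes with a conventional DEG list, and a plain Welch test
keeps it self-contained and exactly testable (its null calibration is
asserted: under a global null the raw $p \le 0.05$ fraction sits at 5%
within Monte-Carlo error on 10,000 genes).

**Overlap and enrichment** (`setOverlap`, `hypergeomEnrichment`,
`termKappa`, `groupTermsByKappa`): gene lists are compared after
whitespace trimming (optional case folding); identifiers are opaque strings
and any symbol/Entrez mapping is the caller's responsibility — unmapped ids
surface in the overlap counts instead of disappearing. Enrichment is the
right-sided hypergeometric tail (`stats::phyper`) of the observed overlap
given a *caller-supplied* universe — published universes vary by database
release, so none is baked in — with BH correction across terms, a
minimum-overlap filter (default 3 genes per term), and Cohen's-kappa
grouping of redundant terms at the conventional 0.4 threshold
(single-linkage over the pairwise kappa graph).

## The synthetic generator

`simulateExperiment` replaces the original cohort with data whose answer is
known. The model is single-factor Gaussian: background gene $g$, sample
$s$ gives $x = \mu_g + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$,
$\mu_g$ uniform on the baseline range; each planted module adds a shared
latent term $\lambda f_s$ ($f_s \sim N(0,1)$ per sample) to its members in
the groups where it is active, so any two members correlate at
$\lambda^2/(\lambda^2 + \sigma^2)$ in the population — a closed form the
tests check sample correlations against. DEG genes get $+\delta$ on case
means. Hubs are realised by letting one gene belong to two modules, which
raises its degree — the structure LRI rewards. The generator is seeded
once and consumes the RNG in a fixed order, so a config is reproducible
byte-for-byte; the seed is mandatory.

Defaults describe the reference validation scenario: 1000 genes, one
10-gene case-only module with $\lambda = 3$, $\sigma = 0.5$ (within-module
correlation $36/37 \approx 0.973$, comfortably above $\tau = 0.9$), ten
shifted genes at $\delta = 3$, 100 case and 100 control samples, log2
baselines on $[4, 12]$ — magnitudes typical of normalised two-channel or
oligo array data. Under these conditions LRI ranking recovers the planted
module at AUC $\ge 0.95$ (asserted), and the DEG arm flags all planted
shifts with empirical FDR $\le 0.1$ across seeds.

What the generator does *not* emulate: probe-level effects and summarisation,
normalisation artefacts, batch structure, heavy-tailed or correlated noise,
and overlapping module hierarchies. Passing recovery tests therefore shows
the pipeline is correct and well-calibrated under its stated model, not
that any particular threshold is optimal on real cohort data.

## Problem sizes used in validation

The shipped test suite works at desk scale, chosen so the full suite runs
in well under a minute: random-network batteries of ≤ 8 genes / ≤ 10 links
(200 networks for the triple-equivalence property), oracle enumeration up
to $2^{11}$–$2^{16}$ coalitions, simulations of 50–1000 genes and 20–200
samples, and a 10,000-gene null for DEG calibration. The closed form
itself is linear in edges after degree computation and handles
genome-scale networks; only the brute-force oracle is exponential by
design.

## Known limitations

* The exact-rational layer stops (rather than degrading to floats) if a
  numerator or denominator would exceed $2^{53}$; in practice this needs
  networks whose degree structure produces enormous denominator lcms,
  which we have not observed at realistic sparsity.
* Only undirected, unweighted networks; no Myerson-value or other
  allocation rules beyond what the oracle needs.
* The DEG arm's plain Welch test will be conservative relative to
  moderated tests at very small sample sizes.
* Enrichment requires the caller to supply consistent identifiers and a
  universe; no live ontology/pathway retrieval is attempted.
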