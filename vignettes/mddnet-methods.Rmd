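---
title: "Methods: similarity fusion and random-walk featurization for microbe-drug-disease networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity fusion and random-walk featurization for microbe-drug-disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddnet)
```

## The problem

Microbes sit between drugs and diseases: dysbiosis of a microbial community
accompanies many diseases, and drugs both act on and are metabolized by
microbes. Curated databases record thousands of validated microbe-disease
and microbe-drug associations, but the observed bipartite networks are
sparse — most true associations are unrecorded. `mddnet` scores candidate
associations from two sources of evidence: *topological* similarity (entities
linked to similar partner sets behave similarly) and *biological* similarity
(shared gene families, shared symptoms, shared chemical substructure), and
then joins predicted and known links through shared microbes into
disease-microbe-drug triples.

## The model, stage by stage

### Gaussian interaction-profile (GIP) kernels

Let $Y$ be the binary microbe $\times$ disease incidence matrix. Row $i$ is
the interaction profile $IP(m_i)$ of microbe $m_i$. Kernel similarity is

$$GM(m_i, m_j) = \exp\!\left(-\eta\,\lVert IP(m_i) - IP(m_j)\rVert^2\right),
\qquad
\eta = \eta' \Big/ \frac{1}{n}\sum_{k=1}^{n} \lVert IP(m_k)\rVert^2 ,$$

with $\eta' = 1$ by default. The bandwidth is therefore normalized by the
average association count per entity, so the kernel scale is comparable
across instantiations. The same operation, applied to the columns of $Y$,
gives the disease kernel $GD$; applied to the columns of the microbe
$\times$ drug matrix, the drug kernel.

Two numerical conventions are worth stating. First, the averaging count is
always the number of profiles on the chosen axis ($n_m$ for microbes, $n_d$
for diseases): the alternative of normalizing one axis by the other axis's
count is dimensionally inconsistent, and we do not do it. Second, entities
with all-zero profiles are allowed inside a non-degenerate matrix and follow
the formula as written; only a matrix whose profiles are *all* zero raises
an error, because the bandwidth is then undefined.

### Functional microbe similarity (FM)

Each microbe maps to a genome described by a gene-family presence/absence
vector; families carry a weighted functional-association network
(STRING-style confidence weights in $[0,1]$). For a genome pair, every
family is `shared`, `A_only`, `B_only` or `absent_both`.

* The **genome-content index** is, under the default shared-presence
  scoring, the number of families present in *both* genomes divided by the
  number of families in the set. On the canonical six-family toy set (two
  shared, two absent from both, one exclusive to each genome) this gives a
  raw score of 2 and an index of $2/6 = 0.33$. A half-weight variant (every
  matched family, present-in-both or absent-from-both, contributes half a
  point) is exposed as `scoring = "half_weight"`; it reproduces the same toy
  numbers, which is exactly why both readings are defensible — we default to
  shared presence because it is the standard genome-content measure.
* The **functional-connectivity index** is the number of network edges (at
  confidence $\ge$ `weight_cutoff`, default 0.4, a conventional
  medium-confidence cutoff) joining an `A_only` family to a `B_only` family,
  divided by $|A_{only}|\times|B_{only}|$, the number of possible
  cross-genomic pairs. The denominator could alternatively be read as all
  pairs among genome-exclusive families; that reading is available via
  `denominator = "all_exclusive_pairs"` but cross pairs is the default, as
  it matches the numerator's definition.
* `FM` combines the two as their arithmetic mean by default (`mode =
  "mean"`); either index alone is selectable. No authoritative combination
  rule exists, and the symmetric mean avoids privileging either signal.
  The diagonal is set to 1.

### Symptom-profile disease similarity (SDM)

Each disease $j$ is a vector of symptom association strengths $w_{i,j}$,
re-weighted TF-IDF style:

$$w'_{i,j} = w_{i,j}\,\log\frac{N}{n_i},$$

where $N$ is the number of diseases and $n_i$ the number of diseases with
symptom $i$ ($\log$ natural; the base rescales weights uniformly per
symptom and is fixed only for determinism). A symptom present in every
disease gets weight exactly 0; a symptom present in none is left at 0
rather than producing $\log\infty$. Similarity is the cosine of the
weighted vectors; all-zero vectors get similarity 0 to everything and 1 to
themselves.

### Drug structural similarity (DS)

The Tanimoto coefficient $|a \wedge b| / |a \vee b|$ between fingerprint
bit vectors, with entries below the acceptance threshold (default 0.8) set
to 0 rather than dropped. Keeping the zeros explicit matters because the
fusion rule below branches on $DS \ne 0$. Fingerprints are an *input*:
computing them from structures (SMILES/SDF) is out of scope, and drugs
without a fingerprint get an all-zero row and column.

### Conditional fusion

Kernel and biological similarities combine by conditional averaging:

$$S(i,j) = \begin{cases}
\dfrac{K(i,j) + B(i,j)}{2} & \text{if } B(i,j) \ne 0\\[4pt]
K(i,j) & \text{otherwise,}
\end{cases}$$

applied to $GM$/$FM$ for microbes and the drug kernel/$DS$ for drugs. For
diseases the default is the *unconditional* average $(GD + SDM)/2$, with
`disease_fusion = "conditional"` available; the unconditional form is the
printed rule for the disease layer, and we follow it while exposing the
plausible intended variant.

### Random walk with restart (RWR)

The fused similarity matrix is column-normalized into a transition matrix
$M$ (all-zero columns become the uniform column $1/n$, the standard
dangling-node teleport; the self-similarity diagonal is kept by default and
removable via `zero_diagonal`). The walk

$$p_i^{t+1} = (1-\varphi)\,M\,p_i^t + \varphi\,e_i$$

has a unique fixed point for $\varphi \in (0,1]$; $\varphi = 0.9$ by
default, which keeps most probability mass near the seed and makes the
profile a *local* network signature. The direct solver computes
$\varphi (I - (1-\varphi)M)^{-1} e_i$ exactly; the iterative solver stops
when the L1 change drops below `tol` ($10^{-10}$; convergence is geometric
with ratio $\le 1-\varphi$) and errors at `max_iter` (1000) rather than
returning an unconverged vector. Profiles are renormalized to sum exactly
1 — a near-no-op when $M$ is exactly stochastic — and assembled per entity
kind into feature matrices $F_d$, $F_m$ and the block matrix
$X = \begin{bmatrix} 0 & F_d \\ F_m & 0\end{bmatrix}$. $X$ is produced and
serialized for downstream use (e.g. as classifier features) but no
classifier is part of this package: prediction proceeds by the neighbor
rule below, which is self-contained and transparent.

### Neighbor-vote prediction

If microbe $X$ is similar to microbes $X_1 \ldots X_n$ and those are linked
to partner $L$, then $X$ is a candidate partner of $L$. Quantitatively,
with the microbe's own row excluded (self-exclusion prevents a known
association from trivially supporting itself):

* `weighted_sum` (default): $\sum_{j \ne i} S(i,j)\,Y(j,l)$ — the simplest
  faithful quantification of "similar microbes vote";
* `weighted_mean`: the same sum divided by $\sum_{j \ne i} S(i,j)$, bounded
  in $[0,1]$;
* `max`: the strongest single supporting neighbor.

Neighbors below `similarity_floor` contribute nothing. Candidates are all
$Y=0$ cells, ordered by score descending with lexicographic (partner id,
microbe id) tie-breaks so output files are reproducible. Triples are the
per-microbe Cartesian product of disease partners and drug partners, each
partner either known or predicted at score $\ge$ `triple_threshold`.

## The synthetic generator

Real curated inputs are large, license-encumbered and unnecessary for
verifying the mathematics, so `synth_generate()` builds all four input
kinds with one shared planted structure: microbes, diseases and drugs are
partitioned into matched blocks; associations appear with probability
`p_in` within matched blocks and `p_out` across; gene-family profiles,
symptom profiles and fingerprints are block prototypes flipped with
probability `noise`. Because one block structure couples every modality,
fused similarity is informative by construction, and a held-out fraction
of positive edges gives labeled positives for ranking evaluation
(`truth_table()` samples an equal number of never-observed cells as
negatives).

Defaults — 60 microbes, 20 diseases, 20 drugs, 3 blocks, `p_in` 0.6,
`p_out` 0.05, `noise` 0.05, 10% holdout — are the package's standing study
conditions: large enough that within/between-block density estimates sit
within binomial error of their targets, small enough that the full
pipeline runs in seconds. Side-data dimensions (40 families, 30 symptoms,
64-bit fingerprints) are small but realistic panel scales. Every draw
derives from a single integer seed through fixed per-modality sub-stream
offsets, so changing one modality's draw count never perturbs another's,
and identical configs are byte-identical.

What the generator does *not* emulate: the heavy-tailed degree
distributions of curated databases, taxonomy-level identifier noise,
cross-database entity-matching ambiguity, and correlated (non-independent)
evidence. Passing recovery tests on planted blocks therefore demonstrates
the machinery is correct and signal-responsive, not that any particular
real-data accuracy will be achieved.

## Numerical and design choices

* **Identifier normalization** is deliberately shallow: case-fold, collapse
  whitespace, drop punctuation-only tokens. No taxonomic or ontological
  reconciliation is attempted; merging source databases well is a curation
  problem, and silently aggressive matching hides data bugs. Unknown ids
  against a supplied registry are a hard error by default
  (`drop_unknown = TRUE` downgrades to a warning).
* **Directionality** (elevated/reduced microbe abundance) is carried as an
  edge annotation only; all similarity mathematics operates on binary
  profiles, and no improvement/exacerbation claim is derived from
  direction.
* **Registry order** is first-seen by default (lexicographic via `sort`);
  every matrix inherits it, which is what makes reruns byte-identical.
* **Degenerate inputs**: all-zero profile matrices error at bandwidth
  computation with an actionable message; all-zero similarity columns
  become uniform teleports; all-zero symptom or fingerprint vectors get
  zero similarity off-diagonal; empty exclusive-family sets give
  connectivity 0.
* **Problem sizes in the test suite** — oracle comparisons at 8–20
  entities, recovery at the 60/20/20 defaults — were chosen so each brute
  force oracle enumerates completely and the whole suite runs in seconds.

## Known limitations

Predictions are similarity-weighted extrapolations of curated bipartite
networks; they inherit every ascertainment bias in those networks (well
studied microbes accumulate associations and therefore votes). The
neighbor rule makes no attempt at causal direction. The package does not
compute fingerprints from chemical structures, reconcile taxonomies, or
mine literature for evidence; and the block feature matrix $X$ is an
export, not a trained model.
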