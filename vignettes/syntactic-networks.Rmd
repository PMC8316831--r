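---
title: "Syntactic dependency networks: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syntactic dependency networks: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntnet)
```

## The model

`syntnet` studies a corpus of dependency-parsed sentences as a single
graph. Each sentence assigns every word a governor (head); the root
carries the relation `HED` and governor index 0. The **word-type
syntactic network** collapses all sentences: vertices are distinct word
forms (NFC-normalized, whitespace-stripped; no case folding, which would
be meaningless for Chinese, the original target language of this kind of
analysis), and an undirected edge joins two types whenever one governs
the other anywhere in the corpus. Repeated pairs raise an edge
multiplicity that is kept for export and diagnostics only: all metrics
are defined on the simple graph, because the clustering, density and
centralization formulas assume loop-free, unweighted graphs. For the
same reason type-level self-loops (a form governing itself, e.g.
reduplication) are dropped and counted in the build log, and the
fictitious root node is never materialized.

The panel computed per network:

* **⟨k⟩** — mean number of distinct syntactic partners per word type,
  2M/N. A proxy for (inverse) lexical richness at fixed token count.
* **C** — mean local clustering `C_i = 2E_i / (k_i(k_i - 1))`, with
  `C_i = 0` for degree < 2 (those vertices stay in the mean; the global
  coefficient averages over all N vertices by definition).
* **L** — mean geodesic distance over unordered vertex pairs.
* **ND** — density M / (N(N−1)/2).
* **NC** — degree centralization, exact form
  `(N/(N-1)) (k_max/(N-1) - ND)`; the familiar large-N approximation
  `k_max/N - ND` is available as an option. The exact form is the
  default because it is well defined at every N and the two differ by
  O(1/N) (tested: < 0.01 for N ≥ 500).
* **γ′, R²** — the scale-free diagnostics below.

### L on disconnected networks

The textbook formula divides the distance sum by N(N−1)/2, which is
infinite as soon as one pair is unreachable — and real treebank networks
are routinely disconnected (short sentences with rare vocabulary form
satellites). The default therefore averages over *reachable* pairs, the
convention of the standard network tools for this analysis, and always
reports component diagnostics (`component_count`,
`largest_component_fraction`, `unreachable_pairs`). Two alternatives are
exposed: `all_pairs` (errors loudly on disconnected input rather than
returning an infinity) and `largest_component`. Which convention a given
published table used is usually unstated; providing all three makes the
choice explicit and auditable.

Geodesics come from breadth-first search implemented in a small C++
kernel (`src/bfs.cpp`) — the one place where pure R is an order of
magnitude too slow at corpus scale (N of a few thousand, ensembles of
30 replicates). The test suite checks the kernel against an independent
brute-force Floyd–Warshall oracle written in R, on hundreds of random
graphs, to 1e−12.

## Scale-freeness: two estimation frameworks, kept apart

A scale-free network has degree law P(k) ~ k^−γ. Empirical work in
quantitative linguistics commonly fits the **cumulative** distribution
P(K ≥ k) — which follows a power law with exponent γ′ = γ − 1 — by
ordinary least squares on log–log axes, and reports that regression's
R² as the goodness-of-fit measure, with "R² above 0.9" as the customary
scale-free criterion. Statisticians instead fit the discrete power law
by maximum likelihood (normalizing by the Hurwitz zeta) and compare
models by information criteria.

These two frameworks answer different questions and give numerically
different exponents, so `fit_power_law()` reports both, labeled:
`gamma_prime` (and `gamma = gamma_prime + 1`) with `R2` from the
cumulative OLS; `gamma_mle`, `loglik` and `aic` from the discrete MLE.
The AIC comparison against the Poisson fit (`compare_models()`) uses the
likelihood route only. Published AIC values for this analysis family
follow conventions that are rarely recoverable from the text (infinite
Poisson AICs, negative power-law AICs suggest a continuous-density fit);
only the *ordering* — power law preferred on corpus networks — is a
reproducible claim, and that is what the tests assert.

Details that matter: the cumulative is inclusive (first point exactly 1,
matching the Zipf framing); degree-0 vertices are excluded from the
distribution support; `k_min` defaults to 1 and is configurable (no
automatic xmin selection — out of scope); the Poisson R² is computed on
the same log10-cumulative domain as the power law's, conditioned on the
support floor, so it can be (and on heavy-tailed data is) strongly
negative. An exact AIC tie is resolved toward Poisson, the
fewer-assumptions default.

## Random baselines and the small-world verdict

The null model is the uniform G(N, M) graph matched on vertex and edge
counts — the two moments every published panel reports. Ensembles
(default 30 replicates, base seed 0, replicate r seeded `seed + r`) are
summarized with the same L and C conventions as the observed network,
alongside the closed forms C ≈ ⟨k⟩/N and L ≈ ln N / ln⟨k⟩ used as
cross-checks. A network is called small-world when
C_obs/C_rand ≥ τ_C = 5 and L_obs/L_rand ≤ τ_L = 1.2. Corpus networks
typically show C-ratios above 20 and L-ratios below 1, so these
thresholds are conservative; they are parameters, not constants, and the
report always carries the raw ratios. Degree-preserving (configuration
model) nulls and σ/ω small-world indices are deliberately out of scope.

## The statistical battery

`run_battery()` operates on a per-corpus metrics table with two
modalities (written, oral), learner levels 1–4 and a native reference.
For each metric in {⟨k⟩, γ′, C, L, ND, NC}:

* **Trend regressions** per modality, with proficiency coded 1, 2, 3, 4
  and native = 5. This coding is a derived convention: it is the unique
  one under which the complete published set of slopes, intercepts and
  R² values for this analysis reproduces, so the battery documents and
  defaults to it (`native_in_regression = TRUE`).
* **Cross-modality t-tests** on the learner levels only (n = 4 per
  modality; the native rows are reference points, not learner data).
  The variant is per-metric: Welch for ⟨k⟩ and NC, pooled for L, C and
  ND — the mapping implied by the degrees of freedom of the published
  comparisons — and configurable. γ′ has no documented variant (the
  source analysis reports only a bare p-value for it) and defaults to
  Welch; its t-test is computed but nothing is asserted about it.
* All tests are two-sided; no multiple-testing correction is applied
  (none is applied in the analyses this battery mirrors).

The OLS, t-test and Pearson routines are closed-form implementations,
cross-checked in the tests against `stats::lm`, `stats::t.test` and
`stats::cor.test`.

## The synthetic-data world

Real graded learner corpora are rarely redistributable, so the generator
(`generate_treebank()`, `default_level_plan()`) states a minimal world
with the features the pipeline is sensitive to:

* **Zipfian lexicon** — rank-r probability ∝ r^−s; the top 5% of ranks
  are flagged "function words". Defaults: s = 1.0 (written), 1.15
  (oral; steeper concentration encodes the more repetitive vocabulary of
  speech — a direction choice made once, not tuned).
* **Hub-biased random recursive trees** — token 1 is the root; each
  later token attaches to an earlier one with weight
  1 + hub_bias·[function word], hub_bias = 5. This produces the
  function-word hubs and heavy-tailed degree distributions of real
  syntactic networks. Linear order and projectivity are *not* modeled:
  the network depends only on the multiset of word pairs.
* **Sentence lengths** — truncated geometric, mean 12, range [2, 40].
* **Corpus scale** — 5,000 tokens per corpus; learner vocabulary
  500 / 800 / 2,000 / 4,000 by level (the graded-curriculum
  progression), native reference 6,000 (a choice: the native corpus is
  not part of any curriculum table).

What a green end-to-end test establishes: that the pipeline detects the
directional regularities it is designed to detect — cumulative fit
R² > 0.9 on hub-biased corpora, ⟨k⟩ (and with it C, ND) falling as
vocabulary grows. What it does not establish: anything about learner
errors, L1 transfer, morphology, genre, or the specific parameter
*values* of real corpora, none of which the generator attempts.

## Numerical and degenerate-input conventions

* Internal computation in double precision; report serialization rounds
  half-to-even at 3 decimals.
* Hurwitz zeta by direct summation (10⁴ terms) plus an Euler–Maclaurin
  tail; MLE exponent by `optimize()` on (1.0001, 20).
* Empty treebanks, all-punctuation treebanks, all-zero degree vectors,
  networks with < 2 vertices or no edges, constant regressors and
  zero-variance equal-mean t-tests raise classed validation errors
  (`syntnet_validation_error`), which the CLI maps to exit code 1
  (runtime errors map to 2).
* Multi-root and rootless sentences are tolerated with warnings —
  learner corpora are fragmentary and no repair rule is defensible; the
  root-label convention (`HED` ⟺ governor 0) is enforced strictly on
  the tabular dialect and downgraded to a warning for foreign CoNLL-U
  root labels.
* The redundant governor-form column of the tabular dialect is
  cross-checked on read; mismatches are reported, never silently fixed.

## Known limitations

* Vertices are surface forms by default; the `form_pos` keying mode
  separates homographs but no lemmatization is offered.
* No directed-network metrics, betweenness/eigenvector centrality,
  community detection, dependency-distance analysis, or
  Kolmogorov–Smirnov-style goodness-of-fit p-values.
* G(N, M) is the only null model.
* The power-law sampler truncates at k = 10⁵ (negligible tail mass for
  the exponents in realistic use, γ > 1.5).
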