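---
title: "Ranking disease-factor associations with an ontology-mapped semantic space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking disease-factor associations with an ontology-mapped semantic space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgf)
```

## The problem

A researcher who wants to know which factors the literature associates
with a disease faces two difficulties at once: the volume of publications,
and the fact that interesting associations are often *indirect* — two
concepts that rarely co-occur in a sentence may still be strongly linked
through shared intermediate vocabulary. `hgf` addresses both with latent
semantic analysis (LSA) over per-factor collections of titles and
abstracts, constrained to a domain-specific dictionary derived from a
controlled vocabulary (MeSH). The output for a query is a ranked list of
factors with cosine association scores, which a statistical disease model
then partitions into established, potential, and unknown associations.
Hypothesis generation targets the middle band: positive but weak scores,
where literature support exists but is not yet consolidated.

## Ontology mapping

MeSH headings are reduced to single words: the tokenizer lowercases,
NFKD-normalizes and strips diacritics, then splits on every run of
non-alphanumeric characters, so hyphens, commas and slashes all delimit.
`"Reproductive and Urinary Physiological Phenomena"` therefore yields five
tokens, of which filtering keeps four: duplicates, stop words (a packaged,
versioned English list; `"and"` is the canonical casualty) and words of
fewer than three characters are removed, and the survivors are sorted in
locale-independent byte order so identical inputs always serialize to
byte-identical dictionaries. Alphanumeric tokens such as `b12` are kept
deliberately — vitamin names depend on them. Only preferred headings are
used (entry-term synonyms are not expanded); with a full descriptor
export the dictionary lands in the 20k-word range, and every query must be
expressible in it. That is a feature, not a restriction: constraining the
vocabulary to curated subject headings is what keeps the semantic space
"crisp" and domain-specific.

## The semantic engine

Each citation (title and abstract, concatenated) is one document; one
column of the term–document matrix. We deliberately do **not** concatenate
a factor's documents into one blob: per-citation columns keep the matrix
well-conditioned and let the factor representation be chosen afterwards.

Three weighting schemes are available; the default is log-entropy
(`log(1 + tf)` local weight times a global entropy weight
`1 + Σⱼ p log p / log n`), the canonical choice for LSA. `none` (raw
counts) and `tf-idf` are selectable, and `none` is what the exactness
tests use, because with identity weighting the engine has a closed-form
ground truth (see below).

The truncated SVD `X ≈ U_k Σ_k V_k'` gives the reduced eigen space:

* document coordinates are the rows of `V_k Σ_k` (i.e. `U_k' X`),
* a query folds in as `Σ_k⁻¹ U_k' w(q)` — the standard pseudo-document
  projection — and is rescaled by `Σ_k` before cosine comparison, which
  places queries and documents in the same coordinate scale,
* a factor is the re-normalized centroid of its documents' coordinates.

The centroid choice matters: factor collections are badly imbalanced in
real corpora (hundreds vs. hundreds of thousands of abstracts per factor),
and a centroid is invariant to collection size, whereas a pooled
pseudo-document is dominated by volume. The pooled variant
(`factor_mode = "pseudo_doc"`) is provided for comparison.

`k` defaults to the smallest dimension capturing 80% of squared
singular-value mass, capped at 300; both the fraction and an explicit `k`
are user-settable, since no universally good dimension exists. Rankings
break score ties lexicographically by factor name so output is
deterministic. Vectors with norm below `1e-12` are treated as degenerate:
their cosine is reported as `NA`, never silently as 0, and they sort last.

A useful exactness property anchors the implementation: with identity
weighting and `k = rank`, the map `x -> U_k' x` is an isometry on the
column space, so for any query whose raw vector lies in the span of the
corpus (for instance the text of an indexed document), eigen-space cosines
equal raw vector-space cosines to machine precision. The test suite and
the acceptance script verify this on random planted corpora; for queries
*outside* the column span the projection discards the out-of-span
component, which is precisely the generalization LSA is used for, and
exact equality is neither expected nor asserted.

## The disease model

Across a factor set, association scores are modelled as a tri-modal
Gaussian-shaped curve

$$f(x) = \sum_{i=1}^{3} \alpha_i \exp\!\big(-((x - \mu_i)/\sigma_i)^2\big),$$

fitted to histogram heights (frequency per bin), not to a normalized
density — the model is a curve fit, so the exponent carries no 1/2 factor
and there is no normalizing constant; each component is a bump of height
α and half-width σ (equivalently a Gaussian with standard deviation
σ/√2). The three modes are read as unassociated (negative scores),
potentially associated (low positive), and established (high positive).

Numerical choices, all of which are visible in the API:

* **Histogram**: 20 equal-width bins over the full cosine range [−1, 1]
  by default — coarse enough for ~100 scores, configurable. Bins are
  left-closed, right-open, the last closed at +1.
* **Fitting**: Levenberg–Marquardt least squares with box constraints
  (α ≥ 0, σ ∈ [10⁻³, 2], μ ∈ [−1, 1]). The formula-interface optimizer
  can report a singular gradient on exactly tri-modal data, so the
  residual-function interface is used directly.
* **Initialization**: peak centers at the 10th/50th/90th weighted
  percentiles of the histogram, widths from the inter-percentile gaps,
  amplitudes from the corresponding bin heights; 20 seeded random
  restarts, keeping the best fit by R². Multimodal least squares has
  local minima and restarts are cheap at this problem size.
* **Goodness of fit**: R² = 1 − SS_res/SS_tot around the observed mean;
  undefined (an error, not a 0) when the observed heights are constant.
* **Components are relabeled** so μ₁ ≤ μ₂ ≤ μ₃ before any downstream use.

### Thresholds

The cutoff between adjacent components is the score where the two weighted
component curves intersect inside `(μᵢ, μᵢ₊₁)` — a closed-form quadratic
(linear when the σ's agree; the exact midpoint when both α and σ agree).
This is the principled reading of "thresholds from the parameters of the
distributions": to the left of the crossing the lower component dominates,
to the right the upper one. When amplitudes vanish or components overlap
so heavily that no crossing lies between the peaks, the package refuses to
guess: a fallback condition recommends manual cutoffs. Manual
configurations — two cutoffs such as 0.1/0.3, or three cutoffs such as
0.05/0.1/0.2 which insert an extra "low" band — reproduce the kind of
banding used in practice for well- and sparsely-documented diseases
respectively.

Band boundaries are left-closed: a score exactly equal to a cutoff joins
the band *above* it (the top band is closed at +1). One convention,
documented and tested, rather than per-dataset choices. Note this means a
score printed as exactly 0.1 under cutoffs 0.05/0.1/0.2 is categorized
as *potential*, not *low*.

## Networks

Categorized factor sets from two or more queries form a disease–disease
network. The default edge weight is the Jaccard overlap of the queries'
established ∪ potential sets (`jaccard_assoc`) — chosen because hypothesis
generation cares about the weakly-positive band, so restricting edges to
established factors only (`jaccard_established`, also available) would
discard exactly the signal of interest. Both queries having empty sets
makes the weight undefined and the edge is omitted; isolated nodes are
retained because absence of overlap is itself a finding. No edge rule is
canonical in the literature-based-discovery setting; Jaccard is this
package's explicit proposal, and the exports (GraphML, TSV) are meant for
downstream graph tooling rather than in-package analytics.

## What the synthetic data does and does not emulate

`generate_planted_corpus()` plants topics: each factor is assigned a
topic, and its documents draw `1 − noise` of their tokens uniformly from
the topic vocabulary and the rest from a shared background vocabulary.
The default configuration — 6 topics × 4 factors, 50 documents per factor,
80 tokens per document, 30% background noise — is the package's standard
evaluation condition: large enough that the engine must separate 24
factors across 1,200 documents, small enough to run in seconds. Document
lengths (~80 tokens) are scaled-down abstracts; vocabulary sizes (12 words
per topic, 40 background) keep the matrix around 100 × 1,200. The
recovery targets the generator supports (same-topic factors outrank
different-topic factors for a topic-word query; tri-modal parameter
recovery within ±0.05 on peak centers from 500 samples) are properties of
the *method*, demonstrated under controlled conditions.

What it does **not** emulate: Zipfian word frequencies, named entities,
synonymy and polysemy, citation-volume imbalance across factors, or the
systematic underestimation of generic factors' scores that volume
imbalance causes in real corpora (a known, unsolved bias of the
approach — see limitations). Passing the planted-corpus tests therefore
shows the machinery is correct, not that real-corpus rankings are
unbiased.

`sample_trimodal()` draws from the probability distribution proportional
to the fitted curve: component `i` is chosen with probability ∝ αᵢσᵢ
(each component integrates to αᵢσᵢ√π) and values are Gaussian with mean
μᵢ and standard deviation σᵢ/√2. Samples are clipped — not rejected — at
[−1, 1]; for the narrow, well-inside-range components used in testing the
boundary mass is negligible, but users placing wide components near ±1
should expect a small spike at the boundary.

## Reproducibility

Every stochastic entry point takes a seed; generators are deterministic
under a fixed seed, dictionaries serialize byte-identically, and the
pipeline manifest records settings, seeds, input checksums, and per-stage
timings so a silent input change is detectable. The pipeline reruns to
checksum-identical rankings.

## Known limitations

* **Generic-factor bias.** Factors with huge literatures are
  systematically underestimated and sparse factors overestimated; no
  normalization correction is implemented, so scores should be compared
  within a query's ranking, not across factors as absolute magnitudes.
* **Fixed mode count.** The disease model always fits three modes; a
  sharply bimodal score distribution (e.g. a clean planted corpus where
  scores are only ~0 or ~1) degenerates the fit and threshold derivation
  falls back to manual cutoffs.
* **Dictionary-bounded queries.** Query words outside the dictionary are
  rejected (with the unrecognized tokens listed), by design.
* **No incremental updates.** A changed corpus means a rebuilt space;
  fold-in is for queries, not for growing the index.
* **Tree structure unused.** MeSH tree numbers are parsed and stored but
  the hierarchy is not used to generate or group factors.
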