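---
title: "Methods: LDA topic trends in abstract corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LDA topic trends in abstract corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

topictrends implements a pipeline for tracking how the topical composition
of a literature corpus — typically PubMed-style abstracts — changes over
time: filter the records, fit a latent Dirichlet allocation (LDA) topic
model to a bag-of-words representation, pick the number of topics by
coherence, estimate weekly topic proportions by concatenating each week's
abstracts into one document, and compare curated category subsets through
distances between their topic distributions. This vignette explains the
models and the choices behind each stage; the README shows the worked
example.

## The corpus model and cleaning rules

A record is (`doc_id`, `date`, `text`, optional category labels). Three
exclusion rules remove records that would pollute the topic model: empty
abstracts, abstracts under 50 characters (too short to carry topical
signal; the count includes whitespace since there is no linguistic reason
to privilege non-space characters), and correction notices identified by
the literal substring "This corrects the article DOI". The marker is
matched case-sensitively as a substring — the conservative superset of a
sentence-level match. Each excluded record is counted under exactly one
rule, with precedence empty > too_short > correction_notice, so the
per-rule counts are disjoint and, together with the kept count, sum exactly
to the input count. Cleaning is idempotent.

Dates accept the Medline dialect (`2020 Mar 15`) and ISO (`2020-03-15`).
Truncated dates are imputed to the first day of the period and flagged
`missing_day`; unparseable dates are kept and flagged, never silently
dropped — downstream temporal binning refuses undated records explicitly.

## Preprocessing

Tokenization lowercases, strips punctuation and numerals, keeps alphabetic
tokens of length >= 2, and removes words from a stopword list frozen inside
the package (no downloads, no locale dependence; reproducibility beats
marginal list quality). No stemming is applied by default — topic-term
reports are more readable with surface forms, and the stopword/length
filters already remove most inflectional noise; pass a custom `stopwords`
argument to change the lexicon.

Bigram merging joins adjacent pairs (a, b) whose phrase score

    score(a, b) = (count(a, b) - min_count) * N / (count(a) * count(b))

exceeds a threshold (defaults min_count = 5, threshold = 10, the standard
defaults for this count-based score), in one greedy left-to-right pass so
overlapping candidates cannot both merge. This is how collocations such as
"mental health" become single model terms (`mental_health`).

The vocabulary keeps terms appearing in at least `no_below` = 2 documents
and at most `no_above` = 90% of them; indices are assigned in lexicographic
order so the same corpus always yields the same index assignment, which in
turn makes every downstream artifact byte-reproducible.

## LDA by collapsed Gibbs sampling

Each document mixes K topics with Dirichlet(α) proportions θ; each topic is
a distribution φ over the V vocabulary terms with symmetric Dirichlet(β)
prior. Inference is collapsed Gibbs sampling: θ and φ are integrated out
and per-token topic assignments are resampled from

    p(z = k | rest) ∝ (n_dk + α_k) (n_kw + β) / (n_k + Vβ).

Collapsed Gibbs was chosen over variational EM because it is simple,
seedable to bit-identical reruns, and checkable against exhaustive
enumeration of the assignment posterior on tiny instances — the package's
sampler is validated that way (agreement within 0.02 on a 2-document,
3-term, K = 2 instance).

Estimator schedule: the first half of the sweeps is burn-in; φ is the
smoothed estimate (n_kw + β)/(n_k + Vβ) averaged over every 10th
post-burn-in sweep (thinning reduces autocorrelation in the average; if the
schedule yields no samples the final state is used). Defaults are α = 1/K
(symmetric), β = 0.01, 500 sweeps — conventional weakly-informative
settings; all are overridable.

Held-out documents are folded in: φ stays fixed, the document's assignments
are Gibbs-sampled from p(z = k) ∝ (n_dk + α_k) φ_kw, and θ is the average
of (n_dk + α_k)/(n_d + Σα) over thinned post-burn-in sweeps. An empty
document returns the prior mean α/Σα. Each document row draws its own RNG
stream from (seed, row), so an estimate never depends on which other
documents are inferred in the same call — and single-document inference
equals the corresponding row of batch inference, a property the category
profiles rely on.

The sampler owns a Mersenne-twister RNG seeded from the user seed,
independent of R's RNG state: identical inputs and seed give bit-identical
φ and θ, which is what makes whole pipeline runs byte-identical.

Perplexity is exp(−Σ_d log p(w_d) / Σ_d N_d) with per-token likelihood
p(w) = Σ_k θ_k φ_kw from the folded-in θ; a model with uniform rows scores
exactly V, a useful calibration point. Topic difference between two models
is the matrix of Jaccard distances between top-term sets, used to compare
fits (a model against itself gives a zero diagonal).

## Choosing K and ranking terms

`select_k()` trains one model per candidate K (default grid capped at 50)
on a common seed and keeps the model with the best aggregate coherence,
ties toward the smaller K. The default measure is UMass coherence over the
top 10 terms per topic: for pairs (w_i later than w_j in the ranking),
Σ log[(D(w_i, w_j) + 1) / D(w_j)] with D counting documents; it needs only
document co-occurrence counts. NPMI over width-10 sliding windows is
available for sensitivity checks. The aggregate is the arithmetic mean over
topics. A pair whose conditioning term never occurs in the scoring
documents is skipped rather than crashing.

A known limitation, reproducible with the synthetic generator: when K
exceeds the true topic count, the surplus topics are near-duplicates of
true topics whose top terms still co-occur, so UMass does not penalize them
strongly; on a 5-topic synthetic corpus the selection prefers K = 5 over
K = 10 only in a modest majority of seeds. Coherence selection separates
far-off K reliably (K = 2 and K = 20 lose clearly) but adjacent
over-parameterizations are close calls — which mirrors how these scores
behave on real corpora.

Topic terms are reported by relevance,

    r(w, k) = λ log φ_kw + (1 − λ) log(φ_kw / p_w),

blending within-topic probability with lift over the corpus marginal p_w
(computed with a 0.5 pseudo-count so the log is finite). λ = 1 is pure
frequency, λ = 0 pure lift; the default λ = 0.6 is the conventional
balance for topic interpretation. `term_weight_in_topics()` answers the
converse question — where does a single word like "mask" carry weight —
by reading the φ column across topics.

## Weekly trends

Records are binned by ISO week (Monday start — the reproducible convention,
since nothing anchors week boundaries in the data). Weeks before a
configurable boundary (default 2020-02-01) are pooled into one merged bin,
because early corpus weeks are typically too sparse for stable weekly
estimates. Zero-count calendar weeks between the first and last occupied
bins are retained, and the first weekly bin is clipped at the merge
boundary so bins are disjoint date intervals.

The train/test split is by whole bins: the boundary whose cumulative
document fraction is nearest the target (default 0.8) ends the training
period — a week is never divided, mirroring a date-cutoff split.

For the trend matrix, each bin's abstracts are concatenated into a single
bag-of-words document (order is irrelevant) and folded in, giving a
bins × topics matrix whose rows sum to 1. Concatenation pools roughly
`docs_per_bin × doc_length` tokens per bin, so the per-bin estimate is far
more stable than averaging per-document θ's, at the cost of weighting
documents by length. Empty bins receive the prior mean and are flagged.

Weekly document counts are summarized by a least-squares Gaussian fit
A·exp(−(t−μ)²/2σ²) over bin midpoints (Levenberg–Marquardt, initialized
from the counts' moments), describing the rise-and-fall of publication
volume. The exported trend CSV orders topics by descending overall
proportion; the heatmap's optional "bilinear" color scale is a two-segment
linear mapping with a breakpoint at the matrix median, which spreads color
resolution across the many small proportions — it affects rendering only,
never exported numbers.

## Category subdivision

For each curated category, the member abstracts are concatenated (a
multi-label abstract contributes its full token counts to every one of its
categories — no fractional weighting) and folded in, yielding a topic
profile per category. Profiles are reported both raw and max-normalized
(divided by the category's largest proportion, so the dominant topic is
exactly 1), and compared pairwise — optionally against the whole-corpus
distribution — with the Hellinger distance

    H(P, Q) = sqrt(1/2 Σ_i (sqrt(p_i) − sqrt(q_i))²),

a bounded [0, 1] metric on the simplex. Temporal curves are compared with
the normalized Euclidean distance, defined here as the root-mean-square
difference — the 1/T normalization makes values comparable across time
spans of different length. Jaccard distances between topics' top-100 term
sets (set size configurable) quantify topic overlap.

## The synthetic generator

Because the original corpora behind such analyses are live query results
with no deposited accession, validation rests on synthetic corpora with
known structure. The generator runs the LDA generative process forward with
time-varying mixtures: K topic-word rows (Dirichlet with concentration 0.1
over V terms — sparse, well-separated topics — or exactly disjoint uniform
blocks for worst-case-separation tests); per-topic trajectory curves
(constant, linear, Gaussian pulse, logistic) stacked and renormalized into
per-bin mixture means m_b; per document θ ~ Dirichlet(alpha_scale · m_b),
token count ~ Poisson(mean 120, abstract-like), tokens by z ~ θ,
w ~ φ_z. The default `alpha_scale = 5` keeps documents leaning toward a
few topics without being degenerate.

Token indices are rendered as purely alphabetic pseudo-words ("waaab", ...)
so the generated text passes through the real tokenizer and vocabulary
builder rather than bypassing them. The reference trajectory set mimics
dynamics seen in pandemic-literature corpora: an early Gaussian pulse (bin
3, width 2 — a topic that spikes and fades), a logistic riser, a linear
faller, and flat remainders. Contamination replaces a small fraction of
documents (defaults 2% too-short, 1% correction notices) so the cleaning
rules are exercised with known ground truth. Category labels, when
requested, tilt a labeled document's Dirichlet mean 80% toward its
categories' topics (a soft tilt rather than a hard restriction, matching
the overlap real curated categories show); about half the clean documents
are labeled and a quarter of those carry two labels.

What the generator does not emulate: real word frequencies (Zipfian tails),
document-length/topic correlations, vocabulary drift over time, or
multilingual noise. Passing recovery tests therefore demonstrates that the
inference machinery is correct and well-calibrated, not that any particular
real-corpus result is right.

## Validation scale and results

The test-suite conditions were sized to run comfortably on one CPU: topic
recovery uses K = 5, V = 200, 2000 documents of ~80 tokens, α = 0.1,
β = 0.01, 500 sweeps (matched-topic mean Hellinger, exact assignment by
permutation search, lands well under the 0.15 acceptance bound); trend
recovery uses 26 bins × 200 documents with the reference trajectories
(per-topic Pearson r against truth > 0.9, pulse peak inside its window);
model selection uses a 1000-document fixture, grid {2, 5, 10, 20}, 200
sweeps per candidate, 10 seeds. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the measured numbers as JSON; every
empirical claim above is computed there or in the test suite, not asserted
from memory.

## Known limitations

- UMass coherence weakly separates the true K from mild
  over-parameterization (see above).
- The Gibbs sampler is single-chain; multimodality is handled by seeds,
  not by chain diagnostics.
- Fold-in θ for very short documents is prior-dominated — by design, but
  worth remembering when interpreting sparse early bins.
- The Medline reader covers the PMID/DP/AB tag dialect with continuation
  lines; exotic field repetitions are concatenated rather than modeled.
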