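# topictrends

Temporal topic-trend analysis for literature abstract corpora.

Researchers tracking a fast-moving literature (the motivating case is the
COVID-19 abstract flood of 2020) need to know *what* the corpus is about
and *how that changes week by week*: which themes spiked early and faded,
which grew steadily, and how curated subject categories decompose into
finer-grained topics. topictrends packages that workflow end to end:

1. **Ingest** — read abstract records (Medline-dialect flat files, JSON
   lines, or CSV), drop empty abstracts, abstracts under 50 characters and
   correction notices ("This corrects the article DOI …"), with a
   conservation-checked exclusion report.
2. **Model** — fit latent Dirichlet allocation by a seed-deterministic
   collapsed Gibbs sampler (Rcpp): documents mix K topics with
   Dirichlet(α) proportions θ, topics are distributions φ over terms with
   prior β, and tokens are resampled from
   p(z = k | ·) ∝ (n_dk + α_k)(n_kw + β)/(n_k + Vβ).
   The topic count is selected by UMass coherence over a grid capped at
   K = 50; topic terms are ranked by relevance
   r(w,k) = λ log φ_kw + (1−λ) log(φ_kw / p_w), λ = 0.6.
3. **Trends** — bin records by ISO week (sparse early weeks merged into
   one bin), split train/test by whole bins at the boundary nearest an
   8:2 document ratio, concatenate each bin's abstracts into a single
   document, and fold it in to get a bins × topics trend matrix. Weekly
   counts get a least-squares Gaussian fit A·exp(−(t−μ)²/2σ²).
4. **Compare** — per-category topic profiles (concatenate, fold in,
   max-normalize), Hellinger distances H(P,Q) = √(½ Σ(√pᵢ−√qᵢ)²) between
   categories and against the whole corpus, normalized (RMS) Euclidean
   distance between temporal curves, and Jaccard distances between topics'
   top-term sets.
5. **Simulate** — generate synthetic corpora from a known LDA process with
   time-varying topic trajectories (pulse / rising / falling / flat),
   planted contamination and category labels, so every stage above can be
   validated against ground truth.

Everything is tidyverse-shaped: record tables in and tibbles out, fitted
objects with `tidy()` / `glance()` methods and `autoplot()` heatmaps.

## Worked example

A synthetic 26-week corpus with an early-pulse topic, a rising topic and a
falling one, generated with known ground truth, then analysed exactly as a
real corpus would be:

```r
library(topictrends)

phi <- gen_topics(K = 5, V = 200, concentration = 0.1, seed = 11)
sim <- gen_corpus(phi, trajectories = default_trajectories(5),
                  n_bins = 26, docs_per_bin = 200, seed = 12)

kept <- clean_corpus(sim$records)
exclusion_report(kept)
#> # A tibble: 1 × 5
#>   n_input n_kept empty too_short correction_notice
#>     <int>  <int> <int>     <int>             <int>
#> 1    5200   5054     0       107                39

corpus <- bow_corpus(tokenize(kept$text), sim$truth$vocab,
                     doc_ids = kept$doc_id)
fit <- train_lda(corpus, K = 5, alpha = 0.1, beta = 0.01,
                 iterations = 300, seed = 13)
fit
#> LDA topic model (collapsed Gibbs)
#>   topics K = 5, vocabulary V = 200
#>   priors: alpha = 0.1 (symmetric), beta = 0.01
#>   300 sweeps (burn-in 150, thin 10, 15 phi samples), seed 13

match_topics(fit$phi, sim$truth$phi)   # recovered topics vs truth
#> # A tibble: 5 × 3
#>   topic_a topic_b distance
#>     <int>   <int>    <dbl>
#> 1       1       1    0.211
#> 2       2       2    0.218
#> 3       3       5    0.228
#> 4       4       4    0.233
#> 5       5       3    0.255
```

(The generator's vocabulary is used directly so the fitted topic-word
matrix aligns column-for-column with the planted one; on a real corpus,
`preprocess_corpus()` builds the vocabulary from the text.) Every fitted
topic pairs off with exactly one planted topic at Hellinger ≈ 0.21–0.26 on
a 0–1 scale — far below the distances between different topics, which sit
near 1 for these sparse topic-word vectors. The mixtures here are
deliberately diffuse (`alpha_scale = 5`); concentrated documents bring the
matched distances down to ~0.03. Weekly trends:

```r
binned <- assign_bins(kept, merge_before = NULL)
wd <- weekly_documents(binned, sim$truth$vocab)
tm <- trend_matrix(fit, wd, seed = 14)
tm
#> Trend matrix: 26 time bins x 5 topics
head(tidy(tm), 3)
#> # A tibble: 3 × 5
#>   bin      start      topic n_docs proportion
#>   <chr>    <date>     <int>  <int>      <dbl>
#> 1 2020-W06 2020-02-03     1    191      0.347
#> 2 2020-W07 2020-02-10     1    190      0.431
#> 3 2020-W08 2020-02-17     1    195      0.487
autoplot(tm, scale = "bilinear")       # weekly heatmap

split_train_test(bin_table(binned), 0.8)$achieved_fraction
#> [1] 0.8074792
```

Each trend-matrix row is the topic mixture of that week's concatenated
abstracts (rows sum to 1); the pulse topic peaks in its planted window.
Weekly publication volume with a rise-and-fall shape gets its standard
summary:

```r
set.seed(15)
weekly <- round(180 * exp(-((1:26) - 14)^2 / (2 * 4.5^2)) + rnorm(26, sd = 4))
fit_gaussian_counts(pmax(weekly, 0))
#> Gaussian count fit: A = 179.33, mu = 14.00, sigma = 4.53, RSS = 309
```

Category subdivision works the same way through `category_profiles()` and
`hellinger_matrix()`, and `relevance_terms(fit, term_marginals(corpus))`
lists each topic's top terms.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/topictrends.R simulate --out fixture --seed 1
Rscript inst/cli/topictrends.R ingest --input fixture/records.jsonl --out runs/ingest
Rscript inst/cli/topictrends.R train --ingest-dir runs/ingest --k-grid 2,5,10 --out runs/train
Rscript inst/cli/topictrends.R trends --ingest-dir runs/ingest --model runs/train/model --out runs/trends
```

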