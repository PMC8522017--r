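# End-to-end pipeline stages: each reads plain-text inputs, runs one stage,
# writes its outputs plus a manifest (effective config, seed, input hashes,
# output paths) under the output directory, and returns its results
# invisibly.  One seed governs all stochastic work in a stage.

log_msg <- function(...) message(sprintf(...))

write_manifest <- function(out_dir, command, config, inputs, outputs) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    config = config,
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs)),
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Ingest: read, clean and preprocess an abstract corpus
#'
#' Reads records, applies the exclusion filters, tokenizes (with optional
#' bigram merging), builds the vocabulary and the sparse document-term
#' matrix, and writes `records_clean.jsonl`, `exclusion_report.csv`,
#' `vocabulary.tsv` and `corpus.mtx` to `out`.
#'
#' @param input path to a Medline, JSONL or CSV record file.
#' @param out output directory.
#' @param format input format for [read_records()].
#' @param min_chars,correction_marker cleaning rules ([clean_corpus()]).
#' @param bigrams,min_count,threshold,no_below,no_above preprocessing
#'   settings ([preprocess_corpus()]).
#' @return Invisibly, a list with `records`, `report`, `vocab`, `corpus`.
#' @export
run_ingest <- function(input, out, format = "auto", min_chars = 50,
                       correction_marker = "This corrects the article DOI",
                       bigrams = TRUE, min_count = 5, threshold = 10,
                       no_below = 2, no_above = 0.9) {
  ensure_dir(out)
  records <- read_records(input, format)
  kept <- clean_corpus(records, min_chars = min_chars,
                       correction_marker = correction_marker)
  report <- exclusion_report(kept)
  if (!nrow(kept)) abort("no records survive cleaning; nothing to ingest")
  pp <- preprocess_corpus(kept, bigrams = bigrams, min_count = min_count,
                          threshold = threshold, no_below = no_below,
                          no_above = no_above)
  rec_path <- file.path(out, "records_clean.jsonl")
  write_records(kept, rec_path, "jsonl")
  readr::write_csv(report, file.path(out, "exclusion_report.csv"),
                   progress = FALSE)
  write_bow_corpus(pp$corpus, pp$vocab, out)
  log_msg("ingest: %d/%d records kept (%d empty, %d too short, %d corrections); V = %d",
          report$n_kept, report$n_input, report$empty, report$too_short,
          report$correction_notice, nrow(pp$vocab))
  cfg <- list(format = format, min_chars = min_chars,
              correction_marker = correction_marker, bigrams = bigrams,
              min_count = min_count, threshold = threshold,
              no_below = no_below, no_above = no_above)
  write_manifest(out, "ingest", cfg, input,
                 c(rec_path, file.path(out, c("exclusion_report.csv",
                                              "vocabulary.tsv", "corpus.mtx"))))
  invisible(list(records = kept, report = report, vocab = pp$vocab,
                 corpus = pp$corpus))
}

read_ingest_dir <- function(dir) {
  records <- read_records(file.path(dir, "records_clean.jsonl"), "jsonl")
  vocab <- readr::read_tsv(file.path(dir, "vocabulary.tsv"),
                           col_types = "icn", progress = FALSE)
  corpus <- methods::as(Matrix::readMM(file.path(dir, "corpus.mtx")),
                        "CsparseMatrix")
  corpus <- methods::as(corpus, "generalMatrix")
  dimnames(corpus) <- list(records$doc_id, vocab$term)
  list(records = records, vocab = vocab, corpus = corpus)
}

#' Train: fit (or select) an LDA model on an ingested corpus
#'
#' With a single `k` trains one model; with `k_grid` trains one model per
#' candidate and keeps the coherence-best ([select_k()]).  Writes the model
#' (`model/model.json`, `model/phi.csv`), the selection table
#' (`selection.csv`) and the relevance-ranked topic terms
#' (`topic_terms.tsv`).
#'
#' @param ingest_dir directory produced by [run_ingest()].
#' @param out output directory.
#' @param k fixed topic count (ignored when `k_grid` is given).
#' @param k_grid candidate topic counts for selection.
#' @param iterations Gibbs sweeps (default 500).
#' @param seed sampler seed.
#' @param alpha,beta priors ([train_lda()]).
#' @param lambda relevance blend weight (default 0.6).
#' @param topn terms per topic in reports (default 10).
#' @return Invisibly, a list with `model`, `scores`, `terms_report`.
#' @export
run_train <- function(ingest_dir, out, k = NULL, k_grid = NULL,
                      iterations = 500, seed = 1, alpha = NULL, beta = 0.01,
                      lambda = 0.6, topn = 10) {
  ensure_dir(out)
  ing <- read_ingest_dir(ingest_dir)
  tokens <- tokenize(ing$records$text)
  if (is.null(k) && is.null(k_grid)) abort("provide k or k_grid")
  if (!is.null(k_grid)) {
    sel <- select_k(ing$corpus, tokens, k_grid = k_grid, seed = seed,
                    iterations = iterations, beta = beta,
                    alpha = if (is.null(alpha)) 1 / max(k_grid) else alpha)
    model <- sel$model
    scores <- sel$scores
  } else {
    model <- train_lda(ing$corpus, K = k,
                       alpha = if (is.null(alpha)) 1 / k else alpha,
                       beta = beta, iterations = iterations, seed = seed)
    coh <- coherence(model, tokens)
    scores <- tibble::tibble(K = k, coherence = coh$score,
                             perplexity = perplexity(model, ing$corpus,
                                                     seed = seed),
                             seed = seed)
  }
  model_dir <- file.path(out, "model")
  write_lda_model(model, model_dir)
  readr::write_csv(scores, file.path(out, "selection.csv"), progress = FALSE)
  report <- relevance_terms(model, term_marginals(ing$corpus),
                            lambda = lambda, topn = topn)
  write_topic_terms(report, file.path(out, "topic_terms.tsv"))
  log_msg("train: selected K = %d (coherence %.4f)", model$K,
          scores$coherence[scores$K == model$K][[1]])
  cfg <- list(k = k, k_grid = k_grid, iterations = iterations, seed = seed,
              beta = beta, lambda = lambda, topn = topn)
  write_manifest(out, "train", cfg,
                 file.path(ingest_dir, c("records_clean.jsonl", "corpus.mtx",
                                         "vocabulary.tsv")),
                 c(file.path(model_dir, c("model.json", "phi.csv")),
                   file.path(out, c("selection.csv", "topic_terms.tsv"))))
  invisible(list(model = model, scores = scores, terms_report = report))
}

#' Trends: weekly binning, train/test split and the trend matrix
#'
#' Bins the ingested records by ISO week (with the early merged bin),
#' reports the whole-bin train/test split nearest the requested fraction,
#' concatenates each bin's abstracts, infers per-bin topic proportions, and
#' fits a Gaussian to the weekly counts.  Writes `trend_matrix.csv`,
#' `bin_counts.csv`, `split.json` and `gaussian_fit.json`.
#'
#' @param ingest_dir directory produced by [run_ingest()].
#' @param model_dir model directory produced by [run_train()] (the `model/`
#'   subdirectory).
#' @param out output directory.
#' @param train_fraction target training fraction (default 0.8).
#' @param merge_before merged-bin boundary date ([assign_bins()]).
#' @param iterations,seed fold-in settings.
#' @return Invisibly, a list with `trend` (a [trend_matrix()]), `split`,
#'   `gaussian` (or NULL when the fit fails).
#' @export
run_trends <- function(ingest_dir, model_dir, out, train_fraction = 0.8,
                       merge_before = as.Date("2020-02-01"),
                       iterations = 200, seed = 1) {
  ensure_dir(out)
  ing <- read_ingest_dir(ingest_dir)
  model <- read_lda_model(model_dir)
  binned <- assign_bins(ing$records, merge_before = merge_before)
  bins <- bin_table(binned)
  split <- split_train_test(bins, train_fraction)
  wd <- weekly_documents(binned, ing$vocab)
  tm <- trend_matrix(model, wd, iterations = iterations, seed = seed)
  write_trend_matrix(tm, file.path(out, "trend_matrix.csv"),
                     counts_path = file.path(out, "bin_counts.csv"))
  jsonlite::write_json(
    list(cutoff_date = format(split$cutoff_date),
         achieved_fraction = split$achieved_fraction,
         n_train_bins = nrow(split$train), n_test_bins = nrow(split$test),
         n_train_docs = sum(split$train$n_docs),
         n_test_docs = sum(split$test$n_docs)),
    file.path(out, "split.json"), auto_unbox = TRUE, digits = NA)
  gauss <- tryCatch(fit_gaussian_counts(bins), error = function(e) {
    warn(paste0("Gaussian count fit failed: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(gauss)) {
    jsonlite::write_json(
      list(amplitude = gauss$amplitude, mu = gauss$mu,
           mu_date = if (!is.null(gauss$mu_date)) format(gauss$mu_date) else NULL,
           sigma_days = gauss$sigma, rss = gauss$rss),
      file.path(out, "gaussian_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  log_msg("trends: %d bins, cutoff %s (%.1f%% train)", nrow(bins),
          format(split$cutoff_date), 100 * split$achieved_fraction)
  cfg <- list(train_fraction = train_fraction,
              merge_before = format(as.Date(merge_before)),
              iterations = iterations, seed = seed)
  write_manifest(out, "trends", cfg,
                 c(file.path(ingest_dir, "records_clean.jsonl"),
                   file.path(model_dir, "phi.csv")),
                 file.path(out, c("trend_matrix.csv", "bin_counts.csv",
                                  "split.json")))
  invisible(list(trend = tm, split = split, gaussian = gauss))
}

#' Categories: per-category topic profiles and their Hellinger matrix
#'
#' Builds each category's concatenated document from the label map (or the
#' records' own `categories` column), infers its topic profile, and writes
#' `category_profiles.csv` plus `hellinger_matrix.csv` (with the whole
#' corpus appended as a reference distribution).
#'
#' @param ingest_dir directory produced by [run_ingest()].
#' @param model_dir model directory produced by [run_train()].
#' @param out output directory.
#' @param category_map_path optional two-column label file
#'   ([read_category_map()]); default: labels carried in the records.
#' @param iterations,seed fold-in settings.
#' @return Invisibly, a list with `profiles`, `hellinger`, `corpus_theta`.
#' @export
run_categories <- function(ingest_dir, model_dir, out,
                           category_map_path = NULL, iterations = 200,
                           seed = 1) {
  ensure_dir(out)
  ing <- read_ingest_dir(ingest_dir)
  model <- read_lda_model(model_dir)
  cmap <- if (!is.null(category_map_path)) {
    read_category_map(category_map_path)
  } else {
    tibble::tibble(
      doc_id = rep(ing$records$doc_id, lengths(ing$records$categories)),
      category = unlist(ing$records$categories, use.names = FALSE) %||%
        character())
  }
  if (!nrow(cmap)) abort("no category labels available; provide category_map_path")
  profiles <- category_profiles(model, ing$corpus, cmap,
                                iterations = iterations, seed = seed)
  whole <- infer_theta(model, Matrix::colSums(ing$corpus),
                       iterations = iterations, seed = seed)
  hm <- hellinger_matrix(profiles, reference = whole)
  write_category_profiles(profiles, file.path(out, "category_profiles.csv"))
  write_distance_matrix(hm, file.path(out, "hellinger_matrix.csv"))
  log_msg("categories: %d profiles over K = %d topics",
          nrow(profile_matrix(profiles)), model$K)
  cfg <- list(category_map = category_map_path, iterations = iterations,
              seed = seed)
  write_manifest(out, "categories", cfg,
                 c(file.path(ingest_dir, "records_clean.jsonl"),
                   file.path(model_dir, "phi.csv")),
                 file.path(out, c("category_profiles.csv",
                                  "hellinger_matrix.csv")))
  invisible(list(profiles = profiles, hellinger = hm, corpus_theta = whole))
}

#' Simulate: write a synthetic fixture corpus with ground truth
#'
#' @param out fixture directory.
#' @param K,V topic and vocabulary counts.
#' @param n_bins,docs_per_bin,doc_length,alpha_scale,contamination,categories
#'   generator settings ([gen_corpus()]).
#' @param topic_mode,concentration topic settings ([gen_topics()]).
#' @param seed RNG seed.
#' @return Invisibly, the [gen_corpus()] result.
#' @export
run_simulate <- function(out, K = 5, V = 200, n_bins = 26,
                         docs_per_bin = 200, doc_length = 120,
                         alpha_scale = 5,
                         contamination = list(short_frac = 0.02,
                                              correction_frac = 0.01),
                         categories = NULL, topic_mode = "dirichlet",
                         concentration = 0.1, seed = 1) {
  ensure_dir(out)
  phi <- gen_topics(K, V, concentration = concentration, mode = topic_mode,
                    seed = seed)
  sim <- gen_corpus(phi, n_bins = n_bins, docs_per_bin = docs_per_bin,
                    doc_length = doc_length, alpha_scale = alpha_scale,
                    contamination = contamination, categories = categories,
                    seed = seed)
  write_fixture(sim, out)
  log_msg("simulate: %d records over %d bins written to %s",
          nrow(sim$records), n_bins, out)
  cfg <- list(K = K, V = V, n_bins = n_bins, docs_per_bin = docs_per_bin,
              doc_length = doc_length, alpha_scale = alpha_scale,
              contamination = contamination, topic_mode = topic_mode,
              concentration = concentration, seed = seed)
  write_manifest(out, "simulate", cfg, character(),
                 file.path(out, c("records.jsonl", "truth/phi.csv",
                                  "truth/trajectories.csv",
                                  "truth/meta.json")))
  invisible(sim)
}
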