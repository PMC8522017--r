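# Coherence scoring, topic-count selection and relevance-ranked topic terms.

#' Topic coherence
#'
#' Scores each topic's top-`topn` terms by corpus co-occurrence and
#' averages over topics.  Two measures:
#' \describe{
#'   \item{umass}{per topic, \eqn{\sum_{i>j} \log[(D(w_i, w_j) + 1) /
#'     D(w_j)]} over ordered top-term pairs, where \eqn{D} counts documents
#'     containing a term (or both).  Values are <= 0; closer to 0 means the
#'     top terms co-occur in the documents that contain them.}
#'   \item{npmi}{mean pairwise normalized pointwise mutual information over
#'     top-term pairs, with probabilities estimated from boolean sliding
#'     windows of width `window` over each document; in \[-1, 1\].}
#' }
#' Top terms that never occur in the scoring corpus contribute the smoothed
#' value implied by each formula rather than an error.
#'
#' @param model a trained [train_lda()] model.
#' @param docs list of token vectors to score against (typically the
#'   training corpus tokens).
#' @param topn number of top terms per topic (default 10).
#' @param measure `"umass"` (default) or `"npmi"`.
#' @param window sliding-window width for npmi (default 10).
#' @return An object of class `coherence_result`: list with `per_topic`
#'   (length-K numeric), `score` (their arithmetic mean) and `measure`.
#' @export
coherence <- function(model, docs, topn = 10, measure = c("umass", "npmi"),
                      window = 10) {
  stopifnot(inherits(model, "lda_model"), topn >= 2, length(docs) > 0)
  measure <- match.arg(measure)
  tops <- top_terms(model, topn)
  per_topic <- if (measure == "umass") {
    umass_scores(tops, docs)
  } else {
    npmi_scores(tops, docs, window)
  }
  structure(list(per_topic = per_topic, score = mean(per_topic),
                 measure = measure),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("Topic coherence (%s): %.4f over %d topics\n", x$measure,
              x$score, length(x$per_topic)))
  invisible(x)
}

#' @describeIn coherence Per-topic coherence as a tibble.
#' @param x a `coherence_result`.
#' @param ... unused.
#' @method tidy coherence_result
#' @export
tidy.coherence_result <- function(x, ...) {
  tibble::tibble(topic = seq_along(x$per_topic), coherence = x$per_topic,
                 measure = x$measure)
}

umass_scores <- function(tops, docs) {
  terms <- unique(unlist(tops))
  # document occurrence sets per term, as sorted integer doc ids
  occ <- purrr::map(terms, function(t) {
    which(purrr::map_lgl(docs, function(tk) t %in% tk))
  })
  names(occ) <- terms
  co_count <- function(a, b) length(intersect(occ[[a]], occ[[b]]))
  purrr::map_dbl(tops, function(tt) {
    s <- 0
    n_pairs <- 0L
    for (i in seq_along(tt)) {
      for (j in seq_len(i - 1)) {
        # w_i ranks below w_j; condition on the higher-ranked term w_j
        dj <- length(occ[[tt[[j]]]])
        if (dj == 0) next  # term absent from scoring docs: pair undefined, skipped
        s <- s + log((co_count(tt[[i]], tt[[j]]) + 1) / dj)
        n_pairs <- n_pairs + 1L
      }
    }
    if (n_pairs == 0) 0 else s
  })
}

npmi_scores <- function(tops, docs, window) {
  terms <- unique(unlist(tops))
  term_id <- stats::setNames(seq_along(terms), terms)
  n_terms <- length(terms)
  single <- numeric(n_terms)
  pair <- new.env(parent = emptyenv())
  n_windows <- 0
  for (tk in docs) {
    n <- length(tk)
    if (n == 0) next
    n_win <- max(1L, n - window + 1L)
    for (s in seq_len(n_win)) {
      w <- tk[s:min(n, s + window - 1L)]
      present <- unique(term_id[intersect(unique(w), terms)])
      if (length(present)) {
        single[present] <- single[present] + 1
        if (length(present) > 1) {
          present <- sort(present)
          for (i in seq_along(present)) {
            for (j in seq_len(i - 1)) {
              key <- paste0(present[[j]], "_", present[[i]])
              pair[[key]] <- (if (is.null(pair[[key]])) 0 else pair[[key]]) + 1
            }
          }
        }
      }
      n_windows <- n_windows + 1
    }
  }
  eps <- 1e-12
  purrr::map_dbl(tops, function(tt) {
    ids <- term_id[tt]
    vals <- c()
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1)) {
        a <- min(ids[[i]], ids[[j]]); b <- max(ids[[i]], ids[[j]])
        pj <- single[a] / n_windows
        pi_ <- single[b] / n_windows
        key <- paste0(a, "_", b)
        pij <- (if (is.null(pair[[key]])) 0 else pair[[key]]) / n_windows
        npmi <- log((pij + eps) / (pi_ * pj + eps)) / -log(pij + eps)
        vals <- c(vals, npmi)
      }
    }
    if (!length(vals)) 0 else mean(vals)
  })
}

#' Select the topic count by coherence over a grid
#'
#' Trains one model per candidate K on a common seed, scores each by
#' aggregate coherence, and returns the best model (ties broken toward the
#' smaller K) together with the full score table.  The default grid caps K
#' at 50.
#'
#' @param corpus document-term matrix ([bow_corpus()]).
#' @param docs token lists for coherence scoring.
#' @param k_grid candidate topic counts (default `c(5, 10, 20, 30, 40, 50)`).
#' @param seed sampler seed shared across candidates.
#' @param iterations Gibbs sweeps per candidate (default 300).
#' @param measure,topn coherence settings, see [coherence()].
#' @param k_max guard on the largest admissible K (default 50); raise it
#'   explicitly to search beyond.
#' @param with_perplexity also record fold-in perplexity per candidate
#'   (default TRUE).
#' @param ... further arguments to [train_lda()].
#' @return A list with `model` (the selected `lda_model`), `K` (its topic
#'   count) and `scores` (tibble with one row per grid entry: `K`,
#'   `coherence`, `perplexity`, `seed`).
#' @export
select_k <- function(corpus, docs, k_grid = c(5, 10, 20, 30, 40, 50),
                     seed = 1, iterations = 300,
                     measure = c("umass", "npmi"), topn = 10, k_max = 50,
                     with_perplexity = TRUE, ...) {
  measure <- match.arg(measure)
  if (!length(k_grid)) abort("k_grid is empty")
  if (max(k_grid) > k_max) {
    abort(sprintf("k_grid exceeds the topic-count cap (%d); raise k_max to override", k_max))
  }
  fits <- vector("list", length(k_grid))
  rows <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    K <- k_grid[[i]]
    fit <- tryCatch(
      train_lda(corpus, K = K, iterations = iterations, seed = seed, ...),
      error = function(e) abort(paste0("training failed for K = ", K, ": ",
                                       conditionMessage(e))))
    coh <- coherence(fit, docs, topn = topn, measure = measure)
    perp <- if (with_perplexity) perplexity(fit, corpus, seed = seed) else NA_real_
    fits[[i]] <- fit
    rows[[i]] <- tibble::tibble(K = K, coherence = coh$score,
                                perplexity = perp, seed = seed)
  }
  scores <- dplyr::bind_rows(rows)
  ord <- order(-scores$coherence, scores$K)
  best <- ord[[1]]
  list(model = fits[[best]], K = k_grid[[best]], scores = scores)
}

#' Relevance-ranked topic terms
#'
#' Ranks each topic's terms by the relevance score
#' \deqn{r(w, k) = \lambda \log \phi_{kw} + (1 - \lambda)
#'   \log(\phi_{kw} / p_w)}
#' which blends a term's within-topic probability with its lift over the
#' corpus marginal \eqn{p_w}.  `lambda = 1` reduces to ranking by
#' within-topic frequency and `lambda = 0` to ranking by lift; the default
#' 0.6 balances the two.
#'
#' @param model a trained model.
#' @param term_marginal strictly positive corpus term probabilities over
#'   the model vocabulary ([term_marginals()]).
#' @param lambda blend weight in \[0, 1\] (default 0.6).
#' @param topn terms reported per topic (default 10).
#' @return A tibble with columns `topic`, `rank`, `term`, `phi`,
#'   `relevance`, ties broken by term index.
#' @export
relevance_terms <- function(model, term_marginal, lambda = 0.6, topn = 10) {
  stopifnot(inherits(model, "lda_model"))
  if (lambda < 0 || lambda > 1) abort("lambda must lie in [0, 1]")
  if (length(term_marginal) != model$V) {
    abort("term_marginal must have one entry per vocabulary term")
  }
  if (!is.null(names(term_marginal))) {
    term_marginal <- term_marginal[model$terms]
  }
  if (any(!is.finite(term_marginal)) || any(term_marginal <= 0)) {
    abort("term_marginal must be strictly positive on the model vocabulary")
  }
  rows <- purrr::map(seq_len(model$K), function(k) {
    phi_k <- model$phi[k, ]
    r <- lambda * log(phi_k) + (1 - lambda) * log(phi_k / term_marginal)
    ord <- order(-r, seq_len(model$V))[seq_len(min(topn, model$V))]
    tibble::tibble(topic = k, rank = seq_along(ord), term = model$terms[ord],
                   phi = as.numeric(phi_k[ord]), relevance = as.numeric(r[ord]))
  })
  dplyr::bind_rows(rows)
}

#' Export a topic-term relevance report as TSV
#'
#' @param report tibble from [relevance_terms()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topic_terms <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
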