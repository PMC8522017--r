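# LDA by collapsed Gibbs sampling: training, fold-in inference, perplexity
# and topic difference.

# sparse document-term matrix -> 0-based (doc, term, count) triplets, ordered
# by document so token instances are grouped per document in the sampler
corpus_triplets <- function(corpus) {
  tri <- Matrix::mat2triplet(corpus)
  ord <- order(tri$i, tri$j)
  list(doc = as.integer(tri$i[ord] - 1L), term = as.integer(tri$j[ord] - 1L),
       count = as.integer(tri$x[ord]))
}

as_dtm <- function(corpus) {
  if (inherits(corpus, "sparseMatrix")) {
    return(methods::as(methods::as(corpus, "CsparseMatrix"), "generalMatrix"))
  }
  if (is.matrix(corpus)) {
    return(methods::as(Matrix::Matrix(corpus, sparse = TRUE), "generalMatrix"))
  }
  abort("corpus must be a (sparse) document-term matrix; see bow_corpus()")
}

expand_alpha <- function(alpha, K) {
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(alpha) != K) abort("alpha must be a scalar or a length-K vector")
  if (any(alpha <= 0)) abort("alpha entries must be positive")
  alpha
}

#' Train an LDA topic model by collapsed Gibbs sampling
#'
#' Fits a K-topic latent Dirichlet allocation model to a bag-of-words
#' corpus.  Inference is collapsed Gibbs sampling: per-token topic
#' assignments are resampled from
#' \deqn{p(z = k \mid \cdot) \propto (n_{dk} + \alpha_k)\,
#'   \frac{n_{kw} + \beta}{n_k + V\beta}}
#' with the topic proportions and topic-word distributions integrated out.
#' The topic-word matrix phi is the smoothed estimator
#' \eqn{(n_{kw}+\beta)/(n_k+V\beta)} averaged over every `thin`-th sweep
#' after a burn-in of the first half of the chain.  A fixed seed makes runs
#' bit-identical for identical inputs.
#'
#' @param corpus document-term count matrix ([bow_corpus()]); rows are
#'   documents, columns vocabulary terms.
#' @param K number of topics (>= 1).
#' @param alpha document-topic Dirichlet prior: scalar or length-K vector
#'   (default `1/K`, symmetric).
#' @param beta topic-word Dirichlet prior, positive scalar (default 0.01).
#' @param iterations Gibbs sweeps over the corpus (default 500).
#' @param seed integer seed for the sampler's own RNG.
#' @param burnin sweeps discarded before averaging (default
#'   `floor(iterations/2)`).
#' @param thin keep every `thin`-th post-burn-in sweep (default 10).
#' @return An object of class `lda_model`: a list with `K`, `V`, `alpha`
#'   (length K), `beta`, `phi` (K x V row-stochastic matrix, term column
#'   names), `seed`, `iterations`, `terms`.
#' @seealso [infer_theta()], [perplexity()], [topic_diff()]
#' @export
train_lda <- function(corpus, K, alpha = 1 / K, beta = 0.01,
                      iterations = 500, seed = 1,
                      burnin = floor(iterations / 2), thin = 10) {
  corpus <- as_dtm(corpus)
  if (nrow(corpus) == 0 || sum(corpus) == 0) abort("corpus is empty")
  if (K < 1) abort("K must be at least 1")
  if (beta <= 0) abort("beta must be positive")
  alpha <- expand_alpha(alpha, K)
  tri <- corpus_triplets(corpus)
  fit <- .gibbs_train(tri$doc, tri$term, tri$count,
                      D = nrow(corpus), V = ncol(corpus), K = as.integer(K),
                      alpha = alpha, beta = beta,
                      iterations = as.integer(iterations),
                      burnin = as.integer(burnin), thin = as.integer(thin),
                      seed = as.numeric(seed))
  phi <- fit$phi
  colnames(phi) <- colnames(corpus)
  rownames(phi) <- paste0("topic", seq_len(K))
  structure(
    list(K = as.integer(K), V = ncol(corpus), alpha = alpha, beta = beta,
         phi = phi, seed = as.integer(seed),
         iterations = as.integer(iterations), burnin = as.integer(burnin),
         thin = as.integer(thin), n_samples = fit$n_samples,
         terms = colnames(corpus)),
    class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("LDA topic model (collapsed Gibbs)\n")
  cat(sprintf("  topics K = %d, vocabulary V = %d\n", x$K, x$V))
  cat(sprintf("  priors: alpha = %s, beta = %g\n",
              if (length(unique(x$alpha)) == 1)
                sprintf("%g (symmetric)", x$alpha[[1]])
              else sprintf("vector of %d", length(x$alpha)), x$beta))
  cat(sprintf("  %d sweeps (burn-in %d, thin %d, %d phi samples), seed %d\n",
              x$iterations, x$burnin, x$thin, x$n_samples, x$seed))
  invisible(x)
}

#' @describeIn train_lda Long tibble of the topic-word distribution:
#'   columns `topic`, `term`, `phi`.
#' @param x,object an `lda_model`.
#' @param ... unused.
#' @method tidy lda_model
#' @export
tidy.lda_model <- function(x, ...) {
  tibble::tibble(
    topic = rep(seq_len(x$K), times = x$V),
    term = rep(x$terms, each = x$K),
    phi = as.vector(x$phi))
}

#' @describeIn train_lda One-row model summary.
#' @method glance lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(K = x$K, V = x$V, beta = x$beta,
                 alpha_sum = sum(x$alpha), iterations = x$iterations,
                 seed = x$seed)
}

# normalize a single-document input (bow tibble from to_bow(), named counts,
# bare counts over the full vocabulary, or 1-row sparse matrix) to a 1 x V row
as_doc_row <- function(doc, model) {
  V <- model$V
  if (inherits(doc, "sparseMatrix") || is.matrix(doc)) {
    if (ncol(doc) != V) abort("document matrix must have V columns")
    return(as_dtm(doc))
  }
  if (is.data.frame(doc)) {
    if (!all(c("index", "count") %in% names(doc))) {
      abort("bag-of-words data frame needs columns `index` and `count`")
    }
    if (nrow(doc) && (max(doc$index) > V || min(doc$index) < 1)) {
      abort("term index out of vocabulary range")
    }
    return(Matrix::sparseMatrix(i = rep(1L, nrow(doc)), j = doc$index,
                                x = doc$count, dims = c(1L, V)))
  }
  if (is.numeric(doc)) {
    if (!is.null(names(doc))) {
      idx <- match(names(doc), model$terms)
      if (anyNA(idx)) {
        abort(paste0("term(s) outside the model vocabulary: ",
                     paste(utils::head(names(doc)[is.na(idx)], 3), collapse = ", ")))
      }
      return(Matrix::sparseMatrix(i = rep(1L, length(idx)), j = idx, x = doc,
                                  dims = c(1L, V)))
    }
    if (length(doc) != V) abort("unnamed count vector must have length V")
    return(as_dtm(matrix(doc, nrow = 1)))
  }
  abort("unsupported document representation")
}

#' Infer topic proportions for held-out documents (fold-in)
#'
#' Runs Gibbs sampling over a document's topic assignments with the trained
#' topic-word distributions held fixed, and averages
#' \eqn{(n_{dk}+\alpha_k)/(n_d+\sum\alpha)} over thinned post-burn-in
#' sweeps.  An empty document returns the prior mean
#' \eqn{\alpha/\sum\alpha}.  Rows are inferred independently, each on its
#' own RNG stream derived from `seed`, so a document's estimate does not
#' depend on its companions.
#'
#' @param model a trained [train_lda()] model.
#' @param docs one document ([to_bow()] tibble, named counts, length-V count
#'   vector) or a document-term matrix of held-out documents.
#' @param iterations Gibbs sweeps per document (default 200).
#' @param seed sampler seed.
#' @param burnin,thin averaging schedule, defaults as in [train_lda()].
#' @return For a matrix input, a D x K matrix of topic proportions (rows sum
#'   to 1); for a single document, a length-K numeric vector.
#' @export
infer_theta <- function(model, docs, iterations = 200, seed = 1,
                        burnin = floor(iterations / 2), thin = 10) {
  stopifnot(inherits(model, "lda_model"))
  single <- !(inherits(docs, "sparseMatrix") || is.matrix(docs))
  dtm <- as_doc_row_or_matrix(docs, model)
  tri <- corpus_triplets(dtm)
  theta <- .gibbs_infer(model$phi, tri$doc, tri$term, tri$count,
                        D = nrow(dtm), alpha = model$alpha,
                        iterations = as.integer(iterations),
                        burnin = as.integer(burnin), thin = as.integer(thin),
                        seed = as.numeric(seed))
  colnames(theta) <- rownames(model$phi)
  rownames(theta) <- rownames(dtm)
  if (single) drop(theta[1, ]) else theta
}

as_doc_row_or_matrix <- function(docs, model) {
  if (inherits(docs, "sparseMatrix") || is.matrix(docs)) {
    dtm <- as_dtm(docs)
    if (ncol(dtm) != model$V) abort("document matrix must have V columns")
    dtm
  } else {
    as_doc_row(docs, model)
  }
}

#' Held-out perplexity
#'
#' Computes \eqn{\exp(-\sum_d \log p(w_d) / \sum_d N_d)} where each
#' document's token likelihood uses its fold-in topic proportions:
#' \eqn{p(w) = \sum_k \theta_k \phi_{kw}}.  Lower is better; a model with
#' uniform topic-word rows has perplexity exactly V.
#'
#' @inheritParams infer_theta
#' @param heldout held-out document-term matrix (or single document).
#' @return A positive number (always >= 1).
#' @export
perplexity <- function(model, heldout, iterations = 200, seed = 1) {
  stopifnot(inherits(model, "lda_model"))
  dtm <- as_doc_row_or_matrix(heldout, model)
  n_tokens <- Matrix::rowSums(dtm)
  if (sum(n_tokens) == 0) abort("held-out set contains no tokens")
  theta <- infer_theta(model, dtm, iterations = iterations, seed = seed)
  pw <- theta %*% model$phi                  # D x V mixture probabilities
  tri <- Matrix::mat2triplet(dtm)
  loglik <- sum(tri$x * log(pw[cbind(tri$i, tri$j)]))
  exp(-loglik / sum(n_tokens))
}

#' Top terms of each topic
#'
#' @param model a trained model.
#' @param topn number of terms per topic.
#' @return A list of `topn` character vectors, one per topic, ordered by
#'   descending phi (ties by term index).
#' @export
top_terms <- function(model, topn = 10) {
  stopifnot(inherits(model, "lda_model"))
  if (topn > model$V) abort("topn exceeds the vocabulary size")
  purrr::map(seq_len(model$K), function(k) {
    ord <- order(-model$phi[k, ], seq_len(model$V))
    model$terms[ord[seq_len(topn)]]
  })
}

#' Topic difference between two models
#'
#' Pairwise Jaccard distance between the top-`topn` term sets of every
#' topic pair across two models sharing a vocabulary space; used to track
#' sampler convergence (a model compared to itself gives a zero diagonal).
#'
#' @param model_a,model_b trained models over the same vocabulary.
#' @param topn number of top terms per topic set (default 100).
#' @return A list with `matrix` (K_a x K_b Jaccard distances) and `mean`
#'   (its arithmetic mean).
#' @export
topic_diff <- function(model_a, model_b, topn = 100) {
  stopifnot(inherits(model_a, "lda_model"), inherits(model_b, "lda_model"))
  if (!identical(model_a$terms, model_b$terms)) {
    abort("models must share the same vocabulary (identical term sets and order)")
  }
  sets_a <- top_terms(model_a, topn)
  sets_b <- top_terms(model_b, topn)
  m <- matrix(0, model_a$K, model_b$K,
              dimnames = list(rownames(model_a$phi), rownames(model_b$phi)))
  for (i in seq_len(model_a$K)) {
    for (j in seq_len(model_b$K)) {
      m[i, j] <- jaccard_distance(sets_a[[i]], sets_b[[j]])
    }
  }
  list(matrix = m, mean = mean(m))
}

#' Serialize / load an LDA model
#'
#' Writes a JSON header (K, V, priors, seed, sweep schedule, terms) and the
#' dense phi matrix as CSV; [read_lda_model()] validates that every re-read
#' phi row sums to 1.
#'
#' @param model a trained model.
#' @param dir output directory; writes `model.json` and `phi.csv`.
#' @return `dir`, invisibly.
#' @export
write_lda_model <- function(model, dir) {
  stopifnot(inherits(model, "lda_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- model[c("K", "V", "alpha", "beta", "seed", "iterations",
                    "burnin", "thin", "n_samples", "terms")]
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  phi_df <- as.data.frame(model$phi)
  readr::write_csv(tibble::as_tibble(phi_df), file.path(dir, "phi.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_lda_model
#' @param dir directory written by [write_lda_model()].
#' @export
read_lda_model <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"),
                                simplifyVector = TRUE)
  phi <- as.matrix(readr::read_csv(file.path(dir, "phi.csv"),
                                   col_types = readr::cols(.default = "d"),
                                   progress = FALSE))
  rs <- rowSums(phi)
  if (any(abs(rs - 1) > 1e-6)) abort("phi rows do not sum to 1; corrupt model file")
  phi <- phi / rs   # restore row sums lost to decimal truncation
  colnames(phi) <- header$terms
  rownames(phi) <- paste0("topic", seq_len(header$K))
  structure(
    list(K = as.integer(header$K), V = as.integer(header$V),
         alpha = as.numeric(header$alpha), beta = as.numeric(header$beta),
         phi = phi, seed = as.integer(header$seed),
         iterations = as.integer(header$iterations),
         burnin = as.integer(header$burnin), thin = as.integer(header$thin),
         n_samples = as.integer(header$n_samples),
         terms = as.character(header$terms)),
    class = "lda_model")
}
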