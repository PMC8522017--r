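# Distances between topic distributions and term sets, category topic
# profiles, and per-term topic weights.

check_prob_vector <- function(p, arg, tol = 1e-6) {
  if (!is.numeric(p)) abort(paste0(arg, " must be numeric"))
  if (any(p < 0)) abort(paste0(arg, " has negative entries"))
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("%s does not sum to 1 (sum = %.8f)", arg, sum(p)))
  }
  invisible(p)
}

#' Hellinger distance between probability vectors
#'
#' \deqn{H(P,Q) = \sqrt{\tfrac{1}{2} \sum_i (\sqrt{p_i} - \sqrt{q_i})^2}}
#' Bounded in \[0, 1\]: 0 for identical distributions, 1 for disjoint
#' support.  Symmetric and a metric (triangle inequality holds).
#'
#' @param p,q probability vectors of equal length (entries >= 0, each
#'   summing to 1 within `tol`).
#' @param tol normalization tolerance (default 1e-6).
#' @return A number in \[0, 1\].
#' @examples
#' hellinger(c(0.5, 0.5), c(0.25, 0.75))
#' @export
hellinger <- function(p, q, tol = 1e-6) {
  if (length(p) != length(q)) abort("p and q must have the same length")
  check_prob_vector(p, "p", tol)
  check_prob_vector(q, "q", tol)
  d2 <- 0.5 * sum((sqrt(p) - sqrt(q))^2)
  sqrt(min(max(d2, 0), 1))
}

#' Normalized Euclidean distance between two curves
#'
#' Root-mean-square difference
#' \deqn{NED(x, y) = \sqrt{\sum_t (x_t - y_t)^2 / T}}
#' used to compare temporal topic-proportion curves of equal length; the
#' 1/T normalization makes values comparable across time spans.
#'
#' @param x,y numeric vectors of equal length T >= 1.
#' @return A nonnegative number.
#' @export
normalized_euclidean <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (!length(x)) abort("vectors must be nonempty")
  sqrt(sum((x - y)^2) / length(x))
}

#' Jaccard distance between term sets
#'
#' \eqn{1 - |a \cap b| / |a \cup b|}; 0 for identical sets (and for two
#' empty sets, by convention), 1 for disjoint nonempty sets.
#'
#' @param a,b character vectors interpreted as sets (duplicates ignored).
#' @return A number in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Per-category topic profiles
#'
#' For every category, concatenates the abstracts of its member documents
#' into one bag-of-words document (a multi-label document contributes its
#' tokens to every one of its categories), infers that document's topic
#' proportions by fold-in, and records both the proportions and their
#' max-normalized form (divided by the largest proportion in the category,
#' so the dominant topic is exactly 1).
#'
#' @param model a trained [train_lda()] model.
#' @param corpus document-term matrix of the records, rows named by
#'   `doc_id` ([bow_corpus()]).
#' @param category_map tibble of (`doc_id`, `category`) pairs
#'   ([read_category_map()]).
#' @param iterations,seed fold-in settings, see [infer_theta()].
#' @return An object of class `category_profiles`: a tibble with one row
#'   per (category, topic) pair and columns `category`, `n_docs`, `topic`,
#'   `proportion`, `norm_proportion`; the C x K theta matrix is attached as
#'   attribute `"theta"`.  Categories with no matching documents are
#'   dropped with a warning.
#' @export
category_profiles <- function(model, corpus, category_map, iterations = 200,
                              seed = 1) {
  stopifnot(inherits(model, "lda_model"))
  corpus <- as_dtm(corpus)
  if (is.null(rownames(corpus))) abort("corpus rows must be named by doc_id")
  cats <- sort(unique(category_map$category), method = "radix")
  rows <- list()
  n_docs <- integer()
  kept <- character()
  for (cc in cats) {
    ids <- unique(category_map$doc_id[category_map$category == cc])
    ids <- intersect(ids, rownames(corpus))
    if (!length(ids)) {
      warn(paste0("category '", cc, "' matches no document in the corpus; omitted"))
      next
    }
    combined <- Matrix::colSums(corpus[ids, , drop = FALSE])
    rows[[length(rows) + 1L]] <- combined
    n_docs <- c(n_docs, length(ids))
    kept <- c(kept, cc)
  }
  if (!length(kept)) abort("no record matches any category")
  dtm <- do.call(rbind, rows)
  dtm <- methods::as(Matrix::Matrix(dtm, sparse = TRUE), "generalMatrix")
  rownames(dtm) <- kept
  theta <- infer_theta(model, dtm, iterations = iterations, seed = seed)
  norm <- theta / apply(theta, 1, max)
  out <- tibble::tibble(
    category = rep(kept, each = model$K),
    n_docs = rep(n_docs, each = model$K),
    topic = rep(seq_len(model$K), times = length(kept)),
    proportion = as.vector(t(theta)),
    norm_proportion = as.vector(t(norm)))
  attr(out, "theta") <- theta
  class(out) <- c("category_profiles", class(out))
  out
}

#' Extract the category-by-topic proportion matrix
#'
#' @param profiles a [category_profiles()] result.
#' @return A C x K matrix, rows named by category.
#' @export
profile_matrix <- function(profiles) {
  th <- attr(profiles, "theta", exact = TRUE)
  if (is.null(th)) abort("input is not a category_profiles object")
  th
}

#' Pairwise Hellinger distance matrix of category profiles
#'
#' @param profiles a [category_profiles()] result, or a matrix of topic
#'   distributions with named rows.
#' @param reference optional extra topic distribution (e.g. the whole
#'   corpus) appended as row/column `"corpus"` (rename via a named length-1
#'   list or a named vector attribute-free input).
#' @param reference_label label for the reference row (default `"corpus"`).
#' @return A symmetric matrix with zero diagonal, labelled rows/columns.
#' @export
hellinger_matrix <- function(profiles, reference = NULL,
                             reference_label = "corpus") {
  theta <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (!is.null(reference)) {
    theta <- rbind(theta, matrix(reference, nrow = 1,
                                 dimnames = list(reference_label, NULL)))
  }
  n <- nrow(theta)
  if (n < 2) abort("need at least two distributions to compare")
  m <- matrix(0, n, n, dimnames = list(rownames(theta), rownames(theta)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- hellinger(theta[i, ], theta[j, ])
    }
  }
  m
}

#' Weight of one term across all topics
#'
#' Looks up the topic-word probability phi\[k, term\] for every topic, the
#' per-term profile used to attribute a word (such as "mask") to the topic
#' where it carries the most weight.
#'
#' @param model a trained model.
#' @param term a vocabulary term (post-tokenization form, e.g.
#'   `"mental_health"` for a merged bigram).
#' @return A tibble with columns `topic`, `weight`, `is_argmax`; the argmax
#'   topic index is attached as attribute `"argmax"`.
#' @export
term_weight_in_topics <- function(model, term) {
  stopifnot(inherits(model, "lda_model"))
  j <- match(term, model$terms)
  if (is.na(j)) abort(paste0("term not in the model vocabulary: '", term, "'"))
  w <- model$phi[, j]
  k_max <- unname(which.max(w))
  out <- tibble::tibble(topic = seq_len(model$K), weight = as.numeric(w),
                        is_argmax = seq_len(model$K) == k_max)
  attr(out, "argmax") <- k_max
  out
}

#' Export category profiles as CSV
#'
#' Wide layout: one row per category with the document count, K proportion
#' columns and K max-normalized columns.
#'
#' @param profiles a [category_profiles()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_category_profiles <- function(profiles, path) {
  theta <- profile_matrix(profiles)
  K <- ncol(theta)
  norm <- theta / apply(theta, 1, max)
  colnames(theta) <- paste0("theta_", seq_len(K))
  colnames(norm) <- paste0("norm_", seq_len(K))
  nd <- dplyr::distinct(tibble::as_tibble(profiles[, c("category", "n_docs")]))
  out <- dplyr::bind_cols(
    tibble::tibble(category = rownames(theta)),
    tibble::as_tibble(theta), tibble::as_tibble(norm))
  out <- dplyr::left_join(nd, out, by = "category")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a labelled distance matrix as CSV
#'
#' @param m a labelled square matrix (e.g. from [hellinger_matrix()]).
#' @param path output path; first column holds the row labels.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  out <- dplyr::bind_cols(tibble::tibble(label = rownames(m)),
                          tibble::as_tibble(m))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
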