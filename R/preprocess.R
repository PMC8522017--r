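# Bag-of-words preprocessing: tokenization, bigram merging, vocabulary
# filtering and sparse count matrices.

the_stopwords <- new.env(parent = emptyenv())

#' Packaged English stopword list
#'
#' A frozen copy of a standard English stopword list, shipped with the
#' package so that tokenization is reproducible across machines and over
#' time (no downloads, no locale dependence).
#'
#' @return Character vector of lowercase stopwords.
#' @export
stopwords_en <- function() {
  if (is.null(the_stopwords$en)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "topictrends")
    the_stopwords$en <- readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  the_stopwords$en
}

#' Tokenize abstract text
#'
#' Lowercases, strips punctuation and numerals, and keeps alphabetic tokens
#' of at least `min_length` characters that are not stopwords.  Hyphenated
#' and slash-joined forms split into their alphabetic parts (so
#' `"COVID-19"` tokenizes to `"covid"`).
#'
#' @param text character vector of documents.
#' @param stopwords character vector of tokens to drop
#'   (default [stopwords_en()]); use `character()` to keep everything.
#' @param min_length minimum token length in characters (default 2).
#' @return A list of character token vectors, one per input document.
#' @examples
#' tokenize("The COVID-19 pandemic spreads.")[[1]]
#' @export
tokenize <- function(text, stopwords = stopwords_en(), min_length = 2) {
  text <- tolower(as.character(text))
  toks <- stringr::str_extract_all(text, "[a-z]+")
  purrr::map(toks, function(tk) {
    tk <- tk[nchar(tk) >= min_length]
    tk[!tk %in% stopwords]
  })
}

#' Merge frequent bigrams into single tokens
#'
#' Scores every adjacent token pair (a, b) across the corpus with the
#' count-based phrase score
#' \deqn{score(a,b) = \frac{(count(a,b) - min\_count) \cdot N}{count(a)\,count(b)}}
#' where N is the total token count, and joins pairs scoring above
#' `threshold` into `"a_b"`.  Merging is a single greedy left-to-right pass
#' per document, so overlapping candidate pairs never both merge.
#'
#' @param docs list of token vectors (from [tokenize()]).
#' @param min_count minimum pair count before a pair can score above zero
#'   (default 5).
#' @param threshold minimum score for merging (default 10).
#' @return A list of token vectors with merged bigrams.
#' @export
merge_bigrams <- function(docs, min_count = 5, threshold = 10) {
  stopifnot(min_count >= 1)
  if (!length(docs)) return(docs)
  all_tokens <- unlist(docs, use.names = FALSE)
  n_total <- length(all_tokens)
  if (n_total < 2) return(docs)
  unigram <- table(all_tokens)
  pair_keys <- unlist(purrr::map(docs, function(tk) {
    if (length(tk) < 2) return(character())
    paste(tk[-length(tk)], tk[-1], sep = "\r")
  }), use.names = FALSE)
  if (!length(pair_keys)) return(docs)
  pair_count <- table(pair_keys)
  parts <- strsplit(names(pair_count), "\r", fixed = TRUE)
  a <- purrr::map_chr(parts, 1)
  b <- purrr::map_chr(parts, 2)
  score <- (as.numeric(pair_count) - min_count) * n_total /
    (as.numeric(unigram[a]) * as.numeric(unigram[b]))
  merged_pairs <- names(pair_count)[score > threshold]
  if (!length(merged_pairs)) return(docs)
  merged_set <- new.env(parent = emptyenv())
  for (k in merged_pairs) assign(k, TRUE, envir = merged_set)
  purrr::map(docs, function(tk) {
    n <- length(tk)
    if (n < 2) return(tk)
    out <- character(n)
    j <- 0L
    i <- 1L
    while (i <= n) {
      if (i < n && !is.null(merged_set[[paste(tk[i], tk[i + 1], sep = "\r")]])) {
        j <- j + 1L
        out[j] <- paste(tk[i], tk[i + 1], sep = "_")
        i <- i + 2L
      } else {
        j <- j + 1L
        out[j] <- tk[i]
        i <- i + 1L
      }
    }
    out[seq_len(j)]
  })
}

#' Build a filtered vocabulary
#'
#' Retains terms whose document frequency is at least `no_below` documents
#' and at most `no_above` as a fraction of the corpus.  Indices are assigned
#' in lexicographic term order, so the same corpus always yields the same
#' index assignment.
#'
#' @param docs list of token vectors.
#' @param no_below minimum document frequency in documents (default 2).
#' @param no_above maximum document frequency as a fraction of documents
#'   (default 0.9).
#' @return A tibble with columns `index` (1-based, dense), `term`,
#'   `doc_freq`, carrying the corpus document count as attribute `n_docs`.
#' @export
build_vocabulary <- function(docs, no_below = 2, no_above = 0.9) {
  stopifnot(no_above > 0, no_above <= 1)
  n_docs <- length(docs)
  df <- table(unlist(purrr::map(docs, unique), use.names = FALSE))
  keep <- as.numeric(df) >= no_below & as.numeric(df) <= no_above * n_docs
  terms <- sort(names(df)[keep], method = "radix")
  if (!length(terms)) {
    abort("vocabulary is empty after document-frequency filtering")
  }
  vocab <- tibble::tibble(index = seq_along(terms), term = terms,
                          doc_freq = as.integer(df[terms]))
  attr(vocab, "n_docs") <- n_docs
  vocab
}

#' Convert one tokenized document to bag-of-words counts
#'
#' Out-of-vocabulary tokens are dropped silently; token order is
#' irrelevant.
#'
#' @param tokens a character token vector.
#' @param vocab a vocabulary tibble from [build_vocabulary()].
#' @return A tibble with columns `index` (strictly increasing), `term`,
#'   `count` (positive integers).
#' @export
to_bow <- function(tokens, vocab) {
  stopifnot(nrow(vocab) > 0)
  idx <- match(tokens, vocab$term)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    return(tibble::tibble(index = integer(), term = character(),
                          count = integer()))
  }
  cnt <- table(idx)
  index <- as.integer(names(cnt))
  tibble::tibble(index = index, term = vocab$term[index],
                 count = as.integer(cnt))
}

#' Build a sparse document-term count matrix
#'
#' @param docs list of token vectors.
#' @param vocab a vocabulary tibble from [build_vocabulary()].
#' @param doc_ids optional row names (defaults to names of `docs` or
#'   `doc1..docD`).
#' @return A `dgCMatrix` of counts, documents in rows and vocabulary terms
#'   in columns.
#' @export
bow_corpus <- function(docs, vocab, doc_ids = NULL) {
  stopifnot(nrow(vocab) > 0)
  D <- length(docs)
  if (is.null(doc_ids)) {
    doc_ids <- names(docs)
    if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_len(D))
  }
  idx <- purrr::map(docs, function(tk) {
    m <- match(tk, vocab$term)
    m[!is.na(m)]
  })
  i <- rep.int(seq_len(D), lengths(idx))
  j <- unlist(idx, use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(j)),
                       dims = c(D, nrow(vocab)),
                       dimnames = list(doc_ids, vocab$term))
}

#' Corpus term marginal probabilities
#'
#' Empirical probability of each vocabulary term among all corpus tokens,
#' the denominator of the lift component of term relevance.
#'
#' @param corpus a document-term `dgCMatrix` from [bow_corpus()].
#' @param smooth additive smoothing pseudo-count per term (default 0.5),
#'   keeping marginals strictly positive for log-lift.
#' @return Named numeric vector over vocabulary terms, summing to 1.
#' @export
term_marginals <- function(corpus, smooth = 0.5) {
  cnt <- Matrix::colSums(corpus) + smooth
  cnt / sum(cnt)
}

#' Export a vocabulary as TSV
#'
#' @param vocab vocabulary tibble.
#' @param path output path (columns `index`, `term`, `doc_freq`).
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_tsv(vocab[, c("index", "term", "doc_freq")], path,
                   progress = FALSE)
  invisible(path)
}

#' Export a bag-of-words corpus as MatrixMarket + vocabulary sidecar
#'
#' @param corpus a document-term `dgCMatrix`.
#' @param vocab the matching vocabulary tibble.
#' @param dir output directory; writes `corpus.mtx` and `vocabulary.tsv`.
#' @return The directory, invisibly.
#' @export
write_bow_corpus <- function(corpus, vocab, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(corpus, file.path(dir, "corpus.mtx"))
  write_vocabulary(vocab, file.path(dir, "vocabulary.tsv"))
  invisible(dir)
}

#' One-call preprocessing pipeline
#'
#' Tokenizes cleaned records, optionally merges bigrams, builds the
#' vocabulary and the document-term matrix.
#'
#' @param records a cleaned record tibble.
#' @param bigrams merge bigrams first? (default TRUE)
#' @param min_count,threshold bigram parameters, see [merge_bigrams()].
#' @param no_below,no_above vocabulary filters, see [build_vocabulary()].
#' @param stopwords stopword list for [tokenize()].
#' @return A list with elements `tokens` (list of token vectors), `vocab`
#'   and `corpus` (document-term `dgCMatrix` with `doc_id` row names).
#' @export
preprocess_corpus <- function(records, bigrams = TRUE, min_count = 5,
                              threshold = 10, no_below = 2, no_above = 0.9,
                              stopwords = stopwords_en()) {
  records <- validate_records(records)
  tokens <- tokenize(records$text, stopwords = stopwords)
  if (bigrams) tokens <- merge_bigrams(tokens, min_count, threshold)
  names(tokens) <- records$doc_id
  vocab <- build_vocabulary(tokens, no_below = no_below, no_above = no_above)
  corpus <- bow_corpus(tokens, vocab, doc_ids = records$doc_id)
  list(tokens = tokens, vocab = vocab, corpus = corpus)
}
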