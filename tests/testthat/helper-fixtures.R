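# Shared fixture builders.  Everything is generated in code; moderately
# expensive simulations are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# hand-assembled lda_model with a fixed phi (no training), for tests that
# need full control over the topic-word distribution
make_model <- function(phi, alpha = rep(1 / nrow(phi), nrow(phi)),
                       beta = 0.01) {
  if (is.null(colnames(phi))) colnames(phi) <- paste0("t", seq_len(ncol(phi)))
  rownames(phi) <- paste0("topic", seq_len(nrow(phi)))
  structure(
    list(K = nrow(phi), V = ncol(phi), alpha = alpha, beta = beta, phi = phi,
         seed = 1L, iterations = 0L, burnin = 0L, thin = 1L, n_samples = 1L,
         terms = colnames(phi)),
    class = "lda_model")
}

# K=2 disjoint-vocabulary model: topic 1 uniform on the first half of the
# vocabulary, topic 2 on the second (smoothed so all entries are positive)
disjoint_model <- function(V = 10, smooth = 1e-6) {
  phi <- gen_topics(2, V, mode = "disjoint_blocks", smooth = smooth)
  make_model(phi, alpha = c(0.5, 0.5))
}

record_tbl <- function(doc_id, date, text, categories = NULL) {
  n <- length(doc_id)
  tibble::tibble(
    doc_id = doc_id, date = as.Date(date), text = text,
    categories = categories %||% rep(list(character()), n),
    date_flag = rep("ok", n))
}

long_text <- function(n = 60, letter = "x") strrep(letter, n)

medline_fixture_lines <- function() {
  c("PMID- 123",
    "DP  - 2020 Mar 15",
    "AB  - Severe acute respiratory syndrome coronavirus abstract body",
    "      continued on a second line.",
    "",
    "PMID- 456",
    "DP  - 2020-04-02",
    "AB  - Another abstract.",
    "")
}

# corpus drawn from a known 5-topic model; shared by recovery-style tests
shared_recovery_sim <- function() {
  cached("recovery_sim", {
    phi <- gen_topics(5, 200, concentration = 0.1, seed = 901)
    sim <- gen_corpus(phi, trajectories = purrr::map(1:5, ~ traj_constant(1)),
                      n_bins = 6, docs_per_bin = 80, doc_length = 80,
                      alpha_scale = 0.5,
                      contamination = list(short_frac = 0, correction_frac = 0),
                      seed = 902)
    tokens <- tokenize(sim$records$text)
    corpus <- bow_corpus(tokens, sim$truth$vocab, doc_ids = sim$records$doc_id)
    list(sim = sim, tokens = tokens, corpus = corpus, phi = phi)
  })
}

shared_recovery_fit <- function() {
  cached("recovery_fit", {
    rs <- shared_recovery_sim()
    train_lda(rs$corpus, K = 5, alpha = 0.1, beta = 0.01, iterations = 300,
              seed = 903)
  })
}

rdirichlet_test <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
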