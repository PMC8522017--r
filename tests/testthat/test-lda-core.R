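# Collapsed Gibbs training, fold-in inference, perplexity, topic difference.

test_that("single-term corpus recovers the smoothed closed-form estimator", {
  # every document is the single term w: phi[1, w] = (N + beta)/(N + V*beta)
  m <- Matrix::sparseMatrix(i = 1:3, j = rep(2L, 3), x = c(2, 1, 3),
                            dims = c(3, 4),
                            dimnames = list(NULL, c("a", "b", "c", "d")))
  beta <- 0.01
  fit <- train_lda(m, K = 1, beta = beta, iterations = 20, seed = 5)
  N <- 6; V <- 4
  expect_equal(fit$phi[1, "b"], (N + beta) / (N + V * beta), tolerance = 1e-12)
  expect_equal(fit$phi[1, "a"], beta / (N + V * beta), tolerance = 1e-12)
  expect_equal(sum(fit$phi), 1, tolerance = 1e-9)
})

test_that("training is bit-identical under a fixed seed", {
  rs <- shared_recovery_sim()
  sub <- rs$corpus[1:60, ]
  f1 <- train_lda(sub, K = 3, iterations = 50, seed = 42)
  f2 <- train_lda(sub, K = 3, iterations = 50, seed = 42)
  expect_identical(f1$phi, f2$phi)
  f3 <- train_lda(sub, K = 3, iterations = 50, seed = 43)
  expect_false(identical(f3$phi, f1$phi))
})

test_that("disjoint-vocabulary topics are recovered from generated text", {
  phi_true <- gen_topics(2, 20, mode = "disjoint_blocks", seed = 77)
  sim <- gen_corpus(phi_true, trajectories = list(traj_constant(1),
                                                  traj_constant(1)),
                    n_bins = 2, docs_per_bin = 60, doc_length = 50,
                    alpha_scale = 0.6,
                    contamination = list(short_frac = 0, correction_frac = 0),
                    seed = 78)
  corpus <- bow_corpus(tokenize(sim$records$text), sim$truth$vocab,
                       doc_ids = sim$records$doc_id)
  fit <- train_lda(corpus, K = 2, alpha = 0.3, beta = 0.01,
                   iterations = 200, seed = 79)
  mt <- match_topics(fit$phi, phi_true)
  expect_lt(attr(mt, "mean_distance"), 0.1)
})

test_that("every phi row is a smoothed probability distribution", {
  fit <- shared_recovery_fit()
  expect_equal(unname(rowSums(fit$phi)), rep(1, 5), tolerance = 1e-9)
  expect_true(all(fit$phi > 0))
})

test_that("fold-in of an empty document returns the prior mean", {
  model <- make_model(rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6)),
                      alpha = c(0.3, 0.7))
  theta <- infer_theta(model, Matrix::sparseMatrix(i = integer(),
                                                   j = integer(), x = numeric(),
                                                   dims = c(1, 3)))
  expect_equal(unname(theta[1, ]), c(0.3, 0.7))
  # single-document (non-matrix) input drops to a vector
  empty_bow <- tibble::tibble(index = integer(), count = integer())
  expect_equal(unname(infer_theta(model, empty_bow)), c(0.3, 0.7))
})

test_that("fold-in attributes pure and mixed documents correctly", {
  model <- disjoint_model(V = 10)
  pure <- c(rep(6, 5), rep(0, 5))           # 30 tokens, all from block A
  names(pure) <- model$terms
  theta <- infer_theta(model, pure, iterations = 400, seed = 9)
  expect_gt(theta[[1]], 0.95)

  mixed <- rep(3, 10)                       # 15 tokens from each block
  names(mixed) <- model$terms
  theta2 <- infer_theta(model, mixed, iterations = 400, seed = 9)
  expect_equal(unname(theta2), c(0.5, 0.5), tolerance = 0.05)
})

test_that("fold-in rejects out-of-vocabulary indices", {
  model <- disjoint_model(V = 4)
  expect_error(infer_theta(model, tibble::tibble(index = 9L, count = 1L)),
               "out of vocabulary")
})

test_that("uniform topic-word rows give perplexity exactly V", {
  V <- 7
  model <- make_model(matrix(1 / V, nrow = 2, ncol = V))
  heldout <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 3, 6),
                                  x = c(2, 1, 4), dims = c(2, V))
  expect_equal(perplexity(model, heldout), V, tolerance = 1e-9)
})

test_that("perplexity is at least 1 and favors the generating model", {
  rs <- shared_recovery_sim()
  fit <- shared_recovery_fit()
  heldout <- rs$corpus[1:50, ]
  p_fit <- perplexity(fit, heldout, seed = 31)
  uniform <- make_model(matrix(1 / 200, nrow = 5, ncol = 200,
                               dimnames = list(NULL, fit$terms)))
  p_unif <- perplexity(uniform, heldout, seed = 31)
  expect_gte(p_fit, 1)
  expect_lt(p_fit, p_unif)
  expect_error(perplexity(fit, rs$corpus[1, , drop = FALSE] * 0), "no tokens")
})

test_that("topic difference is zero on self and one on disjoint top sets", {
  model <- disjoint_model(V = 10)
  self_diff <- topic_diff(model, model, topn = 5)
  expect_equal(unname(diag(self_diff$matrix)), c(0, 0))
  expect_equal(unname(self_diff$matrix[1, 2]), 1)  # disjoint blocks
  expect_equal(self_diff$mean, mean(self_diff$matrix))
})

test_that("topic difference matches set arithmetic on hand-built top lists", {
  # top-3 sets: A1 = {a,b,c}, A2 = {d,e,f}; B1 = {b,c,d}, B2 = {a,e,f}
  terms <- c("a", "b", "c", "d", "e", "f")
  phi_a <- rbind(c(.5, .3, .15, .03, .01, .01),
                 c(.01, .02, .02, .5, .3, .15))
  phi_b <- rbind(c(.03, .5, .3, .15, .01, .01),
                 c(.3, .02, .03, .02, .4, .23))
  colnames(phi_a) <- colnames(phi_b) <- terms
  d <- topic_diff(make_model(phi_a), make_model(phi_b), topn = 3)
  # J({a,b,c},{b,c,d}) = 1 - 2/4; J({a,b,c},{a,e,f}) = 1 - 1/5; etc.
  expect_equal(unname(d$matrix),
               rbind(c(0.5, 0.8), c(0.8, 0.5)))
  expect_error(topic_diff(make_model(phi_a), make_model(phi_b), topn = 10),
               "vocabulary")
})

test_that("model serialization round-trips through JSON + CSV", {
  fit <- shared_recovery_fit()
  dir <- withr::local_tempdir()
  write_lda_model(fit, dir)
  back <- read_lda_model(dir)
  expect_equal(back$phi, fit$phi, tolerance = 1e-12)
  expect_identical(back$K, fit$K)
  expect_identical(back$alpha, fit$alpha)
  expect_identical(back$terms, fit$terms)
  expect_equal(unname(rowSums(back$phi)), rep(1, fit$K), tolerance = 1e-12)
})
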