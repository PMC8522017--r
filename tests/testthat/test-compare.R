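# Distance metrics, category profiles and per-term topic weights.

test_that("Hellinger distance matches direct evaluation of the formula", {
  expect_equal(hellinger(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(hellinger(c(1, 0), c(0, 1)), 1)
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(hellinger(p, q),
               sqrt(0.5 * ((sqrt(0.5) - sqrt(0.25))^2 +
                           (sqrt(0.5) - sqrt(0.75))^2)),
               tolerance = 1e-15)
  expect_error(hellinger(c(1, 0), c(0.2, 0.2)), "sum to 1")
  expect_error(hellinger(c(1, 0), c(0.5, 0.25, 0.25)), "length")
})

test_that("Hellinger is symmetric and satisfies the triangle inequality", {
  set.seed(21)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    p <- as.numeric(rdirichlet_test(1, rep(0.5, k)))
    q <- as.numeric(rdirichlet_test(1, rep(0.5, k)))
    r <- as.numeric(rdirichlet_test(1, rep(0.5, k)))
    expect_equal(hellinger(p, q), hellinger(q, p), tolerance = 1e-15)
    expect_lte(hellinger(p, r), hellinger(p, q) + hellinger(q, r) + 1e-9)
    expect_gte(hellinger(p, q), 0)
    expect_lte(hellinger(p, q), 1)
  }
})

test_that("normalized Euclidean distance is the RMS difference", {
  expect_equal(normalized_euclidean(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(normalized_euclidean(c(0.1, 0.2), c(0.3, 0.2)),
               sqrt(0.04 / 2), tolerance = 1e-15)
  x <- c(0.4, 0.1, 0.8); y <- c(0.2, 0.5, 0.3)
  expect_equal(normalized_euclidean(3 * x, 3 * y),
               3 * normalized_euclidean(x, y), tolerance = 1e-12)
  expect_equal(normalized_euclidean(x, y), normalized_euclidean(y, x))
  expect_error(normalized_euclidean(1:2, 1:3), "length")
})

test_that("Jaccard distance follows set arithmetic", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a"), c("b")), 1)
  expect_equal(jaccard_distance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_distance(character(), character()), 0)
  expect_equal(jaccard_distance(c("a", "a", "b"), c("b", "a")), 0)  # sets
})

test_that("hellinger_matrix is symmetric, zero-diagonal, and exact", {
  th <- rbind(A = c(0.6, 0.3, 0.1), B = c(0.2, 0.5, 0.3),
              C = c(0.1, 0.1, 0.8))
  m <- hellinger_matrix(th)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(m[i, j], hellinger(th[i, ], th[j, ]), tolerance = 1e-15)
  }
  m_ref <- hellinger_matrix(th, reference = c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(dim(m_ref), c(4L, 4L))
  expect_equal(rownames(m_ref)[[4]], "corpus")
  expect_error(hellinger_matrix(th[1, , drop = FALSE]), "at least two")
})

test_that("category profiles recover planted topic concentrations", {
  rs <- shared_recovery_sim()
  fit <- shared_recovery_fit()
  # plant three single-topic categories directly over the fitted topics
  theta_fit <- infer_theta(fit, rs$corpus, iterations = 60, seed = 51)
  lead <- apply(theta_fit, 1, which.max)
  cmap <- tibble::tibble(doc_id = rownames(rs$corpus),
                         category = paste0("cat", lead))
  cmap <- cmap[lead <= 3, ]
  prof <- category_profiles(fit, rs$corpus, cmap, iterations = 120, seed = 52)
  th <- profile_matrix(prof)
  for (k in 1:3) {
    expect_equal(which.max(th[paste0("cat", k), ]), k,
                 ignore_attr = TRUE)
  }
  tb <- tibble::as_tibble(prof)
  expect_equal(max(tb$norm_proportion[tb$category == "cat1"]), 1)
  expect_equal(unname(rowSums(th)), rep(1, 3), tolerance = 1e-9)
})

test_that("multi-label records contribute tokens to every profile", {
  model <- disjoint_model(V = 10)
  corpus <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 6), x = c(4, 2),
                                 dims = c(2, 10),
                                 dimnames = list(c("d1", "d2"), model$terms))
  cmap <- tibble::tibble(doc_id = c("d1", "d1", "d2"),
                         category = c("X", "Y", "Y"))
  prof <- category_profiles(model, corpus, cmap, iterations = 50, seed = 3)
  expect_equal(sort(rownames(profile_matrix(prof))), c("X", "Y"))
  nd <- dplyr::distinct(tibble::as_tibble(prof)[, c("category", "n_docs")])
  expect_equal(nd$n_docs[nd$category == "Y"], 2L)  # d1 counted in both
  expect_warning(
    category_profiles(model, corpus,
                      tibble::tibble(doc_id = c("d1", "zz"),
                                     category = c("X", "Gone")),
                      iterations = 10, seed = 1),
    "Gone")
  expect_error(
    category_profiles(model, corpus,
                      tibble::tibble(doc_id = "zz", category = "Gone"),
                      iterations = 10, seed = 1) |> suppressWarnings(),
    "no record")
})

test_that("single-category profiles equal whole-corpus fold-in", {
  rs <- shared_recovery_sim()
  fit <- shared_recovery_fit()
  sub <- rs$corpus[1:40, ]
  cmap <- tibble::tibble(doc_id = rownames(sub), category = "all")
  prof <- category_profiles(fit, sub, cmap, iterations = 80, seed = 9)
  whole <- infer_theta(fit, Matrix::colSums(sub), iterations = 80, seed = 9)
  expect_equal(unname(profile_matrix(prof)[1, ]), unname(whole),
               tolerance = 1e-12)
})

test_that("term weights are per-topic probabilities with a named argmax", {
  model <- disjoint_model(V = 10)
  w <- term_weight_in_topics(model, model$terms[[2]])  # block-A term
  expect_equal(nrow(w), 2)
  expect_true(all(w$weight > 0 & w$weight < 1))
  expect_equal(attr(w, "argmax"), 1)
  expect_true(w$is_argmax[[1]])
  # the off-block weight sits at the smoothing floor
  expect_lt(w$weight[[2]], 10 * 1e-6)
  expect_error(term_weight_in_topics(model, "missing_term"), "missing_term")
})

test_that("profile and distance-matrix exports carry labels and round-trip", {
  th <- rbind(A = c(0.7, 0.3), B = c(0.4, 0.6))
  m <- hellinger_matrix(th)
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_matrix(m, path)
  back <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  expect_equal(back$label, c("A", "B"))
  expect_equal(back$A, unname(m[, "A"]), tolerance = 1e-12)
})
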