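# Generator correctness: topics, trajectories, contamination, categories,
# fixture round-trips and determinism.

test_that("block topics occupy disjoint vocabulary halves", {
  phi <- gen_topics(2, 10, mode = "disjoint_blocks")
  expect_true(all(phi[1, 6:10] == 0))
  expect_true(all(phi[2, 1:5] == 0))
  expect_equal(unname(rowSums(phi)), c(1, 1), tolerance = 1e-12)
  expect_equal(hellinger(phi[1, ], phi[2, ]), 1, tolerance = 1e-12)
  expect_error(gen_topics(5, 3, mode = "disjoint_blocks"), "V >= K")
})

test_that("Dirichlet topics are row-stochastic and seed-deterministic", {
  p1 <- gen_topics(4, 50, concentration = 0.1, seed = 5)
  p2 <- gen_topics(4, 50, concentration = 0.1, seed = 5)
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(p1 >= 0))
})

test_that("pseudo-words are alphabetic, ordered and tokenizer-safe", {
  w <- pseudo_word(c(1, 2, 200, 26^4))
  expect_true(all(grepl("^w[a-z]{4}$", w)))
  expect_equal(w, sort(w))
  expect_equal(tokenize(paste(w, collapse = " "))[[1]], w)
})

test_that("trajectory stacking renormalizes to simplex rows", {
  M <- trajectory_means(default_trajectories(5), 26)
  expect_equal(dim(M), c(26L, 5L))
  expect_equal(unname(rowSums(M)), rep(1, 26), tolerance = 1e-12)
  # the pulse dominates its center bin and fades later
  expect_gt(M[3, 1], 2 * M[20, 1])
  # the logistic riser grows
  expect_gt(M[26, 2], M[1, 2])
})

test_that("contamination fractions materialize at binomial scale", {
  phi <- gen_topics(3, 30, seed = 61)
  sim <- gen_corpus(phi, trajectories = purrr::map(1:3, ~ traj_constant(1)),
                    n_bins = 5, docs_per_bin = 200, doc_length = 60,
                    contamination = list(short_frac = 0.05,
                                         correction_frac = 0.02),
                    seed = 62)
  n <- nrow(sim$records)
  expect_equal(n, 1000)
  n_short <- sum(sim$truth$contaminated == "short")
  n_corr <- sum(sim$truth$contaminated == "correction")
  # 4-sigma binomial bands around 50 and 20
  expect_lt(abs(n_short - 50), 4 * sqrt(1000 * 0.05 * 0.95) + 1)
  expect_lt(abs(n_corr - 20), 4 * sqrt(1000 * 0.02 * 0.98) + 1)
  # the cleaning report sees exactly the planted records
  rep <- exclusion_report(clean_corpus(sim$records))
  expect_equal(rep$too_short, n_short)
  expect_equal(rep$correction_notice, n_corr)
})

test_that("zero contamination survives cleaning untouched", {
  phi <- gen_topics(2, 20, seed = 63)
  sim <- gen_corpus(phi, trajectories = purrr::map(1:2, ~ traj_constant(1)),
                    n_bins = 2, docs_per_bin = 30, doc_length = 60,
                    contamination = list(short_frac = 0, correction_frac = 0),
                    seed = 64)
  kept <- clean_corpus(sim$records)
  expect_equal(nrow(kept), 60)
  expect_equal(exclusion_report(kept)$n_kept, 60)
})

test_that("flat trajectories give stationary per-bin mixture means", {
  phi <- gen_topics(4, 40, seed = 65)
  sim <- gen_corpus(phi, trajectories = purrr::map(1:4, ~ traj_constant(1)),
                    n_bins = 4, docs_per_bin = 200, doc_length = 60,
                    contamination = list(short_frac = 0, correction_frac = 0),
                    seed = 66)
  global <- colMeans(sim$truth$theta)
  for (b in 1:4) {
    bin_mean <- colMeans(sim$truth$theta[sim$truth$bin == b, ])
    expect_lt(max(abs(bin_mean - global)), 0.05)
  }
})

test_that("category labels tilt document mixtures toward their topics", {
  phi <- gen_topics(4, 60, seed = 67)
  cats <- list(alpha = 1L, beta = 2L)
  sim <- gen_corpus(phi, trajectories = purrr::map(1:4, ~ traj_constant(1)),
                    n_bins = 3, docs_per_bin = 100, doc_length = 60,
                    categories = cats, category_weight = 0.8,
                    label_frac = 0.5, multi_label_frac = 0,
                    contamination = list(short_frac = 0, correction_frac = 0),
                    seed = 68)
  cm <- sim$truth$category_map
  expect_gt(nrow(cm), 50)
  for (cc in names(cats)) {
    ids <- cm$doc_id[cm$category == cc]
    rows <- match(ids, sim$records$doc_id)
    mean_theta <- colMeans(sim$truth$theta[rows, , drop = FALSE])
    expect_equal(which.max(mean_theta), cats[[cc]], ignore_attr = TRUE)
    expect_gt(mean_theta[cats[[cc]]], 0.6)
  }
})

test_that("fixtures round-trip records and truth through plain text", {
  phi <- gen_topics(3, 25, seed = 71)
  sim <- gen_corpus(phi, trajectories = default_trajectories(3),
                    n_bins = 4, docs_per_bin = 20, doc_length = 50,
                    categories = list(one = 1L), seed = 72)
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  expect_equal(back$records, sim$records)
  expect_equal(back$truth$phi, sim$truth$phi, tolerance = 1e-12)
  expect_equal(back$truth$trajectories, sim$truth$trajectories,
               tolerance = 1e-12)
  expect_equal(back$truth$theta, sim$truth$theta, tolerance = 1e-12)
  expect_identical(back$truth$bin, sim$truth$bin)
  expect_identical(back$truth$contaminated, sim$truth$contaminated)
  expect_equal(back$truth$category_map, sim$truth$category_map)
})

test_that("generation is fully determined by the seed", {
  phi <- gen_topics(3, 25, seed = 73)
  args <- list(phi = phi, trajectories = default_trajectories(3),
               n_bins = 3, docs_per_bin = 15, doc_length = 40, seed = 74)
  s1 <- do.call(gen_corpus, args)
  s2 <- do.call(gen_corpus, args)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$theta, s2$truth$theta)
  s3 <- do.call(gen_corpus, modifyList(args, list(seed = 75)))
  expect_false(identical(s1$records$text, s3$records$text))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_corpus(gen_topics(2, 10, seed = 1),
                       trajectories = purrr::map(1:2, ~ traj_constant(1)),
                       n_bins = 2, docs_per_bin = 5, doc_length = 20,
                       seed = 99))
  expect_identical(runif(1), before)
})
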