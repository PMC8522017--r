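# Weekly binning, train/test splits, per-bin documents, trend matrices and
# Gaussian count fits.

test_that("records before the merge boundary share one bin", {
  rec <- record_tbl(c("a", "b", "c"),
                    c("2020-01-17", "2020-01-30", "2020-02-05"),
                    rep(long_text(60), 3))
  binned <- assign_bins(rec)
  expect_equal(binned$bin[[1]], binned$bin[[2]])
  expect_false(binned$bin[[3]] == binned$bin[[1]])
  bins <- bin_table(binned)
  expect_true(bins$is_merged[[1]])
  expect_equal(bins$start[[1]], as.Date("2020-01-17"))
  expect_equal(bins$end[[1]], as.Date("2020-01-31"))
})

test_that("same ISO week implies same bin; weeks start on Monday", {
  rec <- record_tbl(c("a", "b", "c"),
                    c("2020-03-02", "2020-03-08", "2020-03-09"),
                    rep(long_text(60), 3))
  binned <- assign_bins(rec, merge_before = NULL)
  expect_equal(binned$bin[[1]], binned$bin[[2]])   # Mon and Sun of W10
  expect_false(binned$bin[[3]] == binned$bin[[1]]) # next Monday
})

test_that("binning matches a brute-force calendar enumeration", {
  dates <- seq(as.Date("2020-01-17"), as.Date("2020-03-01"), by = 1)
  rec <- record_tbl(sprintf("d%02d", seq_along(dates)), dates,
                    rep(long_text(60), length(dates)))
  binned <- assign_bins(rec)
  bins <- bin_table(binned)
  # oracle: one merged bin (Jan 17-31) + one bin per distinct ISO week of
  # the remaining dates
  weekly <- dates[dates >= as.Date("2020-02-01")]
  expected_weeks <- unique(strftime(weekly, "%G-W%V"))
  expect_equal(bins$label, c("pre-2020-02-01", expected_weeks))
  expect_equal(bins$n_docs[[1]], sum(dates < as.Date("2020-02-01")))
  expect_equal(sum(bins$n_docs), length(dates))
  # brute-force per-week counts
  for (w in expected_weeks) {
    expect_equal(bins$n_docs[bins$label == w],
                 sum(strftime(weekly, "%G-W%V") == w))
  }
  # bins are ordered and date-disjoint
  expect_true(all(diff(order(bins$start)) == 1))
  expect_true(all(bins$start[-1] > bins$end[-nrow(bins)]))
})

test_that("empty calendar weeks are retained with zero counts", {
  rec <- record_tbl(c("a", "b"), c("2020-03-02", "2020-03-23"),
                    rep(long_text(60), 2))
  bins <- bin_table(assign_bins(rec, merge_before = NULL))
  expect_equal(nrow(bins), 4)
  expect_equal(bins$n_docs, c(1L, 0L, 0L, 1L))
})

test_that("undated records abort binning with their ids", {
  rec <- record_tbl(c("ok", "bad"), c("2020-03-02", NA),
                    rep(long_text(60), 2))
  expect_error(assign_bins(rec), "bad")
})

test_that("train/test split picks the boundary nearest the target fraction", {
  mk_bins <- function(counts) {
    tibble::tibble(label = paste0("b", seq_along(counts)),
                   start = as.Date("2020-02-03") + 7 * (seq_along(counts) - 1),
                   end = as.Date("2020-02-09") + 7 * (seq_along(counts) - 1),
                   is_merged = FALSE, n_docs = counts)
  }
  s <- split_train_test(mk_bins(c(8L, 2L)), 0.8)
  expect_equal(nrow(s$train), 1)
  expect_equal(nrow(s$test), 1)
  expect_equal(s$achieved_fraction, 0.8)
  expect_equal(s$cutoff_date, as.Date("2020-02-09"))

  # enumeration: cumulative fractions .2 .4 .6 .8 1; nearest 0.81 is bin 4
  s2 <- split_train_test(mk_bins(rep(10L, 5)), 0.81)
  expect_equal(nrow(s2$train), 4)

  # degenerate: all docs in the middle of three bins; cumulative 0, 1, 1
  s3 <- split_train_test(mk_bins(c(0L, 30L, 0L)), 0.8)
  expect_equal(nrow(s3$train), 2)

  expect_error(split_train_test(mk_bins(10L), 0.8), "two bins")
  expect_error(split_train_test(mk_bins(c(5L, 5L)), 1.2), "between")
  # split partitions the bins
  expect_equal(dplyr::bind_rows(s2$train, s2$test), mk_bins(rep(10L, 5)))
})

test_that("per-bin documents add token counts and ignore order", {
  rec <- record_tbl(c("a", "b", "c"),
                    c("2020-03-02", "2020-03-03", "2020-03-09"),
                    c("apple apple banana", "apple cherry", "banana banana"))
  binned <- assign_bins(rec, merge_before = NULL)
  vocab <- build_vocabulary(tokenize(rec$text), no_below = 1, no_above = 1)
  wd <- weekly_documents(binned, vocab)
  expect_equal(unname(as.matrix(wd)),
               rbind(c(3, 1, 1), c(0, 2, 0)))
  # permuting records leaves the result unchanged
  perm <- binned[c(3, 1, 2), ]
  attr(perm, "bins") <- bin_table(binned)
  expect_equal(as.matrix(weekly_documents(perm, vocab)), as.matrix(wd))
})

test_that("trend matrix rows are simplex points and empty bins take the prior", {
  model <- disjoint_model(V = 10)
  wd <- Matrix::sparseMatrix(i = c(1, 1, 3), j = c(1, 2, 6), x = c(5, 3, 4),
                             dims = c(3, 10),
                             dimnames = list(paste0("w", 1:3), model$terms))
  tm <- trend_matrix(model, wd, iterations = 100, seed = 3)
  expect_s3_class(tm, "trend_matrix")
  expect_equal(unname(rowSums(tm$theta)), rep(1, 3), tolerance = 1e-9)
  expect_equal(tm$empty, c(FALSE, TRUE, FALSE))
  expect_equal(unname(tm$theta[2, ]), c(0.5, 0.5))  # prior mean
  td <- tidy(tm)
  expect_equal(nrow(td), 6)
  expect_equal(glance(tm)$n_bins, 3)
})

test_that("trend export orders topics by overall proportion and round-trips", {
  model <- disjoint_model(V = 10)
  theta <- rbind(c(0.2, 0.8), c(0.3, 0.7))
  tm <- structure(list(
    bins = tibble::tibble(label = c("w1", "w2"),
                          start = as.Date(c("2020-02-03", "2020-02-10")),
                          end = as.Date(c("2020-02-09", "2020-02-16")),
                          is_merged = FALSE, n_docs = c(4L, 6L)),
    theta = theta, n_docs = c(4L, 6L), empty = c(FALSE, FALSE)),
    class = "trend_matrix")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trend_matrix(tm, path)
  back <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  expect_equal(names(back)[1], "bin")
  # topic 2 dominates overall, so it is exported first
  expect_equal(names(back)[-1], c("topic2", "topic1"))
  expect_equal(as.matrix(back[, c("topic1", "topic2")]),
               unname(theta), ignore_attr = TRUE)
})

test_that("noise-free Gaussian counts are recovered near-exactly", {
  t <- 1:20
  counts <- 100 * exp(-(t - 10)^2 / (2 * 3^2))
  fit <- fit_gaussian_counts(counts)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$mu, 10, tolerance = 1e-6)
  expect_equal(fit$sigma, 3, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_equal(tidy(fit)$estimate, c(100, 10, 3), tolerance = 1e-6)
})

test_that("symmetric counts center the fitted mean", {
  counts <- c(1, 4, 9, 14, 9, 4, 1)
  fit <- fit_gaussian_counts(counts)
  expect_equal(fit$mu, 4, tolerance = 1e-6)
})

test_that("the fitted peak stays within one bin under 5% noise", {
  t <- 1:20
  mu_true <- 10
  base <- 100 * exp(-(t - mu_true)^2 / (2 * 3^2))
  for (s in 1:10) {
    set.seed(800 + s)
    noisy <- pmax(base + stats::rnorm(20, sd = 5), 0)
    fit <- fit_gaussian_counts(noisy)
    expect_lt(abs(fit$mu - mu_true), 1)
  }
})

test_that("Gaussian fitting demands enough occupied bins", {
  expect_error(fit_gaussian_counts(c(0, 5, 3, 0)), "at least 4")
})

test_that("Gaussian fit on dated bins reports a calendar peak", {
  starts <- as.Date("2020-02-03") + 7 * (0:19)
  mids <- as.numeric(starts) + 3 - (as.numeric(starts[1]) + 3)
  counts <- round(80 * exp(-(mids / 7 - 9)^2 / (2 * 2.5^2)))
  bins <- tibble::tibble(label = paste0("w", 1:20), start = starts,
                         end = starts + 6, is_merged = FALSE,
                         n_docs = as.integer(counts))
  fit <- fit_gaussian_counts(bins)
  expect_s3_class(fit$mu_date, "Date")
  expect_lt(abs(as.numeric(fit$mu_date - (starts[10] + 3))), 7)
})
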