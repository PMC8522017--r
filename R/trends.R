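# Temporal binning, train/test splitting by date, per-bin concatenated
# documents, the trend matrix, and Gaussian fitting of weekly counts.

iso_monday <- function(d) d - (as.integer(strftime(d, "%u")) - 1L)

#' Assign records to weekly time bins
#'
#' Bins records by ISO week (weeks start on Monday).  Records dated before
#' `merge_before` are pooled into a single merged bin — early sparse weeks
#' (e.g. January 2020 in a COVID corpus) carry too few papers for stable
#' weekly estimates.  Calendar weeks between the first and last occupied
#' bin that contain no records are retained with a count of zero.
#'
#' @param records a dated record tibble ([read_records()]); every record
#'   must have a non-`NA` date.
#' @param merge_before records dated strictly before this date share one
#'   merged bin (default `"2020-02-01"`); `NULL` disables merging.
#' @return The records with a `bin` label column added; the ordered bin
#'   table (columns `label`, `start`, `end`, `is_merged`, `n_docs`) is
#'   attached as attribute `"bins"` and retrieved with [bin_table()].
#' @export
assign_bins <- function(records, merge_before = as.Date("2020-02-01")) {
  records <- validate_records(records)
  undated <- is.na(records$date)
  if (any(undated)) {
    abort(paste0("undated record(s): ",
                 paste(utils::head(records$doc_id[undated], 5), collapse = ", ")))
  }
  if (!nrow(records)) abort("no records to bin")
  if (!is.null(merge_before)) merge_before <- as.Date(merge_before)
  merged <- if (is.null(merge_before)) rep(FALSE, nrow(records)) else
    records$date < merge_before
  weekly_dates <- records$date[!merged]

  bins <- tibble::tibble(label = character(), start = as.Date(character()),
                         end = as.Date(character()), is_merged = logical())
  if (any(merged)) {
    bins <- dplyr::bind_rows(bins, tibble::tibble(
      label = paste0("pre-", format(merge_before)),
      start = min(records$date[merged]),
      end = merge_before - 1L,
      is_merged = TRUE))
  }
  if (length(weekly_dates)) {
    first_monday <- iso_monday(min(weekly_dates))
    last_monday <- iso_monday(max(weekly_dates))
    mondays <- seq(first_monday, last_monday, by = 7L)
    starts <- mondays
    if (any(merged)) {
      # keep bin date ranges disjoint: the first weekly bin may begin
      # mid-week when the merge boundary falls inside it
      starts <- pmax(starts, merge_before)
    }
    bins <- dplyr::bind_rows(bins, tibble::tibble(
      label = strftime(mondays, "%G-W%V"),
      start = starts, end = mondays + 6L, is_merged = FALSE))
  }
  lab <- character(nrow(records))
  lab[merged] <- bins$label[bins$is_merged][1]
  if (length(weekly_dates)) {
    lab[!merged] <- strftime(iso_monday(records$date[!merged]), "%G-W%V")
  }
  records$bin <- lab
  counts <- table(factor(lab, levels = bins$label))
  bins$n_docs <- as.integer(counts)
  attr(records, "bins") <- bins
  records
}

#' Retrieve the bin table from binned records
#'
#' @param x the tibble returned by [assign_bins()].
#' @return Ordered tibble with columns `label`, `start`, `end`,
#'   `is_merged`, `n_docs` (zero-count bins included).
#' @export
bin_table <- function(x) {
  b <- attr(x, "bins", exact = TRUE)
  if (is.null(b)) abort("no bin table attached; was the input produced by assign_bins()?")
  b
}

#' Split time bins into training and testing periods
#'
#' Chooses the bin boundary whose cumulative document fraction is nearest
#' `train_fraction`; all bins up to and including the boundary form the
#' training period.  The split is by whole bins — a week is never divided —
#' mirroring an 8:2 date cutoff.
#'
#' @param bins a bin table ([bin_table()]) with `n_docs` counts.
#' @param train_fraction target training fraction in (0, 1), default 0.8.
#' @return A list with `train` and `test` (disjoint bin tables covering all
#'   bins), `cutoff_date` (last training date, inclusive) and
#'   `achieved_fraction`.
#' @export
split_train_test <- function(bins, train_fraction = 0.8) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  B <- nrow(bins)
  if (B < 2) abort("need at least two bins to split")
  total <- sum(bins$n_docs)
  if (total == 0) abort("bins contain no documents")
  cum_frac <- cumsum(bins$n_docs) / total
  candidates <- seq_len(B - 1)           # test side keeps at least one bin
  i <- candidates[which.min(abs(cum_frac[candidates] - train_fraction))]
  list(train = bins[seq_len(i), , drop = FALSE],
       test = bins[seq(i + 1, B), , drop = FALSE],
       cutoff_date = bins$end[[i]],
       achieved_fraction = cum_frac[[i]])
}

#' Per-bin concatenated bag-of-words documents
#'
#' Pools the token counts of all records in each bin into one combined
#' document (concatenation order is irrelevant under bag-of-words); empty
#' bins yield empty documents.
#'
#' @param records binned records from [assign_bins()].
#' @param vocab vocabulary tibble ([build_vocabulary()]).
#' @param tokens optional pre-computed token lists aligned with `records`
#'   (default: tokenized from `records$text`).
#' @return A B x V sparse count matrix, one row per bin (in bin order,
#'   labelled), with the bin table attached as attribute `"bins"`.
#' @export
weekly_documents <- function(records, vocab, tokens = NULL) {
  bins <- bin_table(records)
  if (is.null(tokens)) tokens <- tokenize(records$text)
  bow <- bow_corpus(tokens, vocab, doc_ids = records$doc_id)
  fac <- factor(records$bin, levels = bins$label)
  S <- Matrix::sparseMatrix(i = as.integer(fac), j = seq_len(nrow(records)),
                            x = 1, dims = c(nrow(bins), nrow(records)))
  out <- methods::as(S %*% bow, "generalMatrix")
  rownames(out) <- bins$label
  colnames(out) <- vocab$term
  attr(out, "bins") <- bins
  out
}

#' Temporal topic-trend matrix
#'
#' Infers, for every time bin, the topic proportions of the bin's
#' concatenated document by fold-in, producing the bins x topics matrix
#' rendered as a weekly trend heatmap.  Empty bins receive the prior mean
#' and are flagged.
#'
#' @param model a trained [train_lda()] model.
#' @param weekly_docs B x V per-bin count matrix ([weekly_documents()]).
#' @param iterations,seed fold-in settings ([infer_theta()]).
#' @param bins optional bin table; defaults to the one attached to
#'   `weekly_docs`.
#' @return An object of class `trend_matrix`: list with `bins` (bin table),
#'   `theta` (B x K matrix, rows sum to 1), `n_docs` (per-bin record
#'   counts) and `empty` (logical flags for prior-mean rows).
#' @export
trend_matrix <- function(model, weekly_docs, iterations = 200, seed = 1,
                         bins = NULL) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(bins)) bins <- attr(weekly_docs, "bins", exact = TRUE)
  if (is.null(bins)) {
    bins <- tibble::tibble(label = rownames(weekly_docs),
                           start = as.Date(NA), end = as.Date(NA),
                           is_merged = FALSE,
                           n_docs = NA_integer_)
  }
  theta <- infer_theta(model, weekly_docs, iterations = iterations, seed = seed)
  empty <- Matrix::rowSums(weekly_docs) == 0
  structure(list(bins = bins, theta = theta, n_docs = bins$n_docs,
                 empty = as.logical(empty)),
            class = "trend_matrix")
}

#' @export
print.trend_matrix <- function(x, ...) {
  cat(sprintf("Trend matrix: %d time bins x %d topics", nrow(x$theta),
              ncol(x$theta)))
  if (any(x$empty)) cat(sprintf(" (%d empty bins at prior mean)", sum(x$empty)))
  cat("\n")
  invisible(x)
}

#' @describeIn trend_matrix Long tibble: one row per (bin, topic) with the
#'   inferred proportion.
#' @param x a `trend_matrix`.
#' @param ... unused.
#' @method tidy trend_matrix
#' @export
tidy.trend_matrix <- function(x, ...) {
  B <- nrow(x$theta); K <- ncol(x$theta)
  tibble::tibble(
    bin = rep(x$bins$label, times = K),
    start = rep(x$bins$start, times = K),
    topic = rep(seq_len(K), each = B),
    n_docs = rep(x$bins$n_docs, times = K),
    proportion = as.vector(x$theta))
}

#' @describeIn trend_matrix One-row summary (bins, topics, empty bins).
#' @param object a `trend_matrix`.
#' @method glance trend_matrix
#' @export
glance.trend_matrix <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$theta), n_topics = ncol(x$theta),
                 n_empty_bins = sum(x$empty),
                 n_docs = sum(x$bins$n_docs))
}

# topics ordered by descending overall proportion (heatmap column order)
topic_display_order <- function(tm) {
  order(-colMeans(tm$theta), seq_len(ncol(tm$theta)))
}

#' Export a trend matrix as CSV
#'
#' Writes the bins x topics proportion matrix with the first column holding
#' bin labels and topic columns sorted by descending corpus-level
#' proportion (the conventional heatmap ordering).  A per-bin document
#' count sidecar can be written alongside.  Values are written at full
#' precision; color-scale choices (see [autoplot.trend_matrix()]) never
#' alter exported numbers.
#'
#' @param tm a [trend_matrix()] result.
#' @param path output CSV path.
#' @param counts_path optional path for a (bin, n_docs) sidecar CSV.
#' @return `path`, invisibly.
#' @export
write_trend_matrix <- function(tm, path, counts_path = NULL) {
  ord <- topic_display_order(tm)
  m <- tm$theta[, ord, drop = FALSE]
  colnames(m) <- paste0("topic", ord)
  out <- dplyr::bind_cols(tibble::tibble(bin = tm$bins$label),
                          tibble::as_tibble(m))
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(counts_path)) {
    readr::write_csv(tibble::tibble(bin = tm$bins$label,
                                    n_docs = tm$bins$n_docs),
                     counts_path, progress = FALSE)
  }
  invisible(path)
}

#' Fit a Gaussian curve to per-bin document counts
#'
#' Least-squares fit of \eqn{A \exp(-(t - \mu)^2 / (2\sigma^2))} to the bin
#' counts over bin midpoints (in days), the standard summary of the
#' rise-and-fall shape of weekly publication volume.
#'
#' @param bins a bin table with `n_docs` (and `start`/`end` dates), or a
#'   bare numeric count vector (then `t` is the bin index).
#' @return An object of class `gaussian_fit`: list with `amplitude`, `mu`
#'   (numeric, on the `t` axis), `mu_date` (Date, when dates are
#'   available), `sigma` (same units as `t`), `rss`, and `data` (tibble of
#'   `t`, `count`, `fitted`).
#' @export
fit_gaussian_counts <- function(bins) {
  if (is.numeric(bins)) {
    counts <- as.numeric(bins)
    t <- seq_along(counts)
    origin <- NULL
  } else {
    counts <- as.numeric(bins$n_docs)
    mid <- as.numeric(bins$start) + (as.numeric(bins$end) - as.numeric(bins$start)) / 2
    origin <- mid[[1]]
    t <- mid - origin
  }
  if (sum(counts > 0) < 4) abort("need at least 4 bins with nonzero counts")
  w <- counts / sum(counts)
  init <- list(A = max(counts), mu = sum(w * t),
               sigma = max(sqrt(sum(w * (t - sum(w * t))^2)), diff(range(t)) / 20))
  df <- data.frame(t = t, count = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ A * exp(-(t - mu)^2 / (2 * sigma^2)),
                      data = df, start = init,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf("Gaussian fit failed to converge (initializer A=%.3g, mu=%.3g, sigma=%.3g): %s",
                    init$A, init$mu, init$sigma, conditionMessage(e)))
    })
  cf <- coef(fit)
  fitted_vals <- cf[["A"]] * exp(-(t - cf[["mu"]])^2 / (2 * cf[["sigma"]]^2))
  structure(
    list(amplitude = cf[["A"]], mu = cf[["mu"]],
         mu_date = if (!is.null(origin)) as.Date(origin + cf[["mu"]],
                                                 origin = "1970-01-01") else NULL,
         sigma = abs(cf[["sigma"]]),
         rss = sum((counts - fitted_vals)^2),
         data = tibble::tibble(t = t, count = counts, fitted = fitted_vals)),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian count fit: A = %.2f, mu = %.2f%s, sigma = %.2f, RSS = %.3g\n",
              x$amplitude, x$mu,
              if (!is.null(x$mu_date)) paste0(" (", format(x$mu_date), ")") else "",
              x$sigma, x$rss))
  invisible(x)
}

#' @describeIn fit_gaussian_counts Parameter estimates as a tibble.
#' @param x a `gaussian_fit`.
#' @param ... unused.
#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "mu", "sigma"),
                 estimate = c(x$amplitude, x$mu, x$sigma))
}

#' @describeIn fit_gaussian_counts One-row fit summary.
#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_bins = nrow(x$data))
}
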