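# Synthetic corpora from a known LDA generative process: ground-truth
# topics, time-varying topic trajectories, category labels and controlled
# contamination, so every pipeline stage can be checked against truth.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Render vocabulary indices as pronounceable pseudo-words
#'
#' Maps 1-based term indices to fixed-width alphabetic codes (`"waaab"`,
#' `"waaac"`, ...).  The rendering is purely alphabetic and lexicographic in
#' the index, so synthetic text survives [tokenize()] and
#' [build_vocabulary()] unchanged and in index order — the full text
#' pipeline is exercised rather than bypassed.
#'
#' @param i integer vector of term indices (>= 1).
#' @param width number of code letters (default 4; supports V up to 26^4).
#' @return Character vector of pseudo-words.
#' @export
pseudo_word <- function(i, width = 4) {
  stopifnot(all(i >= 1), all(i <= 26^width))
  x <- as.integer(i) - 1L
  code <- matrix("", length(x), width)
  for (p in seq(width, 1)) {
    code[, p] <- letters[x %% 26L + 1L]
    x <- x %/% 26L
  }
  paste0("w", apply(code, 1, paste, collapse = ""))
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate ground-truth topic-word distributions
#'
#' @param K number of topics.
#' @param V vocabulary size (V >= K required for block mode).
#' @param concentration Dirichlet concentration per term for
#'   `mode = "dirichlet"` (default 0.1: sparse, well-separated topics).
#' @param mode `"dirichlet"` (rows drawn from a symmetric Dirichlet) or
#'   `"disjoint_blocks"` (row k uniform on its own V/K block of terms,
#'   zero elsewhere).
#' @param seed RNG seed.
#' @param smooth optional additive smoothing applied after block
#'   construction (default 0: exactly disjoint support).
#' @return A K x V row-stochastic matrix with pseudo-word column names.
#' @export
gen_topics <- function(K, V, concentration = 0.1,
                       mode = c("dirichlet", "disjoint_blocks"), seed = 1,
                       smooth = 0) {
  mode <- match.arg(mode)
  if (mode == "disjoint_blocks" && V < K) abort("block mode requires V >= K")
  phi <- with_seed(seed, {
    if (mode == "dirichlet") {
      rdirichlet(K, rep(concentration, V))
    } else {
      m <- matrix(0, K, V)
      bounds <- floor(seq(0, V, length.out = K + 1))
      for (k in seq_len(K)) {
        idx <- seq(bounds[k] + 1, bounds[k + 1])
        m[k, idx] <- 1 / length(idx)
      }
      m
    }
  })
  if (smooth > 0) {
    phi <- phi + smooth
    phi <- phi / rowSums(phi)
  }
  colnames(phi) <- pseudo_word(seq_len(V))
  rownames(phi) <- paste0("topic", seq_len(K))
  phi
}

#' Topic trajectory specifications
#'
#' Constructors for the per-bin weight curves of each topic.  Weights are
#' arbitrary nonnegative values; stacking the K trajectories and
#' renormalizing each bin yields the per-bin topic-mixture means.
#'
#' @param level,from,to,center,width,height,base,midpoint,rate shape
#'   parameters; all induced weights must be nonnegative.
#' @return A `trajectory_spec` list.
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
traj_constant <- function(level = 1) {
  structure(list(kind = "constant", level = level), class = "trajectory_spec")
}

#' @rdname trajectories
#' @export
traj_linear <- function(from = 1, to = 0.5) {
  structure(list(kind = "linear", from = from, to = to),
            class = "trajectory_spec")
}

#' @rdname trajectories
#' @export
traj_pulse <- function(center = 3, width = 2, height = 2, base = 0.15) {
  structure(list(kind = "gaussian_pulse", center = center, width = width,
                 height = height, base = base), class = "trajectory_spec")
}

#' @rdname trajectories
#' @export
traj_logistic <- function(midpoint = 16, rate = 0.4, from = 0.2, to = 1.2) {
  structure(list(kind = "logistic", midpoint = midpoint, rate = rate,
                 from = from, to = to), class = "trajectory_spec")
}

traj_values <- function(spec, n_bins) {
  b <- seq_len(n_bins)
  v <- switch(spec$kind,
    constant = rep(spec$level, n_bins),
    linear = seq(spec$from, spec$to, length.out = n_bins),
    gaussian_pulse = spec$base +
      spec$height * exp(-(b - spec$center)^2 / (2 * spec$width^2)),
    logistic = spec$from + (spec$to - spec$from) /
      (1 + exp(-spec$rate * (b - spec$midpoint))))
  if (any(v < 0)) abort("trajectory induces negative weights")
  v
}

#' Reference trajectory set mimicking observed literature dynamics
#'
#' One early Gaussian pulse (a topic that spikes in the first weeks and
#' fades, like early genome-sequence reports), one logistic riser (a topic
#' that grows through the period, like mental-health studies), one linear
#' faller, and flat trajectories for the remaining topics.
#'
#' @param K number of topics (>= 3).
#' @return A list of K `trajectory_spec` objects.
#' @export
default_trajectories <- function(K) {
  stopifnot(K >= 3)
  c(list(traj_pulse(center = 3, width = 2, height = 2, base = 0.15),
         traj_logistic(midpoint = 16, rate = 0.4, from = 0.2, to = 1.2),
         traj_linear(from = 1.2, to = 0.35)),
    purrr::map(seq_len(K - 3), function(i) traj_constant(0.8)))
}

#' Per-bin topic-mixture means from stacked trajectories
#'
#' @param trajectories list of K `trajectory_spec`s.
#' @param n_bins number of time bins.
#' @return A B x K matrix; each row is a point on the simplex.
#' @export
trajectory_means <- function(trajectories, n_bins) {
  W <- vapply(trajectories, traj_values, numeric(n_bins), n_bins = n_bins)
  W / rowSums(W)
}

#' Generate a synthetic abstract corpus with known structure
#'
#' Ancestral sampling from the LDA generative process with time-varying
#' mixtures: for each bin the Dirichlet mean comes from the renormalized
#' trajectories; each document draws topic proportions
#' `theta ~ Dirichlet(alpha_scale * m)`, a Poisson token count, then tokens
#' by `z ~ theta`, `w ~ phi[z, ]`, rendered as pseudo-words and joined into
#' abstract text.  A contamination fraction of documents is replaced by
#' too-short texts or correction notices (exercising [clean_corpus()]), and
#' an optional category scheme labels documents whose mixtures are tilted
#' toward their categories' topics.
#'
#' @param phi K x V ground-truth topic-word matrix ([gen_topics()]).
#' @param trajectories list of K trajectory specs (default
#'   [default_trajectories()]).
#' @param n_bins number of weekly bins (default 26).
#' @param docs_per_bin documents per bin (default 200).
#' @param doc_length mean Poisson token count per document (default 120,
#'   giving abstract-like lengths of roughly 90-150 tokens).
#' @param alpha_scale Dirichlet concentration multiplier (default 5:
#'   documents lean toward a few topics without being degenerate).
#' @param contamination list with `short_frac` and `correction_frac`
#'   (defaults 0.02 and 0.01), the per-document probabilities of replacing
#'   the abstract with a too-short text or a correction notice.
#' @param categories optional named list mapping category labels to the
#'   topic indices (1-3 each) they concentrate on; `NULL` for no labels.
#' @param label_frac fraction of clean documents receiving labels when
#'   `categories` is given (default 0.5).
#' @param category_weight tilt weight toward a labeled document's category
#'   topics (default 0.8; recovery of the planted argmax expects >= 0.7).
#' @param multi_label_frac fraction of labeled documents carrying two
#'   category labels (default 0.25).
#' @param start_date date of the first bin's Monday (default
#'   `"2020-02-03"`); bins are consecutive calendar weeks.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return A list with `records` (a record tibble, dates spanning the bins)
#'   and `truth`, an object of class `synthetic_truth` holding `phi`,
#'   `trajectories` (B x K renormalized means), `theta` (D x K),
#'   `bin` (per-document bin index), `contaminated` (per-document
#'   `"none"`/`"short"`/`"correction"`), `category_map` (tibble of pairs),
#'   `category_topics`, `vocab`, `seed` and the generation parameters.
#' @export
gen_corpus <- function(phi, trajectories = default_trajectories(nrow(phi)),
                       n_bins = 26, docs_per_bin = 200, doc_length = 120,
                       alpha_scale = 5,
                       contamination = list(short_frac = 0.02,
                                            correction_frac = 0.01),
                       categories = NULL, label_frac = 0.5,
                       category_weight = 0.8, multi_label_frac = 0.25,
                       start_date = as.Date("2020-02-03"), seed = 1) {
  K <- nrow(phi); V <- ncol(phi)
  if (length(trajectories) != K) abort("need one trajectory per topic")
  short_frac <- contamination$short_frac %||% 0
  corr_frac <- contamination$correction_frac %||% 0
  if (short_frac < 0 || corr_frac < 0 || short_frac + corr_frac > 1) {
    abort("contamination fractions must be nonnegative and sum to at most 1")
  }
  if (docs_per_bin < 1) abort("docs_per_bin must be at least 1")
  start_date <- as.Date(start_date)
  M <- trajectory_means(trajectories, n_bins)
  D <- n_bins * docs_per_bin
  words <- colnames(phi)
  if (is.null(words)) words <- pseudo_word(seq_len(V))

  cat_labels <- names(categories)
  out <- with_seed(seed, {
    bin_of <- rep(seq_len(n_bins), each = docs_per_bin)
    dates <- start_date + (bin_of - 1L) * 7L + sample(0:6, D, replace = TRUE)
    u <- runif(D)
    contam <- ifelse(u < short_frac, "short",
                     ifelse(u < short_frac + corr_frac, "correction", "none"))
    labels <- vector("list", D)
    theta <- matrix(0, D, K)
    texts <- character(D)
    for (d in seq_len(D)) {
      m <- M[bin_of[[d]], ]
      if (!is.null(categories) && contam[[d]] == "none" &&
          runif(1) < label_frac) {
        n_lab <- if (length(cat_labels) > 1 && runif(1) < multi_label_frac) 2L else 1L
        labs <- sample(cat_labels, n_lab)
        labels[[d]] <- labs
        cat_t <- unique(unlist(categories[labs]))
        tilt <- numeric(K)
        tilt[cat_t] <- 1 / length(cat_t)
        m <- (1 - category_weight) * m + category_weight * tilt
      }
      th <- rdirichlet(1, alpha_scale * m)[1, ]
      theta[d, ] <- th
      if (contam[[d]] == "short") {
        texts[[d]] <- sprintf("brief note %s", pseudo_word(sample.int(V, 1)))
      } else if (contam[[d]] == "correction") {
        texts[[d]] <- paste("This corrects the article DOI 10.1000/synth.",
                            paste(words[sample.int(V, 6, replace = TRUE)],
                                  collapse = " "))
      } else {
        n_tok <- max(1L, rpois(1, doc_length))
        z <- sample.int(K, n_tok, replace = TRUE, prob = th)
        w_idx <- integer(n_tok)
        for (k in unique(z)) {
          sel <- z == k
          w_idx[sel] <- sample.int(V, sum(sel), replace = TRUE,
                                   prob = phi[k, ])
        }
        texts[[d]] <- paste(words[w_idx], collapse = " ")
      }
    }
    list(bin_of = bin_of, dates = dates, contam = contam, labels = labels,
         theta = theta, texts = texts)
  })

  doc_id <- sprintf("SYN%05d", seq_len(D))
  records <- new_record_tibble(
    doc_id = doc_id, date = out$dates, text = out$texts,
    categories = purrr::map(out$labels, function(x) if (is.null(x)) character() else x),
    date_flag = rep("ok", D))
  category_map <- tibble::tibble(
    doc_id = rep(doc_id, lengths(records$categories)),
    category = unlist(records$categories, use.names = FALSE) %||% character())
  truth <- structure(
    list(phi = phi, trajectories = M, theta = out$theta, bin = out$bin_of,
         contaminated = out$contam, category_map = category_map,
         category_topics = categories,
         vocab = tibble::tibble(index = seq_len(V), term = words),
         seed = seed,
         params = list(K = K, V = V, n_bins = n_bins,
                       docs_per_bin = docs_per_bin, doc_length = doc_length,
                       alpha_scale = alpha_scale,
                       short_frac = short_frac, correction_frac = corr_frac,
                       label_frac = label_frac,
                       category_weight = category_weight,
                       multi_label_frac = multi_label_frac,
                       start_date = as.character(start_date))),
    class = "synthetic_truth")
  list(records = records, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic LDA ground truth: K = %d, V = %d, %d bins x %d docs, seed %d\n",
              p$K, p$V, p$n_bins, p$docs_per_bin, x$seed))
  invisible(x)
}

#' Write / read a synthetic fixture directory
#'
#' Lays out `records.jsonl` plus a `truth/` subdirectory with `phi.csv`,
#' `trajectories.csv`, `theta.csv` and `meta.json`, all plain text, such
#' that [read_fixture()] reproduces records and truth.
#'
#' @param sim the list returned by [gen_corpus()].
#' @param dir fixture directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  truth_dir <- file.path(dir, "truth")
  if (!dir.exists(truth_dir)) dir.create(truth_dir, recursive = TRUE)
  write_records(sim$records, file.path(dir, "records.jsonl"), "jsonl")
  tr <- sim$truth
  readr::write_csv(tibble::as_tibble(as.data.frame(tr$phi)),
                   file.path(truth_dir, "phi.csv"), progress = FALSE)
  traj <- tibble::as_tibble(as.data.frame(tr$trajectories))
  names(traj) <- paste0("topic", seq_len(ncol(tr$trajectories)))
  readr::write_csv(traj, file.path(truth_dir, "trajectories.csv"),
                   progress = FALSE)
  th <- tibble::as_tibble(as.data.frame(tr$theta))
  names(th) <- paste0("topic", seq_len(ncol(tr$theta)))
  readr::write_csv(th, file.path(truth_dir, "theta.csv"), progress = FALSE)
  meta <- list(seed = tr$seed, params = tr$params,
               bin = tr$bin, contaminated = tr$contaminated,
               category_topics = tr$category_topics,
               category_map = as.list(tr$category_map),
               terms = tr$vocab$term)
  jsonlite::write_json(meta, file.path(truth_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fixture
#' @param dir a directory written by [write_fixture()].
#' @export
read_fixture <- function(dir) {
  records <- read_records(file.path(dir, "records.jsonl"), "jsonl")
  truth_dir <- file.path(dir, "truth")
  meta <- jsonlite::read_json(file.path(truth_dir, "meta.json"),
                              simplifyVector = TRUE)
  read_mat <- function(path) {
    as.matrix(readr::read_csv(path, col_types = readr::cols(.default = "d"),
                              progress = FALSE))
  }
  phi <- read_mat(file.path(truth_dir, "phi.csv"))
  colnames(phi) <- meta$terms
  rownames(phi) <- paste0("topic", seq_len(nrow(phi)))
  truth <- structure(
    list(phi = phi,
         trajectories = unname(read_mat(file.path(truth_dir, "trajectories.csv"))),
         theta = unname(read_mat(file.path(truth_dir, "theta.csv"))),
         bin = as.integer(meta$bin),
         contaminated = as.character(meta$contaminated),
         category_map = tibble::as_tibble(meta$category_map),
         category_topics = meta$category_topics,
         vocab = tibble::tibble(index = seq_along(meta$terms),
                                term = as.character(meta$terms)),
         seed = meta$seed, params = meta$params),
    class = "synthetic_truth")
  list(records = records, truth = truth)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, purrr::map(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Match estimated topics to reference topics
#'
#' Finds the assignment of rows of `phi_a` to rows of `phi_b` minimizing
#' the total Hellinger distance: exhaustive over permutations for K <= 8
#' (exact), greedy otherwise; ties broken toward the lowest topic index.
#'
#' @param phi_a,phi_b two K x V row-stochastic matrices over the same
#'   vocabulary.
#' @return A tibble with columns `topic_a`, `topic_b`, `distance`; the
#'   mean matched distance is attached as attribute `"mean_distance"`.
#' @export
match_topics <- function(phi_a, phi_b) {
  K <- nrow(phi_a)
  if (nrow(phi_b) != K || ncol(phi_b) != ncol(phi_a)) {
    abort("phi matrices must have identical dimensions")
  }
  dmat <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) dmat[i, j] <- hellinger(phi_a[i, ], phi_b[j, ])
  }
  if (K <= 8) {
    perms <- all_permutations(K)
    costs <- apply(perms, 1, function(p) sum(dmat[cbind(seq_len(K), p)]))
    assign_b <- perms[which.min(costs), ]
  } else {
    assign_b <- integer(K)
    used <- logical(K)
    for (i in seq_len(K)) {
      d <- dmat[i, ]
      d[used] <- Inf
      j <- which.min(d)
      assign_b[i] <- j
      used[j] <- TRUE
    }
  }
  out <- tibble::tibble(topic_a = seq_len(K), topic_b = as.integer(assign_b),
                        distance = dmat[cbind(seq_len(K), assign_b)])
  attr(out, "mean_distance") <- mean(out$distance)
  out
}
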