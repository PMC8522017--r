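# Reading, writing and cleaning abstract-record corpora.
#
# A corpus is an ordinary tibble with one row per document:
#   doc_id     character, unique
#   date       Date (day precision; NA when unparseable)
#   text       character abstract
#   categories list column of character label vectors
#   date_flag  "ok", "missing_day" (day imputed as 1), "unparseable", "missing"

RECORD_COLUMNS <- c("doc_id", "date", "text", "categories", "date_flag")

new_record_tibble <- function(doc_id = character(), date = as.Date(character()),
                              text = character(), categories = list(),
                              date_flag = character()) {
  tibble::tibble(doc_id = as.character(doc_id), date = date,
                 text = as.character(text), categories = categories,
                 date_flag = date_flag)
}

#' Parse publication dates in Medline or ISO form
#'
#' Accepts `"YYYY Mon DD"` (Medline), `"YYYY-MM-DD"` (ISO), and the truncated
#' forms `"YYYY Mon"` / `"YYYY-MM"` / `"YYYY"`, for which the missing day
#' (and month) are imputed as 1 and the record flagged `"missing_day"`.
#' Unparseable strings give `NA` with flag `"unparseable"`; empty or missing
#' strings give flag `"missing"`.
#'
#' @param x character vector of date strings.
#' @return A tibble with columns `date` (Date) and `date_flag` (character).
#' @export
parse_record_date <- function(x) {
  x <- as.character(x)
  n <- length(x)
  date <- rep(as.Date(NA), n)
  flag <- rep("unparseable", n)
  x_trim <- stringr::str_squish(ifelse(is.na(x), "", x))

  miss <- x_trim == ""
  flag[miss] <- "missing"

  try_fmt <- function(idx, fmt, imputed) {
    if (!length(idx)) return(invisible(NULL))
    d <- as.Date(x_trim[idx], format = fmt)
    hit <- idx[!is.na(d)]
    date[hit] <<- d[!is.na(d)]
    flag[hit] <<- if (imputed) "missing_day" else "ok"
    invisible(NULL)
  }
  todo <- function() which(flag == "unparseable")
  try_fmt(todo(), "%Y-%m-%d", FALSE)
  try_fmt(todo(), "%Y %b %d", FALSE)
  # truncated forms: append day (and month) 1
  idx <- todo()
  if (length(idx)) {
    ym_iso <- grepl("^\\d{4}-\\d{2}$", x_trim[idx])
    if (any(ym_iso)) {
      i <- idx[ym_iso]
      d <- as.Date(paste0(x_trim[i], "-01"), format = "%Y-%m-%d")
      date[i[!is.na(d)]] <- d[!is.na(d)]
      flag[i[!is.na(d)]] <- "missing_day"
    }
  }
  idx <- todo()
  if (length(idx)) {
    d <- as.Date(paste(x_trim[idx], "1"), format = "%Y %b %d")
    date[idx[!is.na(d)]] <- d[!is.na(d)]
    flag[idx[!is.na(d)]] <- "missing_day"
  }
  idx <- todo()
  if (length(idx)) {
    yr <- grepl("^\\d{4}$", x_trim[idx])
    if (any(yr)) {
      i <- idx[yr]
      date[i] <- as.Date(paste0(x_trim[i], "-01-01"))
      flag[i] <- "missing_day"
    }
  }
  tibble::tibble(date = date, date_flag = flag)
}

#' Read abstract records
#'
#' Reads a corpus of abstract records from a Medline-dialect flat file
#' (`PMID`/`DP`/`AB` tags), JSON lines (one object per line with fields
#' `doc_id`, `date`, `text` and optional `categories`), or CSV (columns
#' `doc_id`, `date`, `text`, optional `categories` with `;`-separated
#' labels).  Records with unparseable dates are kept and flagged in the
#' `date_flag` column, never silently dropped.
#'
#' @param path path to the input file.
#' @param format `"medline"`, `"jsonl"`, `"csv"`, or `"auto"` to guess from
#'   the file extension (`.jsonl`/`.ndjson`, `.csv`, anything else Medline).
#' @return A tibble with columns `doc_id`, `date`, `text`, `categories`
#'   (list column) and `date_flag`.
#' @seealso [clean_corpus()], [write_records()]
#' @export
read_records <- function(path, format = c("auto", "medline", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("input file does not exist: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, jsonl = "jsonl", ndjson = "jsonl", csv = "csv",
                     "medline")
  }
  rec <- switch(format,
    medline = read_medline(path),
    jsonl   = read_jsonl_records(path),
    csv     = read_csv_records(path))
  dup <- rec$doc_id[duplicated(rec$doc_id)]
  if (length(dup)) {
    warn(paste0("duplicate doc_id in ", path, ": ",
                paste(utils::head(unique(dup), 5), collapse = ", ")))
  }
  rec
}

read_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list()
  cur <- list()
  tag <- NA_character_
  flush_record <- function(cur) {
    if (!length(cur)) return(NULL)
    list(doc_id = if (is.null(cur$PMID)) NA_character_ else cur$PMID,
         date = if (is.null(cur$DP)) "" else cur$DP,
         text = if (is.null(cur$AB)) "" else cur$AB)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\s*$", line)) {
      r <- flush_record(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- list(); tag <- NA_character_
      next
    }
    m <- regmatches(line, regexec("^([A-Z][A-Z0-9]{1,3})\\s*- (.*)$", line))[[1]]
    if (length(m) == 3L) {
      tag <- m[[2]]
      val <- m[[3]]
      cur[[tag]] <- if (is.null(cur[[tag]])) val else paste(cur[[tag]], val)
    } else if (grepl("^\\s{2,}", line) && !is.na(tag)) {
      cur[[tag]] <- paste(cur[[tag]], stringr::str_trim(line))
    } else {
      abort(paste0("malformed Medline line ", i, " in ", path, ": ",
                   substr(line, 1, 60)))
    }
  }
  r <- flush_record(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  if (!length(recs)) return(new_record_tibble())
  doc_id <- purrr::map_chr(recs, "doc_id")
  pd <- parse_record_date(purrr::map_chr(recs, "date"))
  new_record_tibble(doc_id = doc_id, date = pd$date,
                    text = purrr::map_chr(recs, "text"),
                    categories = rep(list(character()), length(recs)),
                    date_flag = pd$date_flag)
}

read_jsonl_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) return(new_record_tibble())
  objs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    objs[[i]] <- tryCatch(jsonlite::fromJSON(lines[[i]]),
      error = function(e) abort(paste0("unparseable JSON at line ", i,
                                       " of ", path, ": ", conditionMessage(e))))
  }
  get_chr <- function(o, field, default = "") {
    v <- o[[field]]
    if (is.null(v) || !length(v)) default else as.character(v)[[1]]
  }
  doc_id <- purrr::map_chr(objs, get_chr, field = "doc_id", default = NA_character_)
  pd <- parse_record_date(purrr::map_chr(objs, get_chr, field = "date"))
  cats <- purrr::map(objs, function(o) {
    v <- o[["categories"]]
    if (is.null(v)) character() else as.character(unlist(v))
  })
  new_record_tibble(doc_id = doc_id, date = pd$date,
                    text = purrr::map_chr(objs, get_chr, field = "text"),
                    categories = cats, date_flag = pd$date_flag)
}

read_csv_records <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("doc_id", "date", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("CSV ", path, " lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(df)) return(new_record_tibble())
  pd <- parse_record_date(df$date)
  cats <- if ("categories" %in% names(df)) {
    purrr::map(df$categories, function(s) {
      if (is.na(s) || s == "") character() else
        stringr::str_trim(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  } else rep(list(character()), nrow(df))
  new_record_tibble(doc_id = df$doc_id, date = pd$date,
                    text = ifelse(is.na(df$text), "", df$text),
                    categories = cats, date_flag = pd$date_flag)
}

#' Write abstract records
#'
#' Mirrors [read_records()]: writes the corpus as JSON lines, CSV, or
#' Medline-dialect text, UTF-8 encoded, such that reading the file back
#' reproduces the records.
#'
#' @param records a record tibble (see [read_records()]).
#' @param path output path.
#' @param format `"jsonl"`, `"csv"` or `"medline"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("jsonl", "csv", "medline")) {
  format <- match.arg(format)
  records <- validate_records(records)
  if (format == "jsonl") {
    lines <- purrr::pmap_chr(
      list(records$doc_id, as.character(records$date), records$text,
           records$categories),
      function(id, d, tx, cats) {
        jsonlite::toJSON(list(doc_id = id,
                              date = if (is.na(d)) "" else d,
                              text = tx,
                              categories = as.character(cats)),
                         auto_unbox = TRUE)
      })
    writeLines(lines, path, useBytes = TRUE)
  } else if (format == "csv") {
    out <- tibble::tibble(
      doc_id = records$doc_id,
      date = as.character(records$date),
      text = records$text,
      categories = purrr::map_chr(records$categories, paste, collapse = ";"))
    readr::write_csv(out, path, progress = FALSE)
  } else {
    blocks <- purrr::pmap(
      list(records$doc_id, records$date, records$text),
      function(id, d, tx) {
        c(paste0("PMID- ", id),
          paste0("DP  - ", if (is.na(d)) "" else format(d, "%Y %b %d")),
          paste0("AB  - ", tx),
          "")
      })
    writeLines(unlist(blocks), path, useBytes = TRUE)
  }
  invisible(path)
}

validate_records <- function(records, arg = "records") {
  if (!is.data.frame(records)) abort(paste0(arg, " must be a data frame"))
  need <- c("doc_id", "text")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0(arg, " lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  if (!"date" %in% names(records)) records$date <- as.Date(NA)
  if (!"categories" %in% names(records)) {
    records$categories <- rep(list(character()), nrow(records))
  }
  if (!"date_flag" %in% names(records)) {
    records$date_flag <- ifelse(is.na(records$date), "missing", "ok")
  }
  records
}

#' Apply the standard corpus exclusion filters
#'
#' Drops records whose abstract is empty, shorter than `min_chars`
#' characters (whitespace included), or contains the correction-notice
#' marker.  Each excluded record is counted under exactly one rule with
#' precedence empty > too_short > correction_notice, so the per-rule counts
#' are disjoint and sum, with the kept count, to the input count.
#'
#' @param records a record tibble (see [read_records()]).
#' @param min_chars minimum abstract length in characters (default 50).
#' @param correction_marker substring identifying correction notices
#'   (default `"This corrects the article DOI"`); matched case-sensitively.
#' @return The kept records, input order preserved, with the
#'   [exclusion_report()] attached as attribute `"exclusion_report"`.
#' @examples
#' recs <- tibble::tibble(
#'   doc_id = c("a", "b", "c"),
#'   date = as.Date("2020-03-01") + 0:2,
#'   text = c(strrep("x", 60), "too short",
#'            paste(strrep("y", 60), "This corrects the article DOI 10.1/x")))
#' kept <- clean_corpus(recs)
#' exclusion_report(kept)
#' @export
clean_corpus <- function(records, min_chars = 50,
                         correction_marker = "This corrects the article DOI") {
  records <- validate_records(records)
  txt <- records$text
  is_empty <- is.na(txt) | txt == ""
  is_short <- !is_empty & nchar(txt, type = "chars") < min_chars
  is_corr <- !is_empty & !is_short &
    stringr::str_detect(txt, stringr::fixed(correction_marker))
  keep <- !(is_empty | is_short | is_corr)
  report <- tibble::tibble(
    n_input = nrow(records),
    n_kept = sum(keep),
    empty = sum(is_empty),
    too_short = sum(is_short),
    correction_notice = sum(is_corr))
  kept <- records[keep, , drop = FALSE]
  attr(kept, "exclusion_report") <- report
  kept
}

#' Retrieve the exclusion report from a cleaned corpus
#'
#' @param x the tibble returned by [clean_corpus()].
#' @return A one-row tibble with columns `n_input`, `n_kept`, `empty`,
#'   `too_short`, `correction_notice`.
#' @export
exclusion_report <- function(x) {
  rep <- attr(x, "exclusion_report", exact = TRUE)
  if (is.null(rep)) abort("no exclusion report attached; was the input produced by clean_corpus()?")
  rep
}

#' Read a document-to-category label map
#'
#' Reads a two-column delimited file (`doc_id`, `category`; comma, tab or
#' the file's header-declared delimiter) with one pair per line.  A document
#' may appear on several lines and so carry several labels.
#'
#' @param path path to the label file.
#' @return A tibble with columns `doc_id` and `category`, one row per pair.
#' @seealso [category_sets()]
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) abort(paste0("category map file does not exist: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) {
    return(tibble::tibble(doc_id = character(), category = character()))
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(paste0("malformed category-map line ", bad[[1]], " in ", path, ": ",
                 substr(lines[[bad[[1]]]], 1, 60)))
  }
  out <- tibble::tibble(
    doc_id = stringr::str_trim(purrr::map_chr(parts, 1)),
    category = stringr::str_trim(purrr::map_chr(parts, 2)))
  # drop a conventional header row if present
  if (nrow(out) && identical(tolower(out$doc_id[[1]]), "doc_id")) {
    out <- out[-1, , drop = FALSE]
  }
  dplyr::distinct(out)
}

#' Expand a category map into per-document label sets
#'
#' @param map a tibble of (`doc_id`, `category`) pairs from
#'   [read_category_map()].
#' @param doc_ids optional character vector of documents to report; ids
#'   absent from the map get an empty label set.
#' @return A named list of character vectors, one per document.
#' @export
category_sets <- function(map, doc_ids = NULL) {
  sets <- split(map$category, map$doc_id)
  sets <- purrr::map(sets, unique)
  if (is.null(doc_ids)) return(sets)
  out <- purrr::map(doc_ids, function(id) {
    s <- sets[[id]]
    if (is.null(s)) character() else s
  })
  names(out) <- doc_ids
  out
}
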