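#' Construct a forum corpus
#'
#' Bundles a post table with a per-author index. Posts carry the five fields
#' every reader must supply: `post_id`, `author_id`, `thread_id`, `timestamp`
#' (POSIXct, UTC) and `text`. The author index maps each `author_id` to the
#' row indices of that author's posts, sorted by timestamp, and exactly
#' partitions the corpus.
#'
#' @param posts A data.frame with columns `post_id`, `author_id`, `thread_id`,
#'   `timestamp` (POSIXct) and `text`.
#' @return An object of class `ohc_corpus`: a list with elements `posts`
#'   (the table, row order preserved) and `author_index` (named list of
#'   integer row indices per author, timestamp-sorted).
#' @export
ohc_corpus <- function(posts) {
  required <- c("post_id", "author_id", "thread_id", "timestamp", "text")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols) > 0L) {
    stop("posts is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  posts$post_id <- as.character(posts$post_id)
  posts$author_id <- as.character(posts$author_id)
  posts$thread_id <- as.character(posts$thread_id)
  posts$text <- as.character(posts$text)
  if (anyDuplicated(posts$post_id)) {
    dup <- posts$post_id[duplicated(posts$post_id)][1L]
    stop("duplicate post_id: ", dup)
  }
  if (!inherits(posts$timestamp, "POSIXct")) {
    stop("timestamp column must be POSIXct")
  }
  if (anyNA(posts$timestamp)) stop("timestamp column contains missing values")
  if (any(!nzchar(posts$text))) stop("text must be non-empty for every post")
  rownames(posts) <- NULL
  idx <- split(seq_len(nrow(posts)), posts$author_id)
  idx <- lapply(idx, function(i) i[order(posts$timestamp[i], i)])
  structure(list(posts = posts, author_index = idx), class = "ohc_corpus")
}

#' @export
print.ohc_corpus <- function(x, ...) {
  cat(sprintf(
    "<ohc_corpus> %d posts, %d authors, %d threads\n",
    nrow(x$posts), length(x$author_index), length(unique(x$posts$thread_id))
  ))
  invisible(x)
}

parse_timestamps <- function(x) {
  x <- as.character(x)
  ts <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  alt <- is.na(ts)
  if (any(alt)) {
    ts[alt] <- as.POSIXct(x[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  ts
}

#' Read a forum corpus from disk
#'
#' Reads a line-delimited dump of posts in either `jsonl` (one JSON object per
#' line with keys `post_id`, `author_id`, `thread_id`, `timestamp`, `text`)
#' or `csv` (same columns) format. Timestamps are ISO-8601 and interpreted as
#' UTC. In `strict` mode (default) a record with a missing or unparseable
#' timestamp, or a missing field, is an error naming the offending line; in
#' lenient mode such records are dropped and the dropped count reported.
#'
#' @param path Path to the dump.
#' @param format `"jsonl"` or `"csv"`.
#' @param strict Logical; error on bad records (default) or drop them.
#' @return An [ohc_corpus].
#' @export
read_corpus <- function(path, format = c("jsonl", "csv"), strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  required <- c("post_id", "author_id", "thread_id", "timestamp", "text")
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- nzchar(trimws(lines))
    line_no <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) {
      warning("empty corpus file: ", path)
      empty <- data.frame(
        post_id = character(), author_id = character(),
        thread_id = character(),
        timestamp = as.POSIXct(character(), tz = "UTC"),
        text = character(), stringsAsFactors = FALSE
      )
      return(ohc_corpus(empty))
    }
    recs <- vector("list", length(lines))
    bad <- logical(length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      ok <- is.list(rec) && all(required %in% names(rec)) &&
        all(vapply(rec[required], function(v) length(v) == 1L && !is.na(v), TRUE))
      if (!ok) {
        if (strict) stop("malformed record at line ", line_no[i], " of ", path)
        bad[i] <- TRUE
        next
      }
      recs[[i]] <- rec[required]
    }
    recs <- recs[!bad]
    df <- data.frame(
      post_id = vapply(recs, function(r) as.character(r$post_id), ""),
      author_id = vapply(recs, function(r) as.character(r$author_id), ""),
      thread_id = vapply(recs, function(r) as.character(r$thread_id), ""),
      timestamp_raw = vapply(recs, function(r) as.character(r$timestamp), ""),
      text = vapply(recs, function(r) as.character(r$text), ""),
      stringsAsFactors = FALSE
    )
    src_line <- line_no[!bad]
    n_dropped_parse <- sum(bad)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(df) == 0L) {
      warning("empty corpus file: ", path)
      empty <- data.frame(
        post_id = character(), author_id = character(),
        thread_id = character(),
        timestamp = as.POSIXct(character(), tz = "UTC"),
        text = character(), stringsAsFactors = FALSE
      )
      return(ohc_corpus(empty))
    }
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L) stop("corpus csv missing column(s): ", paste(miss, collapse = ", "))
    df$timestamp_raw <- df$timestamp
    df$timestamp <- NULL
    src_line <- seq_len(nrow(df)) + 1L  # header line
    n_dropped_parse <- 0L
  }
  ts <- parse_timestamps(df$timestamp_raw)
  bad_ts <- is.na(ts) | !nzchar(df$timestamp_raw)
  if (any(bad_ts)) {
    if (strict) {
      stop("unparseable timestamp at line ", src_line[which(bad_ts)[1L]], " of ", path)
    }
    df <- df[!bad_ts, , drop = FALSE]
    ts <- ts[!bad_ts]
  }
  n_dropped <- n_dropped_parse + if (strict) 0L else sum(bad_ts)
  if (n_dropped > 0L) ohc_log("read_corpus: dropped %d bad record(s)", n_dropped)
  out <- data.frame(
    post_id = df$post_id, author_id = df$author_id, thread_id = df$thread_id,
    timestamp = ts, text = df$text, stringsAsFactors = FALSE
  )
  corp <- ohc_corpus(out)
  attr(corp, "n_dropped") <- n_dropped
  corp
}

#' Write a corpus as a jsonl dump
#'
#' Inverse of [read_corpus] for the `jsonl` format; timestamps are written as
#' ISO-8601 UTC.
#'
#' @param corpus An [ohc_corpus].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ohc_corpus"))
  p <- corpus$posts
  lines <- vapply(seq_len(nrow(p)), function(i) {
    jsonlite::toJSON(list(
      post_id = p$post_id[i], author_id = p$author_id[i],
      thread_id = p$thread_id[i],
      timestamp = format(p$timestamp[i], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      text = p$text[i]
    ), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
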