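# Per-user treatment catalogues and corpus-level frequency tables.

#' Normalize a treatment term surface
#'
#' Lowercases and collapses whitespace. Morphological variants are *not*
#' merged by default ("chelation" and "chelating" stay distinct treatment
#' terms); an alias table can be supplied to merge variants explicitly.
#'
#' @param surface Character vector of mention surfaces.
#' @param aliases Optional named character vector mapping normalized variant
#'   to canonical term.
#' @return Character vector of normalized terms.
#' @export
#' @examples
#' normalize_term(c("Risperdal ", "speech  therapy"))
normalize_term <- function(surface, aliases = NULL) {
  x <- gsub("\\s+", " ", trimws(tolower(surface)))
  if (!is.null(aliases)) {
    hit <- match(x, names(aliases))
    x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  x
}

#' Build per-user treatment catalogues
#'
#' Groups `pt`-labeled mentions by post author: a user's catalogue records
#' every treatment with an indicated actual use, its mention count and the
#' date range of its mentions. Mentions with other attributions are excluded,
#' as are (with a logged count) mentions in posts whose author cannot be
#' resolved; authors with no `pt` mention have no catalogue.
#'
#' @param corpus An [ohc_corpus].
#' @param spans Labeled span data.frame (`post_id`, `surface`, `label`).
#' @param aliases Optional alias table for [normalize_term].
#' @return Data.frame of class `ohc_catalogues` with columns `author_id`,
#'   `term`, `mention_count`, `first_date`, `last_date`; attribute
#'   `n_unresolved` counts excluded pt mentions.
#' @export
build_catalogues <- function(corpus, spans, aliases = NULL) {
  pt <- spans[spans$label == "pt", , drop = FALSE]
  row_of <- match(pt$post_id, corpus$posts$post_id)
  known <- !is.na(row_of)
  if (any(!known)) {
    bad <- unique(pt$post_id[!known])
    stop("span(s) reference unknown post(s): ",
         paste(utils::head(bad, 3L), collapse = ", "))
  }
  author <- corpus$posts$author_id[row_of]
  unresolved <- is.na(author) | !nzchar(author)
  n_unresolved <- sum(unresolved)
  if (n_unresolved > 0L) {
    ohc_log("build_catalogues: %d pt mention(s) with unresolvable author excluded",
            n_unresolved)
  }
  pt <- pt[!unresolved, , drop = FALSE]
  author <- author[!unresolved]
  ts <- corpus$posts$timestamp[row_of[!unresolved]]
  term <- normalize_term(pt$surface, aliases)
  out <- if (nrow(pt) > 0L) {
    key <- paste(author, term, sep = "\r")
    agg <- lapply(split(seq_along(key), key), function(i) {
      data.frame(author_id = author[i[1L]], term = term[i[1L]],
                 mention_count = length(i),
                 first_date = min(ts[i]), last_date = max(ts[i]),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, agg)
    res <- res[order(res$author_id, res$term), , drop = FALSE]
    rownames(res) <- NULL
    res
  } else {
    data.frame(author_id = character(), term = character(),
               mention_count = integer(),
               first_date = as.POSIXct(character(), tz = "UTC"),
               last_date = as.POSIXct(character(), tz = "UTC"),
               stringsAsFactors = FALSE)
  }
  attr(out, "n_unresolved") <- n_unresolved
  class(out) <- c("ohc_catalogues", class(out))
  out
}

#' Mention-frequency table for one attribution class
#'
#' Counts every mention (no per-user deduplication) of each normalized term
#' carrying the given attribution, sorted by descending count with ties
#' broken lexicographically.
#'
#' @param spans Labeled span data.frame.
#' @param attribution One attribution label, or `"all"`.
#' @param top_k Number of rows to keep (`Inf` for all).
#' @param aliases Optional alias table.
#' @return Data.frame with columns `term`, `mention_count`.
#' @export
frequency_table <- function(spans, attribution = "all", top_k = 10L,
                            aliases = NULL) {
  if (attribution != "all") {
    assert_valid_labels(attribution)
    spans <- spans[spans$label == attribution, , drop = FALSE]
  }
  term <- normalize_term(spans$surface, aliases)
  if (length(term) == 0L) {
    return(data.frame(term = character(), mention_count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(term)
  out <- data.frame(term = names(tab), mention_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mention_count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Treatment prevalence by number of distinct users
#'
#' Counts, for each term, the distinct users whose catalogue contains it:
#' multiple mentions of the same treatment by one user count once, so the
#' figures reflect prevalence of usage rather than volume of discussion.
#'
#' @param catalogues Output of [build_catalogues].
#' @param top_k Number of rows to keep.
#' @return Data.frame with columns `term`, `user_count`, sorted by descending
#'   count then term.
#' @export
user_count_table <- function(catalogues, top_k = 10L) {
  if (nrow(catalogues) == 0L) {
    return(data.frame(term = character(), user_count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(catalogues$term)
  out <- data.frame(term = names(tab), user_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$user_count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Distribution of users over catalogue sizes
#'
#' @param catalogues Output of [build_catalogues].
#' @return Named integer vector mapping number of distinct treatments to
#'   number of users; values sum to the number of catalogued users.
#' @export
treatments_per_user_histogram <- function(catalogues) {
  if (nrow(catalogues) == 0L) return(stats::setNames(integer(0), character(0)))
  per_user <- table(catalogues$author_id)
  tab <- table(as.integer(per_user))
  stats::setNames(as.integer(tab), names(tab))
}

#' Export catalogues as CSV
#'
#' Columns `author_id`, `term`, `count`, `first_date`, `last_date`.
#'
#' @param catalogues Output of [build_catalogues].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalogues <- function(catalogues, path) {
  df <- data.frame(
    author_id = catalogues$author_id, term = catalogues$term,
    count = catalogues$mention_count,
    first_date = format(catalogues$first_date, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    last_date = format(catalogues$last_date, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
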