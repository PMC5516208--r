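# Mention-frequency series aligned to each member's community join date
# (date of first post), split by attribution type.

bin_seconds <- function(bin_unit) {
  switch(bin_unit, day = 86400, week = 7 * 86400,
         stop("unknown bin unit: ", bin_unit))
}

author_first_post <- function(corpus) {
  vapply(corpus$author_index, function(i) {
    as.numeric(min(corpus$posts$timestamp[i]))
  }, 0)
}

#' Offset of a post from its author's community join, in bins
#'
#' The join date is the author's first post; the offset is
#' `floor((timestamp - first_post) / bin)`, so the first post is bin 0.
#'
#' @param corpus An [ohc_corpus].
#' @param post_id Post identifier(s).
#' @param bin_unit `"day"` or `"week"` (7-day blocks from the first post, not
#'   calendar ISO weeks); arithmetic is in UTC.
#' @return Integer bin index per post.
#' @export
join_offset <- function(corpus, post_id, bin_unit = c("week", "day")) {
  bin_unit <- match.arg(bin_unit)
  row <- match(post_id, corpus$posts$post_id)
  if (anyNA(row)) stop("unknown post_id: ", post_id[is.na(row)][1L])
  first <- author_first_post(corpus)
  f <- first[corpus$posts$author_id[row]]
  as.integer(floor((as.numeric(corpus$posts$timestamp[row]) - f) /
                     bin_seconds(bin_unit)))
}

#' Join-aligned mention-frequency series for one term
#'
#' For each bin offset since members' join dates, the rate is the number of
#' mentions of `term` (optionally restricted to the `pt` attribution) divided
#' by the number of posts -- by any author -- falling at that offset. Bins
#' with no posts are absent rather than zero.
#'
#' @param corpus An [ohc_corpus].
#' @param spans Labeled span data.frame.
#' @param term Normalized treatment term.
#' @param attribution `"pt"` or `"all"`.
#' @param bin_unit `"week"` or `"day"`.
#' @param aliases Optional alias table for [normalize_term].
#' @return Data.frame with columns `bin`, `mentions`, `posts`, `rate`
#'   (mentions per post), sorted by `bin`.
#' @export
aligned_series <- function(corpus, spans, term,
                           attribution = c("all", "pt"),
                           bin_unit = c("week", "day"), aliases = NULL) {
  attribution <- match.arg(attribution)
  bin_unit <- match.arg(bin_unit)
  post_bin <- join_offset(corpus, corpus$posts$post_id, bin_unit)
  support <- table(post_bin)
  sel <- normalize_term(spans$surface, aliases) == normalize_term(term, aliases)
  if (attribution == "pt") sel <- sel & spans$label == "pt"
  sp <- spans[sel, , drop = FALSE]
  mention_bin <- if (nrow(sp) > 0L) {
    post_bin[match(sp$post_id, corpus$posts$post_id)]
  } else integer(0)
  mentions <- table(mention_bin)
  bins <- as.integer(names(support))
  idx <- match(names(support), names(mentions))
  men <- ifelse(is.na(idx), 0L, as.integer(mentions)[idx])
  out <- data.frame(
    bin = bins, mentions = as.integer(men), posts = as.integer(support),
    stringsAsFactors = FALSE
  )
  out$rate <- out$mentions / out$posts
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-format longitudinal export for the top terms
#'
#' Builds join-aligned series for the `top_k` most frequently mentioned terms
#' (over all attributions), for both the `all` and `pt` attribution filters
#' and each requested bin unit, in a long table ready for any plotting tool.
#'
#' @param corpus An [ohc_corpus].
#' @param spans Labeled span data.frame.
#' @param top_k Number of terms.
#' @param bin_units Subset of `c("week", "day")`.
#' @param aliases Optional alias table.
#' @return Data.frame with columns `term`, `attribution`, `bin_unit`, `bin`,
#'   `rate`, `support`.
#' @export
series_report <- function(corpus, spans, top_k = 5L,
                          bin_units = c("week", "day"), aliases = NULL) {
  terms <- frequency_table(spans, "all", top_k, aliases)$term
  rows <- list()
  for (tm in terms) {
    for (attr_ in c("all", "pt")) {
      for (bu in bin_units) {
        s <- aligned_series(corpus, spans, tm, attr_, bu, aliases)
        if (nrow(s) > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            term = tm, attribution = attr_, bin_unit = bu, bin = s$bin,
            rate = s$rate, support = s$posts, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    term = character(), attribution = character(), bin_unit = character(),
    bin = integer(), rate = numeric(), support = integer(),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
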