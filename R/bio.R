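#' Encode mention spans as a typed-BIO tag sequence
#'
#' Maps character-offset mention spans onto the tokens of one sentence: the
#' first token of each span receives `B-<label>`, subsequent tokens
#' `I-<label>`, everything else `O`. Spans must align exactly to token
#' boundaries and must not overlap; [tags_to_spans] inverts the encoding.
#'
#' @param tokens Token table for one sentence: columns `surface`,
#'   `char_start`, `char_end` (0-based, half-open offsets into the post text).
#' @param spans Span table: columns `char_start`, `char_end`, `label`
#'   (attribution label).
#' @return Character vector of tags, one per token.
#' @export
#' @examples
#' toks <- data.frame(surface = c("My", "son", "tried", "risperdal"),
#'                    char_start = c(0L, 3L, 7L, 13L),
#'                    char_end = c(2L, 6L, 12L, 22L))
#' spans_to_tags(toks, data.frame(char_start = 13, char_end = 22, label = "pt"))
spans_to_tags <- function(tokens, spans) {
  n <- nrow(tokens)
  tags <- rep("O", n)
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  assert_valid_labels(spans$label)
  o <- order(spans$char_start)
  spans <- spans[o, , drop = FALSE]
  if (nrow(spans) > 1L &&
      any(spans$char_start[-1L] < spans$char_end[-nrow(spans)])) {
    stop("overlapping spans")
  }
  for (k in seq_len(nrow(spans))) {
    s <- spans$char_start[k]; e <- spans$char_end[k]
    if (s >= e) stop("empty span [", s, ",", e, ")")
    first <- which(tokens$char_start == s)
    last <- which(tokens$char_end == e)
    covered <- which(tokens$char_start >= s & tokens$char_end <= e)
    aligned <- length(first) == 1L && length(last) == 1L &&
      length(covered) >= 1L &&
      identical(covered, seq(first, last))
    if (!aligned) {
      stop("span [", s, ",", e, ") does not align to token boundaries")
    }
    tags[first] <- paste0("B-", spans$label[k])
    if (last > first) tags[seq(first + 1L, last)] <- paste0("I-", spans$label[k])
  }
  tags
}

#' Decode a typed-BIO tag sequence into mention spans
#'
#' Inverse of [spans_to_tags]. Invalid sequences coming out of a decoder are
#' repaired rather than rejected: an `I-c` with no compatible predecessor is
#' promoted to `B-c`; the number of repairs is returned as the
#' `repair_count` attribute (and available for logging), so end-to-end
#' evaluation never crashes on decoder output.
#'
#' @param tokens Token table as in [spans_to_tags].
#' @param tags Character vector of tags, same length as `tokens` rows.
#' @param text Optional post text; when given, each span's `surface` is the
#'   exact substring, otherwise token surfaces joined by single spaces.
#' @return Span data.frame with columns `char_start`, `char_end`,
#'   `token_start`, `token_end` (0-based half-open token indices within the
#'   sentence), `surface`, `label`, sorted by `char_start`; attribute
#'   `repair_count` holds the number of I-to-B promotions applied.
#' @export
tags_to_spans <- function(tokens, tags, text = NULL) {
  n <- nrow(tokens)
  if (length(tags) != n) {
    stop("length mismatch: ", length(tags), " tags for ", n, " tokens")
  }
  bad <- setdiff(tags, crf_labels())
  if (length(bad) > 0L) stop("unknown tag symbol(s): ", paste(bad, collapse = ", "))
  p <- parse_tag(tags)
  repairs <- 0L
  # repair pass: orphan I-c becomes B-c
  for (t in seq_len(n)) {
    if (p$prefix[t] == "I") {
      orphan <- t == 1L || p$prefix[t - 1L] == "O" ||
        !identical(p$class[t - 1L], p$class[t])
      if (orphan) {
        p$prefix[t] <- "B"
        repairs <- repairs + 1L
      }
    }
  }
  if (repairs > 0L) ohc_log("tags_to_spans: repaired %d orphan I tag(s)", repairs)
  starts <- which(p$prefix == "B")
  out <- lapply(starts, function(s) {
    e <- s
    while (e < n && p$prefix[e + 1L] == "I" &&
           identical(p$class[e + 1L], p$class[s])) {
      e <- e + 1L
    }
    data.frame(
      char_start = tokens$char_start[s], char_end = tokens$char_end[e],
      token_start = s - 1L, token_end = e,
      surface = NA_character_, label = p$class[s], stringsAsFactors = FALSE
    )
  })
  out <- if (length(out) > 0L) do.call(rbind, out) else data.frame(
    char_start = integer(), char_end = integer(), token_start = integer(),
    token_end = integer(), surface = character(), label = character(),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) {
    out$surface <- if (!is.null(text)) {
      substr(rep(text, nrow(out)), out$char_start + 1L, out$char_end)
    } else {
      vapply(seq_len(nrow(out)), function(k) {
        paste(tokens$surface[(out$token_start[k] + 1L):out$token_end[k]],
              collapse = " ")
      }, "")
    }
    out <- out[order(out$char_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "repair_count") <- repairs
  out
}

#' Write token/tag sequences in CoNLL format
#'
#' One token per line as `token<TAB>tag`; sentences are separated by one blank
#' line and posts by two blank lines. [read_conll] inverts the serialization
#' exactly.
#'
#' @param conll Data.frame with columns `post` (integer or id), `sentence`
#'   (integer within post), `token`, `tag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(conll, path) {
  lines <- character(0)
  if (nrow(conll) > 0L) {
    posts <- unique(conll$post)
    chunks <- lapply(posts, function(pid) {
      pc <- conll[conll$post == pid, , drop = FALSE]
      sent_chunks <- lapply(unique(pc$sentence), function(sid) {
        sc <- pc[pc$sentence == sid, , drop = FALSE]
        paste(sc$token, sc$tag, sep = "\t")
      })
      unlist(lapply(sent_chunks, function(x) c(x, "")))  # blank line after sentence
    })
    # one blank after each sentence; post boundary adds a second blank
    lines <- unlist(lapply(chunks, function(x) c(x, "")))
    # trim trailing blank lines
    while (length(lines) > 0L && lines[length(lines)] == "") {
      lines <- lines[-length(lines)]
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CoNLL-format annotation file
#'
#' @param path Path written by [write_conll].
#' @return Data.frame with columns `post`, `sentence`, `token`, `tag`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  post <- 1L; sent <- 1L
  blanks <- 0L
  rows <- vector("list", length(lines))
  started <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") {
      blanks <- blanks + 1L
      next
    }
    if (started) {
      if (blanks >= 2L) {
        post <- post + 1L; sent <- 1L
      } else if (blanks == 1L) {
        sent <- sent + 1L
      }
    }
    blanks <- 0L
    started <- TRUE
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed CoNLL line ", i, ": ", ln)
    if (!parts[2L] %in% crf_labels()) {
      stop("unknown tag '", parts[2L], "' at line ", i)
    }
    rows[[i]] <- data.frame(post = post, sentence = sent, token = parts[1L],
                            tag = parts[2L], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(post = integer(), sentence = integer(),
                      token = character(), tag = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a character-offset span file
#'
#' The span file is a CSV with columns `post_id`, `char_start`, `char_end`,
#' `surface`, `label`; offsets are 0-based half-open into the post text.
#'
#' @param spans Span data.frame (extra columns are dropped on write).
#' @param path File path.
#' @return `read_spans` returns the span data.frame; `write_spans` returns
#'   `path` invisibly.
#' @export
write_spans <- function(spans, path) {
  cols <- c("post_id", "char_start", "char_end", "surface", "label")
  miss <- setdiff(cols, names(spans))
  if (length(miss) > 0L) stop("span table missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(spans[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spans
#' @export
read_spans <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(post_id = "character"))
  assert_valid_labels(df$label)
  df
}
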