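# Deterministic heuristic linguistic annotation: sentence split, tokenize,
# coarse POS + lemma, subject/predicate heads. Stands behind the pluggable
# Annotator interface; real taggers/parsers can be registered under a name.

POS_TAGSET <- c("NOUN", "VERB", "ADJ", "ADV", "PRON", "DET", "ADP",
                "NUM", "PUNCT", "SYM", "X")

AUX_VERBS <- c("be", "is", "are", "was", "were", "been", "being", "am",
               "have", "has", "had", "having", "do", "does", "did",
               "will", "would", "can", "could", "shall", "should",
               "may", "might", "must")

.ling <- new.env(parent = emptyenv())

ling_data <- function() {
  if (is.null(.ling$closed_class)) {
    cc_path <- system.file("extdata", "closed_class.tsv", package = "ohctreat")
    cc <- utils::read.csv(cc_path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
    .ling$closed_class <- stats::setNames(cc$pos, cc$word)
    ab_path <- system.file("extdata", "abbreviations.txt", package = "ohctreat")
    ab <- readLines(ab_path, warn = FALSE)
    ab <- trimws(ab[!grepl("^\\s*(#|$)", ab)])
    .ling$abbrev <- tolower(ab)
  }
  .ling
}

#' Split raw post text into sentences
#'
#' Splits after runs of `.`, `!` or `?` that are followed by whitespace and a
#' capital letter or digit, unless the preceding word is on the abbreviation
#' guard list (shipped in `extdata/abbreviations.txt`). Returned spans are
#' 0-based half-open character offsets, disjoint, ordered, and cover all
#' non-whitespace text.
#'
#' @param text A single post text.
#' @return Data.frame with columns `char_start`, `char_end`; zero rows for
#'   empty or all-whitespace input.
#' @export
sentence_split <- function(text) {
  empty <- data.frame(char_start = integer(), char_end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  abbrev <- ling_data()$abbrev
  mlist <- gregexpr("[.!?]+[ \t\r\n]+[A-Z0-9]", text)
  m <- mlist[[1L]]
  mats <- regmatches(text, mlist)[[1L]]
  cut_after <- integer(0)  # 1-based index of last char of each sentence
  if (m[1L] != -1L) {
    for (k in seq_along(m)) {
      start <- m[k]
      seg <- mats[k]
      punct_len <- attr(regexpr("^[.!?]+", seg), "match.length")
      # word immediately before the punctuation run
      before <- substr(text, 1L, start - 1L)
      word <- sub("^.*?([A-Za-z.]+)$", "\\1", before)
      if (tolower(word) %in% abbrev) next
      cut_after <- c(cut_after, start + punct_len - 1L)
    }
  }
  bounds <- c(0L, cut_after, nchar(text))  # 0-based segment starts/ends
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    seg_start <- bounds[k]; seg_end <- bounds[k + 1L]
    seg <- substr(text, seg_start + 1L, seg_end)
    lead_ws <- attr(regexpr("^\\s*", seg), "match.length")
    trail_ws <- attr(regexpr("\\s*$", seg), "match.length")
    s <- seg_start + lead_ws
    e <- seg_end - trail_ws
    if (e > s) out[[length(out) + 1L]] <- data.frame(char_start = s, char_end = e)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

LEAD_PUNCT <- c("(", "[", "{", "\"", "'", "“", "‘")
TRAIL_PUNCT <- c(".", ",", "!", "?", ";", ":", ")", "]", "}", "\"", "'",
                 "”", "’")

#' Tokenize one sentence
#'
#' Whitespace tokenization followed by peeling leading/trailing punctuation
#' into their own tokens. Internal hyphens, slashes and apostrophes are kept,
#' so drug names like `B-12` survive intact. `@`-prefixed username mentions
#' are single tokens. Offsets are into the original post text.
#'
#' @param sentence_text Sentence substring.
#' @param base_offset 0-based offset of the sentence within the post text.
#' @return Token data.frame with columns `surface`, `char_start`, `char_end`.
#' @export
#' @examples
#' tokenize("on risperdal.")$surface
tokenize <- function(sentence_text, base_offset = 0L) {
  out_surface <- character(0); out_start <- integer(0); out_end <- integer(0)
  m <- gregexpr("\\S+", sentence_text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(surface = character(), char_start = integer(),
                      char_end = integer(), stringsAsFactors = FALSE))
  }
  chunks <- regmatches(sentence_text, list(m))[[1L]]
  starts <- as.integer(m) - 1L  # 0-based within sentence
  for (k in seq_along(chunks)) {
    chunk <- chunks[k]
    pos <- starts[k]
    lead <- character(0); trail <- character(0)
    repeat {
      if (nchar(chunk) > 1L && substr(chunk, 1L, 1L) %in% LEAD_PUNCT) {
        lead <- c(lead, substr(chunk, 1L, 1L))
        chunk <- substr(chunk, 2L, nchar(chunk))
      } else break
    }
    repeat {
      nc <- nchar(chunk)
      if (nc > 1L && substr(chunk, nc, nc) %in% TRAIL_PUNCT) {
        trail <- c(substr(chunk, nc, nc), trail)
        chunk <- substr(chunk, 1L, nc - 1L)
      } else break
    }
    pieces <- c(lead, chunk, trail)
    p <- pos
    for (piece in pieces) {
      out_surface <- c(out_surface, piece)
      out_start <- c(out_start, p)
      out_end <- c(out_end, p + nchar(piece))
      p <- p + nchar(piece)
    }
  }
  data.frame(surface = out_surface,
             char_start = out_start + base_offset,
             char_end = out_end + base_offset,
             stringsAsFactors = FALSE)
}

lemma_rules <- function(surface, pos) {
  w <- tolower(surface)
  n <- nchar(w)
  if (pos == "VERB") {
    if (grepl("ied$", w)) return(sub("ied$", "y", w))
    if (grepl("ies$", w)) return(sub("ies$", "y", w))
    if (grepl("ing$", w) && n > 5L) {
      b <- sub("ing$", "", w)
      nb <- nchar(b)
      if (nb >= 3L && substr(b, nb, nb) == substr(b, nb - 1L, nb - 1L) &&
          !grepl("[aeiou]", substr(b, nb, nb))) {
        b <- substr(b, 1L, nb - 1L)
      }
      return(b)
    }
    if (grepl("ed$", w) && n > 3L) {
      b <- if (n > 4L) sub("ed$", "", w) else sub("d$", "", w)
      nb <- nchar(b)
      if (nb >= 3L && substr(b, nb, nb) == substr(b, nb - 1L, nb - 1L) &&
          !grepl("[aeiou]", substr(b, nb, nb))) {
        b <- substr(b, 1L, nb - 1L)
      }
      return(b)
    }
    if (grepl("[^s]s$", w) && n > 3L) return(sub("s$", "", w))
    return(w)
  }
  if (pos == "NOUN") {
    if (grepl("ies$", w) && n > 4L) return(sub("ies$", "y", w))
    if (grepl("(s|x|z|ch|sh)es$", w)) return(sub("es$", "", w))
    if (grepl("[^su]s$", w) && n > 3L) return(sub("s$", "", w))
    return(w)
  }
  w
}

#' Coarse POS tags and lemmas for a token sequence
#'
#' Closed-class words are tagged from a shipped ~300-entry lexicon; the rest
#' fall through suffix rules (`-ly` adverbs, `-ed`/`-ied` verbs, `-ing` verbs
#' after an auxiliary and nouns otherwise, adjectival suffixes), with
#' punctuation, numbers and `@`-mentions recognized structurally and NOUN the
#' default. Lemmas are lowercase with deterministic plural / `-ing` / `-ed`
#' stripping.
#'
#' @param surfaces Character vector of token surfaces.
#' @return List with elements `pos` and `lemma`, parallel to `surfaces`.
#' @export
heuristic_pos_lemma <- function(surfaces) {
  cc <- ling_data()$closed_class
  n <- length(surfaces)
  pos <- character(n)
  for (i in seq_len(n)) {
    w <- surfaces[i]
    lw <- tolower(w)
    if (grepl("^[[:punct:]]+$", w) && !grepl("^@", w)) {
      pos[i] <- "PUNCT"
    } else if (grepl("^[0-9]+([.,][0-9]+)*$", w) || grepl("^[0-9]+(st|nd|rd|th)$", lw)) {
      pos[i] <- "NUM"
    } else if (grepl("^[@#]", w)) {
      pos[i] <- "SYM"
    } else if (!is.na(cc[lw])) {
      pos[i] <- unname(cc[lw])
    } else if (grepl("ly$", lw) && nchar(lw) > 3L) {
      pos[i] <- "ADV"
    } else if (grepl("(ied|ed)$", lw) && nchar(lw) > 3L) {
      pos[i] <- "VERB"
    } else if (grepl("ing$", lw) && nchar(lw) > 4L) {
      prev_aux <- i > 1L && tolower(surfaces[i - 1L]) %in% AUX_VERBS
      pos[i] <- if (prev_aux) "VERB" else "NOUN"
    } else if (grepl("(ous|ful|ive|ical|able|ible)$", lw) && nchar(lw) > 4L) {
      pos[i] <- "ADJ"
    } else if (grepl("ic$", lw) && nchar(lw) > 4L) {
      pos[i] <- "ADJ"
    } else {
      pos[i] <- "NOUN"
    }
  }
  lemma <- vapply(seq_len(n), function(i) lemma_rules(surfaces[i], pos[i]), "")
  list(pos = pos, lemma = lemma)
}

#' Identify subject and predicate heads of a sentence
#'
#' The predicate is the first non-auxiliary VERB (falling back to the first
#' VERB when only auxiliaries exist); the subject head is the last token of
#' the longest maximal run of PRON/DET/NOUN/ADJ tokens strictly before the
#' predicate (the run closest to the predicate on ties). Both are `NA` when
#' the sentence has no verb.
#'
#' @param pos Character vector of coarse POS tags.
#' @param lemma Character vector of lemmas (used to detect auxiliaries).
#' @return List with integer elements `subject_index`, `predicate_index`
#'   (1-based token indices, or `NA`).
#' @export
find_subject_predicate <- function(pos, lemma) {
  verbs <- which(pos == "VERB")
  if (length(verbs) == 0L) {
    return(list(subject_index = NA_integer_, predicate_index = NA_integer_))
  }
  non_aux <- verbs[!(lemma[verbs] %in% AUX_VERBS)]
  pred <- if (length(non_aux) > 0L) non_aux[1L] else verbs[1L]
  subj <- NA_integer_
  if (pred > 1L) {
    nom <- pos[seq_len(pred - 1L)] %in% c("PRON", "DET", "NOUN", "ADJ")
    r <- rle(nom)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) > 0L) {
      best <- runs[r$lengths[runs] == max(r$lengths[runs])]
      best <- best[length(best)]  # closest to predicate on ties
      subj <- ends[best]
    }
  }
  list(subject_index = subj, predicate_index = pred)
}

#' Annotate post text with the shipped heuristic annotator
#'
#' Runs sentence splitting, tokenization, POS/lemma tagging and
#' subject/predicate identification. Deterministic: identical input yields
#' identical output.
#'
#' @param text Raw post text.
#' @return List of annotated sentences; each is a list with elements `tokens`
#'   (data.frame `surface`, `char_start`, `char_end`, `pos`, `lemma`),
#'   `subject_index`, `predicate_index`, `char_start`, `char_end`.
#' @export
heuristic_annotate <- function(text) {
  sents <- sentence_split(text)
  out <- vector("list", nrow(sents))
  for (k in seq_len(nrow(sents))) {
    s <- sents$char_start[k]; e <- sents$char_end[k]
    toks <- tokenize(substr(text, s + 1L, e), base_offset = s)
    pl <- heuristic_pos_lemma(toks$surface)
    toks$pos <- pl$pos
    toks$lemma <- pl$lemma
    sp <- find_subject_predicate(toks$pos, toks$lemma)
    out[[k]] <- list(tokens = toks,
                     subject_index = sp$subject_index,
                     predicate_index = sp$predicate_index,
                     char_start = s, char_end = e)
  }
  out
}

.annotators <- new.env(parent = emptyenv())

#' Pluggable annotator registry
#'
#' An annotator is any deterministic function `text -> list of annotated
#' sentences` with the structure produced by [heuristic_annotate]. The
#' heuristic annotator is pre-registered under `"heuristic"`; users may
#' register wrappers around real taggers/parsers under other names and select
#' them by name in run configs.
#'
#' @param name Annotator name.
#' @param fn Function implementing the annotator (for `register_annotator`).
#' @return `get_annotator` returns the annotator function.
#' @export
get_annotator <- function(name = "heuristic") {
  if (name == "heuristic") return(heuristic_annotate)
  fn <- .annotators[[name]]
  if (is.null(fn)) stop("unknown annotator: ", name)
  fn
}

#' @rdname get_annotator
#' @export
register_annotator <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .annotators)
  invisible(name)
}
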