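# Corpus-level glue: annotation, gold alignment, training-data assembly and
# whole-corpus decoding.

#' Annotate every post of a corpus
#'
#' @param corpus An [ohc_corpus].
#' @param annotator Annotator name (see [get_annotator]).
#' @return Named list mapping `post_id` to the post's annotated sentences.
#' @export
annotate_corpus <- function(corpus, annotator = "heuristic") {
  ann <- get_annotator(annotator)
  out <- lapply(corpus$posts$text, ann)
  names(out) <- corpus$posts$post_id
  out
}

#' Assemble per-sentence CRF data from a corpus
#'
#' Annotates each post, extracts the selected feature families per token and,
#' when gold spans are given, encodes them as typed-BIO tag sequences. Spans
#' that do not fall inside a single sentence or do not align to token
#' boundaries are an error when `strict`, otherwise skipped with a logged
#' count (attribute `n_skipped_spans`).
#'
#' @param corpus An [ohc_corpus].
#' @param spans Optional gold span table (`post_id`, `char_start`, `char_end`,
#'   `label`).
#' @param families Feature families to extract.
#' @param gazetteers List of [gazetteer] objects (for semantic features).
#' @param annotator Annotator name.
#' @param usernames Optional member-name list for the username-mention flag.
#' @param strict Error (default) or skip on unalignable gold spans.
#' @return List of sentences, each `list(features, tags, post_id, tokens)`
#'   (`tags` is `NULL` without gold); attribute `n_skipped_spans` counts
#'   skipped gold spans.
#' @export
corpus_sentences <- function(corpus, spans = NULL,
                             families = FEATURE_FAMILIES,
                             gazetteers = list(), annotator = "heuristic",
                             usernames = character(0), strict = TRUE) {
  annotated <- annotate_corpus(corpus, annotator)
  out <- list()
  skipped <- 0L
  for (pid in names(annotated)) {
    sents <- annotated[[pid]]
    post_spans <- if (!is.null(spans)) {
      spans[spans$post_id == pid, , drop = FALSE]
    } else NULL
    assigned <- if (!is.null(post_spans) && nrow(post_spans) > 0L) {
      rep(NA_integer_, nrow(post_spans))
    } else integer(0)
    if (length(assigned) > 0L) {
      for (k in seq_len(nrow(post_spans))) {
        hit <- which(vapply(sents, function(s) {
          post_spans$char_start[k] >= s$char_start &&
            post_spans$char_end[k] <= s$char_end
        }, TRUE))
        if (length(hit) == 1L) assigned[k] <- hit
      }
      if (anyNA(assigned)) {
        if (strict) {
          stop("gold span outside any single sentence in post ", pid)
        }
        skipped <- skipped + sum(is.na(assigned))
      }
    }
    tok_offset <- 0L
    for (si in seq_along(sents)) {
      s <- sents[[si]]
      if (nrow(s$tokens) == 0L) next
      feats <- sentence_features(s, families, gazetteers, usernames)
      tags <- NULL
      if (!is.null(post_spans)) {
        sel <- which(assigned == si)
        sp <- post_spans[sel, , drop = FALSE]
        tags <- tryCatch(
          spans_to_tags(s$tokens, sp),
          error = function(e) if (strict) stop(e) else NULL
        )
        if (is.null(tags)) {
          skipped <- skipped + nrow(sp)
          tags <- rep("O", nrow(s$tokens))
        }
      }
      out[[length(out) + 1L]] <- list(
        features = feats, tags = tags, post_id = pid,
        tokens = s$tokens, sentence = s, tok_offset = tok_offset
      )
      tok_offset <- tok_offset + nrow(s$tokens)
    }
  }
  if (skipped > 0L) ohc_log("corpus_sentences: skipped %d unalignable gold span(s)", skipped)
  attr(out, "n_skipped_spans") <- skipped
  out
}

#' Decode treatment mentions over a whole corpus
#'
#' Runs the trained CRF over every sentence (batched Viterbi) and decodes the
#' tag sequences into labeled mention spans with post-level character offsets.
#' Any BIO repairs applied while decoding are totalled in attribute
#' `repair_count` (zero whenever the model was trained with the transition
#' mask on).
#'
#' @param model A trained [crf_model].
#' @param corpus An [ohc_corpus].
#' @inheritParams corpus_sentences
#' @return Span data.frame (`post_id`, `char_start`, `char_end`,
#'   `token_start`, `token_end`, `surface`, `label`).
#' @export
predict_spans <- function(model, corpus, families = FEATURE_FAMILIES,
                          gazetteers = list(), annotator = "heuristic",
                          usernames = character(0)) {
  sentences <- corpus_sentences(corpus, NULL, families, gazetteers,
                                annotator, usernames)
  out <- predict_spans_sentences(model, sentences, corpus)
  rc <- attr(out, "repair_count")
  out$.sent <- NULL
  attr(out, "repair_count") <- rc
  out
}

# shared decoding path; `sentences` as produced by corpus_sentences
predict_spans_sentences <- function(model, sentences, corpus) {
  empty <- data.frame(post_id = character(), char_start = integer(),
                      char_end = integer(), token_start = integer(),
                      token_end = integer(), surface = character(),
                      label = character(), .sent = integer(),
                      stringsAsFactors = FALSE)
  if (length(sentences) == 0L) {
    attr(empty, "repair_count") <- 0L
    return(empty)
  }
  comp <- crf_compile(model, sentences)
  E <- as.matrix(comp$X %*% model$W)
  path <- crf_batch_viterbi(E, comp$lengths, eff_trans(model),
                            eff_bos(model), model$eos)
  tags_all <- model$labels[path + 1L]
  offs <- c(0L, cumsum(comp$lengths))
  text_by_id <- stats::setNames(corpus$posts$text, corpus$posts$post_id)
  repairs <- 0L
  spans <- vector("list", length(sentences))
  for (k in seq_along(sentences)) {
    s <- sentences[[k]]
    tags <- tags_all[(offs[k] + 1L):offs[k + 1L]]
    sp <- tags_to_spans(s$tokens, tags, text = text_by_id[[s$post_id]])
    repairs <- repairs + attr(sp, "repair_count")
    if (nrow(sp) > 0L) {
      sp$post_id <- s$post_id
      # promote sentence-relative token indices to post-level indices
      sp$token_start <- sp$token_start + s$tok_offset
      sp$token_end <- sp$token_end + s$tok_offset
      sp$.sent <- k
      spans[[k]] <- sp[, c("post_id", "char_start", "char_end", "token_start",
                           "token_end", "surface", "label", ".sent")]
    }
  }
  spans <- spans[!vapply(spans, is.null, TRUE)]
  out <- if (length(spans) > 0L) do.call(rbind, spans) else empty
  rownames(out) <- NULL
  attr(out, "repair_count") <- repairs
  out
}

#' Split a corpus into train and test partitions by post
#'
#' @param corpus An [ohc_corpus].
#' @param fraction Fraction of posts assigned to the training partition.
#' @param seed Integer seed controlling the random assignment.
#' @return List with `ohc_corpus` elements `train` and `test`.
#' @export
split_corpus <- function(corpus, fraction = 0.7, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(corpus$posts)
  if (n < 2L) stop("corpus too small to split")
  idx <- with_local_seed(seed, sample.int(n, size = max(1L, round(fraction * n))))
  list(train = ohc_corpus(corpus$posts[sort(idx), , drop = FALSE]),
       test = ohc_corpus(corpus$posts[-sort(idx), , drop = FALSE]))
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
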