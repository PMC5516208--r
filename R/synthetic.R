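# Seeded generator of gold-annotated forum corpora. Users get join dates and
# posting timelines; each sentence instantiates a class-specific template
# around a gazetteer term sampled with Zipf weights, yielding exact gold
# spans with the five attribution labels. Task difficulty is tuned by the
# share of "ambiguous" templates whose surface cue underdetermines the class.

#' The shipped ASD-treatment gazetteer
#'
#' Roughly 150 lowercase treatment terms (drugs, supplements, diets and
#' psychosocial therapies commonly discussed in autism parent forums),
#' including multi-word terms such as "cod liver oil" and
#' "early intervention".
#'
#' @return An [gazetteer] named `"treatments"`.
#' @export
reference_gazetteer <- function() {
  read_gazetteer(system.file("extdata", "asd_treatments.txt",
                             package = "ohctreat"),
                 name = "treatments")
}

#' Read a sentence-template bank
#'
#' Tab-separated file with columns `class` (an attribution label or `none`),
#' `template` (sentence text with exactly one `{TREATMENT}` slot, none for
#' `none`), and `kind` (`plain` or `ambiguous`; ambiguous templates appear
#' under more than one class and carry cues that underdetermine the label).
#'
#' @param path Template file; defaults to the shipped bank.
#' @return Data.frame with columns `class`, `template`, `kind`.
#' @export
read_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "templates.tsv", package = "ohctreat")
  }
  df <- utils::read.csv(path, sep = "\t", header = TRUE, quote = "",
                        stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("class", "template", "kind") %in% names(df)))
  ok_class <- df$class %in% c(attribution_labels(), "none")
  if (any(!ok_class)) stop("bad template class: ", df$class[!ok_class][1L])
  n_slots <- lengths(gregexpr("{TREATMENT}", df$template, fixed = TRUE)) -
    (regexpr("{TREATMENT}", df$template, fixed = TRUE) == -1L)
  need <- ifelse(df$class == "none", 0L, 1L)
  if (any(n_slots != need)) {
    stop("template with wrong number of {TREATMENT} slots: ",
         df$template[n_slots != need][1L])
  }
  df
}

#' Generator configuration
#'
#' The configuration fixes the statistical structure of the synthetic forum:
#' community size, per-author posting volume (geometric), sentences per post,
#' the per-sentence mixture over attribution classes (plus `none` for
#' mention-free sentences), Zipf-weighted treatment-term sampling, the share
#' of ambiguous cue templates, the community timespan and the seed, which
#' fully determines the output.
#'
#' @param n_authors Number of community members.
#' @param posts_per_author List `list(dist = "geometric", mean = m)` or
#'   `list(dist = "constant", value = k)`.
#' @param sentences_per_post Same distribution spec form.
#' @param class_mixture Named probabilities over
#'   `c(attribution_labels(), "none")`, summing to 1. The default follows the
#'   attribution proportions observed in annotated autism-forum data
#'   (patient-use and generic mentions dominant; caregiver rare) with a 0.41
#'   mass on mention-free sentences.
#' @param zipf_exponent Exponent of the rank-frequency law for term sampling.
#' @param cue_ambiguity Probability in `[0, 1]` that a sentence uses an
#'   ambiguous template when one exists for its class.
#' @param timespan_days Length of the community observation window.
#' @param seed Integer seed.
#' @param gaz Treatment-term [gazetteer]; defaults to [reference_gazetteer()].
#' @param templates Template bank; defaults to [read_templates()].
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_authors = 100L,
                             posts_per_author = list(dist = "geometric", mean = 6),
                             sentences_per_post = list(dist = "constant", value = 3L),
                             class_mixture = c(pt = 0.257, `pt-gen` = 0.061,
                                               cg = 0.013, others = 0.030,
                                               gen = 0.230, none = 0.409),
                             zipf_exponent = 1.2, cue_ambiguity = 0.15,
                             timespan_days = 365L, seed = 1L,
                             gaz = NULL, templates = NULL) {
  stopifnot(n_authors >= 1L, timespan_days >= 1L,
            cue_ambiguity >= 0, cue_ambiguity <= 1)
  want <- c(attribution_labels(), "none")
  if (!setequal(names(class_mixture), want)) {
    stop("class_mixture must be named over ",
         paste(want, collapse = ", "))
  }
  class_mixture <- class_mixture[want]
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class_mixture must sum to 1 (got ", sum(class_mixture), ")")
  }
  if (is.null(gaz)) gaz <- reference_gazetteer()
  if (is.null(templates)) templates <- read_templates()
  structure(list(
    n_authors = as.integer(n_authors), posts_per_author = posts_per_author,
    sentences_per_post = sentences_per_post, class_mixture = class_mixture,
    zipf_exponent = zipf_exponent, cue_ambiguity = cue_ambiguity,
    timespan_days = as.integer(timespan_days), seed = as.integer(seed),
    gaz = gaz, templates = templates
  ), class = "generator_config")
}

draw_counts <- function(spec, n) {
  if (spec$dist == "constant") {
    rep(as.integer(spec$value), n)
  } else if (spec$dist == "geometric") {
    stopifnot(spec$mean >= 1)
    1L + stats::rgeom(n, prob = 1 / spec$mean)
  } else {
    stop("unknown distribution spec: ", spec$dist)
  }
}

capitalize1 <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

#' Generate a gold-annotated synthetic forum corpus
#'
#' Samples members with join dates and posting timelines over the configured
#' timespan, sentence classes from the class mixture, treatment terms from
#' the Zipf-weighted gazetteer, and instantiates per-class sentence
#' templates, recording exact gold character spans with attribution labels.
#' Fully reproducible from the config seed.
#'
#' @param config A [generator_config].
#' @return List with elements `corpus` ([ohc_corpus]) and `gold`
#'   (span data.frame with `post_id`, `char_start`, `char_end`, `surface`,
#'   `label`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    terms <- config$gaz$terms
    zw <- seq_along(terms)^(-config$zipf_exponent)
    zw <- zw / sum(zw)
    tpl <- config$templates
    tpl_plain <- split(tpl$template[tpl$kind == "plain"],
                       tpl$class[tpl$kind == "plain"])
    tpl_ambig <- split(tpl$template[tpl$kind == "ambiguous"],
                       tpl$class[tpl$kind == "ambiguous"])
    n_posts <- draw_counts(config$posts_per_author, config$n_authors)
    origin <- as.POSIXct("2009-01-01 00:00:00", tz = "UTC")
    posts <- list(); gold <- list()
    post_counter <- 0L
    for (a in seq_len(config$n_authors)) {
      author_id <- sprintf("a%04d", a)
      join_day <- stats::runif(1, 0, config$timespan_days * 0.3)
      later <- sort(stats::runif(n_posts[a] - 1L, 0,
                                 config$timespan_days * 0.7))
      days <- join_day + c(0, later)
      n_sent <- draw_counts(config$sentences_per_post, n_posts[a])
      for (p in seq_len(n_posts[a])) {
        post_counter <- post_counter + 1L
        post_id <- sprintf("p%06d", post_counter)
        classes <- sample(names(config$class_mixture), n_sent[p],
                          replace = TRUE, prob = config$class_mixture)
        sents <- character(n_sent[p])
        offset <- 0L
        for (si in seq_len(n_sent[p])) {
          cl <- classes[si]
          use_ambig <- !is.null(tpl_ambig[[cl]]) &&
            stats::runif(1) < config$cue_ambiguity
          bank <- if (use_ambig) tpl_ambig[[cl]] else tpl_plain[[cl]]
          template <- bank[sample.int(length(bank), 1L)]
          if (cl == "none") {
            sent <- capitalize1(template)
          } else {
            term <- terms[sample.int(length(terms), 1L, prob = zw)]
            parts <- strsplit(template, "{TREATMENT}", fixed = TRUE)[[1L]]
            prefix <- parts[1L]
            suffix <- if (length(parts) > 1L) parts[2L] else ""
            sent <- capitalize1(paste0(prefix, term, suffix))
            s0 <- offset + nchar(prefix)
            gold[[length(gold) + 1L]] <- data.frame(
              post_id = post_id, char_start = s0,
              char_end = s0 + nchar(term),
              surface = substr(sent, nchar(prefix) + 1L,
                               nchar(prefix) + nchar(term)),
              label = cl, stringsAsFactors = FALSE
            )
          }
          sents[si] <- sent
          offset <- offset + nchar(sent) + 1L  # single-space joiner
        }
        posts[[post_counter]] <- data.frame(
          post_id = post_id, author_id = author_id,
          thread_id = "", timestamp = origin + days[p] * 86400,
          text = paste(sents, collapse = " "), stringsAsFactors = FALSE
        )
      }
    }
    posts <- do.call(rbind, posts)
    # threads: ~5 posts per thread on average, assigned randomly
    n_threads <- max(1L, nrow(posts) %/% 5L)
    posts$thread_id <- sprintf("t%05d", sample.int(n_threads, nrow(posts),
                                                   replace = TRUE))
    posts$timestamp <- as.POSIXct(round(as.numeric(posts$timestamp)),
                                  origin = "1970-01-01", tz = "UTC")
    gold <- if (length(gold) > 0L) do.call(rbind, gold) else data.frame(
      post_id = character(), char_start = integer(), char_end = integer(),
      surface = character(), label = character(), stringsAsFactors = FALSE
    )
    rownames(gold) <- NULL
    list(corpus = ohc_corpus(posts), gold = gold)
  })
}

#' Add character-level typo noise outside gold spans
#'
#' Randomly drops or swap-transposes characters of each post, restricted to
#' positions outside every gold span so the gold surfaces stay intact; gold
#' offsets are re-synchronized after deletions.
#'
#' @param corpus An [ohc_corpus].
#' @param gold Gold span table for the corpus.
#' @param typo_rate Per-character edit probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with the corrupted `corpus` and offset-adjusted `gold`.
#' @export
corrupt_corpus <- function(corpus, gold, typo_rate, seed = 1L) {
  stopifnot(typo_rate >= 0, typo_rate < 1)
  if (typo_rate == 0) return(list(corpus = corpus, gold = gold))
  with_local_seed(seed, {
    posts <- corpus$posts
    for (r in seq_len(nrow(posts))) {
      pid <- posts$post_id[r]
      g_idx <- which(gold$post_id == pid)
      chars <- strsplit(posts$text[r], "", fixed = TRUE)[[1L]]
      n <- length(chars)
      protected <- rep(FALSE, n)
      for (k in g_idx) {
        protected[(gold$char_start[k] + 1L):gold$char_end[k]] <- TRUE
      }
      edit_at <- which(!protected & stats::runif(n) < typo_rate)
      # keep edit sites >= 2 chars apart so right-to-left edits never interact
      if (length(edit_at) > 1L) {
        keep <- c(TRUE, diff(edit_at) >= 2L)
        edit_at <- edit_at[keep]
      }
      if (length(edit_at) == 0L) next
      is_swap <- stats::runif(length(edit_at)) < 0.5
      for (j in rev(seq_along(edit_at))) {  # right-to-left keeps offsets easy
        p <- edit_at[j]
        if (is_swap[j] && p < length(chars) && !protected[p + 1L]) {
          tmp <- chars[p]; chars[p] <- chars[p + 1L]; chars[p + 1L] <- tmp
        } else {
          if (length(chars) <= 1L) next
          chars <- chars[-p]
          shift <- gold$post_id == pid & gold$char_start > (p - 1L)
          gold$char_start[shift] <- gold$char_start[shift] - 1L
          gold$char_end[shift] <- gold$char_end[shift] - 1L
        }
      }
      posts$text[r] <- paste(chars, collapse = "")
    }
    # invariant: every gold surface still equals its indexed substring
    if (nrow(gold) > 0L) {
      txt <- stats::setNames(posts$text, posts$post_id)[gold$post_id]
      got <- substr(txt, gold$char_start + 1L, gold$char_end)
      stopifnot(identical(unname(got), gold$surface))
    }
    list(corpus = ohc_corpus(posts), gold = gold)
  })
}
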