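# Per-token feature extraction: three families (lex:, sem:, syn:), emitted as
# named indicator features in the crfsuite style (name carries the value,
# e.g. "lex:w0=risperdal"); numeric-valued features are supported by the
# model but all shipped templates are indicators.

FEATURE_FAMILIES <- c("lexical", "semantic", "syntactic")

#' Construct a gazetteer
#'
#' A gazetteer is a named, case-insensitive list of (possibly multi-word)
#' treatment terms used for dictionary matching and semantic features. Terms
#' are normalized to lowercase with collapsed whitespace.
#'
#' @param terms Character vector of terms.
#' @param name Gazetteer name (used as the feature-name component).
#' @return Object of class `ohc_gazetteer`.
#' @export
gazetteer <- function(terms, name = "gaz") {
  terms <- trimws(tolower(terms))
  terms <- gsub("\\s+", " ", terms)
  terms <- unique(terms[nzchar(terms)])
  if (length(terms) == 0L) stop("gazetteer has no terms")
  ntok <- lengths(strsplit(terms, " ", fixed = TRUE))
  structure(list(name = name, terms = terms,
                 max_term_tokens = max(ntok)),
            class = "ohc_gazetteer")
}

#' @export
print.ohc_gazetteer <- function(x, ...) {
  cat(sprintf("<ohc_gazetteer '%s'> %d terms (longest %d tokens)\n",
              x$name, length(x$terms), x$max_term_tokens))
  invisible(x)
}

#' Read a gazetteer file
#'
#' UTF-8 text, one term per line; `#` starts a comment.
#'
#' @param path File path.
#' @param name Gazetteer name; defaults to the file stem.
#' @return An [gazetteer] object.
#' @export
read_gazetteer <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  gazetteer(lines, name = name)
}

#' Match gazetteer terms over a token sequence
#'
#' Greedy leftmost-longest matching of lowercased token n-grams (up to the
#' gazetteer's longest term) against the term list; overlapping candidates are
#' resolved by taking the leftmost match and, at equal start, the longest.
#'
#' @param surfaces Character vector of token surfaces.
#' @param gaz An [gazetteer].
#' @return Character vector over `{"O","B","I"}`, one tag per token.
#' @export
#' @examples
#' gazetteer_match(c("cod", "liver", "oil"), gazetteer("cod liver oil"))
gazetteer_match <- function(surfaces, gaz) {
  stopifnot(inherits(gaz, "ohc_gazetteer"))
  n <- length(surfaces)
  out <- rep("O", n)
  if (n == 0L) return(out)
  low <- tolower(surfaces)
  maxlen <- min(gaz$max_term_tokens, n)
  # precompute n-gram membership per length
  hits <- vector("list", maxlen)
  grams <- low
  for (len in seq_len(maxlen)) {
    if (len > 1L) {
      grams <- paste(grams[-length(grams)], low[-seq_len(len - 1L)])
    }
    hits[[len]] <- grams %in% gaz$terms
  }
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
      if (hits[[len]][i]) { matched <- len; break }
    }
    if (matched > 0L) {
      out[i] <- "B"
      if (matched > 1L) out[(i + 1L):(i + matched - 1L)] <- "I"
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  out
}

fmt_off <- function(d) ifelse(d > 0L, paste0("+", d), as.character(d))

bucket_dist <- function(d) {
  if (is.na(d)) return("none")
  a <- abs(d)
  s <- if (d >= 0L) "+" else "-"
  if (a == 0L) "0"
  else if (a <= 2L) paste0(s, a)
  else if (a <= 5L) paste0(s, "3-5")
  else paste0(s, "6+")
}

# vectorized per-sentence extraction; returns a list (one element per token)
# of character vectors of active indicator feature names
sentence_features <- function(sentence, families = FEATURE_FAMILIES,
                              gazetteers = list(), usernames = character(0)) {
  bad <- setdiff(families, FEATURE_FAMILIES)
  if (length(bad) > 0L) stop("unknown feature family: ", paste(bad, collapse = ", "))
  if (length(families) == 0L) stop("families must be non-empty")
  toks <- sentence$tokens
  n <- nrow(toks)
  if (n == 0L) return(list())
  feats <- replicate(n, character(0), simplify = FALSE)
  if ("lexical" %in% families) {
    surf <- toks$surface
    low <- tolower(surf)
    lem <- toks$lemma
    pos <- toks$pos
    pad <- function(x, d) {
      if (d == 0L) return(x)
      if (d < 0L) c(rep("<BOS>", -d), utils::head(x, n + d))
      else c(x[-seq_len(d)], rep("<EOS>", d))
    }
    base <- vector("list", n)
    for (d in -2:2) {
      tagd <- fmt_off(d)
      wd <- pad(surf, d); lwd <- pad(low, d)
      lemd <- pad(lem, d); posd <- pad(pos, d)
      for (i in seq_len(n)) {
        base[[i]] <- c(base[[i]],
                       paste0("lex:w", tagd, "=", wd[i]),
                       paste0("lex:lw", tagd, "=", lwd[i]),
                       paste0("lex:lem", tagd, "=", lemd[i]),
                       paste0("lex:pos", tagd, "=", posd[i]))
      }
    }
    shape_cap <- grepl("^[A-Z]", surf)
    shape_allcap <- grepl("^[A-Z0-9]+$", surf) & grepl("[A-Z]", surf)
    shape_digit <- grepl("[0-9]", surf)
    shape_hyph <- grepl("-", surf, fixed = TRUE)
    sent_q <- any(surf == "?")
    sent_ex <- any(surf == "!")
    sent_user <- any(grepl("^@.", surf)) ||
      (length(usernames) > 0L && any(low %in% tolower(usernames)))
    sent_flags <- c(if (sent_q) "lex:sent_q=1", if (sent_ex) "lex:sent_ex=1",
                    if (sent_user) "lex:sent_user=1")
    for (i in seq_len(n)) {
      shp <- c(if (shape_cap[i]) "lex:cap=1", if (shape_allcap[i]) "lex:allcap=1",
               if (shape_digit[i]) "lex:digit=1", if (shape_hyph[i]) "lex:hyphen=1")
      feats[[i]] <- c(feats[[i]], base[[i]], shp, sent_flags)
    }
  }
  if ("semantic" %in% families) {
    for (g in gazetteers) {
      m <- gazetteer_match(toks$surface, g)
      for (d in -1:1) {
        tagd <- fmt_off(d)
        md <- if (d == 0L) m else if (d < 0L) c(rep("O", -d), utils::head(m, n + d))
              else c(m[-seq_len(d)], rep("O", d))
        nm <- paste0("sem:", g$name, tagd, "=", md)
        for (i in seq_len(n)) feats[[i]] <- c(feats[[i]], nm[i])
      }
    }
  }
  if ("syntactic" %in% families) {
    si <- sentence$subject_index
    pi <- sentence$predicate_index
    subj_word <- if (!is.na(si)) toks$lemma[si] else "<none>"
    pred_word <- if (!is.na(pi)) toks$lemma[pi] else "<none>"
    subj_fp <- !is.na(si) && toks$lemma[si] %in% c("i", "we")
    subj_my <- FALSE
    if (!is.na(si)) {
      run_start <- si
      while (run_start > 1L &&
             toks$pos[run_start - 1L] %in% c("PRON", "DET", "NOUN", "ADJ")) {
        run_start <- run_start - 1L
      }
      subj_my <- any(toks$lemma[run_start:si] %in% c("my", "our"))
    }
    common <- c(paste0("syn:subj_word=", subj_word),
                paste0("syn:pred_word=", pred_word),
                paste0("syn:subj_fp=", as.integer(subj_fp)),
                paste0("syn:subj_my_np=", as.integer(subj_my)))
    for (i in seq_len(n)) {
      ds <- if (is.na(si)) NA_integer_ else i - si
      dp <- if (is.na(pi)) NA_integer_ else i - pi
      feats[[i]] <- c(feats[[i]], common,
                      paste0("syn:dist_subj=", bucket_dist(ds)),
                      paste0("syn:dist_pred=", bucket_dist(dp)))
    }
  }
  feats
}

as_feature_vector <- function(names) {
  stats::setNames(rep(1, length(names)), names)
}

#' Lexical features for one token
#'
#' Token identity, lowercase form, lemma and POS for positions i-2..i+2 (with
#' `<BOS>`/`<EOS>` padding), word shape (capitalization, digits, hyphen), and
#' sentence-level flags for question marks, exclamation marks and username
#' mentions (`@`-pattern or a configured username list).
#'
#' @param sentence Annotated sentence (see [heuristic_annotate]).
#' @param i Token index (1-based).
#' @param usernames Optional character vector of community member names.
#' @return Named numeric feature vector (indicators are 1).
#' @export
lexical_features <- function(sentence, i, usernames = character(0)) {
  n <- nrow(sentence$tokens)
  if (i < 1L || i > n) stop("token index out of range: ", i)
  as_feature_vector(sentence_features(sentence, "lexical",
                                      usernames = usernames)[[i]])
}

#' Semantic (gazetteer) features for one token
#'
#' For each gazetteer, the B/I/O match tag at positions i-1..i+1.
#'
#' @inheritParams lexical_features
#' @param gazetteers List of [gazetteer] objects.
#' @return Named numeric feature vector.
#' @export
semantic_features <- function(sentence, i, gazetteers) {
  n <- nrow(sentence$tokens)
  if (i < 1L || i > n) stop("token index out of range: ", i)
  as_feature_vector(sentence_features(sentence, "semantic",
                                      gazetteers = gazetteers)[[i]])
}

#' Syntactic features for one token
#'
#' Subject and predicate head lemmas, bucketed signed token distances to each
#' (buckets 0, ±1, ±2, ±3-5, ±6+, none), and first-person-subject /
#' my-in-subject-NP indicators. Distances are token distances; when a plugged
#' annotator supplies parses a tree distance can be substituted behind the
#' same names.
#'
#' @inheritParams lexical_features
#' @return Named numeric feature vector.
#' @export
syntactic_features <- function(sentence, i) {
  n <- nrow(sentence$tokens)
  if (i < 1L || i > n) stop("token index out of range: ", i)
  as_feature_vector(sentence_features(sentence, "syntactic")[[i]])
}

#' Extract all selected feature families for every token of a sentence
#'
#' The family subset is the ablation axis of the evaluation grid
#' (`lexical`, `lexical+semantic`, `lexical+semantic+syntactic`).
#'
#' @inheritParams semantic_features
#' @param families Non-empty subset of
#'   `c("lexical", "semantic", "syntactic")`.
#' @return List of named numeric feature vectors, one per token.
#' @export
extract_all <- function(sentence, families = FEATURE_FAMILIES,
                        gazetteers = list(), usernames = character(0)) {
  lapply(sentence_features(sentence, families, gazetteers, usernames),
         as_feature_vector)
}
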