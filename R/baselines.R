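# Comparison systems: dictionary-match mention detection, lasso multinomial
# logistic regression for attribution, and the hybrid ("baseline+") that
# labels CRF-detected spans with the logistic classifier.

#' Dictionary-match mention detection for one sentence
#'
#' Leftmost-longest gazetteer matching (see [gazetteer_match]) turned into
#' unlabeled candidate spans.
#'
#' @param tokens Token data.frame (`surface`, `char_start`, `char_end`).
#' @param gaz An [gazetteer].
#' @param text Optional post text for exact surfaces.
#' @return Span data.frame with `label = NA`.
#' @export
dict_detect <- function(tokens, gaz, text = NULL) {
  m <- gazetteer_match(tokens$surface, gaz)
  n <- length(m)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (m[i] == "B") {
      e <- i
      while (e < n && m[e + 1L] == "I") e <- e + 1L
      out[[length(out) + 1L]] <- data.frame(
        char_start = tokens$char_start[i], char_end = tokens$char_end[e],
        token_start = i - 1L, token_end = e, stringsAsFactors = FALSE
      )
      i <- e + 1L
    } else i <- i + 1L
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else data.frame(
    char_start = integer(), char_end = integer(),
    token_start = integer(), token_end = integer(), stringsAsFactors = FALSE
  )
  res$surface <- if (nrow(res) > 0L) {
    if (!is.null(text)) {
      substr(rep(text, nrow(res)), res$char_start + 1L, res$char_end)
    } else {
      vapply(seq_len(nrow(res)), function(k) {
        paste(tokens$surface[(res$token_start[k] + 1L):res$token_end[k]],
              collapse = " ")
      }, "")
    }
  } else character(0)
  res$label <- rep(NA_character_, nrow(res))
  res
}

#' Aggregate token features over a candidate span
#'
#' The span classifier uses the same per-token feature families as the CRF,
#' aggregated as the union of in-span token features (prefix `in:`) plus the
#' features of the tokens immediately before and after the span (prefixes
#' `ctx:L|` and `ctx:R|`).
#'
#' @param sentence Annotated sentence.
#' @param token_start,token_end 0-based half-open token indices within the
#'   sentence.
#' @inheritParams extract_all
#' @return Named numeric feature vector.
#' @export
span_features <- function(sentence, token_start, token_end,
                          families = FEATURE_FAMILIES, gazetteers = list(),
                          usernames = character(0)) {
  n <- nrow(sentence$tokens)
  stopifnot(token_start >= 0L, token_end <= n, token_start < token_end)
  base <- sentence_features(sentence, families, gazetteers, usernames)
  inside <- unique(unlist(base[(token_start + 1L):token_end], use.names = FALSE))
  nm <- paste0("in:", inside)
  if (token_start >= 1L) {
    nm <- c(nm, paste0("ctx:L|", base[[token_start]]))
  } else {
    nm <- c(nm, "ctx:L|<BOS>")
  }
  if (token_end < n) {
    nm <- c(nm, paste0("ctx:R|", base[[token_end + 1L]]))
  } else {
    nm <- c(nm, "ctx:R|<EOS>")
  }
  as_feature_vector(unique(nm))
}

#' Construct a span-attribution logistic model
#'
#' Container for a multinomial logistic classifier over attribution labels;
#' normally produced by [lr_train] but constructible directly (e.g. for
#' degenerate-weight checks).
#'
#' @param classes Class labels, in tie-break order.
#' @param feature_names Feature vocabulary.
#' @param intercepts Numeric vector, one per class.
#' @param W Feature-by-class weight matrix.
#' @param l1_lambda The lasso penalty used (if any).
#' @return Object of class `lr_model`.
#' @export
lr_model <- function(classes, feature_names, intercepts = NULL, W = NULL,
                     l1_lambda = NA_real_) {
  if (is.null(intercepts)) intercepts <- rep(0, length(classes))
  if (is.null(W)) W <- matrix(0, length(feature_names), length(classes))
  stopifnot(length(intercepts) == length(classes),
            nrow(W) == length(feature_names), ncol(W) == length(classes))
  structure(list(classes = classes, feature_names = feature_names,
                 intercepts = intercepts, W = W, l1_lambda = l1_lambda),
            class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf("<lr_model> %d classes, %d features, lambda=%s, %d nonzero weights\n",
              length(x$classes), length(x$feature_names),
              format(x$l1_lambda), sum(x$W != 0)))
  invisible(x)
}

lr_design <- function(feature_vectors, feature_names) {
  per <- vapply(feature_vectors, length, 0L)
  nm <- unlist(lapply(feature_vectors, names), use.names = FALSE)
  val <- unlist(lapply(feature_vectors, unname), use.names = FALSE)
  col <- match(nm, feature_names)
  keep <- !is.na(col)
  Matrix::sparseMatrix(i = rep(seq_along(per), per)[keep], j = col[keep],
                       x = val[keep],
                       dims = c(length(feature_vectors), length(feature_names)))
}

#' Train the lasso logistic attribution classifier
#'
#' Multinomial logistic regression with an L1 penalty, fit with
#' \pkg{glmnet}. When `l1_lambda` is `NULL` it is chosen by 5-fold
#' cross-validation over glmnet's lambda grid, with fold assignment
#' deterministic in `seed`.
#'
#' @param feature_vectors List of span feature vectors (see [span_features]).
#' @param labels Gold attribution labels, one per span.
#' @param l1_lambda Lasso penalty; `NULL` for CV selection.
#' @param seed Integer seed for the CV fold assignment.
#' @param classes Candidate class order (tie-break order); classes absent
#'   from `labels` are dropped.
#' @return An [lr_model].
#' @export
lr_train <- function(feature_vectors, labels, l1_lambda = NULL, seed = 1L,
                     classes = attribution_labels()) {
  stopifnot(length(feature_vectors) == length(labels))
  classes <- classes[classes %in% labels]
  extra <- setdiff(labels, classes)
  if (length(extra) > 0L) classes <- c(classes, sort(extra))
  if (length(classes) < 2L) {
    stop("degenerate training data: fewer than 2 classes present")
  }
  fnames <- unique(unlist(lapply(feature_vectors, names), use.names = FALSE))
  X <- lr_design(feature_vectors, fnames)
  y <- factor(labels, levels = classes)
  if (is.null(l1_lambda)) {
    folds <- with_local_seed(seed, sample(rep_len(1:5, length(labels))))
    cv <- glmnet::cv.glmnet(X, y, family = "multinomial", alpha = 1,
                            foldid = folds, standardize = FALSE)
    l1_lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 1,
                          standardize = FALSE)
  }
  cf <- glmnet::coef.glmnet(fit, s = l1_lambda, exact = FALSE)
  W <- do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1L, 1L]))
  intercepts <- vapply(cf, function(m) as.matrix(m)[1L, 1L], 0)
  colnames(W) <- classes
  lr_model(classes, fnames, intercepts = unname(intercepts), W = W,
           l1_lambda = l1_lambda)
}

#' Classify a span feature vector
#'
#' Linear scores `intercept + w . x` per class; argmax with ties broken
#' toward the lower class index.
#'
#' @param model An [lr_model].
#' @param feature_vector Named numeric span feature vector, or a list of them.
#' @return Character vector of predicted class labels.
#' @export
lr_classify <- function(model, feature_vector) {
  fvs <- if (is.list(feature_vector)) feature_vector else list(feature_vector)
  X <- lr_design(fvs, model$feature_names)
  scores <- as.matrix(X %*% model$W) +
    matrix(model$intercepts, nrow(X), length(model$classes), byrow = TRUE)
  model$classes[apply(scores, 1L, which.max)]
}

#' Run the dictionary + logistic baseline over a corpus
#'
#' Mention spans come from leftmost-longest dictionary matching against
#' `dict_gaz`; each detected span is then labeled by the logistic classifier.
#' The span set is independent of the classifier.
#'
#' @param corpus An [ohc_corpus].
#' @param dict_gaz [gazetteer] used for mention detection.
#' @param lr A trained [lr_model].
#' @inheritParams corpus_sentences
#' @return Labeled span data.frame as in [predict_spans].
#' @export
run_baseline <- function(corpus, dict_gaz, lr, families = FEATURE_FAMILIES,
                         gazetteers = list(), annotator = "heuristic",
                         usernames = character(0)) {
  sentences <- corpus_sentences(corpus, NULL, families, gazetteers,
                                annotator, usernames)
  text_by_id <- stats::setNames(corpus$posts$text, corpus$posts$post_id)
  rows <- list(); fvs <- list()
  for (s in sentences) {
    det <- dict_detect(s$tokens, dict_gaz, text = text_by_id[[s$post_id]])
    for (k in seq_len(nrow(det))) {
      fvs[[length(fvs) + 1L]] <- span_features(
        s$sentence, det$token_start[k], det$token_end[k],
        families, gazetteers, usernames
      )
      rows[[length(rows) + 1L]] <- data.frame(
        post_id = s$post_id, char_start = det$char_start[k],
        char_end = det$char_end[k],
        token_start = det$token_start[k] + s$tok_offset,
        token_end = det$token_end[k] + s$tok_offset,
        surface = det$surface[k], label = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    post_id = character(), char_start = integer(), char_end = integer(),
    token_start = integer(), token_end = integer(), surface = character(),
    label = character(), stringsAsFactors = FALSE
  )
  if (nrow(out) > 0L) out$label <- lr_classify(lr, fvs)
  rownames(out) <- NULL
  out
}

#' Run the baseline+ hybrid: CRF spans, logistic labels
#'
#' Decodes mention spans with the CRF (attributions stripped) and labels each
#' span with the logistic classifier, so the span set coincides exactly with
#' the CRF's and mention-only scores are identical between the two systems.
#'
#' @param corpus An [ohc_corpus].
#' @param crf A trained [crf_model].
#' @param lr A trained [lr_model].
#' @inheritParams corpus_sentences
#' @return Labeled span data.frame as in [predict_spans].
#' @export
run_baseline_plus <- function(corpus, crf, lr, families = FEATURE_FAMILIES,
                              gazetteers = list(), annotator = "heuristic",
                              usernames = character(0)) {
  sentences <- corpus_sentences(corpus, NULL, families, gazetteers,
                                annotator, usernames)
  sp <- predict_spans_sentences(crf, sentences, corpus)
  if (nrow(sp) > 0L) {
    fvs <- lapply(seq_len(nrow(sp)), function(k) {
      s <- sentences[[sp$.sent[k]]]
      span_features(s$sentence,
                    sp$token_start[k] - s$tok_offset,
                    sp$token_end[k] - s$tok_offset,
                    families, gazetteers, usernames)
    })
    sp$label <- lr_classify(lr, fvs)
  }
  rc <- attr(sp, "repair_count")
  sp$.sent <- NULL
  attr(sp, "repair_count") <- rc
  rownames(sp) <- NULL
  sp
}

#' Save / load a logistic span classifier as flat text
#'
#' Mirrors the CRF model format: versioned header, class list, feature table
#' and weights at 17 significant digits so `load o save` is the identity.
#'
#' @param model An [lr_model].
#' @param path File path.
#' @return `lr_load` returns the model; `lr_save` returns `path` invisibly.
#' @export
lr_save <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c(
    "ohctreat-lr v1",
    paste0("l1_lambda\t", num(model$l1_lambda)),
    paste0("classes\t", paste(model$classes, collapse = "\t")),
    paste0("n_features\t", length(model$feature_names)),
    paste0("intercepts\t", paste(num(model$intercepts), collapse = "\t"))
  ), con)
  writeLines(model$feature_names, con)
  writeLines(paste0("W\t", apply(model$W, 1, function(r)
    paste(num(r), collapse = "\t"))), con)
  invisible(path)
}

#' @rdname lr_save
#' @export
lr_load <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (lines[1L] != "ohctreat-lr v1") stop("unrecognized model file: ", path)
  kv <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1L]][-1L]
  l1_lambda <- as.numeric(kv(2L))
  classes <- kv(3L)
  n_feat <- as.integer(kv(4L))
  intercepts <- as.numeric(kv(5L))
  fnames <- if (n_feat > 0L) lines[5L + seq_len(n_feat)] else character(0)
  W <- matrix(0, n_feat, length(classes))
  if (n_feat > 0L) {
    rows <- lines[5L + n_feat + seq_len(n_feat)]
    W <- do.call(rbind, lapply(rows, function(r) {
      parts <- strsplit(r, "\t", fixed = TRUE)[[1L]]
      if (parts[1L] != "W") stop("model file corrupt near '", r, "'")
      as.numeric(parts[-1L])
    }))
  }
  colnames(W) <- classes
  lr_model(classes, fnames, intercepts = intercepts, W = W,
           l1_lambda = l1_lambda)
}
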