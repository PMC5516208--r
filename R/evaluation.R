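# Span-level evaluation in three regimes (mention-only, five-class,
# binary pt/non-pt), micro-averaged P/R/F from pooled counts, and token-level
# Cohen's kappa for inter-annotator agreement.

span_keys <- function(spans, typed) {
  k <- paste(spans$post_id, spans$char_start, spans$char_end, sep = "\r")
  if (typed) k <- paste(k, spans$label, sep = "\r")
  k
}

check_no_overlap <- function(spans, what) {
  if (nrow(spans) < 2L) return(invisible(TRUE))
  for (pid in unique(spans$post_id)) {
    s <- spans[spans$post_id == pid, , drop = FALSE]
    s <- s[order(s$char_start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$char_start[-1L] < s$char_end[-nrow(s)])) {
      stop("overlapping spans in ", what, " for post ", pid)
    }
  }
  invisible(TRUE)
}

#' Match predicted against gold spans with exact boundaries
#'
#' A predicted span is a true positive iff some gold span has the identical
#' `(post_id, char_start, char_end)` and, when `typed`, the identical
#' attribution label; matching is one-to-one, and partial overlaps earn no
#' credit. Unmatched predictions are false positives, unmatched gold spans
#' false negatives.
#'
#' @param gold,pred Span data.frames (`post_id`, `char_start`, `char_end`,
#'   `label`).
#' @param typed Require the label to match as well.
#' @return List with `tp`, `fp`, `fn` counts and `pairs`, a data.frame of
#'   matched `(gold, pred)` row indices.
#' @export
match_spans <- function(gold, pred, typed = TRUE) {
  check_no_overlap(gold, "gold")
  check_no_overlap(pred, "pred")
  gk <- span_keys(gold, typed)
  pk <- span_keys(pred, typed)
  m <- match(pk, gk)
  # one-to-one: exact keys cannot repeat across non-overlapping spans
  matched <- !is.na(m)
  list(tp = sum(matched), fp = sum(!matched), fn = nrow(gold) - sum(matched),
       pairs = data.frame(gold = m[matched], pred = which(matched)))
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

EVAL_REGIMES <- c("mention_only", "five_class", "binary_pt")

#' Precision / recall / F report for one evaluation regime
#'
#' `mention_only` scores boundaries regardless of labels; `five_class`
#' requires boundary and attribution to match and reports the five classes
#' plus the micro average over pooled tp/fp/fn; `binary_pt` first merges
#' labels on both sides with [binary_merge] and scores `pt` and `non-pt`.
#'
#' @inheritParams match_spans
#' @param regime One of `"mention_only"`, `"five_class"`, `"binary_pt"`.
#' @return Object of class `eval_report`: list with `regime`, `per_class`
#'   (data.frame `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`),
#'   `micro`, and `repair_count` (copied from `pred`'s attribute when set).
#' @export
prf_report <- function(gold, pred, regime = c("five_class", "mention_only",
                                              "binary_pt")) {
  regime <- match.arg(regime)
  repair <- attr(pred, "repair_count")
  if (is.null(repair)) repair <- 0L
  if (regime == "mention_only") {
    m <- match_spans(gold, pred, typed = FALSE)
    per <- data.frame(class = "mention", tp = m$tp, fp = m$fp, fn = m$fn,
                      stringsAsFactors = FALSE)
  } else {
    g <- gold; p <- pred
    classes <- attribution_labels()
    if (regime == "binary_pt") {
      g$label <- binary_merge(g$label)
      p$label <- binary_merge(p$label)
      classes <- c("pt", "non-pt")
    }
    m <- match_spans(g, p, typed = TRUE)
    matched_pred <- m$pairs$pred
    matched_gold <- m$pairs$gold
    per <- do.call(rbind, lapply(classes, function(cl) {
      tp <- sum(p$label[matched_pred] == cl)
      fp <- sum(p$label == cl) - tp
      fn <- sum(g$label == cl) - sum(g$label[matched_gold] == cl)
      data.frame(class = cl, tp = tp, fp = fp, fn = fn,
                 stringsAsFactors = FALSE)
    }))
  }
  stats_ <- t(vapply(seq_len(nrow(per)),
                     function(i) prf(per$tp[i], per$fp[i], per$fn[i]),
                     c(precision = 0, recall = 0, f1 = 0)))
  per <- cbind(per, as.data.frame(stats_))
  micro <- prf(sum(per$tp), sum(per$fp), sum(per$fn))
  structure(list(regime = regime, per_class = per,
                 micro = as.list(micro), repair_count = repair),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_report: %s>\n", x$regime))
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("micro: P=%.*f R=%.*f F=%.*f\n", digits, x$micro$precision,
              digits, x$micro$recall, digits, x$micro$f1))
  invisible(x)
}

#' Token-level attribution labels induced by a span annotation
#'
#' Tokenizes every post of the corpus with the chosen annotator and labels
#' each token with the attribution of the span covering it (or `O`). Used to
#' put two annotations of the same posts on a common token universe for
#' [cohen_kappa].
#'
#' @param corpus An [ohc_corpus].
#' @param spans Span data.frame.
#' @param annotator Annotator name.
#' @return Character vector of per-token labels over `{O}` and the five
#'   attribution labels, in corpus order.
#' @export
annotation_token_labels <- function(corpus, spans, annotator = "heuristic") {
  annotated <- annotate_corpus(corpus, annotator)
  out <- character(0)
  for (pid in names(annotated)) {
    sp <- spans[spans$post_id == pid, , drop = FALSE]
    for (s in annotated[[pid]]) {
      toks <- s$tokens
      lab <- rep("O", nrow(toks))
      for (k in seq_len(nrow(sp))) {
        cov <- toks$char_start >= sp$char_start[k] &
          toks$char_end <= sp$char_end[k]
        lab[cov] <- sp$label[k]
      }
      out <- c(out, lab)
    }
  }
  out
}

#' Cohen's kappa between two token-label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement over the 6-way token label set (five
#' attributions plus `O`). When both annotators are constant and identical
#' (`p_e = 1`), kappa is reported as 1 with attribute `degenerate = TRUE`
#' and a warning.
#'
#' @param a,b Character vectors of per-token labels over the same token
#'   universe (see [annotation_token_labels]).
#' @return Kappa as a single numeric value.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) {
    stop("token universes differ: ", length(a), " vs ", length(b), " tokens")
  }
  n <- length(a)
  if (n == 0L) stop("empty annotation")
  cats <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pa <- table(factor(a, cats)) / n
  pb <- table(factor(b, cats)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (pe >= 1 - 1e-15) {
    warning("degenerate annotation pair (expected agreement = 1); kappa reported as 1")
    return(structure(1, degenerate = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Run the full evaluation grid over a corpus
#'
#' Reproduces the experimental grid: for each feature-family set, trains the
#' CRF (and the logistic span classifier on gold spans of the training
#' partition), runs the requested systems on the test partition and scores
#' them under the requested regimes.
#'
#' @param corpus Annotated corpus ([ohc_corpus]).
#' @param gold Gold span table for the whole corpus.
#' @param family_sets Named list of feature-family vectors, e.g.
#'   `list("lexical" = "lexical", "lexical+semantic" = c("lexical","semantic"))`.
#' @param systems Subset of `c("crf", "baseline", "baseline_plus")`.
#' @param regimes Subset of the three regimes.
#' @param dict_gaz Gazetteer for the dictionary baseline.
#' @param gazetteers Gazetteers for semantic features.
#' @param split_fraction,seed Train/test split by post.
#' @param l2_sigma,max_iterations CRF training configuration.
#' @param l1_lambda Lasso penalty for the span classifier (`NULL` = CV).
#' @param annotator Annotator name.
#' @return Data.frame with columns `system`, `families`, `regime`, `class`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1` (micro rows have class
#'   `"micro"`); the fitted models are in attribute `models`.
#' @export
ablation_run <- function(corpus, gold,
                         family_sets = list(
                           "lexical" = "lexical",
                           "lexical+semantic" = c("lexical", "semantic"),
                           "lexical+semantic+syntactic" = FEATURE_FAMILIES
                         ),
                         systems = c("crf", "baseline", "baseline_plus"),
                         regimes = EVAL_REGIMES,
                         dict_gaz = NULL, gazetteers = list(),
                         split_fraction = 0.7, seed = 1L,
                         l2_sigma = 10, max_iterations = 150L,
                         l1_lambda = 0.01, annotator = "heuristic") {
  if (is.null(names(family_sets)) || any(names(family_sets) == "")) {
    names(family_sets) <- vapply(family_sets, paste, "", collapse = "+")
  }
  stopifnot(all(unlist(family_sets) %in% FEATURE_FAMILIES))
  systems <- match.arg(systems, several.ok = TRUE)
  regimes <- match.arg(regimes, c(EVAL_REGIMES), several.ok = TRUE)
  if (("baseline" %in% systems) && is.null(dict_gaz)) {
    stop("dict_gaz is required when the dictionary baseline is run")
  }
  halves <- split_corpus(corpus, split_fraction, seed)
  gold_train <- gold[gold$post_id %in% halves$train$posts$post_id, , drop = FALSE]
  gold_test <- gold[gold$post_id %in% halves$test$posts$post_id, , drop = FALSE]
  if (nrow(gold_train) == 0L || nrow(gold_test) == 0L) {
    stop("empty split: no gold spans on one side of the train/test partition")
  }
  rows <- list(); models <- list()
  for (fam_name in names(family_sets)) {
    fams <- family_sets[[fam_name]]
    train_sents <- corpus_sentences(halves$train, gold_train, fams,
                                    gazetteers, annotator)
    crf <- crf_train(train_sents, l2_sigma = l2_sigma,
                     max_iterations = max_iterations)
    lr <- NULL
    if (any(c("baseline", "baseline_plus") %in% systems)) {
      fvs <- list(); labs <- character(0)
      for (s in train_sents) {
        sp <- tags_to_spans(s$tokens, s$tags)
        for (k in seq_len(nrow(sp))) {
          fvs[[length(fvs) + 1L]] <- span_features(
            s$sentence, sp$token_start[k], sp$token_end[k], fams, gazetteers)
          labs <- c(labs, sp$label[k])
        }
      }
      lr <- lr_train(fvs, labs, l1_lambda = l1_lambda, seed = seed)
    }
    preds <- list()
    if ("crf" %in% systems) {
      preds$crf <- predict_spans(crf, halves$test, fams, gazetteers, annotator)
    }
    if ("baseline" %in% systems) {
      preds$baseline <- run_baseline(halves$test, dict_gaz, lr, fams,
                                     gazetteers, annotator)
    }
    if ("baseline_plus" %in% systems) {
      preds$baseline_plus <- run_baseline_plus(halves$test, crf, lr, fams,
                                               gazetteers, annotator)
    }
    models[[fam_name]] <- list(crf = crf, lr = lr)
    for (sys in names(preds)) {
      for (reg in regimes) {
        rep_ <- prf_report(gold_test, preds[[sys]], reg)
        per <- rep_$per_class
        per <- rbind(per, data.frame(
          class = "micro", tp = sum(per$tp), fp = sum(per$fp),
          fn = sum(per$fn), precision = rep_$micro$precision,
          recall = rep_$micro$recall, f1 = rep_$micro$f1,
          stringsAsFactors = FALSE
        ))
        per$system <- sys; per$families <- fam_name; per$regime <- reg
        rows[[length(rows) + 1L]] <-
          per[, c("system", "families", "regime", "class", "tp", "fp", "fn",
                  "precision", "recall", "f1")]
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}
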