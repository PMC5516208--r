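# Linear-chain CRF over the 11-symbol typed-BIO alphabet. State features are
# (feature-name x label) weights; transitions include BOS->label and
# label->EOS blocks. Disallowed transitions (invalid BIO) are masked with a
# large negative score and carry no trainable weight.

MASK_SCORE <- -1e30

# allowed transition structure for valid typed BIO
bio_masks <- function(labels) {
  L <- length(labels)
  p <- parse_tag(labels)
  trans_ok <- matrix(TRUE, L, L, dimnames = list(labels, labels))
  for (j in seq_len(L)) {
    if (p$prefix[j] == "I") {
      for (i in seq_len(L)) {
        trans_ok[i, j] <- p$prefix[i] %in% c("B", "I") &&
          identical(p$class[i], p$class[j])
      }
    }
  }
  bos_ok <- p$prefix != "I"
  list(trans = trans_ok, bos = bos_ok)
}

#' Construct a linear-chain CRF model
#'
#' Creates an (untrained, zero-weight) CRF over the typed-BIO alphabet with a
#' fixed feature-name registry. With `mask = TRUE` (default) transitions that
#' would produce invalid BIO output (`O -> I-c`, `B-c -> I-c'` for `c != c'`,
#' and `BOS -> I-c`) are forbidden, so decoded sequences are always valid.
#'
#' @param feature_names Character vector of state feature names.
#' @param l2_sigma Gaussian prior scale; the penalty is `sum(w^2) / (2 sigma^2)`.
#' @param mask Forbid invalid-BIO transitions.
#' @param labels Tag alphabet; defaults to [crf_labels()].
#' @return Object of class `crf_model`.
#' @export
crf_model <- function(feature_names = character(0), l2_sigma = 10,
                      mask = TRUE, labels = crf_labels()) {
  stopifnot(l2_sigma > 0)
  feature_names <- unique(as.character(feature_names))
  L <- length(labels)
  masks <- if (mask) bio_masks(labels) else
    list(trans = matrix(TRUE, L, L), bos = rep(TRUE, L))
  structure(list(
    labels = labels,
    feature_names = feature_names,
    W = matrix(0, length(feature_names), L,
               dimnames = list(NULL, labels)),
    trans = matrix(0, L, L, dimnames = list(labels, labels)),
    bos = rep(0, L), eos = rep(0, L),
    mask_trans = masks$trans, mask_bos = masks$bos,
    l2_sigma = l2_sigma, masked = mask, trained = FALSE
  ), class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf(
    "<crf_model> %d labels, %d state features (%strained, mask %s, sigma=%g)\n",
    length(x$labels), length(x$feature_names),
    if (x$trained) "" else "un", if (x$masked) "on" else "off", x$l2_sigma
  ))
  invisible(x)
}

# effective (masked) transition scores
eff_trans <- function(model) {
  tr <- model$trans
  tr[!model$mask_trans] <- MASK_SCORE
  tr
}
eff_bos <- function(model) {
  b <- model$bos
  b[!model$mask_bos] <- MASK_SCORE
  b
}

norm_feats <- function(feats) {
  lapply(feats, function(f) {
    if (is.character(f)) as_feature_vector(f) else f
  })
}

# dense emission-score matrix (T x L) for one sentence
sentence_emissions <- function(model, feats) {
  feats <- norm_feats(feats)
  E <- matrix(0, length(feats), length(model$labels))
  for (t in seq_along(feats)) {
    f <- feats[[t]]
    idx <- match(names(f), model$feature_names)
    keep <- !is.na(idx)
    if (any(keep)) {
      E[t, ] <- as.vector(unname(f[keep]) %*% model$W[idx[keep], , drop = FALSE])
    }
  }
  E
}

tag_indices <- function(model, tags) {
  idx <- match(tags, model$labels)
  if (anyNA(idx)) {
    stop("unknown tag: ", paste(tags[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Unnormalized log-score of a tag sequence
#'
#' Sum of state-feature scores for each `(features_t, tag_t)` plus transition
#' scores for consecutive tags, including the BOS and EOS transitions.
#' Computed by explicit summation.
#'
#' @param model A [crf_model].
#' @param feats List of per-token feature vectors (named numeric, or character
#'   vectors of indicator names).
#' @param tags Character tag sequence.
#' @return A single numeric log-score.
#' @export
score_sequence <- function(model, feats, tags) {
  stopifnot(length(feats) == length(tags))
  idx <- tag_indices(model, tags)
  E <- sentence_emissions(model, feats)
  tr <- eff_trans(model)
  s <- eff_bos(model)[idx[1L]] + model$eos[idx[length(idx)]]
  for (t in seq_along(idx)) {
    s <- s + E[t, idx[t]]
    if (t > 1L) s <- s + tr[idx[t - 1L], idx[t]]
  }
  s
}

#' Log partition function of one sentence
#'
#' Forward algorithm in log space; equals the log of the sum of
#' `exp(score_sequence)` over all `L^T` tag sequences (masked transitions
#' excluded).
#'
#' @inheritParams score_sequence
#' @return A single numeric value.
#' @export
log_partition <- function(model, feats) {
  E <- sentence_emissions(model, feats)
  out <- crf_batch_fb(E, length(feats), eff_trans(model), eff_bos(model),
                      model$eos)
  out$logZ[1L]
}

#' Per-position marginal label probabilities
#'
#' Forward-backward marginals; each row sums to one.
#'
#' @inheritParams score_sequence
#' @return `T x L` matrix of probabilities with label column names.
#' @export
crf_marginals <- function(model, feats) {
  E <- sentence_emissions(model, feats)
  out <- crf_batch_fb(E, length(feats), eff_trans(model), eff_bos(model),
                      model$eos)
  m <- out$marginals
  colnames(m) <- model$labels
  m
}

#' Viterbi decoding
#'
#' Highest-scoring tag sequence; ties are broken deterministically toward the
#' lower label index at each backtrack step. With the BIO transition mask on,
#' output is always a valid BIO sequence.
#'
#' @inheritParams score_sequence
#' @return Character vector of tags.
#' @export
crf_viterbi <- function(model, feats) {
  E <- sentence_emissions(model, feats)
  path <- crf_batch_viterbi(E, length(feats), eff_trans(model),
                            eff_bos(model), model$eos)
  model$labels[path + 1L]
}

# ---- parameter packing -------------------------------------------------

crf_parameters <- function(model) {
  c(as.vector(model$W), model$trans[model$mask_trans],
    model$bos[model$mask_bos], model$eos)
}

crf_set_parameters <- function(model, theta) {
  F <- length(model$feature_names); L <- length(model$labels)
  nW <- F * L
  nT <- sum(model$mask_trans)
  nB <- sum(model$mask_bos)
  stopifnot(length(theta) == nW + nT + nB + L)
  model$W <- matrix(theta[seq_len(nW)], F, L, dimnames = list(NULL, model$labels))
  model$trans[model$mask_trans] <- theta[nW + seq_len(nT)]
  model$bos[model$mask_bos] <- theta[nW + nT + seq_len(nB)]
  model$eos <- theta[nW + nT + nB + seq_len(L)]
  model
}

# ---- batch machinery ---------------------------------------------------

# compile a list of sentences (each list(features, tags)) against a model's
# feature index: sparse design matrix X (tokens x features), lengths, gold
crf_compile <- function(model, data) {
  feats <- lapply(data, function(s) norm_feats(s$features))
  lengths <- vapply(feats, length, 0L)
  if (any(lengths == 0L)) stop("empty sentence in training data")
  all_names <- unlist(lapply(feats, function(s) lapply(s, names)),
                      use.names = FALSE)
  all_vals <- unlist(lapply(feats, function(s) lapply(s, unname)),
                     use.names = FALSE)
  per_tok <- unlist(lapply(feats, function(s) vapply(s, length, 0L)),
                    use.names = FALSE)
  row_id <- rep(seq_along(per_tok), per_tok)
  col_id <- match(all_names, model$feature_names)
  keep <- !is.na(col_id)
  X <- Matrix::sparseMatrix(
    i = row_id[keep], j = col_id[keep], x = all_vals[keep],
    dims = c(sum(lengths), length(model$feature_names))
  )
  gold <- NULL
  if (!is.null(data[[1L]]$tags)) {
    gold <- unlist(lapply(data, function(s) s$tags), use.names = FALSE)
    gold <- tag_indices(model, gold) - 1L
  }
  list(X = X, lengths = lengths, gold = gold)
}

crf_nll_grad_compiled <- function(model, comp) {
  E <- as.matrix(comp$X %*% model$W)
  tr <- eff_trans(model); b <- eff_bos(model)
  fb <- crf_batch_fb(E, comp$lengths, tr, b, model$eos)
  gc_ <- crf_gold_counts(E, comp$lengths, tr, b, model$eos, comp$gold)
  sigma2 <- model$l2_sigma^2
  theta <- crf_parameters(model)
  nll <- sum(fb$logZ) - gc_$score + sum(theta^2) / (2 * sigma2)
  # emission gradient: marginals minus one-hot gold
  eg <- fb$marginals
  eg[cbind(seq_len(nrow(eg)), comp$gold + 1L)] <-
    eg[cbind(seq_len(nrow(eg)), comp$gold + 1L)] - 1
  gW <- as.matrix(Matrix::crossprod(comp$X, eg)) + model$W / sigma2
  gtrans <- (fb$trans_exp - gc_$trans_emp)[model$mask_trans] +
    model$trans[model$mask_trans] / sigma2
  gbos <- (fb$bos_exp - gc_$bos_emp)[model$mask_bos] +
    model$bos[model$mask_bos] / sigma2
  geos <- (fb$eos_exp - gc_$eos_emp) + model$eos / sigma2
  list(value = nll, gradient = c(as.vector(gW), gtrans, gbos, geos))
}

#' Penalized negative log-likelihood and its gradient
#'
#' The convex training objective: the negative conditional log-likelihood of
#' the gold tag sequences plus the Gaussian penalty `sum(w^2)/(2 sigma^2)`.
#' The gradient is expected feature counts minus empirical counts plus
#' `w / sigma^2`, laid out as the model's flat parameter vector (state
#' weights, allowed transitions, BOS, EOS).
#'
#' @param model A [crf_model].
#' @param data List of sentences, each a list with elements `features`
#'   (per-token feature vectors) and `tags` (gold tag sequence).
#' @return List with elements `value` and `gradient`.
#' @export
crf_nll_gradient <- function(model, data) {
  comp <- crf_compile(model, data)
  if (is.null(comp$gold)) stop("training data must carry gold tags")
  crf_nll_grad_compiled(model, comp)
}

#' Train a CRF by regularized maximum likelihood
#'
#' Collects the feature vocabulary from the training data, then minimizes the
#' penalized negative log-likelihood with L-BFGS from zero initialization.
#' Deterministic given the data order and configuration.
#'
#' @param data Training sentences as in [crf_nll_gradient].
#' @param l2_sigma Gaussian prior scale.
#' @param max_iterations Optimizer iteration cap.
#' @param gradient_tolerance Projected-gradient tolerance passed to L-BFGS.
#' @param mask Forbid invalid-BIO transitions (default `TRUE`).
#' @param labels Tag alphabet.
#' @param verbose Log per-iteration objective values.
#' @return A trained [crf_model]; the per-evaluation objective trace is in
#'   attribute `objective_trace`.
#' @export
crf_train <- function(data, l2_sigma = 10, max_iterations = 200L,
                      gradient_tolerance = 1e-5, mask = TRUE,
                      labels = crf_labels(), verbose = FALSE) {
  if (length(data) == 0L) stop("empty training set")
  stopifnot(max_iterations >= 1L)
  fnames <- unique(unlist(lapply(data, function(s) {
    unlist(lapply(norm_feats(s$features), names), use.names = FALSE)
  }), use.names = FALSE))
  model <- crf_model(fnames, l2_sigma = l2_sigma, mask = mask, labels = labels)
  comp <- crf_compile(model, data)
  if (is.null(comp$gold)) stop("training data must carry gold tags")
  trace_env <- new.env(parent = emptyenv())
  trace_env$obj <- numeric(0)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) {
      return(cache$res)
    }
    m <- crf_set_parameters(model, theta)
    res <- crf_nll_grad_compiled(m, comp)
    if (!is.finite(res$value)) {
      stop("non-finite objective during CRF training (value = ", res$value, ")")
    }
    cache$theta <- theta
    cache$res <- res
    trace_env$obj <- c(trace_env$obj, res$value)
    if (verbose) ohc_log("crf_train: nll+penalty = %.6f", res$value)
    res
  }
  theta0 <- crf_parameters(model)
  opt <- stats::optim(
    theta0,
    fn = function(th) evaluate(th)$value,
    gr = function(th) evaluate(th)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = max_iterations, pgtol = gradient_tolerance,
                   factr = 1e7)
  )
  model <- crf_set_parameters(model, opt$par)
  model$trained <- TRUE
  attr(model, "objective_trace") <- trace_env$obj
  attr(model, "convergence") <- opt$convergence
  model
}

# ---- serialization -----------------------------------------------------

#' Save / load a CRF model as a versioned flat text file
#'
#' The file holds the label list, the feature-name table and the full weight
#' array, with doubles printed at 17 significant digits so that
#' `load o save` is the identity.
#'
#' @param model A [crf_model].
#' @param path File path.
#' @return `crf_load` returns the model; `crf_save` returns `path` invisibly.
#' @export
crf_save <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c(
    "ohctreat-crf v1",
    paste0("l2_sigma\t", num(model$l2_sigma)),
    paste0("masked\t", as.integer(model$masked)),
    paste0("trained\t", as.integer(model$trained)),
    paste0("labels\t", paste(model$labels, collapse = "\t")),
    paste0("n_features\t", length(model$feature_names))
  ), con)
  writeLines(model$feature_names, con)
  writeLines(paste0("W\t", apply(model$W, 1, function(r)
    paste(num(r), collapse = "\t"))), con)
  writeLines(paste0("trans\t", apply(model$trans, 1, function(r)
    paste(num(r), collapse = "\t"))), con)
  writeLines(paste0("bos\t", paste(num(model$bos), collapse = "\t")), con)
  writeLines(paste0("eos\t", paste(num(model$eos), collapse = "\t")), con)
  invisible(path)
}

#' @rdname crf_save
#' @export
crf_load <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (lines[1L] != "ohctreat-crf v1") stop("unrecognized model file: ", path)
  kv <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1L]][-1L]
  l2_sigma <- as.numeric(kv(2L))
  masked <- as.integer(kv(3L)) == 1L
  trained <- as.integer(kv(4L)) == 1L
  labels <- kv(5L)
  n_feat <- as.integer(kv(6L))
  fnames <- if (n_feat > 0L) lines[6L + seq_len(n_feat)] else character(0)
  model <- crf_model(fnames, l2_sigma = l2_sigma, mask = masked,
                     labels = labels)
  pos <- 6L + n_feat
  L <- length(labels)
  parse_rows <- function(prefix, n) {
    rows <- lines[pos + seq_len(n)]
    pos <<- pos + n
    vals <- lapply(rows, function(r) {
      parts <- strsplit(r, "\t", fixed = TRUE)[[1L]]
      if (parts[1L] != prefix) stop("model file corrupt near '", r, "'")
      as.numeric(parts[-1L])
    })
    do.call(rbind, vals)
  }
  if (n_feat > 0L) {
    model$W <- parse_rows("W", n_feat)
    colnames(model$W) <- labels
  }
  model$trans <- parse_rows("trans", L)
  dimnames(model$trans) <- list(labels, labels)
  model$bos <- as.vector(parse_rows("bos", 1L))
  model$eos <- as.vector(parse_rows("eos", 1L))
  model$trained <- trained
  model
}
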