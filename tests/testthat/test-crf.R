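test_that("transition mask permits exactly the valid typed-BIO moves", {
  m <- crf_model(c("f1"), mask = TRUE)
  labs <- m$labels
  et <- ohctreat:::eff_trans(m)
  # I-c reachable only from B-c or I-c
  for (cl in attribution_labels()) {
    i_tag <- paste0("I-", cl)
    ok_from <- c(paste0("B-", cl), i_tag)
    for (from in labs) {
      if (from %in% ok_from) {
        expect_gt(et[from, i_tag], -1e20)
      } else {
        expect_lt(et[from, i_tag], -1e20)
      }
    }
  }
  # BOS cannot enter any I tag
  eb <- ohctreat:::eff_bos(m)
  expect_true(all(eb[grepl("^I-", labs)] < -1e20))
  expect_true(all(eb[!grepl("^I-", labs)] > -1e20))
})

test_that("score_sequence + log_partition reproduce the sequence probability", {
  set.seed(101)
  m <- random_small_model()
  feats <- random_feats(3)
  en <- crf_enumerate(m, feats)
  labs <- m$labels
  total <- 0
  for (a in labs) for (b in labs) for (c in labs) {
    total <- total + exp(score_sequence(m, feats, c(a, b, c)) - en$log_partition)
  }
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("forward-backward and Viterbi agree with enumeration on small inputs", {
  set.seed(77)
  for (r in 1:20) {
    m <- random_small_model(mask = r %% 2 == 0)
    feats <- random_feats(sample(1:4, 1))
    en <- crf_enumerate(m, feats)
    expect_equal(log_partition(m, feats), en$log_partition, tolerance = 1e-10)
    expect_equal(crf_marginals(m, feats), en$marginals, tolerance = 1e-10)
    vt <- crf_viterbi(m, feats)
    expect_identical(vt, en$best_tags)
    expect_equal(score_sequence(m, feats, vt), en$best_score,
                 tolerance = 1e-10)
  }
})

test_that("Viterbi breaks exact ties toward the lower label index", {
  # all-zero weights with the mask on: every valid sequence ties, and the
  # lowest-index choice at every step is O
  m <- crf_model(c("f1"), mask = TRUE)
  feats <- list("f1", "f1", "f1")
  expect_identical(crf_viterbi(m, feats), c("O", "O", "O"))
  # break the tie at position 1 only; O remains preferred downstream
  m$W[1, "B-pt"] <- 5
  expect_identical(crf_viterbi(m, list("f1")), "B-pt")
})

test_that("marginals are uniform over reachable labels for a zero unmasked model", {
  m <- crf_model(c("f1"), mask = FALSE)
  mg <- crf_marginals(m, list("f1", "f1"))
  expect_equal(as.vector(mg), rep(1 / 11, 22), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(5)
  gen <- generate_corpus(generator_config(n_authors = 3L, seed = 5L))
  sents <- corpus_sentences(gen$corpus, gen$gold,
                            gazetteers = list(treat = reference_gazetteer()))
  fnames <- unique(unlist(lapply(sents, function(s) {
    unlist(lapply(s$features, names))
  })))
  m <- crf_model(fnames, l2_sigma = 10)
  th <- ohctreat:::crf_parameters(m)
  th[] <- stats::rnorm(length(th)) * 0.1
  m <- ohctreat:::crf_set_parameters(m, th)
  g <- crf_nll_gradient(m, sents)
  eps <- 1e-5
  for (i in sample(length(th), 12)) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    fd <- (crf_nll_gradient(ohctreat:::crf_set_parameters(m, tp), sents)$value -
           crf_nll_gradient(ohctreat:::crf_set_parameters(m, tm), sents)$value) /
          (2 * eps)
    rel <- abs(fd - g$gradient[i]) / max(1, abs(fd), abs(g$gradient[i]))
    expect_lt(rel, 1e-5)
  }
})

test_that("training monotonically improves the objective and fits the data", {
  gen <- generate_corpus(generator_config(n_authors = 6L, seed = 8L,
                                          cue_ambiguity = 0))
  gz <- list(treat = reference_gazetteer())
  sents <- corpus_sentences(gen$corpus, gen$gold, gazetteers = gz)
  m <- crf_train(sents, max_iterations = 60L)
  trace <- attr(m, "objective_trace")
  expect_gt(length(trace), 2L)
  expect_lt(trace[length(trace)], trace[1])
  pred <- predict_spans(m, gen$corpus, gazetteers = gz)
  rep_ <- prf_report(gen$gold, pred, "five_class")
  expect_gt(rep_$micro$f1, 0.95)
})

test_that("training is deterministic given identical data and settings", {
  gen <- generate_corpus(generator_config(n_authors = 4L, seed = 13L))
  gz <- list(treat = reference_gazetteer())
  sents <- corpus_sentences(gen$corpus, gen$gold, gazetteers = gz)
  m1 <- crf_train(sents, max_iterations = 25L)
  m2 <- crf_train(sents, max_iterations = 25L)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$trans, m2$trans)
})

test_that("model serialization round trip is the identity", {
  set.seed(31)
  m <- random_small_model(paste0("feat:x=", 1:7))
  path <- withr::local_tempfile(fileext = ".crf")
  crf_save(m, path)
  back <- crf_load(path)
  expect_identical(back$feature_names, m$feature_names)
  expect_identical(back$labels, m$labels)
  expect_identical(back$W, m$W)
  expect_identical(back$trans, m$trans)
  expect_identical(back$bos, m$bos)
  expect_identical(back$eos, m$eos)
  expect_identical(back$l2_sigma, m$l2_sigma)
  # decoding behavior is identical too
  feats <- random_feats(4, m$feature_names)
  expect_identical(crf_viterbi(back, feats), crf_viterbi(m, feats))
  expect_error(crf_load(withr::local_tempfile(lines = "garbage")),
               "model file")
})
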