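test_that("dict_detect emits unlabeled spans from gazetteer hits", {
  gz <- gazetteer(c("cod liver oil", "melatonin"), "d")
  toks <- tokenize("we tried cod liver oil and melatonin today")
  sp <- dict_detect(toks, gz, "we tried cod liver oil and melatonin today")
  expect_identical(nrow(sp), 2L)
  expect_identical(sp$surface, c("cod liver oil", "melatonin"))
  expect_true(all(is.na(sp$label)))
  expect_identical(sp$char_start, c(9L, 27L))
})

test_that("span_features aggregates in-span and context features with prefixes", {
  s <- heuristic_annotate("We started probiotics last month.")[[1]]
  i_t <- which(s$tokens$surface == "probiotics")
  fv <- span_features(s, i_t - 1L, i_t)
  nm <- names(fv)
  expect_true(all(grepl("^(in:|ctx:L\\||ctx:R\\|)", nm)))
  expect_true(any(grepl("^in:lex:w0=probiotics$", nm)))
  expect_true(any(grepl("^ctx:L\\|lex:w0=started$", nm)))
  # sentence-initial span gets the BOS context marker
  fv0 <- span_features(s, 0L, 1L)
  expect_true("ctx:L|<BOS>" %in% names(fv0))
})

test_that("lasso classifier separates a separable toy problem", {
  texts <- c(pt = "My son is on %s now.",
             `pt-gen` = "The doctor suggested %s for my son.",
             gen = "There are many studies about %s online.")
  terms <- c("melatonin", "chelation", "probiotics", "zinc")
  fvs <- list(); ys <- character(0)
  for (cl in names(texts)) {
    for (tm in terms) {
      s <- heuristic_annotate(sprintf(texts[[cl]], tm))[[1]]
      i_t <- which(s$tokens$surface == tm)
      fvs[[length(fvs) + 1L]] <- span_features(s, i_t - 1L, i_t)
      ys <- c(ys, cl)
    }
  }
  lr <- lr_train(fvs, ys, l1_lambda = 0.001)
  expect_identical(lr_classify(lr, fvs), ys)
})

test_that("lr_classify breaks score ties toward the lower class index", {
  m <- lr_model(c("pt", "gen"), c("in:a"))
  expect_identical(lr_classify(m, c("in:a" = 1)), "pt")
  m$W[1, 2] <- 1
  expect_identical(lr_classify(m, c("in:a" = 1)), "gen")
})

test_that("lr serialization round trip is the identity", {
  set.seed(17)
  m <- lr_model(attribution_labels(), paste0("in:f", 1:6),
                intercepts = rnorm(5),
                W = matrix(rnorm(30), 6, 5,
                           dimnames = list(NULL, attribution_labels())),
                l1_lambda = 0.01)
  path <- withr::local_tempfile(fileext = ".lr")
  lr_save(m, path)
  back <- lr_load(path)
  expect_identical(back$classes, m$classes)
  expect_identical(back$feature_names, m$feature_names)
  expect_identical(back$intercepts, m$intercepts)
  expect_identical(unname(back$W), unname(m$W))
  expect_identical(back$l1_lambda, m$l1_lambda)
})

test_that("baseline+ uses CRF spans so mention-only scores match the CRF", {
  gen <- generate_corpus(generator_config(n_authors = 12L, seed = 19L))
  gz <- list(treat = reference_gazetteer())
  sents <- corpus_sentences(gen$corpus, gen$gold, gazetteers = gz)
  crf <- crf_train(sents, max_iterations = 40L)
  fvs <- list(); ys <- character(0)
  for (s in sents) {
    sp <- tags_to_spans(s$tokens, s$tags)
    for (k in seq_len(nrow(sp))) {
      fvs[[length(fvs) + 1L]] <- span_features(s$sentence, sp$token_start[k],
                                               sp$token_end[k],
                                               gazetteers = gz)
      ys <- c(ys, sp$label[k])
    }
  }
  lr <- lr_train(fvs, ys, l1_lambda = 0.01)
  p_crf <- predict_spans(crf, gen$corpus, gazetteers = gz)
  p_plus <- run_baseline_plus(gen$corpus, crf, lr, gazetteers = gz)
  expect_identical(p_plus$char_start, p_crf$char_start)
  expect_identical(p_plus$char_end, p_crf$char_end)
  m_crf <- prf_report(gen$gold, p_crf, "mention_only")
  m_plus <- prf_report(gen$gold, p_plus, "mention_only")
  expect_identical(m_crf$micro, m_plus$micro)
})
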