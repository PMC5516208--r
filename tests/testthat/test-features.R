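test_that("gazetteer normalizes terms and matches greedily leftmost-longest", {
  gz <- gazetteer(c("Cod  Liver Oil", "cod", "oil of oregano"), "g")
  expect_true("cod liver oil" %in% gz$terms)
  m <- gazetteer_match(c("we", "tried", "Cod", "Liver", "Oil", "today"), gz)
  expect_identical(m, c("O", "O", "B", "I", "I", "O"))
  # the unigram term still matches when the longer one cannot
  m2 <- gazetteer_match(c("plain", "cod", "today"), gz)
  expect_identical(m2, c("O", "B", "O"))
})

test_that("greedy matcher agrees with a brute-force reference", {
  gz <- reference_gazetteer()
  set.seed(41)
  vocab <- c(unlist(strsplit(sample(gz$terms, 40), " ")),
             c("we", "the", "again", "tried", "my", "son"))
  for (r in 1:25) {
    surfaces <- sample(vocab, sample(3:12, 1), replace = TRUE)
    expect_identical(gazetteer_match(surfaces, gz),
                     naive_gazetteer_match(surfaces, gz),
                     info = paste(surfaces, collapse = " "))
  }
})

test_that("every feature name carries its family prefix", {
  gz <- reference_gazetteer()
  s <- heuristic_annotate("My son is on melatonin now.")[[1]]
  for (i in seq_len(nrow(s$tokens))) {
    expect_true(all(grepl("^lex:", names(lexical_features(s, i)))))
    expect_true(all(grepl("^sem:",
                          names(semantic_features(s, i, list(treat = gz))))))
    expect_true(all(grepl("^syn:", names(syntactic_features(s, i)))))
  }
  both <- extract_all(s, gazetteers = list(treat = gz))
  expect_true(all(grepl("^(lex|sem|syn):", unlist(lapply(both, names)))))
  expect_length(both, nrow(s$tokens))
})

test_that("lexical window features use BOS/EOS padding at the edges", {
  s <- heuristic_annotate("We tried chelation.")[[1]]
  n <- nrow(s$tokens)
  expect_true("lex:w-1=<BOS>" %in% names(lexical_features(s, 1L)))
  expect_true("lex:w+1=<EOS>" %in% names(lexical_features(s, n)))
  # token identity feature present at every position
  for (i in seq_len(n)) {
    expect_true(any(grepl("^lex:w0=", names(lexical_features(s, i)))))
  }
  expect_error(lexical_features(s, n + 1L), "out of range")
})

test_that("semantic features expose gazetteer BIO flags in a +-1 window", {
  gz <- gazetteer("cod liver oil", "treat")
  s <- heuristic_annotate("We tried cod liver oil today.")[[1]]
  i_b <- which(s$tokens$surface == "cod")
  nm <- names(semantic_features(s, i_b, list(treat = gz)))
  expect_true("sem:treat0=B" %in% nm)
  expect_true("sem:treat+1=I" %in% nm)
  expect_true("sem:treat-1=O" %in% nm)
})

test_that("syntactic features encode subject/predicate lemmas and distances", {
  s <- heuristic_annotate("The doctor suggested chelation for my son.")[[1]]
  i_t <- which(s$tokens$surface == "chelation")
  nm <- names(syntactic_features(s, i_t))
  expect_true("syn:subj_word=doctor" %in% nm)
  expect_true("syn:pred_word=suggest" %in% nm)
  expect_true(any(grepl("^syn:dist_pred=", nm)))
  s2 <- heuristic_annotate("I take melatonin myself for stress.")[[1]]
  nm2 <- names(syntactic_features(s2, which(s2$tokens$surface == "melatonin")))
  expect_true("syn:subj_fp=1" %in% nm2)
})

test_that("first-person possessive noun-phrase subject flag fires", {
  s <- heuristic_annotate("My son is on melatonin now.")[[1]]
  i_t <- which(s$tokens$surface == "melatonin")
  expect_true("syn:subj_my_np=1" %in% names(syntactic_features(s, i_t)))
})

test_that("family selection controls exactly which features appear", {
  gz <- reference_gazetteer()
  s <- heuristic_annotate("We started probiotics last month.")[[1]]
  only_lex <- extract_all(s, families = "lexical",
                          gazetteers = list(treat = gz))
  expect_false(any(grepl("^(sem|syn):", unlist(lapply(only_lex, names)))))
  expect_error(extract_all(s, families = "phonological"), "famil")
})
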