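mk_spans <- function(post_id, starts, ends, labels) {
  data.frame(post_id = post_id, char_start = starts, char_end = ends,
             surface = "x", label = labels, stringsAsFactors = FALSE)
}

test_that("typed span matching requires exact boundaries and labels", {
  gold <- mk_spans("p", c(0L, 10L), c(5L, 15L), c("pt", "gen"))
  pred <- mk_spans("p", c(0L, 10L), c(5L, 14L), c("pt", "gen"))
  m <- match_spans(gold, pred, typed = TRUE)
  expect_identical(m$tp, 1L)
  expect_identical(m$fp, 1L)
  expect_identical(m$fn, 1L)
  # same boundaries, wrong label: no typed match, but an untyped one
  pred2 <- mk_spans("p", c(0L, 10L), c(5L, 15L), c("gen", "gen"))
  expect_identical(match_spans(gold, pred2, typed = TRUE)$tp, 1L)
  expect_identical(match_spans(gold, pred2, typed = FALSE)$tp, 2L)
})

test_that("hand-computed P/R/F fixtures are matched exactly", {
  # fixture: gold has 4 pt + 2 gen; system finds 3 pt correctly, 1 pt wrong
  # boundary (fp+fn), both gen correct, plus 1 spurious gen
  gold <- mk_spans("p", c(0, 10, 20, 30, 40, 50) * 1L,
                   c(5, 15, 25, 35, 45, 55) * 1L,
                   c("pt", "pt", "pt", "pt", "gen", "gen"))
  pred <- mk_spans("p", c(0, 10, 20, 31, 40, 50, 60) * 1L,
                   c(5, 15, 25, 35, 45, 55, 65) * 1L,
                   c("pt", "pt", "pt", "pt", "gen", "gen", "gen"))
  rep_ <- prf_report(gold, pred, "five_class")
  pt <- rep_$per_class[rep_$per_class$class == "pt", ]
  gen <- rep_$per_class[rep_$per_class$class == "gen", ]
  expect_identical(c(pt$tp, pt$fp, pt$fn), c(3L, 1L, 1L))
  expect_identical(pt$precision, 3 / 4)
  expect_identical(pt$recall, 3 / 4)
  expect_identical(pt$f1, 0.75)
  expect_identical(c(gen$tp, gen$fp, gen$fn), c(2L, 1L, 0L))
  expect_identical(gen$precision, 2 / 3)
  expect_identical(gen$recall, 1)
  expect_identical(gen$f1, 2 * (2 / 3) / (2 / 3 + 1))
  expect_identical(rep_$micro$precision, 5 / 7)
  expect_identical(rep_$micro$recall, 5 / 6)
  expect_identical(rep_$micro$f1, 2 * (5 / 7) * (5 / 6) / (5 / 7 + 5 / 6))
})

test_that("0/0 conventions give zero precision, recall, and F", {
  gold <- mk_spans("p", 0L, 5L, "pt")
  empty <- gold[0, ]
  r1 <- prf_report(gold, empty, "five_class")
  expect_identical(r1$micro$precision, 0)
  expect_identical(r1$micro$recall, 0)
  expect_identical(r1$micro$f1, 0)
  r2 <- prf_report(empty, empty, "five_class")
  expect_identical(r2$micro$f1, 0)
})

test_that("mention_only ignores labels; binary_pt merges non-pt labels", {
  gold <- mk_spans("p", c(0L, 10L), c(5L, 15L), c("pt", "gen"))
  pred <- mk_spans("p", c(0L, 10L), c(5L, 15L), c("gen", "others"))
  expect_identical(prf_report(gold, pred, "mention_only")$micro$f1, 1)
  rb <- prf_report(gold, pred, "binary_pt")
  # gold pt vs pred non-pt fails; gold non-pt vs pred non-pt matches
  expect_identical(rb$micro$precision, 1 / 2)
  expect_identical(binary_merge(c("pt", "gen", "cg", "others", "pt-gen")),
                   c("pt", "non-pt", "non-pt", "non-pt", "non-pt"))
})

test_that("predictions with overlapping spans are rejected", {
  gold <- mk_spans("p", 0L, 5L, "pt")
  bad <- mk_spans("p", c(0L, 3L), c(5L, 8L), c("pt", "pt"))
  expect_error(prf_report(gold, bad, "five_class"), "overlap")
})

test_that("Cohen's kappa matches the closed form on a 10-token fixture", {
  a <- c("O", "O", "B-pt", "I-pt", "O", "B-gen", "O", "O", "B-pt", "O")
  b <- c("O", "B-pt", "B-pt", "I-pt", "O", "B-gen", "O", "O", "O", "O")
  po <- 8 / 10
  pa <- table(factor(a, levels = unique(c(a, b)))) / 10
  pb <- table(factor(b, levels = unique(c(a, b)))) / 10
  pe <- sum(pa * pb)
  expect_equal(as.numeric(cohen_kappa(a, b)), (po - pe) / (1 - pe),
               tolerance = 1e-12)
  expect_identical(as.numeric(cohen_kappa(a, a)), 1)
})

test_that("degenerate kappa (chance agreement 1) returns 1 with a warning", {
  expect_warning(k <- cohen_kappa(rep("O", 5), rep("O", 5)), "degenerate")
  expect_identical(as.numeric(k), 1)
  expect_true(attr(k, "degenerate"))
  expect_error(cohen_kappa(c("O"), c("O", "O")), "differ")
})

test_that("annotation_token_labels projects spans onto heuristic tokens", {
  corp <- tiny_corpus()
  labs <- annotation_token_labels(corp, tiny_gold())
  expect_true(all(labs %in% c("O", attribution_labels())))
  expect_identical(sum(labs == "pt"), 2L)
  expect_identical(sum(labs != "O"), nrow(tiny_gold()))
})

test_that("ablation grid covers systems x families x regimes with micro rows", {
  gen <- generate_corpus(generator_config(n_authors = 14L, seed = 23L))
  gz <- reference_gazetteer()
  dict <- gazetteer(gz$terms[seq(1, length(gz$terms), 2)], "dict")
  res <- ablation_run(gen$corpus, gen$gold,
                      family_sets = list(lexical = "lexical"),
                      systems = c("crf", "baseline"),
                      regimes = c("mention_only", "five_class"),
                      dict_gaz = dict, gazetteers = list(treat = gz),
                      seed = 3L, max_iterations = 40L)
  expect_setequal(unique(res$system), c("crf", "baseline"))
  expect_setequal(unique(res$regime), c("mention_only", "five_class"))
  micro <- res[res$class == "micro", ]
  expect_identical(nrow(micro), 4L)
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
  # pooled micro counts equal the per-class sums
  for (r in seq_len(nrow(micro))) {
    sub <- res[res$system == micro$system[r] & res$regime == micro$regime[r] &
               res$class != "micro", ]
    expect_identical(micro$tp[r], sum(sub$tp))
    expect_identical(micro$fp[r], sum(sub$fp))
  }
})
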