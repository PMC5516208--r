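test_that("generator config validates its inputs", {
  expect_error(generator_config(class_mixture = c(pt = 0.5, gen = 0.4)),
               "mixture")
  expect_error(generator_config(n_authors = 0L))
  cfg <- generator_config(n_authors = 5L, seed = 1L)
  expect_s3_class(cfg, "generator_config")
})

test_that("generation is reproducible from the seed and changes with it", {
  g1 <- generate_corpus(generator_config(n_authors = 10L, seed = 4L))
  g2 <- generate_corpus(generator_config(n_authors = 10L, seed = 4L))
  expect_identical(g1$corpus$posts, g2$corpus$posts)
  expect_identical(g1$gold, g2$gold)
  g3 <- generate_corpus(generator_config(n_authors = 10L, seed = 5L))
  expect_false(identical(g1$corpus$posts$text, g3$corpus$posts$text))
})

test_that("generation preserves the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_corpus(generator_config(n_authors = 3L, seed = 9L)))
  expect_identical(.Random.seed, before)
})

test_that("gold spans index exactly their surfaces in the post text", {
  gen <- generate_corpus(generator_config(n_authors = 15L, seed = 6L))
  text <- gen$corpus$posts$text[match(gen$gold$post_id,
                                      gen$corpus$posts$post_id)]
  cut <- substr(text, gen$gold$char_start + 1L, gen$gold$char_end)
  expect_identical(cut, gen$gold$surface)
  expect_true(all(gen$gold$label %in% attribution_labels()))
  # every surface is a gazetteer term up to normalization
  expect_true(all(normalize_term(gen$gold$surface) %in%
                    reference_gazetteer()$terms))
})

test_that("class mixture and Zipf skew show up at scale", {
  gen <- generate_corpus(generator_config(n_authors = 150L, seed = 14L))
  tab <- table(gen$gold$label)
  # pt is the dominant mention class, cg the rarest (as configured)
  expect_identical(names(which.max(tab)), "pt")
  expect_identical(names(which.min(tab)), "cg")
  ft <- frequency_table(gen$gold, "all", Inf)
  # the head term dominates: at least 3x the 5th-ranked term
  expect_gt(ft$mention_count[1], 3 * ft$mention_count[5])
})

test_that("authors join at different times and post in order", {
  gen <- generate_corpus(generator_config(n_authors = 20L, seed = 16L))
  corp <- gen$corpus
  firsts <- vapply(corp$author_index, function(i) {
    as.numeric(min(corp$posts$timestamp[i]))
  }, 0)
  expect_gt(length(unique(firsts)), 10L)
  for (i in corp$author_index) {
    expect_true(!is.unsorted(as.numeric(corp$posts$timestamp[i])))
  }
})

test_that("typo corruption never touches gold surfaces and fixes offsets", {
  gen <- generate_corpus(generator_config(n_authors = 12L, seed = 18L))
  noisy <- corrupt_corpus(gen$corpus, gen$gold, typo_rate = 0.03, seed = 2L)
  expect_false(identical(noisy$corpus$posts$text, gen$corpus$posts$text))
  text <- noisy$corpus$posts$text[match(noisy$gold$post_id,
                                        noisy$corpus$posts$post_id)]
  cut <- substr(text, noisy$gold$char_start + 1L, noisy$gold$char_end)
  expect_identical(cut, noisy$gold$surface)
  expect_identical(noisy$gold$surface, gen$gold$surface)
  # zero rate is the identity
  clean <- corrupt_corpus(gen$corpus, gen$gold, typo_rate = 0, seed = 2L)
  expect_identical(clean$corpus$posts$text, gen$corpus$posts$text)
})

test_that("ambiguity knob controls how often ambiguous templates are drawn", {
  g0 <- generate_corpus(generator_config(n_authors = 60L, seed = 21L,
                                         cue_ambiguity = 0))
  g1 <- generate_corpus(generator_config(n_authors = 60L, seed = 21L,
                                         cue_ambiguity = 1))
  ambig <- read_templates()
  ambig <- unique(ambig$template[ambig$kind == "ambiguous"])
  has_ambig <- function(gen) {
    pats <- vapply(strsplit(ambig, "{TREATMENT}", fixed = TRUE),
                   function(p) trimws(p[1]), "")
    pats <- pats[nzchar(pats)]
    any(vapply(pats, function(p) {
      any(grepl(p, tolower(gen$corpus$posts$text), fixed = TRUE))
    }, TRUE))
  }
  expect_false(has_ambig(g0))
  expect_true(has_ambig(g1))
})
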