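test_that("normalize_term lowercases and collapses whitespace only", {
  expect_identical(normalize_term("  Cod   Liver Oil "), "cod liver oil")
  # no stemming: morphological variants stay distinct
  expect_false(normalize_term("chelation") == normalize_term("chelating"))
  expect_identical(normalize_term("B-12"), "b-12")
})

test_that("alias table folds variants during normalization", {
  aliases <- c("mb12" = "methyl b12", "methyl-b12" = "methyl b12")
  expect_identical(normalize_term("MB12", aliases), "methyl b12")
  expect_identical(normalize_term("zinc", aliases), "zinc")
})

test_that("catalogues keep only pt spans, keyed by author and term", {
  corp <- tiny_corpus()
  cat_ <- build_catalogues(corp, tiny_gold())
  # gold has 2 pt spans, both by alice, distinct terms
  expect_identical(nrow(cat_), 2L)
  expect_true(all(cat_$author_id == "alice"))
  expect_setequal(cat_$term, c("melatonin", "probiotics"))
  expect_true(all(cat_$mention_count == 1L))
  expect_s3_class(cat_$first_date, "POSIXct")
  expect_error(build_catalogues(corp, transform(tiny_gold(), post_id = "nope")),
               "unknown post")
})

test_that("catalogue counts conserve the number of pt spans", {
  gen <- generate_corpus(generator_config(n_authors = 25L, seed = 33L))
  cat_ <- build_catalogues(gen$corpus, gen$gold)
  expect_identical(sum(cat_$mention_count),
                   sum(gen$gold$label == "pt"))
})

test_that("user_count deduplicates repeat mentions within a user", {
  posts <- data.frame(
    post_id = sprintf("p%02d", 1:51),
    author_id = c(rep("heavy", 50), "light"),
    thread_id = "t1",
    timestamp = as.POSIXct("2009-01-01", tz = "UTC") + (1:51) * 3600,
    text = "We started melatonin today.",
    stringsAsFactors = FALSE
  )
  corp <- ohc_corpus(posts)
  spans <- data.frame(post_id = posts$post_id, char_start = 11L,
                      char_end = 20L, surface = "melatonin", label = "pt",
                      stringsAsFactors = FALSE)
  cat_ <- build_catalogues(corp, spans)
  uc <- user_count_table(cat_)
  expect_identical(uc$user_count[uc$term == "melatonin"], 2L)
  expect_identical(cat_$mention_count[cat_$author_id == "heavy"], 50L)
  # per-term user_count can never exceed mention totals
  ft <- frequency_table(spans, "pt")
  expect_true(all(uc$user_count <= ft$mention_count[match(uc$term, ft$term)]))
})

test_that("frequency tables filter by attribution and rank by count", {
  gold <- tiny_gold()
  all_tab <- frequency_table(gold, "all", top_k = 10L)
  expect_identical(sum(all_tab$mention_count), nrow(gold))
  expect_true(all(diff(all_tab$mention_count) <= 0))
  pt_tab <- frequency_table(gold, "pt")
  expect_identical(sum(pt_tab$mention_count), sum(gold$label == "pt"))
  expect_identical(frequency_table(gold, "cg")$term, "melatonin")
})

test_that("treatments-per-user histogram counts distinct terms per author", {
  corp <- tiny_corpus()
  h <- treatments_per_user_histogram(build_catalogues(corp, tiny_gold()))
  # alice has 2 distinct pt treatments; no other author has any
  expect_identical(h[["2"]], 1L)
  expect_identical(sum(h), 1L)
})

test_that("catalogue CSV export round trips", {
  cat_ <- build_catalogues(tiny_corpus(), tiny_gold())
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalogues(cat_, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$author_id, cat_$author_id)
  expect_identical(back$term, cat_$term)
  expect_identical(back$count, cat_$mention_count)
})
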