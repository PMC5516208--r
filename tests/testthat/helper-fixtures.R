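# Shared fixtures for the test suite. Everything here is deterministic.

# A small hand-made corpus: 2 authors, 4 posts, fixed UTC timestamps.
tiny_corpus <- function() {
  posts <- data.frame(
    post_id = c("p1", "p2", "p3", "p4"),
    author_id = c("alice", "alice", "bob", "alice"),
    thread_id = c("t1", "t1", "t2", "t2"),
    timestamp = as.POSIXct(
      c("2009-03-01 10:00:00", "2009-03-08 10:00:00",
        "2009-03-02 09:30:00", "2009-03-22 18:00:00"),
      tz = "UTC"
    ),
    text = c(
      "My son is on melatonin now. We had a rough night again.",
      "The doctor suggested chelation for my son.",
      "I take melatonin myself for stress.",
      "We started probiotics last month. Everyone keeps debating chelation here."
    ),
    stringsAsFactors = FALSE
  )
  ohc_corpus(posts)
}

# Gold spans for tiny_corpus(), hand-located char offsets (0-based half-open).
tiny_gold <- function() {
  data.frame(
    post_id = c("p1", "p2", "p3", "p4", "p4"),
    char_start = c(13L, 21L, 7L, 11L, 58L),
    char_end = c(22L, 30L, 16L, 21L, 67L),
    surface = c("melatonin", "chelation", "melatonin", "probiotics",
                "chelation"),
    label = c("pt", "pt-gen", "cg", "pt", "gen"),
    stringsAsFactors = FALSE
  )
}

# A fully random small CRF model over the typed-BIO alphabet.
random_small_model <- function(feature_names = paste0("f", 1:5),
                               mask = TRUE, sd = 1) {
  m <- crf_model(feature_names, mask = mask)
  L <- length(m$labels)
  m$W[] <- stats::rnorm(length(m$W), sd = sd)
  m$trans[] <- stats::rnorm(L * L, sd = sd)
  m$bos[] <- stats::rnorm(L, sd = sd)
  m$eos[] <- stats::rnorm(L, sd = sd)
  m
}

# Random per-token feature activations for a sentence of length T.
random_feats <- function(T, feature_names = paste0("f", 1:5)) {
  lapply(seq_len(T), function(i) {
    sample(feature_names, sample.int(length(feature_names) - 1L, 1L))
  })
}

# Brute-force reference for greedy leftmost-longest gazetteer matching.
naive_gazetteer_match <- function(surfaces, gaz) {
  lo <- tolower(surfaces)
  n <- length(lo)
  tags <- rep("O", n)
  max_len <- max(c(1L, lengths(strsplit(gaz$terms, " ", fixed = TRUE))))
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      cand <- paste(lo[i:(i + len - 1L)], collapse = " ")
      if (cand %in% gaz$terms) { hit_len <- len; break }
    }
    if (hit_len > 0L) {
      tags[i] <- "B"
      if (hit_len > 1L) tags[(i + 1L):(i + hit_len - 1L)] <- "I"
      i <- i + hit_len
    } else i <- i + 1L
  }
  tags
}

expect_same_spans <- function(a, b) {
  key <- function(s) {
    s <- s[order(s$post_id, s$char_start), , drop = FALSE]
    paste(s$post_id, s$char_start, s$char_end, s$label, sep = "|")
  }
  expect_identical(key(a), key(b))
}
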