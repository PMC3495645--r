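# corpus module: tokenization, schemes, BIO <-> segments, CoNLL I/O

test_that("tokenize detaches punctuation and keeps hyphenated terms", {
  expect_identical(tokenize("Irregular, flared metaphyses"),
                   c("Irregular", ",", "flared", "metaphyses"))
  expect_identical(tokenize("bone-in-bone appearance"),
                   c("bone-in-bone", "appearance"))
  expect_identical(tokenize("x"), "x")
  expect_identical(tokenize("coxa vara; 1st metatarsal (short)"),
                   c("coxa", "vara", ";", "1st", "metatarsal",
                     "(", "short", ")"))
  expect_error(tokenize("   "), "empty")
  expect_error(tokenize(""), "empty")
})

test_that("label schemes carry the expected inventories and continuations", {
  p1 <- label_scheme("phase1")
  expect_setequal(p1$labels, c("A-B", "A-I", "Q-B", "Q-I", "C-B", "C-I", "O"))
  pa <- label_scheme("phase2_anatomy")
  expect_setequal(pa$labels, c("A-B", "A-I", "AP-B", "AP-I", "PB",
                               "C-B", "C-I", "O"))
  pq <- label_scheme("phase2_quality")
  expect_setequal(pq$labels, c("Q-B", "Q-I", "QF-B", "QF-I", "C-B",
                               "C-I", "O"))
  # every X-I reachable only from X-B / X-I; PB has no continuation
  expect_identical(pa$continuation[["AP-I"]], c("AP-B", "AP-I"))
  expect_null(pa$continuation[["PB"]])
  expect_error(labeled_sequence(c("a", "b"), c("O", "A-I"), p1), "transition")
  expect_warning(
    s <- labeled_sequence(c("a", "b"), c("O", "A-I"), p1,
                          on_invalid = "repair"),
    "repaired")
  expect_identical(s$labels, c("O", "A-B"))
})

test_that("segments_from_bio joins maximal runs and handles coordinates", {
  p1 <- label_scheme("phase1")
  s <- labeled_sequence(c("streaky", "sclerosis"), c("Q-B", "Q-I"), p1)
  seg <- segments_from_bio(s)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$entity_class, "Q")
  expect_equal(c(seg$start, seg$end), c(0L, 2L))
  expect_equal(seg$text, "streaky sclerosis")

  expect_equal(nrow(segments_from_bio(
    labeled_sequence(c("in", "year"), c("O", "O"), p1))), 0L)

  s2 <- labeled_sequence(c("a", "b", "c", "d"),
                         c("A-B", "A-I", "C-B", "A-B"), p1)
  seg2 <- segments_from_bio(s2)
  expect_equal(seg2$entity_class, c("A", "C", "A"))
  expect_equal(seg2$start, c(0L, 2L, 3L))
  expect_equal(seg2$end, c(2L, 3L, 4L))

  pa <- label_scheme("phase2_anatomy")
  s3 <- labeled_sequence(c("proximal", "femur"), c("PB", "A-B"), pa)
  seg3 <- segments_from_bio(s3)
  expect_equal(seg3$entity_class, c("P", "A"))
  expect_equal(seg3$end - seg3$start, c(1L, 1L))
})

test_that("bio_from_segments inverts segments_from_bio", {
  expect_identical(bio_from_segments(NULL, 3L), c("O", "O", "O"))
  seg <- data.frame(entity_class = "Q", start = 0L, end = 2L)
  expect_identical(bio_from_segments(seg, 2L), c("Q-B", "Q-I"))
  bad <- data.frame(entity_class = c("A", "Q"), start = c(0L, 1L),
                    end = c(2L, 3L))
  expect_error(bio_from_segments(bad, 3L), "overlap")
  # property: round trip on random valid labelings of both phase schemes
  for (scheme in list(label_scheme("phase1"), label_scheme("phase2_anatomy"))) {
    set.seed(99)
    for (rep in 1:50) {
      n <- sample(1:8, 1L)
      labels <- bio_repair(sample(scheme$labels, n, replace = TRUE), scheme)
      s <- labeled_sequence(paste0("t", seq_len(n)), labels, scheme)
      expect_identical(bio_from_segments(segments_from_bio(s), n), labels)
    }
  }
})

test_that("corpus read/write round-trips byte-identically and validates", {
  corp <- small_corpus(n = 15L, seed = 3L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, f1)
  back <- read_corpus(f1, label_scheme("phase1"))
  expect_equal(length(back), length(corp))
  for (i in seq_along(corp$sequences)) {
    expect_identical(back$sequences[[i]]$tokens, corp$sequences[[i]]$tokens)
    expect_identical(back$sequences[[i]]$labels, corp$sequences[[i]]$labels)
  }
  write_corpus(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tZ-B", ""), bad)
  expect_error(read_corpus(bad, label_scheme("phase1")), "line 1")
  one <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metaphyses\tA-B", ""), one)
  cp <- read_corpus(one, label_scheme("phase1"))
  expect_equal(length(cp), 1L)
  expect_identical(cp$sequences[[1]]$tokens, "metaphyses")
})

test_that("the worked-example description round-trips through the format", {
  p1 <- label_scheme("phase1")
  s <- labeled_sequence(fig1_tokens, fig1_labels, p1, "fig1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(pheno_corpus(list(s), p1), f)
  back <- read_corpus(f, p1)
  expect_identical(back$sequences[[1]]$labels, fig1_labels)
  expect_identical(back$sequences[[1]]$description_id, "fig1")
})
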