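# synthetic module: generator determinism, calibration, phase II derivation

test_that("generation is deterministic and respects n", {
  cfg <- grammar_config(n_descriptions = 25L, seed = 3L)
  c1 <- generate_phase1(cfg)
  c2 <- generate_phase1(cfg)
  expect_equal(length(c1), 25L)
  for (i in seq_along(c1$sequences)) {
    expect_identical(c1$sequences[[i]]$tokens, c2$sequences[[i]]$tokens)
    expect_identical(c1$sequences[[i]]$labels, c2$sequences[[i]]$labels)
  }
  expect_equal(length(generate_phase1(grammar_config(0L))), 0L)
  expect_error(grammar_config(slot_probs = c(atomic = 1.4)), "\\[0, 1\\]")
})

test_that("generated corpora validate under their schemes", {
  corp <- small_corpus(n = 60L, seed = 14L)
  p1 <- label_scheme("phase1")
  for (s in corp$sequences) {
    expect_true(phenoseg:::bio_valid(s$labels, p1))
    expect_false(any(grepl("[[:space:]]", s$tokens)))
  }
  ph2 <- derive_phase2(corp)
  for (s in ph2$anatomy$sequences)
    expect_true(phenoseg:::bio_valid(s$labels, label_scheme("phase2_anatomy")))
  for (s in ph2$quality$sequences)
    expect_true(phenoseg:::bio_valid(s$labels, label_scheme("phase2_quality")))
})

test_that("forcing all optional slots yields the full template", {
  cfg <- grammar_config(n_descriptions = 1L, seed = 2L,
                        slot_probs = c(atomic = 0, qualifier = 1,
                                       second_quality = 1, part_form = 1,
                                       coordinate = 1, second_coordinate = 1,
                                       with_clause = 1, o_tail = 1,
                                       comma = 1))
  s <- generate_phase1(cfg)$sequences[[1]]
  cls <- label_class(s$labels)
  # qualifier+quality, comma, qualifier+quality, coordinate-conj-coordinate
  # part of-the main, with, qualifier+quality, O tail
  expect_identical(cls[1:5], c("Q", "Q", "O", "Q", "Q"))
  expect_true("C" %in% cls)            # the "with" connective
  expect_gte(sum(cls == "O"), 3L)      # comma plus the temporal tail
  fine <- attr(s, "fine_labels")
  expect_true(all(c("PB", "AP-B", "C-B", "A-B") %in% fine[cls == "A"]))
})

test_that("default calibration approximates the reference label shares", {
  corp <- cached("calib_corpus",
                 generate_phase1(grammar_config(n_descriptions = 1000L,
                                                seed = 7L)))
  cls <- unlist(lapply(corp$sequences, function(s) label_class(s$labels)))
  shareA <- 100 * mean(cls == "A")
  shareQ <- 100 * mean(cls == "Q")
  expect_lt(abs(shareA - 70.08), 5)
  expect_lt(abs(shareQ - 29.45), 5)
})

test_that("phase II derivation relabels and de-duplicates", {
  p1 <- label_scheme("phase1")
  mk <- function(id) {
    s <- labeled_sequence(c("short", "femur"), c("Q-B", "A-B"), p1, id)
    attr(s, "fine_labels") <- c("Q-B", "A-B")
    s
  }
  corp <- pheno_corpus(list(mk("d1"), mk("d2")), p1)
  ph2 <- derive_phase2(corp)
  expect_equal(length(ph2$anatomy), 1L)  # "femur" retained once
  expect_equal(length(ph2$quality), 1L)  # "short" retained once

  # fine structure of a full anatomical phrase
  toks <- c("proximal", "metaphyses", "of", "the", "long", "bones")
  s <- labeled_sequence(toks, rep(c("A-B", "A-I"), c(1, 5)), p1, "a1")
  attr(s, "fine_labels") <- c("PB", "AP-B", "C-B", "C-I", "A-B", "A-I")
  ph2b <- derive_phase2(pheno_corpus(list(s), p1))
  seq_a <- ph2b$anatomy$sequences[[1]]
  segs <- segments_from_bio(seq_a)
  expect_identical(segs$text[segs$entity_class == "P"], "proximal")
  expect_identical(segs$text[segs$entity_class == "AP"], "metaphyses")
  expect_identical(segs$text[segs$entity_class == "C"], "of the")
  expect_identical(segs$text[segs$entity_class == "A"], "long bones")

  expect_equal(length(derive_phase2(pheno_corpus(list(), p1))$anatomy), 0L)
  # corpora without bookkeeping are rejected
  bare <- pheno_corpus(list(labeled_sequence("femur", "A-B", p1, "x")), p1)
  expect_error(derive_phase2(bare), "bookkeeping")
})

test_that("fixture writer emits corpora, gazetteers and lexicon", {
  d <- withr::local_tempdir()
  write_synthetic_fixtures(d, grammar_config(n_descriptions = 8L, seed = 1L))
  expect_true(all(file.exists(file.path(d,
    c("phase1.tsv", "anatomy.tsv", "quality.tsv", "anatomy.txt",
      "qualities.txt", "lexicon.tsv")))))
  back <- read_corpus(file.path(d, "phase1.tsv"), label_scheme("phase1"))
  expect_equal(length(back), 8L)
  res <- load_resources(d)
  expect_gt(length(res$gazetteers$anatomy$terms), 10L)
})
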