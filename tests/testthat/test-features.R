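# features module: orthographic maps, contexts, dictionary features,
# inventory composition

test_that("token shape, brief shape, vowel and digit patterns", {
  expect_identical(token_shape("metaphyses"), "aaaaaaaaaa")
  expect_identical(token_shape("FGFR3"), "AAAA0")
  expect_identical(token_shape("-"), "-")
  expect_identical(brief_shape("metaphyses"), "a")
  expect_identical(brief_shape("FGFR3"), "A0")
  expect_identical(brief_shape(""), "")
  expect_identical(vowel_pattern("metaphyses"), "-e-a----e-")
  expect_identical(vowel_pattern("aeiou"), "aeiou")
  expect_identical(vowel_pattern("xyz"), "---")  # y is not a vowel
  expect_identical(digit_pattern("metaphyses"), "no")
  expect_identical(digit_pattern("T2"), "T*")
  expect_identical(digit_pattern("123"), "***")
  expect_identical(punct_flag("metaphyses"), "no")
  expect_identical(punct_flag("vara."), "punct")
  expect_identical(punct_flag(","), "punct")
  # shape and vowel pattern preserve token length
  for (t in c("metaphyses", "FGFR3", "bone-in-bone", "1st")) {
    expect_equal(nchar(token_shape(t)), nchar(t))
    expect_equal(nchar(vowel_pattern(t)), nchar(t))
    expect_lte(nchar(brief_shape(t)), nchar(token_shape(t)))
  }
})

test_that("affixes grow by length and truncate on short tokens", {
  a <- affixes("metaphyses", 5)
  expect_identical(a$prefix, c("m", "me", "met", "meta", "metap"))
  expect_identical(a$suffix, c("s", "es", "ses", "yses", "hyses"))
  ab <- affixes("ab", 5)
  expect_identical(ab$prefix, c("a", "ab"))
  expect_identical(ab$suffix, c("b", "ab"))
})

test_that("n-gram contexts pad with @ and have the stated cardinalities", {
  expect_identical(ngram_context(fig1_tokens, 2, 1, 3),
                   c("@", "irregular", "flared", "metaphyses", "of", "the",
                     "long"))
  expect_identical(ngram_context(c("flared", "metaphyses", "of"), 1, 2, 1),
                   c("flared-metaphyses", "metaphyses-of"))
  expect_identical(ngram_context("x", 0, 1, 1), c("@", "x", "@"))
  # |unigram| = 2w+1; |ngram| = 2w+2-n
  for (w in 1:3) for (n in 1:3) {
    ctx <- ngram_context(fig1_tokens, 4, n, w)
    expect_length(ctx, 2 * w + 2 - n)
  }
  # edge positions pad for n >= 2 as well
  expect_identical(ngram_context(fig1_tokens, 0, 2, 1),
                   c("@-irregular", "irregular-flared"))
})

test_that("dictionary contexts mirror n-gram structure over flags", {
  gq <- gazetteer(c("irregular", "flared", "streaky", "sclerosis"),
                  "qualities")
  lex <- fixture_resources$lexicon
  expect_identical(dict_context(fig1_tokens, 2, 3, gq, 1),
                   c("no", "qual", "qual", "no", "no", "no", "no"))
  # base lookup: "flared" only hits through its base "flare"
  gb <- gazetteer(c("irregular", "flare"), "qualities")
  expect_identical(dict_context(fig1_tokens, 2, 3, gb, 1, use_bases = TRUE,
                                lexicon = lex),
                   c("no", "qual", "qual", "no", "no", "no", "no"))
  g0 <- gazetteer(character(), "qualities")
  expect_identical(dict_context(fig1_tokens, 2, 3, g0, 1),
                   rep("no", 7))
  bi <- dict_context(fig1_tokens, 2, 1, gq, 2)
  expect_length(bi, 2)
  expect_true(all(grepl("^(no|qual)-(no|qual)$", bi)))
})

test_that("extract_features yields the full inventory and ablates cleanly", {
  full <- feature_config(window = 3, affix_size = 5)
  fv <- extract_features(fig1_tokens, 2, full, fixture_resources)
  expect_identical(fv$token, "metaphyses")
  expect_identical(fv$base, "metaphysis")
  expect_identical(fv$category, "noun")
  expect_identical(fv$uni.base,
                   c("@", "irregular", "flare", "metaphysis", "of", "the",
                     "long"))
  # ablation removes exactly the 2 domain-dictionary features + 9 combined
  noDom <- feature_config(window = 3, affix_size = 5,
                          use_domain_dicts = FALSE)
  fv2 <- extract_features(fig1_tokens, 2, noDom, fixture_resources)
  gone <- setdiff(names(fv), names(fv2))
  expect_setequal(gone,
                  c("dict.anatomy", "dict.qualities", "base.anat",
                    "base.qual", "uni.anat", "uni.qual", "bi.anat",
                    "bi.qual", "uni.base", "uni.base.anat", "uni.base.qual"))
  for (nm in names(fv2)) expect_identical(fv2[[nm]], fv[[nm]])
  # coordinates/ordinals flags drop for the quality-task configuration
  noCoord <- feature_config(3, 5, use_domain_dicts = FALSE,
                            use_coord_ord_dicts = FALSE)
  fv3 <- extract_features(fig1_tokens, 2, noCoord, fixture_resources)
  expect_setequal(setdiff(names(fv2), names(fv3)),
                  c("dict.coordinates", "dict.ordinals"))
})

test_that("feature extraction is deterministic and position-local", {
  cfg <- feature_config(2, 4)
  a <- extract_features(fig1_tokens, 3, cfg, fixture_resources)
  b <- extract_features(fig1_tokens, 3, cfg, fixture_resources)
  expect_identical(a, b)
  # appending tokens beyond the window changes nothing at position 0
  w1 <- extract_features(fig1_tokens[1:4], 0, feature_config(1, 3),
                         fixture_resources)
  w2 <- extract_features(c(fig1_tokens[1:4], "extra", "tokens"), 0,
                         feature_config(1, 3), fixture_resources)
  expect_identical(w1, w2)
})

test_that("feature strings serialize positionally for the learners", {
  strs <- phenoseg:::featurize_strings(fig1_tokens, feature_config(2, 3),
                                       fixture_resources)
  expect_length(strs, length(fig1_tokens))
  expect_true("token=metaphyses" %in% strs[[3]])
  expect_true("uni[-1]=flared" %in% strs[[3]])
  expect_true(any(grepl("^suffix\\[3\\]=ses$", strs[[3]])))
  # short tokens omit unavailable affixes instead of duplicating
  strs2 <- phenoseg:::featurize_strings("ab", feature_config(1, 5),
                                        fixture_resources)
  expect_false(any(grepl("^prefix\\[3\\]", strs2[[1]])))
})
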