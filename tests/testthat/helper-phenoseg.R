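# Shared fixtures: the worked-example token stream, fixture resources, a
# small separable training corpus, and lazily trained small models reused
# across test files.

fig1_tokens <- c("irregular", "flared", "metaphyses", "of", "the", "long",
                 "bones", "with", "streaky", "sclerosis")
fig1_labels <- c("Q-B", "Q-B", "A-B", "A-I", "A-I", "A-I", "A-I", "C-B",
                 "Q-B", "Q-I")

fixture_resources <- synthetic_resources()

small_corpus <- function(n = 50L, seed = 1L) {
  generate_phase1(grammar_config(n_descriptions = n, seed = seed))
}

# random single-labeler-style assignment set over n positions
random_assignments <- function(n, labels = label_scheme("phase1")$labels) {
  assignment_set(seq_len(n) - 1L, sample(labels, n, replace = TRUE))
}

# lazy caches so expensive fixtures are built once per test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

trained_small_crf <- function() {
  cached("crf_small", train_labeler(
    small_corpus(), labeler_config("crf_a", feature_config(2, 4), seed = 1L),
    fixture_resources))
}

# a small trained four-member phase 1 ensemble plus held-out corpus
small_ensemble <- function() {
  cached("ens_small", {
    # connective/outside slots boosted so the rare C and O classes carry
    # enough training signal at this small corpus size
    corp <- generate_phase1(grammar_config(
      n_descriptions = 150, seed = 11,
      slot_probs = c(with_clause = 0.3, o_tail = 0.02, comma = 0.05,
                     second_quality = 0.4)))
    cfgs <- make_default_ensemble("1", seed = 11)
    members <- lapply(cfgs, function(cf)
      train_labeler(corp, cf, fixture_resources))
    list(corpus = corp, members = members)
  })
}

# trained phase II models over the small corpus
small_phase2_models <- function() {
  cached("ph2_small", {
    corp <- small_ensemble()$corpus
    ph2 <- derive_phase2(corp)
    lapply(list(anatomy = ph2$anatomy, quality = ph2$quality), function(cp) {
      cfg <- labeler_config("crf_a",
                            feature_config(2, 4, use_domain_dicts = FALSE),
                            seed = 5L)
      train_labeler(cp, cfg, fixture_resources)
    })
  })
}
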