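# ensemble module: set operations, majority voting with veto, dispatch

test_that("union and intersection follow set semantics on pairs", {
  a <- assignment_set(0L, "Q-B")
  b <- assignment_set(0L, "A-B")
  u <- union_assignments(a, b)
  expect_equal(nrow(u), 2L)  # one position may carry two labels
  expect_setequal(u$label, c("Q-B", "A-B"))
  expect_identical(union_assignments(a, a), a)

  x <- assignment_set(c(0L, 1L), c("Q-B", "A-B"))
  y <- assignment_set(c(0L, 1L), c("Q-B", "A-I"))
  i <- intersect_assignments(x, y)
  expect_identical(i, assignment_set(0L, "Q-B"))
  expect_identical(intersect_assignments(x, x), x)
})

test_that("combined aggregation is intersection of bracket unions", {
  a <- assignment_set(0L, "Q-B"); b <- assignment_set(0L, "A-B")
  expect_identical(combined_assignments(a, a, a, a), a)
  cc <- combined_assignments(a, b, a, b)
  expect_equal(nrow(cc), 2L)  # both brackets contain both labels
  # and result is contained in union(a, b)
  expect_true(all(phenoseg:::as_pairs(cc) %in%
                  phenoseg:::as_pairs(union_assignments(a, b))))
})

test_that("set-operation laws hold on random assignment pairs", {
  set.seed(10)
  for (rep in 1:200) {
    n <- sample(1:12, 1)
    a <- random_assignments(n)
    b <- random_assignments(n)
    u <- union_assignments(a, b)
    i <- intersect_assignments(a, b)
    expect_identical(u, union_assignments(b, a))
    expect_identical(i, intersect_assignments(b, a))
    expect_gte(nrow(u), max(nrow(a), nrow(b)))
    pu <- phenoseg:::as_pairs(u); pi <- phenoseg:::as_pairs(i)
    pa <- phenoseg:::as_pairs(a); pb <- phenoseg:::as_pairs(b)
    expect_true(all(pa %in% pu) && all(pb %in% pu))
    expect_true(all(pi %in% pa) && all(pi %in% pb))
  }
})

test_that("majority_vote implements the four consensus rules", {
  # three-way (or better) agreement wins regardless of veto
  expect_identical(majority_vote(c("Q-B", "Q-B", "Q-B", "A-B"), "A-B"), "Q-B")
  expect_identical(majority_vote(rep("A-I", 4), "A-I"), "A-I")
  # two agree, other two mutually contradict -> the pair's label
  expect_identical(majority_vote(c("Q-B", "Q-B", "A-B", "O"), "O"), "Q-B")
  # 2-2 tie -> veto owner's vote
  expect_identical(majority_vote(c("Q-B", "Q-B", "A-B", "A-B"), "A-B"), "A-B")
  expect_identical(majority_vote(c("Q-B", "Q-B", "A-B", "A-B"), "Q-B"), "Q-B")
  # all four distinct -> veto owner's vote
  expect_identical(majority_vote(c("Q-B", "A-B", "O", "C-B"), "A-B"), "A-B")
})

test_that("majority_vote is permutation-invariant except through the veto", {
  set.seed(11)
  labels <- label_scheme("phase1")$labels
  for (rep in 1:100) {
    votes <- sample(labels, 4, replace = TRUE)
    veto <- sample(votes, 1)
    r0 <- majority_vote(votes, veto)
    for (p in 1:3)
      expect_identical(majority_vote(sample(votes), veto), r0)
  }
})

test_that("aggregation specs validate and dispatch correctly", {
  expect_error(aggregation_spec("voting", members = c("crf_a", "crf_b")),
               "4 members")
  expect_error(aggregation_spec("voting", veto_owner = "nope"),
               "veto_owner")
  expect_error(aggregation_spec("combined",
                                brackets = list(c("crf_a", "crf_b"),
                                                c("crf_a", "svm_1vs1"))),
               "partition")

  a <- assignment_set(0:1, c("Q-B", "Q-I"))
  sets <- list(crf_a = a, crf_b = a, svm_1vs1 = a, svm_1vsall = a)
  expect_identical(
    aggregate_assignments(aggregation_spec("single", members = "crf_a"),
                          sets), a)
  expect_identical(
    aggregate_assignments(aggregation_spec("voting"), sets), a)
  expect_identical(
    aggregate_assignments(aggregation_spec("combined"), sets), a)
  b <- assignment_set(0:1, c("A-B", "A-I"))
  sets2 <- list(crf_a = a, crf_b = b, svm_1vs1 = a, svm_1vsall = b)
  uu <- aggregate_assignments(
    aggregation_spec("union_pair", members = c("crf_a", "crf_b")), sets2)
  expect_equal(nrow(uu), 4L)
  ii <- aggregate_assignments(
    aggregation_spec("intersection_pair", members = c("crf_a", "crf_b")),
    sets2)
  expect_equal(nrow(ii), 0L)
  # voting resolves the 2-2 tie by the veto owner's own vote
  vv <- aggregate_assignments(
    aggregation_spec("voting", veto_owner = "crf_b"), sets2)
  expect_identical(vv$label, b$label)
})
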