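# Aggregation of labeler outputs: set operations on (position, label)
# assignment pairs, and simple majority voting with a veto owner.

#' Construct an assignment set
#'
#' The common currency of single labelers, set operations, voting and
#' scoring: a set of `(position, label)` pairs for one sequence. A single
#' labeler's output has exactly one pair per position; set operations may
#' leave 0-2 pairs per position.
#'
#' @param pos Integer vector of 0-based token positions.
#' @param label Character vector of labels, same length as `pos`.
#' @return An `assignment_set`: data frame with columns `pos` and `label`,
#'   unique pairs, sorted by position then label.
#' @export
assignment_set <- function(pos, label) {
  stopifnot(length(pos) == length(label))
  df <- data.frame(pos = as.integer(pos), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$pos < 0L)) stop("assignment_set(): negative position",
                               call. = FALSE)
    df <- unique(df)
    df <- df[order(df$pos, df$label), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("assignment_set", "data.frame")
  df
}

as_pairs <- function(a) paste(a$pos, a$label, sep = "\r")

#' Union of two assignment sets
#'
#' Assumes both inputs correct: keeps every `(position, label)` pair from
#' either, so a position may carry two labels.
#'
#' @param a,b [assignment_set()]s.
#' @return An [assignment_set()].
#' @export
union_assignments <- function(a, b) {
  assignment_set(c(a$pos, b$pos), c(a$label, b$label))
}

#' Intersection of two assignment sets
#'
#' Keeps only the pairs present in both inputs; positions of disagreement
#' carry no label.
#'
#' @inheritParams union_assignments
#' @return An [assignment_set()].
#' @export
intersect_assignments <- function(a, b) {
  keep <- as_pairs(a) %in% as_pairs(b)
  assignment_set(a$pos[keep], a$label[keep])
}

#' Combined (bracketed) aggregation of four assignment sets
#'
#' `intersection(union(a, b), union(c, d))`: the union in each bracket
#' gathers the positives of its two members, the final intersection prunes
#' pairs only one bracket believes in.
#'
#' @param a,b,c,d [assignment_set()]s.
#' @return An [assignment_set()].
#' @export
combined_assignments <- function(a, b, c, d) {
  intersect_assignments(union_assignments(a, b), union_assignments(c, d))
}

#' Simple majority vote over four labels with veto
#'
#' Decision rule for one token position: if at least three of the four
#' votes agree, return that label; if exactly two agree and the remaining
#' two contradict each other, return the pair's label; on a 2-2 tie between
#' two distinct pairs, or when all four votes differ, return the veto
#' owner's own vote.
#'
#' @param votes Character vector of exactly 4 labels.
#' @param veto_label The veto owner's own vote (one of `votes`).
#' @return A single label.
#' @export
#' @examples
#' majority_vote(c("Q-B", "Q-B", "A-B", "O"), veto_label = "O")   # "Q-B"
#' majority_vote(c("Q-B", "Q-B", "A-B", "A-B"), veto_label = "A-B")
majority_vote <- function(votes, veto_label) {
  stopifnot(length(votes) == 4L)
  counts <- table(votes)
  top <- max(counts)
  if (top >= 3L) return(names(counts)[which.max(counts)])
  if (top == 2L) {
    pairs <- names(counts)[counts == 2L]
    if (length(pairs) == 1L) return(pairs)  # 2 agree, other 2 contradict
    return(veto_label)                      # 2-2 tie
  }
  veto_label                                # all four distinct
}

#' Specification of an aggregation strategy
#'
#' @param strategy One of `"single"`, `"union_pair"`,
#'   `"intersection_pair"`, `"combined"`, `"voting"`.
#' @param members Ordered character vector of labeler ids the strategy
#'   consumes: 1 for `single`, 2 for the paired set operations, 4 for
#'   `combined` and `voting`.
#' @param veto_owner For `voting`: the labeler id holding the veto; must be
#'   a member.
#' @param brackets For `combined`: list of two character vectors
#'   partitioning the four members into the two union brackets. Default
#'   pairs each chunker with a different global model.
#' @return An `aggregation_spec`.
#' @export
aggregation_spec <- function(strategy = c("single", "union_pair",
                                          "intersection_pair", "combined",
                                          "voting"),
                             members = LABELER_IDS,
                             veto_owner = "svm_1vsall",
                             brackets = list(c("crf_a", "svm_1vsall"),
                                             c("crf_b", "svm_1vs1"))) {
  strategy <- match.arg(strategy)
  need <- switch(strategy, single = 1L, union_pair = 2L,
                 intersection_pair = 2L, 4L)
  if (length(members) != need)
    stop("aggregation_spec(): strategy '", strategy, "' needs ", need,
         " members", call. = FALSE)
  if (strategy == "voting" && !(veto_owner %in% members))
    stop("aggregation_spec(): veto_owner must be a member", call. = FALSE)
  if (strategy == "combined") {
    flat <- sort(unlist(brackets))
    if (length(brackets) != 2L || !identical(flat, sort(members)))
      stop("aggregation_spec(): brackets must partition the 4 members",
           call. = FALSE)
  }
  structure(list(strategy = strategy, members = members,
                 veto_owner = veto_owner, brackets = brackets),
            class = "aggregation_spec")
}

# voting over full single-labeler outputs: each set must have exactly one
# label per position and identical position coverage
vote_sets <- function(sets, veto_idx) {
  pos <- sets[[1L]]$pos
  for (s in sets) {
    if (!identical(s$pos, pos))
      stop("voting requires one label per position from every member",
           call. = FALSE)
  }
  labs <- vapply(seq_along(pos), function(i) {
    votes <- vapply(sets, function(s) s$label[i], "")
    majority_vote(votes, veto_label = votes[veto_idx])
  }, "")
  assignment_set(pos, labs)
}

#' Aggregate per-labeler assignment sets under a strategy
#'
#' @param spec An [aggregation_spec()].
#' @param sets Named list of [assignment_set()]s, one per labeler id named
#'   in `spec$members`.
#' @return An [assignment_set()]. Voting (like a single labeler) yields
#'   exactly one label per position; set operations may yield 0-2.
#' @export
aggregate_assignments <- function(spec, sets) {
  stopifnot(inherits(spec, "aggregation_spec"))
  missing <- setdiff(spec$members, names(sets))
  if (length(missing))
    stop("aggregate_assignments(): missing member outputs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- sets[spec$members]
  switch(spec$strategy,
    single = m[[1L]],
    union_pair = union_assignments(m[[1L]], m[[2L]]),
    intersection_pair = intersect_assignments(m[[1L]], m[[2L]]),
    combined = {
      b <- spec$brackets
      combined_assignments(sets[[b[[1L]][1L]]], sets[[b[[1L]][2L]]],
                           sets[[b[[2L]][1L]]], sets[[b[[2L]][2L]]])
    },
    voting = vote_sets(m, match(spec$veto_owner, spec$members))
  )
}
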