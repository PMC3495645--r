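# Token-assignment-level precision/recall/F1 (micro and per label) and
# stratified k-fold cross-validation of aggregation strategies.

f1_of <- function(p, r) ifelse(p + r == 0, 0, 2 * p * r / (p + r))

#' Score predicted assignments against gold
#'
#' `correct = |pred intersect gold|`; micro precision = correct / |pred|,
#' micro recall = correct / |gold|, both in percent; per-label figures
#' restrict both sets to that label. For one-label-per-position predictions
#' (single labelers, voting) |pred| = |gold|, hence micro P = R = F
#' exactly; unions/intersections break that symmetry.
#'
#' @param pred,gold [assignment_set()]s for the same sequence (or pooled
#'   over many sequences with disjoint position spaces).
#' @return A `seg_metrics` object: list with `micro` (named vector
#'   `precision`, `recall`, `f1`, percentages) and `per_label` (data frame
#'   with `label`, `precision`, `recall`, `f1`, `support`).
#' @export
score_assignments <- function(pred, gold) {
  if (nrow(gold) == 0L)
    warning("score_assignments(): empty gold standard; recall reported as 0",
            call. = FALSE)
  correct_pairs <- as_pairs(pred) %in% as_pairs(gold)
  n_correct <- sum(correct_pairs)
  p <- if (nrow(pred)) 100 * n_correct / nrow(pred) else 0
  r <- if (nrow(gold)) 100 * n_correct / nrow(gold) else 0
  labels <- sort(unique(c(pred$label, gold$label)))
  per <- do.call(rbind, lapply(labels, function(l) {
    np <- sum(pred$label == l)
    ng <- sum(gold$label == l)
    nc <- sum(correct_pairs & pred$label == l)
    pl <- if (np) 100 * nc / np else 0
    rl <- if (ng) 100 * nc / ng else 0
    data.frame(label = l, precision = pl, recall = rl,
               f1 = f1_of(pl, rl), support = ng, stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(label = character(), precision = numeric(),
                      recall = numeric(), f1 = numeric(),
                      support = integer(), stringsAsFactors = FALSE)
  structure(list(micro = c(precision = p, recall = r, f1 = f1_of(p, r)),
                 per_label = per),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("micro P %.2f%%  R %.2f%%  F1 %.2f%%\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  print(x$per_label, row.names = FALSE)
  invisible(x)
}

# label-category (A/Q/C/AP/QF/P/O) proportions of one sequence
category_props <- function(seq, categories) {
  cl <- label_class(seq$labels)
  tab <- table(factor(cl, levels = categories))
  as.numeric(tab) / length(cl)
}

#' Stratified fold assignment
#'
#' Greedy balancer: descriptions are sorted by length (largest first, ties
#' shuffled under `seed`) and each is assigned to the fold, among those
#' with remaining capacity, that minimizes the L1 divergence between the
#' fold's label-category proportions and the corpus-level proportions.
#' Fold sizes differ by at most one. Deterministic given `seed`.
#'
#' @param corpus A [pheno_corpus()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `k`, `seed` and `assignments` (named
#'   integer vector, description_id -> fold in 1..k).
#' @export
stratified_folds <- function(corpus, k = 10L, seed = 1L) {
  n <- length(corpus$sequences)
  if (k > n)
    stop("stratified_folds(): k exceeds corpus size", call. = FALSE)
  categories <- unique(label_class(corpus$scheme$labels))
  props <- t(vapply(corpus$sequences, category_props,
                    numeric(length(categories)), categories = categories))
  weights <- vapply(corpus$sequences, function(s) length(s$tokens), 0L)
  target <- colSums(props * weights) / sum(weights)
  ord <- with_seed(seed, {
    jitter_order <- sample.int(n)
    jitter_order[order(-weights[jitter_order])]
  })
  cap <- rep(floor(n / k), k)
  extra <- n %% k
  if (extra > 0L) cap[seq_len(extra)] <- cap[seq_len(extra)] + 1L
  fold_tok <- rep(0, k)
  fold_cat <- matrix(0, k, length(categories))
  sizes <- rep(0L, k)
  fold_of <- integer(n)
  for (i in ord) {
    # folds fill in lock-step (only minimum-size folds are candidates), so
    # runs of similar descriptions spread across folds instead of pooling
    # in whichever fold still has capacity; within the round, pick the fold
    # whose category proportions the description improves most
    open <- which(sizes < cap)
    open <- open[sizes[open] == min(sizes[open])]
    div <- vapply(open, function(f) {
      newcat <- fold_cat[f, ] + props[i, ] * weights[i]
      newtok <- fold_tok[f] + weights[i]
      old <- if (fold_tok[f] > 0)
        sum(abs(fold_cat[f, ] / fold_tok[f] - target)) else 0
      sum(abs(newcat / newtok - target)) - old
    }, 0)
    f <- open[which.min(div)]
    fold_of[i] <- f
    sizes[f] <- sizes[f] + 1L
    fold_tok[f] <- fold_tok[f] + weights[i]
    fold_cat[f, ] <- fold_cat[f, ] + props[i, ] * weights[i]
  }
  ids <- vapply(corpus$sequences, `[[`, "", "description_id")
  names(fold_of) <- ids
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignments = fold_of),
            class = "fold_plan")
}

# gold assignment set of a corpus slice, with positions offset so that
# sequences occupy disjoint position ranges when pooled
pooled_gold <- function(sequences) {
  off <- 0L
  pos <- integer(); lab <- character()
  for (s in sequences) {
    pos <- c(pos, off + seq_along(s$labels) - 1L)
    lab <- c(lab, s$labels)
    off <- off + length(s$labels)
  }
  assignment_set(pos, lab)
}

#' Score a trained labeler on a corpus
#'
#' Predicts every sequence, pools predictions and gold over disjoint
#' position ranges, and scores them.
#'
#' @param labeler A `trained_labeler`.
#' @param corpus A [pheno_corpus()] under the labeler's scheme.
#' @param resources A [seg_resources()].
#' @return A [score_assignments()] result.
#' @export
evaluate_labeler <- function(labeler, corpus, resources) {
  off <- 0L
  pos <- integer(); lab <- character()
  for (s in corpus$sequences) {
    a <- predict_labeler(labeler, s$tokens, resources)
    pos <- c(pos, a$pos + off)
    lab <- c(lab, a$label)
    off <- off + length(s$tokens)
  }
  score_assignments(assignment_set(pos, lab), pooled_gold(corpus$sequences))
}

#' Cross-validate an aggregation strategy
#'
#' For each fold: train every ensemble member on the out-of-fold
#' descriptions, predict the in-fold ones, aggregate the member outputs
#' under `agg_spec`, and score the pooled assignments against gold.
#' Fold results are averaged unweighted.
#'
#' @param corpus A [pheno_corpus()].
#' @param configs Named list of [labeler_config()]s covering
#'   `agg_spec$members` (e.g. [make_default_ensemble()]).
#' @param agg_spec An [aggregation_spec()].
#' @param resources A [seg_resources()].
#' @param k Number of folds.
#' @param seed Integer seed (fold plan and training).
#' @param max_epochs Passed to the learners.
#' @return A `cv_result`: list with `average` (micro vector and per-label
#'   data frame of fold-mean P/R/F1) and `per_fold` (list of
#'   [score_assignments()] results).
#' @export
cross_validate <- function(corpus, configs, agg_spec, resources,
                           k = 10L, seed = 1L, max_epochs = 8L) {
  stopifnot(inherits(agg_spec, "aggregation_spec"))
  members <- agg_spec$members
  missing <- setdiff(members, names(configs))
  if (length(missing))
    stop("cross_validate(): no config for members: ",
         paste(missing, collapse = ", "), call. = FALSE)
  plan <- stratified_folds(corpus, k, seed)
  # featurize once per distinct feature configuration
  fz <- lapply(configs[members], function(cf)
    featurize_corpus(corpus, cf$feature_config, resources))
  y <- lapply(corpus$sequences, function(s)
    match(s$labels, corpus$scheme$labels))
  scheme <- corpus$scheme
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(plan$assignments == f)
    train_idx <- setdiff(seq_along(corpus$sequences), test_idx)
    sets <- lapply(members, function(mid) {
      cf <- configs[[mid]]
      fzm <- fz[[mid]]
      model <- fit_labeler(fzm$ids[train_idx], y[train_idx], fzm$feats,
                           scheme, cf, max_epochs)
      off <- 0L
      pos <- integer(); lab <- character()
      for (i in test_idx) {
        pred <- decode_ids(model, fzm$ids[[i]])
        labs <- bio_repair(scheme$labels[pred], scheme)
        pos <- c(pos, off + seq_along(labs) - 1L)
        lab <- c(lab, labs)
        off <- off + length(labs)
      }
      assignment_set(pos, lab)
    })
    names(sets) <- members
    agg <- aggregate_assignments(agg_spec, sets)
    gold <- pooled_gold(corpus$sequences[test_idx])
    per_fold[[f]] <- score_assignments(agg, gold)
  }
  micro <- rowMeans(vapply(per_fold, function(m) m$micro, numeric(3L)))
  labels <- sort(unique(unlist(lapply(per_fold, function(m)
    m$per_label$label))))
  per_label <- do.call(rbind, lapply(labels, function(l) {
    rows <- lapply(per_fold, function(m)
      m$per_label[m$per_label$label == l, , drop = FALSE])
    rows <- do.call(rbind, rows[vapply(rows, nrow, 0L) > 0L])
    data.frame(label = l, precision = mean(rows$precision),
               recall = mean(rows$recall), f1 = mean(rows$f1),
               support = sum(rows$support), stringsAsFactors = FALSE)
  }))
  structure(list(average = list(micro = micro, per_label = per_label),
                 per_fold = per_fold, plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV  micro P %.2f%%  R %.2f%%  F1 %.2f%%\n",
              x$plan$k, x$average$micro["precision"],
              x$average$micro["recall"], x$average$micro["f1"]))
  print(x$average$per_label, row.names = FALSE)
  invisible(x)
}
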