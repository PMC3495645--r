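# Four divergent sequence labelers behind one train/predict contract.
#
# Family "crf": an averaged structured perceptron with first-order
# transition weights and global Viterbi decoding (two ensemble members,
# differing in feature configuration).
# Family "svm_chunker": greedy left-to-right classification over the
# feature window with the two previous predicted labels as dynamic
# features, with genuine one-vs-one (pairwise binary, vote) and one-vs-all
# (per-label binary, argmax margin) multiclass modes.
#
# All learners are averaged perceptrons (sparse updates, lazily averaged
# weights) and are deterministic under the config seed.

LABELER_IDS <- c("crf_a", "crf_b", "svm_1vs1", "svm_1vsall")

#' Configuration of one ensemble member
#'
#' @param labeler_id One of `"crf_a"`, `"crf_b"`, `"svm_1vs1"`,
#'   `"svm_1vsall"`. The family (`crf` vs `svm_chunker`) and multiclass
#'   mode (`none`, `one_vs_one`, `one_vs_all`) follow from the id.
#' @param feature_config A [feature_config()].
#' @param seed Integer seed; training is reproducible given
#'   (corpus, config, seed).
#' @return A `labeler_config` object.
#' @export
labeler_config <- function(labeler_id, feature_config = phenoseg::feature_config(),
                           seed = 1L) {
  labeler_id <- match.arg(labeler_id, LABELER_IDS)
  family <- if (startsWith(labeler_id, "crf")) "crf" else "svm_chunker"
  multiclass <- switch(labeler_id, svm_1vs1 = "one_vs_one",
                       svm_1vsall = "one_vs_all", "none")
  stopifnot(inherits(feature_config, "feature_config"))
  structure(list(labeler_id = labeler_id, family = family,
                 multiclass = multiclass, feature_config = feature_config,
                 seed = as.integer(seed)),
            class = "labeler_config")
}

#' The default four-member divergent ensemble
#'
#' Divergence comes from the model families/multiclass modes and from
#' distinct window and affix sizes: `crf_a` (window 2, affix 4), `crf_b`
#' (window 3, affix 5), `svm_1vs1` (window 2, affix 5), `svm_1vsall`
#' (window 3, affix 4).
#'
#' Dictionary flags follow the phase: phase II never uses the domain
#' dictionaries, and the quality task additionally drops the coordinates
#' and ordinals dictionaries.
#'
#' @param phase `"1"`, `"anatomy"` or `"quality"`.
#' @param use_domain_dicts For phase 1 only: include the anatomy/qualities
#'   dictionaries and combined features.
#' @param seed Base seed; member i uses `seed + i - 1`.
#' @return Named list of four [labeler_config()]s.
#' @export
make_default_ensemble <- function(phase = c("1", "anatomy", "quality"),
                                  use_domain_dicts = TRUE, seed = 1L) {
  phase <- match.arg(phase)
  dom <- switch(phase, "1" = isTRUE(use_domain_dicts), FALSE)
  coord <- phase != "quality"
  geom <- list(crf_a = c(2L, 4L), crf_b = c(3L, 5L),
               svm_1vs1 = c(2L, 5L), svm_1vsall = c(3L, 4L))
  out <- lapply(seq_along(geom), function(i) {
    g <- geom[[i]]
    labeler_config(names(geom)[i],
                   feature_config(window = g[1L], affix_size = g[2L],
                                  use_domain_dicts = dom,
                                  use_coord_ord_dicts = coord),
                   seed = as.integer(seed) + i - 1L)
  })
  names(out) <- names(geom)
  out
}

# evaluate expr under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# ---- internal fitting on pre-featurized integer ids ---------------------

# Xids: list over sequences of lists over positions of integer feature ids
# y:    list over sequences of integer label vectors (1..L)
fit_structured_perceptron <- function(Xids, y, L, n_feat, seed,
                                      max_epochs = 8L) {
  W <- matrix(0, n_feat, L); U <- matrix(0, n_feat, L)
  Tm <- matrix(0, L + 1L, L); TU <- matrix(0, L + 1L, L)
  step <- 1
  n_seq <- length(Xids)
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      mistakes <- 0L
      for (s in sample.int(n_seq)) {
        ids <- Xids[[s]]; gold <- y[[s]]
        n <- length(gold)
        if (n == 0L) next
        E <- t(vapply(ids, function(ii) .colSums(W[ii, , drop = FALSE],
                                                 length(ii), L),
                      numeric(L)))
        pred <- viterbi_decode(E, Tm, L, n)
        if (!identical(pred, gold)) {
          mistakes <- mistakes + 1L
          diff <- which(pred != gold)
          for (p in diff) {
            ii <- ids[[p]]
            W[ii, gold[p]] <- W[ii, gold[p]] + 1
            U[ii, gold[p]] <- U[ii, gold[p]] + step
            W[ii, pred[p]] <- W[ii, pred[p]] - 1
            U[ii, pred[p]] <- U[ii, pred[p]] - step
          }
          gprev <- c(L + 1L, gold[-n]); pprev <- c(L + 1L, pred[-n])
          gi <- cbind(gprev, gold); pi <- cbind(pprev, pred)
          Tm[gi] <- Tm[gi] + 1; TU[gi] <- TU[gi] + step
          Tm[pi] <- Tm[pi] - 1; TU[pi] <- TU[pi] - step
        }
        step <- step + 1
      }
      if (mistakes == 0L) break
    }
  })
  list(W = W - U / step, Tm = Tm - TU / step)
}

viterbi_decode <- function(E, Tm, L, n) {
  back <- matrix(1L, n, L)
  delta <- Tm[L + 1L, ] + E[1L, ]
  if (n > 1L) for (t in 2L:n) {
    M <- delta + Tm[seq_len(L), , drop = FALSE]  # M[k, j] = delta_k + T_kj
    arg <- max.col(t(M), ties.method = "first")
    back[t, ] <- arg
    delta <- M[cbind(arg, seq_len(L))] + E[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (t in n:2L) path[t - 1L] <- back[t, path[t]]
  path
}

# dynamic feature ids for the chunkers: appended after the n_feat static ids
dyn_ids <- function(n_feat, L) {
  list(prev1 = function(lab) n_feat + lab,             # lab in 1..L, BOS = L+1
       prev2 = function(lab) n_feat + (L + 1L) + lab,
       total = n_feat + 2L * (L + 1L))
}

fit_chunker <- function(Xids, y, L, n_feat, mode, seed, max_epochs = 8L) {
  dyn <- dyn_ids(n_feat, L)
  FP <- dyn$total
  if (mode == "one_vs_all") {
    W <- matrix(0, FP, L); U <- matrix(0, FP, L)
    pa <- pb <- NULL
  } else {
    pr <- utils::combn(L, 2L)
    pa <- pr[1L, ]; pb <- pr[2L, ]
    W <- matrix(0, FP, ncol(pr)); U <- matrix(0, FP, ncol(pr))
  }
  step <- 1
  n_seq <- length(Xids)
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      mistakes <- 0L
      for (s in sample.int(n_seq)) {
        ids <- Xids[[s]]; gold <- y[[s]]
        n <- length(gold)
        if (n == 0L) next
        for (p in seq_len(n)) {
          p1 <- if (p > 1L) gold[p - 1L] else L + 1L
          p2 <- if (p > 2L) gold[p - 2L] else L + 1L
          x <- c(ids[[p]], dyn$prev1(p1), dyn$prev2(p2))
          if (mode == "one_vs_all") {
            sc <- .colSums(W[x, , drop = FALSE], length(x), L)
            tgt <- rep(-1, L); tgt[gold[p]] <- 1
            wrong <- which(tgt * sc <= 0)
            if (length(wrong)) {
              mistakes <- mistakes + 1L
              W[x, wrong] <- W[x, wrong] +
                rep(tgt[wrong], each = length(x))
              U[x, wrong] <- U[x, wrong] +
                rep(step * tgt[wrong], each = length(x))
            }
          } else {
            cols <- which(pa == gold[p] | pb == gold[p])
            sc <- .colSums(W[x, cols, drop = FALSE], length(x), length(cols))
            tgt <- ifelse(pa[cols] == gold[p], 1, -1)
            wrong <- which(tgt * sc <= 0)
            if (length(wrong)) {
              mistakes <- mistakes + 1L
              cw <- cols[wrong]
              W[x, cw] <- W[x, cw] + rep(tgt[wrong], each = length(x))
              U[x, cw] <- U[x, cw] + rep(step * tgt[wrong], each = length(x))
            }
          }
          step <- step + 1
        }
      }
      if (mistakes == 0L) break
    }
  })
  list(W = W - U / step, pa = pa, pb = pb, dyn_n_feat = n_feat)
}

chunker_decode <- function(model, ids, L, mode) {
  n <- length(ids)
  if (n == 0L) return(integer())
  dyn <- dyn_ids(model$dyn_n_feat, L)
  W <- model$W
  out <- integer(n)
  for (p in seq_len(n)) {
    p1 <- if (p > 1L) out[p - 1L] else L + 1L
    p2 <- if (p > 2L) out[p - 2L] else L + 1L
    x <- c(ids[[p]], dyn$prev1(p1), dyn$prev2(p2))
    if (mode == "one_vs_all") {
      sc <- .colSums(W[x, , drop = FALSE], length(x), L)
      out[p] <- which.max(sc)
    } else {
      sc <- .colSums(W[x, , drop = FALSE], length(x), ncol(W))
      winner <- ifelse(sc > 0, model$pa, model$pb)
      votes <- tabulate(winner, nbins = L)
      margin <- vapply(seq_len(L),
                       function(l) sum(abs(sc)[winner == l]), 0)
      best <- which(votes == max(votes))
      if (length(best) > 1L) best <- best[which.max(margin[best])]
      out[p] <- best[1L]
    }
  }
  out
}

# featurize a corpus once under a config; returns list(ids=..., feats=...)
featurize_corpus <- function(corpus, fconfig, resources) {
  strs <- lapply(corpus$sequences, function(s)
    featurize_strings(s$tokens, fconfig, resources))
  feats <- unique(unlist(strs, use.names = FALSE))
  ids <- lapply(strs, function(seq_strs)
    lapply(seq_strs, function(v) match(v, feats)))
  list(ids = ids, feats = feats)
}

fit_labeler <- function(Xids, y, feats, scheme, config, max_epochs = 8L) {
  L <- length(scheme$labels)
  gold_labels <- unique(unlist(y, use.names = FALSE))
  model <- NULL
  constant <- NULL
  if (length(gold_labels) < 2L) {
    warning("train(): corpus contains a single label class; ",
            "returning a constant predictor", call. = FALSE)
    constant <- gold_labels
  } else if (config$family == "crf") {
    model <- fit_structured_perceptron(Xids, y, L, length(feats),
                                       config$seed, max_epochs)
  } else {
    model <- fit_chunker(Xids, y, L, length(feats), config$multiclass,
                         config$seed, max_epochs)
  }
  structure(list(config = config, scheme = scheme, features = feats,
                 model = model, constant = constant),
            class = "trained_labeler")
}

#' Train one sequence labeler
#'
#' @param corpus A non-empty [pheno_corpus()].
#' @param config A [labeler_config()].
#' @param resources A [seg_resources()] satisfying the feature
#'   configuration.
#' @param max_epochs Maximum perceptron epochs (training stops early once an
#'   epoch makes no mistakes).
#' @return A `trained_labeler`.
#' @export
train_labeler <- function(corpus, config, resources, max_epochs = 8L) {
  stopifnot(inherits(corpus, "pheno_corpus"), inherits(config, "labeler_config"),
            inherits(resources, "seg_resources"))
  if (!length(corpus$sequences))
    stop("train_labeler(): empty corpus", call. = FALSE)
  fz <- featurize_corpus(corpus, config$feature_config, resources)
  y <- lapply(corpus$sequences, function(s)
    match(s$labels, corpus$scheme$labels))
  fit_labeler(fz$ids, y, fz$feats, corpus$scheme, config, max_epochs)
}

#' @export
print.trained_labeler <- function(x, ...) {
  cat("<trained_labeler ", x$config$labeler_id, "> scheme ", x$scheme$name,
      ", ", length(x$features), " features\n", sep = "")
  invisible(x)
}

# decode pre-matched ids (NA entries already dropped) into integer labels
decode_ids <- function(labeler, ids) {
  n <- length(ids)
  L <- length(labeler$scheme$labels)
  if (n == 0L) return(integer())
  if (!is.null(labeler$constant)) return(rep(labeler$constant, n))
  if (labeler$config$family == "crf") {
    W <- labeler$model$W
    E <- t(vapply(ids, function(ii) .colSums(W[ii, , drop = FALSE],
                                             length(ii), L),
                  numeric(L)))
    viterbi_decode(E, labeler$model$Tm, L, n)
  } else {
    chunker_decode(labeler$model, ids, L, labeler$config$multiclass)
  }
}

match_ids <- function(strs, feats) {
  lapply(strs, function(v) {
    m <- match(v, feats)
    m[!is.na(m)]
  })
}

#' Predict labels for one token sequence
#'
#' Runs the labeler and applies BIO repair (orphan `X-I` promoted to
#' `X-B`), so the output is always a legal labeling with exactly one label
#' per position.
#'
#' @param labeler A `trained_labeler` from [train_labeler()].
#' @param tokens Character vector of tokens (may be empty).
#' @param resources A [seg_resources()].
#' @return An [assignment_set()] with one `(position, label)` pair per
#'   token.
#' @export
predict_labeler <- function(labeler, tokens, resources) {
  stopifnot(inherits(labeler, "trained_labeler"))
  if (!length(tokens)) return(assignment_set(integer(), character()))
  strs <- featurize_strings(tokens, labeler$config$feature_config, resources)
  ids <- match_ids(strs, labeler$features)
  pred <- decode_ids(labeler, ids)
  labels <- bio_repair(labeler$scheme$labels[pred], labeler$scheme)
  assignment_set(seq_along(tokens) - 1L, labels)
}
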