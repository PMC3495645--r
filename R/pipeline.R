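# End-to-end two-phase decomposition: phase I ensemble segmentation,
# join/re-order of entities by class, phase II class-specific segmentation,
# and assembly into a structured result.

# A phase model is either a single trained_labeler or a list
# (members = named list of trained_labelers, spec = aggregation_spec).
predict_phase <- function(model, tokens, resources) {
  if (inherits(model, "trained_labeler")) {
    list(set = predict_labeler(model, tokens, resources),
         scheme = model$scheme)
  } else if (is.list(model) && !is.null(model$members)) {
    sets <- lapply(model$members, predict_labeler, tokens = tokens,
                   resources = resources)
    list(set = aggregate_assignments(model$spec, sets),
         scheme = model$members[[1L]]$scheme)
  } else {
    stop("expected a trained_labeler or list(members=, spec=)",
         call. = FALSE)
  }
}

# Reduce an assignment set to one label per position over [0, n).
# Positions with no pair become O; positions with several pairs (possible
# under union) are resolved by class priority A > Q > C > O (anatomy
# dominates the corpus), preferring B over I within a class. BIO repair
# runs last.
resolve_assignments <- function(aset, n, scheme) {
  prio <- c(A = 1, AP = 1, Q = 2, QF = 2, P = 1.5, C = 3, O = 4)
  labels <- rep("O", n)
  if (nrow(aset)) {
    sp <- split(aset$label, aset$pos)
    for (key in names(sp)) {
      cand <- sp[[key]]
      r <- prio[label_class(cand)] + ifelse(grepl("-I$", cand), 0.1, 0)
      labels[as.integer(key) + 1L] <- cand[which.min(r)]
    }
  }
  bio_repair(labels, scheme)
}

#' Run the phase I ensemble over one token sequence
#'
#' @param tokens Character vector of tokens.
#' @param model A `trained_labeler` or `list(members=, spec=)` ensemble
#'   under the `phase1` scheme.
#' @param resources A [seg_resources()].
#' @return A [labeled_sequence()] with one phase-1 label per token (set
#'   operation strategies are resolved to single labels; see
#'   `resolve_assignments` in the source for the priority rule).
#' @export
run_phase1 <- function(tokens, model, resources) {
  scheme <- label_scheme("phase1")
  if (!length(tokens))
    return(labeled_sequence(character(), character(), scheme, ""))
  pr <- predict_phase(model, tokens, resources)
  labels <- resolve_assignments(pr$set, length(tokens), scheme)
  labeled_sequence(tokens, labels, scheme, "")
}

#' Join tokens into entities and partition them by class
#'
#' Applies [segments_from_bio()] and partitions the segments into quality,
#' anatomy and connective lists, preserving the original order within each
#' class.
#'
#' @param seq A [labeled_sequence()] under the `phase1` scheme.
#' @return List of three segment data frames: `quality`, `anatomy`,
#'   `connective`.
#' @export
join_and_reorder <- function(seq) {
  segs <- segments_from_bio(seq)
  list(quality = segs[segs$entity_class == "Q", , drop = FALSE],
       anatomy = segs[segs$entity_class == "A", , drop = FALSE],
       connective = segs[segs$entity_class == "C", , drop = FALSE])
}

#' Fine-grained segmentation of one phase I entity
#'
#' Labels the tokens of a single quality or anatomy segment under the
#' class-specific phase II scheme and returns its sub-segments. Phase II is
#' strictly intra-segment: it never relabels across segment boundaries.
#'
#' @param tokens Character vector: the tokens of one phase I segment.
#' @param model Phase II model for the segment's class (`trained_labeler`
#'   or `list(members=, spec=)`), under `phase2_anatomy` or
#'   `phase2_quality`.
#' @param resources A [seg_resources()].
#' @return Segment data frame as from [segments_from_bio()], with spans
#'   relative to the segment.
#' @export
run_phase2 <- function(tokens, model, resources) {
  if (is.null(model))
    stop("run_phase2(): no model for this segment class", call. = FALSE)
  pr <- predict_phase(model, tokens, resources)
  scheme <- pr$scheme
  labels <- resolve_assignments(pr$set, length(tokens), scheme)
  segments_from_bio(labeled_sequence(tokens, labels, scheme, ""))
}

#' Decompose a phenotype description end to end
#'
#' Tokenizes the input, runs the phase I ensemble, joins and re-orders the
#' resulting entities, applies the class-specific phase II models inside
#' each quality and anatomy segment, and assembles the structured result.
#' Every input token position is accounted for exactly once across the
#' groups, the connectives and the outside tokens.
#'
#' @param text A phenotype description string.
#' @param models List with elements `phase1`, `anatomy`, `quality`, each a
#'   `trained_labeler` or `list(members=, spec=)`.
#' @param resources A [seg_resources()].
#' @return A `decomposed_phenotype`: list with `text`, `tokens`,
#'   `quality_groups` (each: `qualities`, `qualifiers`, `source_span`),
#'   `anatomy_groups` (each: `main`, `parts`, `coordinates`,
#'   `source_span`), `connectives`, and `outside` (O-labeled tokens).
#'   Qualities are emitted before anatomy groups.
#' @export
decompose <- function(text, models, resources) {
  tokens <- tokenize(text)
  seq1 <- run_phase1(tokens, models$phase1, resources)
  parts <- join_and_reorder(seq1)
  quality_groups <- lapply(seq_len(nrow(parts$quality)), function(i) {
    sg <- parts$quality[i, ]
    toks <- tokens[(sg$start + 1L):sg$end]
    sub <- run_phase2(toks, models$quality, resources)
    list(qualities = sub$text[sub$entity_class == "Q"],
         qualifiers = sub$text[sub$entity_class == "QF"],
         source_span = c(sg$start, sg$end))
  })
  anatomy_groups <- lapply(seq_len(nrow(parts$anatomy)), function(i) {
    sg <- parts$anatomy[i, ]
    toks <- tokens[(sg$start + 1L):sg$end]
    sub <- run_phase2(toks, models$anatomy, resources)
    list(main = paste(sub$text[sub$entity_class == "A"], collapse = " "),
         parts = sub$text[sub$entity_class == "AP"],
         coordinates = sub$text[sub$entity_class == "P"],
         source_span = c(sg$start, sg$end))
  })
  structure(list(text = text, tokens = tokens, labels = seq1$labels,
                 quality_groups = quality_groups,
                 anatomy_groups = anatomy_groups,
                 connectives = parts$connective$text,
                 outside = tokens[seq1$labels == "O"]),
            class = "decomposed_phenotype")
}

#' @export
print.decomposed_phenotype <- function(x, ...) {
  cat("<decomposed_phenotype> ", x$text, "\n", sep = "")
  for (g in x$quality_groups)
    cat("  quality: ", paste(g$qualities, collapse = ", "),
        if (length(g$qualifiers))
          paste0("  [qualifiers: ", paste(g$qualifiers, collapse = ", "), "]")
        else "", "\n", sep = "")
  for (g in x$anatomy_groups)
    cat("  anatomy: ", g$main,
        if (length(g$parts))
          paste0("  [parts: ", paste(g$parts, collapse = ", "), "]") else "",
        if (length(g$coordinates))
          paste0("  [coordinates: ", paste(g$coordinates, collapse = ", "),
                 "]") else "", "\n", sep = "")
  if (length(x$connectives))
    cat("  connectives: ", paste(x$connectives, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Serialize a decomposed phenotype to JSON
#'
#' The JSON round-trips: `decompose_from_json(decompose_to_json(x))`
#' reproduces `x`.
#'
#' @param x A `decomposed_phenotype`.
#' @return A JSON string.
#' @export
decompose_to_json <- function(x) {
  stopifnot(inherits(x, "decomposed_phenotype"))
  jsonlite::toJSON(unclass(x), auto_unbox = FALSE, digits = NA)
}

#' @rdname decompose_to_json
#' @param json A JSON string produced by [decompose_to_json()].
#' @export
decompose_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  x$quality_groups <- lapply(x$quality_groups, function(g) {
    g$source_span <- as.integer(g$source_span); g
  })
  x$anatomy_groups <- lapply(x$anatomy_groups, function(g) {
    g$source_span <- as.integer(g$source_span); g
  })
  structure(x, class = "decomposed_phenotype")
}
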