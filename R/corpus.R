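# Domain types and corpus I/O: label schemes, tokenization, BIO <-> segment
# conversion, CoNLL-style two-column TSV reading/writing.

#' Label schemes for the two segmentation phases
#'
#' A label scheme fixes the BIO label inventory of one segmentation task and
#' the legal continuation structure (which `X-I` label may follow which
#' `X-B`/`X-I` label).
#'
#' Three schemes are defined:
#' \describe{
#'   \item{`phase1`}{`A-B, A-I` (anatomical entity), `Q-B, Q-I` (quality),
#'     `C-B, C-I` (connective), `O` (outside). Coarse segmentation of a whole
#'     description.}
#'   \item{`phase2_anatomy`}{`A-B, A-I` (main anatomical concept),
#'     `AP-B, AP-I` (anatomical sub-part), `PB` (anatomical coordinate,
#'     always a single token, no continuation label), `C-B, C-I`, `O`.
#'     Fine segmentation within one anatomical entity.}
#'   \item{`phase2_quality`}{`Q-B, Q-I` (quality), `QF-B, QF-I` (qualifier),
#'     `C-B, C-I`, `O`. Fine segmentation within one quality entity.}
#' }
#'
#' @param name One of `"phase1"`, `"phase2_anatomy"`, `"phase2_quality"`.
#' @return A `label_scheme` object: list with `name`, `labels` (character
#'   vector in canonical order) and `continuation` (named list mapping each
#'   `X-I` label to its legal predecessors).
#' @export
#' @examples
#' sc <- label_scheme("phase1")
#' sc$labels
label_scheme <- function(name = c("phase1", "phase2_anatomy", "phase2_quality")) {
  name <- match.arg(name)
  labels <- switch(name,
    phase1         = c("A-B", "A-I", "Q-B", "Q-I", "C-B", "C-I", "O"),
    phase2_anatomy = c("A-B", "A-I", "AP-B", "AP-I", "PB", "C-B", "C-I", "O"),
    phase2_quality = c("Q-B", "Q-I", "QF-B", "QF-I", "C-B", "C-I", "O")
  )
  i_labels <- grep("-I$", labels, value = TRUE)
  continuation <- lapply(i_labels, function(li) {
    cls <- sub("-I$", "", li)
    c(paste0(cls, "-B"), paste0(cls, "-I"))
  })
  names(continuation) <- i_labels
  structure(list(name = name, labels = labels, continuation = continuation),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme ", x$name, ">: ", paste(x$labels, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Entity class of a BIO label
#'
#' Maps labels to their entity class: `A-B`/`A-I` -> `A`, `PB` -> `P`,
#' `O` -> `O`, etc. Vectorized.
#'
#' @param label Character vector of labels.
#' @return Character vector of classes (`A`, `Q`, `C`, `AP`, `QF`, `P`, `O`).
#' @export
label_class <- function(label) {
  out <- sub("-[BI]$", "", label)
  out[label == "PB"] <- "P"
  out
}

# TRUE where `labels` is a legal sequence under `scheme`
bio_valid <- function(labels, scheme) {
  if (!all(labels %in% scheme$labels)) return(FALSE)
  prev <- c("O", labels[-length(labels)])  # "O" stands in for sequence start
  for (k in seq_along(labels)) {
    allowed <- scheme$continuation[[labels[k]]]
    if (!is.null(allowed) && !(prev[k] %in% allowed)) return(FALSE)
  }
  TRUE
}

# Promote orphan X-I labels (no legal predecessor) to X-B. Used on predicted
# output; gold corpora reject invalid transitions instead.
bio_repair <- function(labels, scheme) {
  for (k in seq_along(labels)) {
    allowed <- scheme$continuation[[labels[k]]]
    if (!is.null(allowed)) {
      prev <- if (k == 1L) "O" else labels[k - 1L]
      if (!(prev %in% allowed)) labels[k] <- sub("-I$", "-B", labels[k])
    }
  }
  labels
}

#' Tokenize a phenotype description
#'
#' Whitespace tokenization with detachment of the punctuation characters
#' `, . ; : ( )` into their own tokens. Hyphens and slashes stay inside
#' tokens, so metaphorical terms like `"bone-in-bone"` and ordinals like
#' `"1st"` remain single tokens.
#'
#' @param text A single non-empty string.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize("Irregular, flared metaphyses")
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text)))
    stop("tokenize(): empty or whitespace-only input", call. = FALSE)
  text <- gsub("([,.;:()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

#' Construct a labeled sequence
#'
#' One description: tokens plus one BIO label per token, validated against a
#' label scheme.
#'
#' @param tokens Character vector of tokens (non-empty, no whitespace).
#' @param labels Character vector of labels, same length as `tokens`.
#' @param scheme A [label_scheme()].
#' @param description_id Identifier string.
#' @param on_invalid `"error"` to reject illegal BIO transitions, `"repair"`
#'   to promote orphan `X-I` to `X-B` with a warning.
#' @return A `labeled_sequence` object.
#' @export
labeled_sequence <- function(tokens, labels, scheme, description_id = "",
                             on_invalid = c("error", "repair")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(inherits(scheme, "label_scheme"))
  tokens <- as.character(tokens)
  labels <- as.character(labels)
  if (length(tokens) != length(labels))
    stop("labeled_sequence(): |labels| != |tokens|", call. = FALSE)
  if (any(!nzchar(tokens)) || any(grepl("[[:space:]]", tokens)))
    stop("labeled_sequence(): tokens must be non-empty and whitespace-free",
         call. = FALSE)
  bad <- setdiff(unique(labels), scheme$labels)
  if (length(bad))
    stop("labeled_sequence(): labels outside scheme '", scheme$name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!bio_valid(labels, scheme)) {
    if (on_invalid == "error")
      stop("labeled_sequence(): illegal BIO transition in '", description_id,
           "'", call. = FALSE)
    warning("labeled_sequence(): repaired orphan I-labels in '",
            description_id, "'", call. = FALSE)
    labels <- bio_repair(labels, scheme)
  }
  structure(list(description_id = as.character(description_id),
                 tokens = tokens, labels = labels, scheme_name = scheme$name),
            class = "labeled_sequence")
}

#' Construct a corpus
#'
#' @param sequences List of [labeled_sequence()] objects, all under `scheme`.
#' @param scheme A [label_scheme()].
#' @return A `pheno_corpus` object.
#' @export
pheno_corpus <- function(sequences, scheme) {
  stopifnot(inherits(scheme, "label_scheme"), is.list(sequences))
  for (s in sequences) {
    stopifnot(inherits(s, "labeled_sequence"))
    if (s$scheme_name != scheme$name)
      stop("pheno_corpus(): sequence '", s$description_id,
           "' uses scheme '", s$scheme_name, "', corpus uses '",
           scheme$name, "'", call. = FALSE)
  }
  ids <- vapply(sequences, `[[`, "", "description_id")
  nz <- ids[nzchar(ids)]
  if (anyDuplicated(nz))
    stop("pheno_corpus(): duplicated description_ids", call. = FALSE)
  structure(list(sequences = sequences, scheme = scheme),
            class = "pheno_corpus")
}

#' @export
print.pheno_corpus <- function(x, ...) {
  n_tok <- sum(vapply(x$sequences, function(s) length(s$tokens), 0L))
  cat("<pheno_corpus> ", length(x$sequences), " descriptions, ", n_tok,
      " tokens, scheme ", x$scheme$name, "\n", sep = "")
  invisible(x)
}

#' @export
length.pheno_corpus <- function(x) length(x$sequences)

#' Read a CoNLL-style labeled corpus
#'
#' Format: UTF-8, one `token<TAB>label` pair per line, blank line between
#' descriptions, optional `# id` comment line opening a description and
#' carrying its identifier.
#'
#' @param path File path.
#' @param scheme A [label_scheme()].
#' @param on_invalid Passed to [labeled_sequence()]: reject (`"error"`) or
#'   repair (`"repair"`) illegal BIO transitions in the file.
#' @return A [pheno_corpus()].
#' @export
read_corpus <- function(path, scheme, on_invalid = c("error", "repair")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path))
    stop("read_corpus(): no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  sequences <- list()
  toks <- character()
  labs <- character()
  id <- ""
  n_anon <- 0L
  flush <- function() {
    if (!length(toks)) return()
    if (!nzchar(id)) {
      n_anon <<- n_anon + 1L
      id <<- sprintf("d%04d", n_anon)
    }
    sequences[[length(sequences) + 1L]] <<-
      labeled_sequence(toks, labs, scheme, id, on_invalid = on_invalid)
    toks <<- character(); labs <<- character(); id <<- ""
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) { flush(); next }
    if (startsWith(line, "#")) { id <- trimws(sub("^#", "", line)); next }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("read_corpus(): line ", ln, ": expected token<TAB>label",
           call. = FALSE)
    if (!(parts[2L] %in% scheme$labels))
      stop("read_corpus(): line ", ln, ": label '", parts[2L],
           "' not in scheme '", scheme$name, "'", call. = FALSE)
    toks <- c(toks, parts[1L])
    labs <- c(labs, parts[2L])
  }
  flush()
  pheno_corpus(sequences, scheme)
}

#' Write a corpus in the CoNLL-style format read by [read_corpus()]
#'
#' `write_corpus()` followed by [read_corpus()] is byte-identical on
#' normalized files (LF endings, `# id` comment per description).
#'
#' @param corpus A [pheno_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "pheno_corpus"))
  blocks <- vapply(corpus$sequences, function(s) {
    paste0("# ", s$description_id, "\n",
           paste0(s$tokens, "\t", s$labels, collapse = "\n"))
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(blocks, con, sep = "\n\n", useBytes = TRUE)
  invisible(path)
}

#' Extract entity segments from a BIO labeling
#'
#' Maximal runs `X-B (X-I)*` become one segment of class `X`; each `PB`
#' token becomes its own single-token coordinate segment; `O` tokens produce
#' no segment.
#'
#' @param seq A [labeled_sequence()].
#' @return A data frame with columns `entity_class`, `start`, `end`
#'   (0-based, half-open token indices) and `text` (space-joined tokens),
#'   sorted by `start`.
#' @export
#' @examples
#' sc <- label_scheme("phase1")
#' s <- labeled_sequence(c("streaky", "sclerosis"), c("Q-B", "Q-I"), sc)
#' segments_from_bio(s)
segments_from_bio <- function(seq) {
  stopifnot(inherits(seq, "labeled_sequence"))
  labels <- seq$labels
  n <- length(labels)
  cls <- character(); st <- integer(); en <- integer()
  k <- 1L
  while (k <= n) {
    lab <- labels[k]
    if (lab == "O") { k <- k + 1L; next }
    if (lab == "PB") {
      cls <- c(cls, "P"); st <- c(st, k - 1L); en <- c(en, k)
      k <- k + 1L
      next
    }
    c0 <- sub("-[BI]$", "", lab)
    start <- k
    k <- k + 1L
    while (k <= n && labels[k] == paste0(c0, "-I")) k <- k + 1L
    cls <- c(cls, c0); st <- c(st, start - 1L); en <- c(en, k - 1L)
  }
  data.frame(entity_class = cls, start = st, end = en,
             text = vapply(seq_along(st), function(i)
               paste(seq$tokens[(st[i] + 1L):en[i]], collapse = " "), ""),
             stringsAsFactors = FALSE)
}

#' Rebuild a BIO label vector from segments
#'
#' Inverse of [segments_from_bio()]: positions not covered by a segment get
#' `O`; class `P` segments must span a single token and become `PB`.
#'
#' @param segments Data frame with columns `entity_class`, `start`, `end`
#'   (0-based half-open).
#' @param n_tokens Sequence length.
#' @return Character vector of `n_tokens` labels.
#' @export
bio_from_segments <- function(segments, n_tokens) {
  labels <- rep("O", n_tokens)
  if (is.null(segments) || nrow(segments) == 0L) return(labels)
  stopifnot(all(segments$start < segments$end),
            all(segments$start >= 0L), all(segments$end <= n_tokens))
  covered <- rep(FALSE, n_tokens)
  for (i in seq_len(nrow(segments))) {
    idx <- (segments$start[i] + 1L):segments$end[i]
    if (any(covered[idx]))
      stop("bio_from_segments(): overlapping segments", call. = FALSE)
    covered[idx] <- TRUE
    cls <- segments$entity_class[i]
    if (cls == "P") {
      if (length(idx) != 1L)
        stop("bio_from_segments(): coordinate (P) segments are single tokens",
             call. = FALSE)
      labels[idx] <- "PB"
    } else {
      labels[idx] <- c(paste0(cls, "-B"),
                       rep(paste0(cls, "-I"), length(idx) - 1L))
    }
  }
  labels
}
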