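# Pluggable lexical resources: six gazetteers (conjunctions, connections,
# coordinates, ordinals, anatomy, qualities), a lexical-record table giving
# token bases and categories, and a deterministic rule-based POS/lemma
# tagger used as the test fixture for the pluggable tagger interface.

GAZETTEER_NAMES <- c("conjunctions", "connections", "coordinates",
                     "ordinals", "anatomy", "qualities")

gaz_hit_flag <- function(name) {
  switch(name, anatomy = "anat", qualities = "qual", name)
}

normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Construct a gazetteer
#'
#' @param terms Character vector of terms; normalized to lowercase with
#'   single internal spaces, duplicates dropped.
#' @param name One of `"conjunctions"`, `"connections"`, `"coordinates"`,
#'   `"ordinals"`, `"anatomy"`, `"qualities"`. Determines the flag returned
#'   on a dictionary hit (`"anat"`, `"qual"`, or the gazetteer name).
#' @return A `gazetteer` object.
#' @export
gazetteer <- function(terms, name) {
  name <- match.arg(name, GAZETTEER_NAMES)
  terms <- unique(normalize_term(terms))
  terms <- terms[nzchar(terms)]
  # constituent tokens of multi-word terms, for token-aligned context features
  token_set <- unique(unlist(strsplit(terms, " ", fixed = TRUE)))
  structure(list(name = name, terms = terms, token_set = token_set,
                 hit_flag = gaz_hit_flag(name)),
            class = "gazetteer")
}

#' Load a gazetteer from a plain-text file (one term per line)
#'
#' @param path File path, UTF-8.
#' @inheritParams gazetteer
#' @return A [gazetteer()].
#' @export
load_gazetteer <- function(path, name) {
  if (!file.exists(path))
    stop("load_gazetteer(): no such file: ", path, call. = FALSE)
  terms <- readLines(path, encoding = "UTF-8")
  terms <- terms[nzchar(trimws(terms))]
  if (!length(terms))
    warning("load_gazetteer(): empty gazetteer file: ", path, call. = FALSE)
  gazetteer(terms, name)
}

#' Dictionary-membership flag
#'
#' @param g A [gazetteer()].
#' @param term A string; normalized before lookup (case-insensitive).
#' @return The gazetteer's hit flag (e.g. `"anat"`) if the term is present,
#'   else `"no"`. Vectorized over `term`.
#' @export
#' @examples
#' g <- gazetteer(c("central", "left"), "coordinates")
#' member_flag(g, "Left")
member_flag <- function(g, term) {
  stopifnot(inherits(g, "gazetteer"))
  ifelse(normalize_term(term) %in% g$terms, g$hit_flag, "no")
}

# Token-level flag used by context features: a token hits if it is a
# gazetteer term or a constituent token of a multi-word term.
gaz_token_flags <- function(g, tokens) {
  ifelse(normalize_term(tokens) %in% g$token_set, g$hit_flag, "no")
}

#' Deterministic fallback stemmer
#'
#' Fixed suffix table applied when a token is absent from the lexical
#' table: `-yses -> -ysis`, `-oses -> -osis`, strip final `-s`, `-ed`,
#' `-ing` (first matching rule; a token is never reduced to the empty
#' string).
#'
#' @param token Character vector.
#' @return Character vector of stems.
#' @export
fallback_stem <- function(token) {
  vapply(tolower(token), function(t) {
    out <- if (grepl("yses$", t)) sub("yses$", "ysis", t)
      else if (grepl("oses$", t)) sub("oses$", "osis", t)
      else if (grepl("[^s]s$", t)) sub("s$", "", t)
      else if (grepl("..ed$", t)) sub("ed$", "", t)
      else if (grepl("..ing$", t)) sub("ing$", "", t)
      else t
    if (nzchar(out)) out else t
  }, "", USE.NAMES = FALSE)
}

#' Construct a lexical-record table
#'
#' A small stand-in for a syntactic lexicon of biomedical English: each
#' record maps an inflected surface form to its base form and lexical
#' category.
#'
#' @param surface,base,category Character vectors of equal length.
#' @return A data frame of class `lexical_table` with unique surfaces
#'   (lowercased).
#' @export
lexical_table <- function(surface = character(), base = character(),
                          category = character()) {
  stopifnot(length(surface) == length(base),
            length(surface) == length(category))
  df <- data.frame(surface = tolower(surface), base = base,
                   category = category, stringsAsFactors = FALSE)
  df <- df[!duplicated(df$surface), , drop = FALSE]
  if (any(!nzchar(df$base)))
    stop("lexical_table(): empty base", call. = FALSE)
  class(df) <- c("lexical_table", "data.frame")
  df
}

#' Read a lexical table from a 3-column TSV (surface, base, category)
#'
#' @param path File path.
#' @return A [lexical_table()].
#' @export
read_lexical_table <- function(path) {
  if (!file.exists(path))
    stop("read_lexical_table(): no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) != 3L)
    stop("read_lexical_table(): expected 3 columns", call. = FALSE)
  lexical_table(df[[1L]], df[[2L]], df[[3L]])
}

#' Base form and lexical category of a token
#'
#' Exact case-insensitive surface lookup in the lexical table; on a miss the
#' base falls back to [fallback_stem()] and the category to `"unknown"`.
#' Total: never fails.
#'
#' @param table A [lexical_table()] (may be empty).
#' @param token Character vector of tokens.
#' @return A list with character vectors `base` and `category`.
#' @export
#' @examples
#' tab <- lexical_table("metaphyses", "metaphysis", "noun")
#' base_and_category(tab, "metaphyses")
base_and_category <- function(table, token) {
  idx <- match(tolower(token), table$surface)
  base <- ifelse(is.na(idx), fallback_stem(token), table$base[idx])
  category <- ifelse(is.na(idx), "unknown", table$category[idx])
  list(base = as.character(base), category = as.character(category))
}

# closed-class word lists for the fixture tagger
.TAGGER_PREP <- c("of", "in", "at", "on", "with", "to", "the", "a", "an")
.TAGGER_CONJ <- c("and", "or", "but")

#' Deterministic rule-based POS/lemma tagger (fixture implementation)
#'
#' The feature extractor takes any tagger with signature
#' `function(tokens) -> list(lemma=, pos=)`. This default is a small,
#' fully deterministic rule set (closed-class lists plus suffix rules) so
#' tests need no external NLP model; it makes no claim of linguistic
#' accuracy beyond being stable.
#'
#' @param tokens Character vector.
#' @return List with character vectors `lemma` and `pos`.
#' @export
rule_tagger <- function(tokens) {
  low <- tolower(tokens)
  pos <- rep("NN", length(tokens))
  pos[grepl("^[[:punct:]]+$", tokens)] <- "PUNCT"
  pos[grepl("^[0-9]+(st|nd|rd|th)?$", low)] <- "CD"
  pos[grepl("..(al|ar|ic|ous|ive|like|oid)$", low)] <- "JJ"
  pos[grepl("...ed$", low)] <- "VBN"
  pos[grepl("...ing$", low)] <- "VBG"
  pos[grepl("..ly$", low)] <- "RB"
  pos[grepl("[^su]s$", low) & pos == "NN"] <- "NNS"
  pos[low %in% .TAGGER_PREP] <- "IN"
  pos[low %in% .TAGGER_CONJ] <- "CC"
  list(lemma = fallback_stem(low), pos = pos)
}

#' Bundle segmentation resources
#'
#' @param gazetteers Named list of [gazetteer()] objects; any of the six
#'   canonical names may be present, missing ones default to empty.
#' @param lexicon A [lexical_table()]; defaults to empty.
#' @param tagger A `function(tokens) -> list(lemma=, pos=)`; defaults to
#'   [rule_tagger()].
#' @return A `seg_resources` object.
#' @export
seg_resources <- function(gazetteers = list(), lexicon = lexical_table(),
                          tagger = rule_tagger) {
  gz <- lapply(GAZETTEER_NAMES, function(nm) {
    g <- gazetteers[[nm]]
    if (is.null(g)) gazetteer(character(), nm) else g
  })
  names(gz) <- GAZETTEER_NAMES
  stopifnot(inherits(lexicon, "lexical_table"), is.function(tagger))
  structure(list(gazetteers = gz, lexicon = lexicon, tagger = tagger),
            class = "seg_resources")
}

#' Load resources from a directory
#'
#' Expects `<name>.txt` for each gazetteer present and `lexicon.tsv` for the
#' lexical table; missing files yield empty resources of that kind.
#'
#' @param dir Directory path.
#' @return A [seg_resources()].
#' @export
load_resources <- function(dir) {
  gz <- list()
  for (nm in GAZETTEER_NAMES) {
    p <- file.path(dir, paste0(nm, ".txt"))
    if (file.exists(p)) gz[[nm]] <- load_gazetteer(p, nm)
  }
  lx <- file.path(dir, "lexicon.tsv")
  lexicon <- if (file.exists(lx)) read_lexical_table(lx) else lexical_table()
  seg_resources(gz, lexicon)
}

#' Built-in fixture resources
#'
#' Loads the small gazetteers and lexical table shipped under
#' `inst/extdata/` (generated jointly with the synthetic grammar;
#' deliberately incomplete to emulate imperfect real-world dictionaries).
#'
#' @return A [seg_resources()].
#' @export
default_resources <- function() {
  load_resources(system.file("extdata", package = "phenoseg"))
}
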