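# Per-token feature inventory: local/orthographic features, n-gram contexts,
# dictionary flags, and combined (context x dictionary x base) features.
# All context features pad absent positions with "@".

#' Feature extraction configuration
#'
#' @param window Context half-width for the n-gram features (1-3 in the
#'   default ensemble).
#' @param affix_size Maximum prefix/suffix length (3-5 in the default
#'   ensemble).
#' @param use_domain_dicts Include the anatomy/qualities domain-dictionary
#'   features and the nine combined features that depend on them.
#' @param use_coord_ord_dicts Include the coordinates and ordinals
#'   dictionary features (dropped for the phase II quality task).
#' @return A `feature_config` object.
#' @export
feature_config <- function(window = 3L, affix_size = 5L,
                           use_domain_dicts = TRUE,
                           use_coord_ord_dicts = TRUE) {
  window <- as.integer(window); affix_size <- as.integer(affix_size)
  stopifnot(window >= 1L, affix_size >= 1L)
  structure(list(window = window, affix_size = affix_size,
                 use_domain_dicts = isTRUE(use_domain_dicts),
                 use_coord_ord_dicts = isTRUE(use_coord_ord_dicts)),
            class = "feature_config")
}

#' Orthographic token shape
#'
#' Uppercase letters become `A`, lowercase letters `a`, digits `0`; all
#' other characters are unchanged. Vectorized.
#'
#' @param token Character vector.
#' @return Character vector, same element lengths as the input.
#' @export
#' @examples
#' token_shape("FGFR3")
token_shape <- function(token) {
  token <- gsub("[[:upper:]]", "A", token)
  token <- gsub("[[:lower:]]", "a", token)
  gsub("[0-9]", "0", token)
}

#' Brief token shape
#'
#' [token_shape()] with consecutive equal symbols collapsed to one.
#'
#' @inheritParams token_shape
#' @return Character vector.
#' @export
#' @examples
#' brief_shape("metaphyses")  # "a"
brief_shape <- function(token) {
  gsub("(.)\\1+", "\\1", token_shape(token))
}

#' Vowel pattern
#'
#' Every character except the vowels `a e i o u` (case-insensitive, `y`
#' excluded) is replaced by `-`.
#'
#' @inheritParams token_shape
#' @return Character vector, same element lengths as the input.
#' @export
vowel_pattern <- function(token) {
  gsub("[^aeiouAEIOU]", "-", token)
}

#' Digit pattern
#'
#' For tokens containing at least one digit, digits are replaced by `*`;
#' digit-free tokens yield the literal flag `"no"`.
#'
#' @inheritParams token_shape
#' @return Character vector.
#' @export
digit_pattern <- function(token) {
  ifelse(grepl("[0-9]", token), gsub("[0-9]", "*", token), "no")
}

#' Trailing-punctuation flag
#'
#' @inheritParams token_shape
#' @return `"punct"` where the token ends with a punctuation character,
#'   else `"no"`.
#' @export
punct_flag <- function(token) {
  ifelse(grepl("[[:punct:]]$", token), "punct", "no")
}

#' Token prefixes and suffixes of increasing length
#'
#' @param token A single token.
#' @param size Maximum affix length; shorter tokens yield all available
#'   affixes.
#' @return List with character vectors `prefix` and `suffix`, each ordered
#'   by increasing length.
#' @export
#' @examples
#' affixes("metaphyses", 5)
affixes <- function(token, size) {
  stopifnot(length(token) == 1L, size >= 1L)
  k <- seq_len(min(size, nchar(token)))
  list(prefix = substring(token, 1L, k),
       suffix = substring(token, nchar(token) - k + 1L, nchar(token)))
}

# pad a token vector with `w` "@" symbols on each side
pad_window <- function(x, w, pad = "@") c(rep(pad, w), x, rep(pad, w))

# n x (2w+1) matrix: row i holds the padded window centered at position i
window_matrix <- function(padded, n, w) {
  idx <- outer(seq_len(n) - 1L, 0L:(2L * w), `+`) + 1L
  matrix(padded[idx], nrow = n)
}

# contiguous n-grams over a window matrix, joined with "-"
gram_matrix <- function(M, n) {
  k <- ncol(M) - n + 1L
  out <- M[, seq_len(k), drop = FALSE]
  for (j in seq_len(n - 1L))
    out <- matrix(paste0(out, "-", M[, seq_len(k) + j, drop = FALSE]),
                  nrow = nrow(M))
  out
}

#' n-gram context around one position
#'
#' For `n = 1`, the `2*window + 1` tokens centered at position `i`, with
#' `"@"` padding for absent positions; for `n >= 2`, all contiguous n-grams
#' over that padded window, joined with `-` (hence `2*window + 2 - n`
#' values).
#'
#' @param tokens Character vector of sequence tokens.
#' @param i 0-based focus position.
#' @param n Gram order, 1-3.
#' @param window Context half-width.
#' @return Ordered character vector of context values.
#' @export
#' @examples
#' toks <- c("irregular", "flared", "metaphyses", "of", "the", "long",
#'           "bones", "with", "streaky", "sclerosis")
#' ngram_context(toks, 2, 1, 3)
ngram_context <- function(tokens, i, n, window) {
  stopifnot(n %in% 1:3, window >= 1L, i >= 0L, i < length(tokens))
  M <- window_matrix(pad_window(tokens, window), length(tokens), window)
  if (n > 1L) M <- gram_matrix(M, n)
  M[i + 1L, ]
}

#' Dictionary-flag context around one position
#'
#' The n-gram context of [ngram_context()] with each token (or its lexical
#' base, when `use_bases`) replaced by its membership flag against a
#' gazetteer; for `n = 2` flags are paired with `-` exactly as token bigrams
#' are. Padding positions flag as `"no"`.
#'
#' @inheritParams ngram_context
#' @param g A [gazetteer()].
#' @param use_bases Look up lexical bases instead of surface tokens.
#' @param lexicon A [lexical_table()]; required when `use_bases`.
#' @return Ordered character vector of flag values.
#' @export
dict_context <- function(tokens, i, window, g, n = 1L, use_bases = FALSE,
                         lexicon = lexical_table()) {
  stopifnot(n %in% 1:3, window >= 1L, i >= 0L, i < length(tokens))
  x <- if (use_bases) base_and_category(lexicon, tokens)$base else tokens
  flags <- gaz_token_flags(g, x)
  M <- window_matrix(pad_window(flags, window, pad = "no"),
                     length(tokens), window)
  if (n > 1L) M <- gram_matrix(M, n)
  M[i + 1L, ]
}

# Compute every feature for every position of one sequence at once.
# Returns a named list: scalar features are length-n character vectors,
# context/affix features are n x k character matrices whose column names
# are the serialized sub-feature names. Order of the list is the canonical
# feature inventory order.
featurize_values <- function(tokens, config, resources) {
  stopifnot(inherits(config, "feature_config"),
            inherits(resources, "seg_resources"))
  n <- length(tokens)
  if (n == 0L) return(list())
  w <- config$window
  gz <- resources$gazetteers
  tagged <- resources$tagger(tokens)
  bc <- base_and_category(resources$lexicon, tokens)

  named_mat <- function(vals, name, keys) {
    colnames(vals) <- paste0(name, "[", keys, "]")
    vals
  }
  uniM <- window_matrix(pad_window(tokens, w), n, w)
  offs <- -w:w

  out <- list(
    token      = tokens,
    lemma      = tagged$lemma,
    base       = bc$base,
    pos        = tagged$pos,
    category   = bc$category,
    shape      = token_shape(tokens),
    brief_shape = brief_shape(tokens),
    uni = named_mat(uniM, "uni", offs),
    bi  = named_mat(gram_matrix(uniM, 2L), "bi", seq_len(2L * w)),
    tri = named_mat(gram_matrix(uniM, 3L), "tri", seq_len(2L * w - 1L)),
    punct = punct_flag(tokens),
    digit = digit_pattern(tokens),
    vowel = vowel_pattern(tokens)
  )

  # ragged affixes: matrix padded with NA beyond the token length
  a <- config$affix_size
  nc <- nchar(tokens)
  pre <- suf <- matrix(NA_character_, nrow = n, ncol = a)
  for (k in seq_len(a)) {
    ok <- nc >= k
    pre[ok, k] <- substring(tokens[ok], 1L, k)
    suf[ok, k] <- substring(tokens[ok], nc[ok] - k + 1L, nc[ok])
  }
  out$prefix <- named_mat(pre, "prefix", seq_len(a))
  out$suffix <- named_mat(suf, "suffix", seq_len(a))

  out$dict.conjunctions <- gaz_token_flags(gz$conjunctions, tokens)
  out$dict.connections  <- gaz_token_flags(gz$connections, tokens)
  if (config$use_coord_ord_dicts) {
    out$dict.coordinates <- gaz_token_flags(gz$coordinates, tokens)
    out$dict.ordinals    <- gaz_token_flags(gz$ordinals, tokens)
  }

  if (config$use_domain_dicts) {
    anat_tok <- gaz_token_flags(gz$anatomy, tokens)
    qual_tok <- gaz_token_flags(gz$qualities, tokens)
    anat_base <- gaz_token_flags(gz$anatomy, bc$base)
    qual_base <- gaz_token_flags(gz$qualities, bc$base)
    out$dict.anatomy   <- anat_tok
    out$dict.qualities <- qual_tok
    # nine combined features
    out$base.anat <- anat_base
    out$base.qual <- qual_base
    anatM <- window_matrix(pad_window(anat_tok, w, pad = "no"), n, w)
    qualM <- window_matrix(pad_window(qual_tok, w, pad = "no"), n, w)
    out$uni.anat <- named_mat(anatM, "uni.anat", offs)
    out$uni.qual <- named_mat(qualM, "uni.qual", offs)
    out$bi.anat <- named_mat(gram_matrix(anatM, 2L), "bi.anat",
                             seq_len(2L * w))
    out$bi.qual <- named_mat(gram_matrix(qualM, 2L), "bi.qual",
                             seq_len(2L * w))
    baseM <- window_matrix(pad_window(bc$base, w), n, w)
    out$uni.base <- named_mat(baseM, "uni.base", offs)
    anatbM <- window_matrix(pad_window(anat_base, w, pad = "no"), n, w)
    qualbM <- window_matrix(pad_window(qual_base, w, pad = "no"), n, w)
    out$uni.base.anat <- named_mat(anatbM, "uni.base.anat", offs)
    out$uni.base.qual <- named_mat(qualbM, "uni.base.qual", offs)
  }
  out
}

#' Extract the full feature vector for one token position
#'
#' Computes the complete feature inventory for the token at 0-based
#' position `i`: token/lemma/base/POS/category, shapes, uni/bi/tri-gram
#' contexts at the configured window, punctuation/digit/vowel patterns,
#' prefixes/suffixes at the configured size, the simple dictionary flags,
#' and (iff `use_domain_dicts`) the domain-dictionary and nine combined
#' features. Deterministic and position-local.
#'
#' @param tokens Character vector of sequence tokens.
#' @param i 0-based focus position.
#' @param config A [feature_config()].
#' @param resources A [seg_resources()].
#' @return Named list mapping feature names to character values (context
#'   and affix features hold ordered multi-values).
#' @export
#' @examples
#' toks <- c("irregular", "flared", "metaphyses", "of", "the", "long",
#'           "bones", "with", "streaky", "sclerosis")
#' fv <- extract_features(toks, 2, feature_config(), seg_resources())
#' fv$shape
extract_features <- function(tokens, i, config, resources) {
  stopifnot(i >= 0L, i < length(tokens))
  vals <- featurize_values(tokens, config, resources)
  lapply(vals, function(v) {
    if (is.matrix(v)) unname(v[i + 1L, !is.na(v[i + 1L, ])]) else v[i + 1L]
  })
}

# Serialize per-position features as "name=value" strings for the learners.
# Returns a list of character vectors, one per position.
featurize_strings <- function(tokens, config, resources) {
  n <- length(tokens)
  if (n == 0L) return(list())
  vals <- featurize_values(tokens, config, resources)
  cols <- vector("list", 0L)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.matrix(v)) {
      for (j in seq_len(ncol(v)))
        cols[[colnames(v)[j]]] <- v[, j]
    } else {
      cols[[nm]] <- v
    }
  }
  big <- matrix(unlist(cols, use.names = FALSE), nrow = n)
  big <- sweep_paste(big, names(cols))
  lapply(seq_len(n), function(i) {
    row <- big[i, ]
    row[!is.na(row)]
  })
}

# paste0(colname, "=", cell) for a character matrix, column-wise; NA cells
# (absent affixes) stay NA
sweep_paste <- function(M, names) {
  out <- M
  for (j in seq_len(ncol(M))) {
    keep <- !is.na(M[, j])
    out[keep, j] <- paste0(names[j], "=", M[keep, j])
  }
  out
}
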