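# Synthetic labeled corpora emulating the grammatical shapes of skeletal
# phenotype descriptions ("irregular flared metaphyses of the long bones
# with streaky sclerosis") and the label-category proportions of the
# reference corpus (phase I: anatomy ~70%, quality ~29.5%, connectives and
# outside tokens each ~0.2%). The generator keeps per-token fine-grained
# (phase II) labels as bookkeeping so the two phase II corpora can be
# derived mechanically.
#
# Hard cases are planted deliberately: a token ("radial") used both as an
# anatomical coordinate and inside a multi-token main anatomical concept,
# hyphenated metaphorical terms kept as single tokens, and atomic
# phenotypes labeled wholly as qualities.

#' Default grammar vocabulary
#'
#' Per-slot token lists for the synthetic description grammar. All lists
#' are plain character vectors; multi-word entries are space-separated and
#' tokenized by the generator.
#'
#' @return Named list of character vectors.
#' @export
default_vocab <- function() {
  list(
    qualifiers = c("streaky", "severe", "mild", "marked", "diffuse",
                   "patchy", "generalized", "focal", "progressive",
                   "symmetric"),
    qualities = c("sclerosis", "ossification", "shortening", "widening",
                  "broadening", "bowing", "fusion", "irregularity",
                  "hypoplasia", "aplasia", "dysplasia", "erosion",
                  "fragmentation", "thickening", "flattening", "cupping",
                  "flaring", "demineralization", "calcification",
                  "irregular", "flared", "short", "broad", "dense",
                  "sclerotic", "osteopenia", "lucency", "osteolysis"),
    atomic = c("acromelia", "brachydactyly", "platyspondyly", "micromelia",
               "rhizomelia", "dysostosis multiplex",
               "bone-in-bone appearance", "genu varum", "coxa vara",
               "madelung deformity", "angel-shaped phalanges"),
    coordinates = c("proximal", "distal", "lateral", "medial", "central",
                    "anterior", "posterior", "left", "right", "bilateral",
                    "radial"),
    parts = c("metaphyses", "epiphyses", "diaphyses", "metadiaphyses",
              "apophyses", "cortex", "trabeculae"),
    mains = c("femur", "tibia", "radius", "ulna", "humerus", "vertebrae",
              "ribs", "pelvis", "skull", "clavicles", "scapulae",
              "phalanges", "metacarpals", "metatarsals", "long bones",
              "tubular bones", "femoral necks", "iliac wings",
              "radial club hand"),
    anat_connective = "of the",
    clause_connective = "with",
    conjunctions = c("and", "or"),
    o_tails = c("in first year", "at birth", "in early childhood")
  )
}

#' Default optional-slot probabilities of the grammar
#'
#' Calibrated once so that, at the default settings, the phase I
#' label-category shares approximate the reference corpus distribution
#' (anatomy ~70%, quality ~29.5%, connectives ~0.2%, outside ~0.2%).
#'
#' @return Named numeric vector in `[0, 1]`.
#' @export
default_slot_probs <- function() {
  c(atomic = 0.05,        # description is an atomic phenotype (all quality)
    qualifier = 0.30,     # quality entity carries a qualifier
    second_quality = 0.30,# a second quality entity precedes the anatomy
    part_form = 0.80,     # anatomy phrase is "part of the main" (vs direct)
    coordinate = 0.40,    # anatomy phrase opens with a coordinate
    second_coordinate = 0.10, # a conjoined second coordinate
    with_clause = 0.012,  # trailing "with <quality>" clause (connective C)
    o_tail = 0.004,       # trailing temporal note, labeled O
    comma = 0.008)        # comma between quality entities, labeled O
}

#' Grammar configuration for the synthetic corpus generator
#'
#' @param n_descriptions Number of descriptions to generate.
#' @param seed Integer seed; generation is deterministic given the config.
#' @param vocab Per-slot token lists, see [default_vocab()].
#' @param slot_probs Optional-slot probabilities, see
#'   [default_slot_probs()]; partial vectors override the defaults.
#' @return A `grammar_config`.
#' @export
grammar_config <- function(n_descriptions = 1000L, seed = 7L,
                           vocab = default_vocab(),
                           slot_probs = default_slot_probs()) {
  probs <- default_slot_probs()
  probs[names(slot_probs)] <- slot_probs
  if (any(probs < 0 | probs > 1) || anyNA(probs))
    stop("grammar_config(): slot probabilities must lie in [0, 1]",
         call. = FALSE)
  for (nm in c("qualifiers", "qualities", "atomic", "coordinates", "parts",
               "mains", "conjunctions", "o_tails"))
    if (!length(vocab[[nm]]))
      stop("grammar_config(): empty vocab slot '", nm, "'", call. = FALSE)
  structure(list(n_descriptions = as.integer(n_descriptions),
                 seed = as.integer(seed), vocab = vocab,
                 slot_probs = probs),
            class = "grammar_config")
}

split_term <- function(term) strsplit(term, " ", fixed = TRUE)[[1L]]

# one quality entity: [qualifier] quality; returns tokens/phase1/fine
gen_quality_entity <- function(vocab, probs, first_label = "Q-B") {
  toks <- character(); fine <- character()
  if (stats::runif(1) < probs[["qualifier"]]) {
    toks <- sample(vocab$qualifiers, 1L)
    fine <- "QF-B"
  }
  toks <- c(toks, sample(vocab$qualities, 1L))
  fine <- c(fine, "Q-B")
  p1 <- c("Q-B", rep("Q-I", length(toks) - 1L))
  list(tokens = toks, phase1 = p1, fine = fine)
}

gen_anatomy_phrase <- function(vocab, probs) {
  toks <- character(); fine <- character()
  if (stats::runif(1) < probs[["coordinate"]]) {
    toks <- sample(vocab$coordinates, 1L)
    fine <- "PB"
    if (stats::runif(1) < probs[["second_coordinate"]]) {
      toks <- c(toks, sample(vocab$conjunctions, 1L),
                sample(setdiff(vocab$coordinates, toks), 1L))
      fine <- c(fine, "C-B", "PB")
    }
  }
  if (stats::runif(1) < probs[["part_form"]]) {
    toks <- c(toks, sample(vocab$parts, 1L))
    fine <- c(fine, "AP-B")
    conn <- split_term(vocab$anat_connective)
    toks <- c(toks, conn)
    fine <- c(fine, "C-B", rep("C-I", length(conn) - 1L))
  }
  main <- split_term(sample(vocab$mains, 1L))
  toks <- c(toks, main)
  fine <- c(fine, "A-B", rep("A-I", length(main) - 1L))
  list(tokens = toks,
       phase1 = c("A-B", rep("A-I", length(toks) - 1L)),
       fine = fine)
}

#' Generate a synthetic phase I corpus
#'
#' Draws descriptions from the template grammar (quality entities, an
#' anatomical phrase with optional coordinates and part-of structure, rare
#' connective clauses and outside tails, and occasional atomic
#' phenotypes). Gold BIO labels under the `phase1` scheme are emitted
#' alongside the tokens; the fine-grained phase II labels of each token
#' are attached as the `"fine_labels"` attribute of every sequence for
#' [derive_phase2()].
#'
#' @param config A [grammar_config()].
#' @return A [pheno_corpus()] under the `phase1` scheme.
#' @export
generate_phase1 <- function(config) {
  stopifnot(inherits(config, "grammar_config"))
  scheme <- label_scheme("phase1")
  vocab <- config$vocab
  probs <- config$slot_probs
  sequences <- with_seed(config$seed, {
    lapply(seq_len(config$n_descriptions), function(i) {
      toks <- character(); p1 <- character(); fine <- character()
      add <- function(piece) {
        toks <<- c(toks, piece$tokens)
        p1 <<- c(p1, piece$phase1)
        fine <<- c(fine, piece$fine)
      }
      if (stats::runif(1) < probs[["atomic"]]) {
        at <- split_term(sample(vocab$atomic, 1L))
        add(list(tokens = at,
                 phase1 = c("Q-B", rep("Q-I", length(at) - 1L)),
                 fine = c("Q-B", rep("Q-I", length(at) - 1L))))
      } else {
        add(gen_quality_entity(vocab, probs))
        if (stats::runif(1) < probs[["second_quality"]]) {
          if (stats::runif(1) < probs[["comma"]])
            add(list(tokens = ",", phase1 = "O", fine = NA_character_))
          add(gen_quality_entity(vocab, probs))
        }
        add(gen_anatomy_phrase(vocab, probs))
        if (stats::runif(1) < probs[["with_clause"]]) {
          add(list(tokens = vocab$clause_connective, phase1 = "C-B",
                   fine = NA_character_))
          add(gen_quality_entity(vocab, probs))
        }
        if (stats::runif(1) < probs[["o_tail"]]) {
          tail_toks <- split_term(sample(vocab$o_tails, 1L))
          add(list(tokens = tail_toks,
                   phase1 = rep("O", length(tail_toks)),
                   fine = rep(NA_character_, length(tail_toks))))
        }
      }
      s <- labeled_sequence(toks, p1, scheme, sprintf("syn%05d", i))
      attr(s, "fine_labels") <- fine
      s
    })
  })
  pheno_corpus(sequences, scheme)
}

#' Derive the two phase II corpora from a generated phase I corpus
#'
#' Extracts every anatomical (A) and quality (Q) segment, relabels its
#' tokens with the generator's fine-label bookkeeping (`"fine_labels"`
#' attribute), and de-duplicates segments by exact text, so each distinct
#' entity appears once per corpus.
#'
#' @param corpus A corpus produced by [generate_phase1()].
#' @return List with elements `anatomy` (corpus under `phase2_anatomy`)
#'   and `quality` (corpus under `phase2_quality`).
#' @export
derive_phase2 <- function(corpus) {
  stopifnot(inherits(corpus, "pheno_corpus"),
            corpus$scheme$name == "phase1")
  sc_a <- label_scheme("phase2_anatomy")
  sc_q <- label_scheme("phase2_quality")
  seen_a <- character(); seen_q <- character()
  seqs_a <- list(); seqs_q <- list()
  for (s in corpus$sequences) {
    fine <- attr(s, "fine_labels")
    if (is.null(fine))
      stop("derive_phase2(): corpus lacks fine-label bookkeeping ",
           "(not produced by generate_phase1())", call. = FALSE)
    segs <- segments_from_bio(s)
    for (i in seq_len(nrow(segs))) {
      cls <- segs$entity_class[i]
      if (!(cls %in% c("A", "Q"))) next
      idx <- (segs$start[i] + 1L):segs$end[i]
      text <- segs$text[i]
      if (cls == "A" && !(text %in% seen_a)) {
        seen_a <- c(seen_a, text)
        seqs_a[[length(seqs_a) + 1L]] <-
          labeled_sequence(s$tokens[idx], fine[idx], sc_a, text)
      } else if (cls == "Q" && !(text %in% seen_q)) {
        seen_q <- c(seen_q, text)
        seqs_q[[length(seqs_q) + 1L]] <-
          labeled_sequence(s$tokens[idx], fine[idx], sc_q, text)
      }
    }
  }
  list(anatomy = pheno_corpus(seqs_a, sc_a),
       quality = pheno_corpus(seqs_q, sc_q))
}

# deterministically thin a term list: drop every `keep_out`-th term of the
# sorted list, making fixture dictionaries informative but incomplete
thin_terms <- function(terms, keep_out = 4L) {
  terms <- sort(terms)
  terms[seq_along(terms) %% keep_out != 0L]
}

#' Fixture gazetteers and lexical table matching the synthetic grammar
#'
#' Gazetteers are built from the grammar vocabulary with every fourth term
#' deliberately dropped (real-world dictionaries never cover a corpus
#' fully); the lexical table records plural/inflected surfaces of the
#' vocabulary with their bases and categories.
#'
#' @param vocab A vocabulary list, see [default_vocab()].
#' @return A [seg_resources()].
#' @export
synthetic_resources <- function(vocab = default_vocab()) {
  gaz <- list(
    conjunctions = gazetteer(vocab$conjunctions, "conjunctions"),
    connections = gazetteer(c("of", "the", "in", "at", "with", "to"),
                            "connections"),
    coordinates = gazetteer(thin_terms(vocab$coordinates), "coordinates"),
    ordinals = gazetteer(c("1st", "2nd", "3rd", "4th", "5th", "first",
                           "second", "third", "fourth", "fifth"),
                         "ordinals"),
    anatomy = gazetteer(thin_terms(c(vocab$parts, vocab$mains)), "anatomy"),
    qualities = gazetteer(thin_terms(vocab$qualities), "qualities")
  )
  surfaces <- c(
    metaphyses = "metaphysis", epiphyses = "epiphysis",
    diaphyses = "diaphysis", metadiaphyses = "metadiaphysis",
    apophyses = "apophysis", trabeculae = "trabecula",
    vertebrae = "vertebra", ribs = "rib", clavicles = "clavicle",
    scapulae = "scapula", phalanges = "phalanx", metacarpals = "metacarpal",
    metatarsals = "metatarsal", bones = "bone", necks = "neck",
    wings = "wing", femur = "femur", tibia = "tibia", radius = "radius",
    ulna = "ulna", humerus = "humerus", pelvis = "pelvis", skull = "skull",
    cortex = "cortex", hand = "hand"
  )
  noun_cat <- rep("noun", length(surfaces))
  adj_surf <- c(irregular = "irregular", streaky = "streaky",
                long = "long", short = "short", broad = "broad",
                dense = "dense", proximal = "proximal", distal = "distal",
                lateral = "lateral", medial = "medial", central = "central",
                severe = "severe", mild = "mild")
  verb_surf <- c(flared = "flare", flaring = "flare", cupping = "cup")
  lex <- lexical_table(
    surface = c(names(surfaces), names(adj_surf), names(verb_surf)),
    base = c(unname(surfaces), unname(adj_surf), unname(verb_surf)),
    category = c(noun_cat, rep("adj", length(adj_surf)),
                 rep("verb", length(verb_surf)))
  )
  seg_resources(gazetteers = gaz, lexicon = lex)
}

#' Write the synthetic corpora and fixture resources to a directory
#'
#' Writes `phase1.tsv`, `anatomy.tsv`, `quality.tsv` (CoNLL-style), the six
#' gazetteer files `<name>.txt` and `lexicon.tsv`.
#'
#' @param dir Output directory (created if needed).
#' @param config A [grammar_config()].
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(dir, config = grammar_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_phase1(config)
  ph2 <- derive_phase2(corpus)
  write_corpus(corpus, file.path(dir, "phase1.tsv"))
  write_corpus(ph2$anatomy, file.path(dir, "anatomy.tsv"))
  write_corpus(ph2$quality, file.path(dir, "quality.tsv"))
  res <- synthetic_resources(config$vocab)
  for (nm in GAZETTEER_NAMES)
    writeLines(res$gazetteers[[nm]]$terms,
               file.path(dir, paste0(nm, ".txt")))
  lex <- res$lexicon
  writeLines(paste(lex$surface, lex$base, lex$category, sep = "\t"),
             file.path(dir, "lexicon.tsv"))
  invisible(dir)
}
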