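## Deterministic synthetic report corpus with gold annotations.
##
## Templates are modeled on the short declarative clause shapes the
## extractor targets; every instantiated sentence carries a hand-built gold
## parse tree and the gold triples/tags the pipeline must reproduce, so the
## whole pipeline is testable offline with no external parser or licensed
## vocabulary.

PATTERN_IDS <- c("P1", "P2", "P3", "P4", "SIMPLE", "PP_ONLY")

#' Specification for a synthetic fixture corpus
#'
#' @param seed Integer seed; the generator draws everything from one PRNG
#'   stream keyed by it, so equal seeds give byte-identical bundles.
#' @param n_documents Number of documents.
#' @param sentences_per_doc Integer range `c(lo, hi)` of sentences per
#'   document.
#' @param pattern_mix Named proportions over the six pattern ids; must sum
#'   to 1.
#' @param noise Fraction of entity phrases replaced by out-of-lexicon
#'   tokens (tagged `NONE` in gold).
#' @param disagreement Probability that the second simulated rater departs
#'   from the first on a unit.
#' @param ref_flip Probability that the raters' consensus departs from the
#'   machine's gold category (drives non-trivial precision/recall).
#' @param novel_tag_rate Probability a rater invents a relationship tag the
#'   model does not list (drives relationship coverage below 1).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_documents = 20L,
                         sentences_per_doc = c(3L, 5L),
                         pattern_mix = stats::setNames(rep(1 / 6, 6), PATTERN_IDS),
                         noise = 0.05, disagreement = 0.08,
                         ref_flip = 0.10, novel_tag_rate = 0.03) {
  if (is.null(names(pattern_mix)) || !all(names(pattern_mix) %in% PATTERN_IDS))
    stop("pattern_mix must be named with pattern ids: ",
         paste(PATTERN_IDS, collapse = ", "))
  if (abs(sum(pattern_mix) - 1) > 1e-8) stop("pattern_mix must sum to 1")
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  stopifnot(length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1L,
            sentences_per_doc[2] >= sentences_per_doc[1])
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 pattern_mix = pattern_mix[PATTERN_IDS[PATTERN_IDS %in%
                                                         names(pattern_mix)]],
                 noise = noise, disagreement = disagreement,
                 ref_flip = ref_flip, novel_tag_rate = novel_tag_rate),
            class = "fixture_spec")
}

np_node <- function(tokens) parse_tree("NP", lapply(tokens, function(t)
  parse_tree("NN", token = t)))

leaf <- function(tag, tok) parse_tree(tag, token = tok)

# one template instantiation: returns text, tree, gold triple rows and the
# per-slot gold types. Slots are character vectors of tokens; types their
# gold semantic types ("NONE" for noise slots).
instantiate <- function(pattern, slots, types, doc_id, seg) {
  s <- slots$S; o <- slots$O; o2 <- slots$O2
  s_txt <- paste(s, collapse = " ")
  o_txt <- paste(o, collapse = " ")
  rel_row <- function(subject, relation, object, pid, s_type, o_type)
    data.frame(doc_id = doc_id, segment_index = seg, pattern_id = pid,
               subject = subject, relation = relation, object = object,
               subject_type = s_type, object_type = o_type,
               stringsAsFactors = FALSE)
  if (pattern == "SIMPLE") {
    verb <- slots$verb
    tree <- parse_tree("S", list(np_node(s),
      parse_tree("VP", list(leaf("VBZ", verb), np_node(o)))))
    text <- paste(s_txt, verb, o_txt)
    gold <- rel_row(s_txt, verb, o_txt, "SIMPLE", types$S, types$O)
  } else if (pattern == "P1") {
    v <- slots$verb2  # c(aux, participle)
    tree <- parse_tree("S", list(np_node(s),
      parse_tree("VP", list(leaf("VBZ", v[1]),
        parse_tree("VP", list(leaf("VBN", v[2]), np_node(o)))))))
    text <- paste(s_txt, v[1], v[2], o_txt)
    gold <- rel_row(s_txt, paste(v, collapse = " "), o_txt, "P1",
                    types$S, types$O)
  } else if (pattern == "P2") {
    v <- slots$verb_prep  # c(verb, prep)
    tree <- parse_tree("S", list(np_node(s),
      parse_tree("VP", list(leaf("VBZ", v[1]),
        parse_tree("PP", list(leaf("IN", v[2]), np_node(o)))))))
    text <- paste(s_txt, v[1], v[2], o_txt)
    gold <- rel_row(s_txt, paste(v, collapse = " "), o_txt, "P2",
                    types$S, types$O)
  } else if (pattern == "P3") {
    v <- slots$verb3  # c(aux, participle, prep)
    tree <- parse_tree("S", list(np_node(s),
      parse_tree("VP", list(leaf("VBZ", v[1]),
        parse_tree("VP", list(leaf("VBN", v[2]),
          parse_tree("PP", list(leaf("IN", v[3]), np_node(o)))))))))
    text <- paste(s_txt, v[1], v[2], v[3], o_txt)
    gold <- rel_row(s_txt, paste(v, collapse = " "), o_txt, "P3",
                    types$S, types$O)
  } else if (pattern == "P4") {
    verb <- slots$verb
    prep <- slots$prep
    o2_txt <- paste(o2, collapse = " ")
    tree <- parse_tree("S", list(np_node(s),
      parse_tree("VP", list(leaf("VBD", verb), np_node(o),
        parse_tree("PP", list(leaf("IN", prep), np_node(o2)))))))
    text <- paste(s_txt, verb, o_txt, prep, o2_txt)
    comb <- paste(o_txt, prep, o2_txt)
    # last-recognizable rule on the combined span: the rightmost typed slot
    comb_type <- if (types$O2 != "NONE") types$O2 else types$O
    gold <- rbind(
      rel_row(s_txt, verb, comb, "P4", types$S, comb_type),
      rel_row(o_txt, prep, o2_txt, "PP_ONLY", types$O, types$O2))
  } else { # PP_ONLY
    prep <- slots$prep
    tree <- parse_tree("NP", list(np_node(s),
      parse_tree("PP", list(leaf("IN", prep), np_node(o)))))
    text <- paste(s_txt, prep, o_txt)
    gold <- rel_row(s_txt, prep, o_txt, "PP_ONLY", types$S, types$O)
  }
  list(text = text, tree = tree, gold = gold)
}

#' Generate a deterministic synthetic corpus with gold annotations
#'
#' Entity slots cycle through a seeded shuffle of the whole bundled
#' mini-lexicon, so with the default mix every pattern id and every semantic
#' category appears once `n_documents >= 20`. At `noise = 0`, running
#' [extract_sro()] and [tag_triples()] over the generated trees reproduces
#' the gold triples and tags exactly.
#'
#' @param spec A [fixture_spec()].
#' @param lexicon Lexicon used to fill entity slots (default
#'   [mini_lexicon()]).
#' @return A gold bundle: `documents` (list of [document()]), `trees`,
#'   `index` (doc_id, segment_index, line_number), `lexicon`,
#'   `gold_triples` (with gold types), `gold_tags`, `raters` (simulated
#'   annotation records), `relationship_tags`, `spec`.
#' @export
generate_fixtures <- function(spec = fixture_spec(), lexicon = mini_lexicon()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  terms <- names(lexicon)
  map <- default_category_map()

  queue <- character(0)
  next_term <- function() {
    if (length(queue) == 0L) queue <<- sample(terms)
    t <- queue[1L]; queue <<- queue[-1L]
    t
  }
  oov_i <- 0L
  draw_slot <- function() {
    if (spec$noise > 0 && stats::runif(1) < spec$noise) {
      oov_i <<- oov_i + 1L
      list(tokens = paste0("zqx", oov_i), type = "NONE")
    } else {
      t <- next_term()
      list(tokens = strsplit(t, " ", fixed = TRUE)[[1]],
           type = unname(lexicon[t]))
    }
  }

  verbs_simple <- c("shows", "reveals", "includes")
  verbs_p1 <- list(c("has", "become"), c("had", "become"))
  verbs_p2 <- list(c("presents", "with"), c("arises", "from"))
  verbs_p3 <- list(c("is", "associated", "with"), c("was", "complicated", "by"))
  verbs_p4 <- c("demonstrated", "showed")
  preps <- c("of", "in", "with")

  n_sents <- sample(seq.int(spec$sentences_per_doc[1], spec$sentences_per_doc[2]),
                    spec$n_documents, replace = TRUE)
  total <- sum(n_sents)
  mix <- spec$pattern_mix
  counts <- floor(mix * total)
  rem <- total - sum(counts)
  if (rem > 0) {
    frac <- mix * total - counts
    extra <- order(-frac)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  pattern_seq <- sample(rep(names(counts), counts))

  documents <- vector("list", spec$n_documents)
  trees <- list()
  index <- list()
  gold <- list()
  k <- 0L
  for (d in seq_len(spec$n_documents)) {
    doc_id <- sprintf("doc%03d", d)
    sent_texts <- character(n_sents[d])
    for (s in seq_len(n_sents[d])) {
      k <- k + 1L
      pat <- pattern_seq[k]
      S <- draw_slot(); O <- draw_slot()
      slots <- list(S = S$tokens, O = O$tokens, O2 = NULL,
                    verb = sample(if (pat == "P4") verbs_p4 else verbs_simple, 1),
                    verb2 = verbs_p1[[sample.int(length(verbs_p1), 1)]],
                    verb_prep = verbs_p2[[sample.int(length(verbs_p2), 1)]],
                    verb3 = verbs_p3[[sample.int(length(verbs_p3), 1)]],
                    prep = sample(preps, 1))
      types <- list(S = S$type, O = O$type, O2 = "NONE")
      if (pat == "P4") {
        O2 <- draw_slot()
        slots$O2 <- O2$tokens
        types$O2 <- O2$type
      }
      inst <- instantiate(pat, slots, types, doc_id, s - 1L)
      sent_texts[s] <- inst$text
      trees[[length(trees) + 1L]] <- inst$tree
      index[[length(index) + 1L]] <-
        data.frame(doc_id = doc_id, segment_index = s - 1L,
                   line_number = length(trees), stringsAsFactors = FALSE)
      gold[[length(gold) + 1L]] <- inst$gold
    }
    documents[[d]] <- document(doc_id, paste(sent_texts, collapse = ". "),
                               metadata = list(source = "synthetic"))
  }
  gold_triples <- do.call(rbind, gold)
  rownames(gold_triples) <- NULL

  # phrase-level gold tags: subject and object of every gold triple
  gt <- gold_triples
  gold_tags <- rbind(
    data.frame(doc_id = gt$doc_id, segment_index = gt$segment_index,
               role = "Subject", phrase = gt$subject,
               semantic_type = gt$subject_type, stringsAsFactors = FALSE),
    data.frame(doc_id = gt$doc_id, segment_index = gt$segment_index,
               role = "Object", phrase = gt$object,
               semantic_type = gt$object_type, stringsAsFactors = FALSE))
  gold_tags <- gold_tags[order(gold_tags$doc_id, gold_tags$segment_index,
                               gold_tags$role), , drop = FALSE]
  rownames(gold_tags) <- NULL

  # simulated rater annotations over phrase units
  cats <- attr(map, "categories")
  machine <- category_of(map, gold_tags$semantic_type)
  machine[gold_tags$semantic_type == "NONE"] <- "OUT_OF_MODEL"
  reference <- flip_labels(machine, spec$ref_flip, cats)
  rater2 <- flip_labels(reference, spec$disagreement, cats)
  raters <- data.frame(
    unit_id = paste(gold_tags$doc_id, gold_tags$segment_index,
                    seq_len(nrow(gold_tags)), sep = ":"),
    unit_kind = "phrase",
    machine_label = machine, rater1_label = reference,
    rater2_label = rater2, consensus_label = reference,
    stringsAsFactors = FALSE)

  # relationship tags per pair, from the default label table
  labels_df <- utils::read.delim(
    system.file("extdata", "default_labels.tsv", package = "sublangr",
                mustWork = TRUE), stringsAsFactors = FALSE, quote = "",
    comment.char = "#")
  subj_cat <- category_of(map, gt$subject_type)
  obj_cat <- category_of(map, gt$object_type)
  rel_tags <- vapply(seq_len(nrow(gt)), function(i) {
    hit <- labels_df$subject_category == subj_cat[i] &
      labels_df$object_category == obj_cat[i] &
      (labels_df$relation_surface == gt$relation[i] |
         !nzchar(labels_df$relation_surface))
    if (any(hit)) labels_df$label[which(hit)[1]] else "Related_to"
  }, character(1))
  novel <- stats::runif(nrow(gt)) < spec$novel_tag_rate
  rel_tags[novel] <- paste0("Unlisted_", seq_len(sum(novel)))

  structure(list(documents = documents, trees = trees,
                 index = do.call(rbind, index), lexicon = lexicon,
                 gold_triples = gold_triples, gold_tags = gold_tags,
                 raters = raters, relationship_tags = rel_tags,
                 spec = spec),
            class = "gold_bundle")
}

#' Simulate a second annotator departing at a fixed rate
#'
#' Each label is replaced, with probability `rate`, by a different label
#' drawn uniformly from `labels`; agreement with the input tends to
#' `1 - rate` as the list grows.
#'
#' @param x Character vector of labels.
#' @param rate Departure probability per unit.
#' @param labels Label universe to draw replacements from.
#' @return Character vector like `x`.
#' @export
flip_labels <- function(x, rate, labels) {
  if (rate <= 0) return(x)
  flip <- stats::runif(length(x)) < rate
  for (i in which(flip)) {
    alt <- setdiff(labels, x[i])
    x[i] <- alt[sample.int(length(alt), 1)]
  }
  x
}

#' Write a gold bundle to a directory of plain-text artifacts
#'
#' Writes `documents.jsonl`, `trees.ptb`, `index.tsv`, `lexicon.tsv`,
#' `gold_triples.tsv`, `gold_tags.tsv`, `raters.tsv`.
#'
#' @param bundle A gold bundle from [generate_fixtures()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_documents(bundle$documents, file.path(dir, "documents.jsonl"))
  write_ptb(bundle$trees, file.path(dir, "trees.ptb"))
  tsv <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)
  tsv(bundle$index, "index.tsv")
  tsv(data.frame(term = names(bundle$lexicon),
                 semantic_type = unname(bundle$lexicon),
                 stringsAsFactors = FALSE), "lexicon.tsv")
  tsv(bundle$gold_triples, "gold_triples.tsv")
  tsv(bundle$gold_tags, "gold_tags.tsv")
  tsv(bundle$raters, "raters.tsv")
  writeLines(bundle$relationship_tags, file.path(dir, "relationship_tags.txt"))
  invisible(dir)
}

#' The built-in worked example sentences with gold analyses
#'
#' Seven short radiology-style sentences, each with a hand-built gold parse
#' tree and the gold SRO triples the extractor must produce: the four
#' embedded-structure exemplars ("A has become B", "A present with B",
#' "A is associated with B", "A demonstrated a patient with previous
#' history"), two report sentences ("Serial IVU films showing widely
#' separated pubic bones with absent symphysis", "Complex L-transposition
#' of the great arteries with cardiac pacemaker"), and the existential
#' chain "There are foci of intensely increased radiotracer uptake in T9"
#' whose gold analysis is exactly three triples.
#'
#' @return A gold bundle (as [generate_fixtures()], without rater files).
#' @export
example_corpus <- function() {
  ptb <- c(
    "(S (NP (NN A)) (VP (VBZ has) (VP (VBN become) (NP (NN B)))))",
    "(S (NP (NN A)) (VP (VBP present) (PP (IN with) (NP (NN B)))))",
    "(S (NP (NN A)) (VP (VBZ is) (VP (VBN associated) (PP (IN with) (NP (NN B))))))",
    paste0("(S (NP (NN A)) (VP (VBD demonstrated) (NP (DT a) (NN patient)) ",
           "(PP (IN with) (NP (JJ previous) (NN history)))))"),
    paste0("(S (NP (JJ Serial) (NN IVU) (NNS films)) (VP (VBG showing) ",
           "(NP (NP (ADJP (RB widely) (VBN separated)) (JJ pubic) (NNS bones)) ",
           "(PP (IN with) (NP (JJ absent) (NN symphysis))))))"),
    paste0("(NP (NP (JJ Complex) (NN L-transposition)) (PP (IN of) ",
           "(NP (NP (DT the) (JJ great) (NNS arteries)) ",
           "(PP (IN with) (NP (JJ cardiac) (NN pacemaker))))))"),
    paste0("(S (NP (EX There)) (VP (VBP are) (NP (NP (NNS foci)) ",
           "(PP (IN of) (NP (NP (ADJP (RB intensely) (VBN increased)) ",
           "(NN radiotracer) (NN uptake)) (PP (IN in) (NP (NN T9))))))))"))
  trees <- read_ptb(ptb)
  texts <- vapply(trees, function(t) paste(tree_tokens(t), collapse = " "),
                  character(1))
  ids <- sprintf("ex%d", seq_along(trees))
  documents <- Map(document, ids, texts)
  g <- function(doc, pid, s, r, o)
    data.frame(doc_id = doc, segment_index = 0L, pattern_id = pid,
               subject = s, relation = r, object = o, stringsAsFactors = FALSE)
  gold_triples <- rbind(
    g("ex1", "P1", "A", "has become", "B"),
    g("ex2", "P2", "A", "present with", "B"),
    g("ex3", "P3", "A", "is associated with", "B"),
    g("ex4", "P4", "A", "demonstrated", "a patient with previous history"),
    g("ex4", "PP_ONLY", "a patient", "with", "previous history"),
    g("ex5", "SIMPLE", "Serial IVU films", "showing",
      "widely separated pubic bones"),
    g("ex5", "PP_ONLY", "widely separated pubic bones", "with",
      "absent symphysis"),
    g("ex6", "PP_ONLY", "Complex L-transposition", "of",
      "the great arteries with cardiac pacemaker"),
    g("ex6", "PP_ONLY", "the great arteries", "with", "cardiac pacemaker"),
    g("ex7", "SIMPLE", "There", "are", "foci"),
    g("ex7", "PP_ONLY", "foci", "of",
      "intensely increased radiotracer uptake in T9"),
    g("ex7", "PP_ONLY", "intensely increased radiotracer uptake", "in", "T9"))
  index <- data.frame(doc_id = ids, segment_index = 0L,
                      line_number = seq_along(trees), stringsAsFactors = FALSE)
  structure(list(documents = documents, trees = trees, index = index,
                 lexicon = mini_lexicon(), gold_triples = gold_triples),
            class = "gold_bundle")
}
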