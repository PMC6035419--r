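## Subject:Relationship:Object extraction from constituency parse trees.
##
## Entities are the *maximal* NP/ADJP nodes (no NP/ADJP ancestor). Relations
## come from four embedded verb-phrase structures plus a plain transitive
## pattern and a preposition-only pattern for verbless segments:
##
##   P1      NP + VP(V + VP(V + NP))             relation = "has become"
##   P2      NP + VP(V + PP(P + NP))             relation = "present with"
##   P3      NP + VP(V + VP(V + PP(P + NP)))     relation = "is associated with"
##   P4      NP + VP(V + NP + PP(P + NP))        relation = verb; object = NP+PP
##   SIMPLE  NP + VP(V + NP)                     relation = verb
##   PP_ONLY NP(NP + PP(P + NP))                 relation = preposition
##
## A PP nested *inside* an object NP leaves the verb's object as the NP core
## and spawns a PP_ONLY chain (so "There are foci of X in T9" yields three
## triples); a PP that is a *sibling* of the object NP (P4) is combined into
## the object span. Relation strings keep the tokens as found, preserving
## tense and inflection.

VERB_TAGS <- c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "MD")
PREP_TAGS <- c("IN", "TO")
ADV_TAGS <- c("RB", "RBR", "RBS")

node_label <- function(node) base_label(node$label)

phrase_span <- function(node, start, role = "Standalone") {
  list(text = paste(tree_tokens(node), collapse = " "),
       syntactic_label = node_label(node),
       start = start, end = start + n_leaves(node), role = role)
}

span_of <- function(tokens, start, end, label = "NP", role = "Standalone") {
  list(text = paste(tokens[seq.int(start + 1L, end)], collapse = " "),
       syntactic_label = label, start = start, end = end, role = role)
}

#' Extract maximal NP/ADJP entity phrases from a parse tree
#'
#' Returns every NP or ADJP node that is not dominated by another NP/ADJP,
#' in document order: an inner NP of a returned phrase is never returned
#' separately ("right breast pain" is one entity, not three).
#'
#' @param tree A [parse_tree()].
#' @return List of phrase spans: `text`, `syntactic_label`, half-open
#'   0-based token interval `start`/`end`, and `role` (`"Standalone"` here).
#' @export
find_entities <- function(tree) {
  recs <- tree_spans(tree)
  keep <- Filter(function(r) {
    !is_leaf(r$node) &&
      base_label(r$label) %in% c("NP", "ADJP") &&
      !any(r$ancestors %in% c("NP", "ADJP"))
  }, recs)
  keep <- keep[order(vapply(keep, function(r) r$start, integer(1)))]
  lapply(keep, function(r) phrase_span(r$node, r$start))
}

# -- internal helpers over positioned nodes ---------------------------------

# children of `node` together with their absolute token offsets
child_offsets <- function(node, offset) {
  out <- vector("list", length(node$children))
  for (i in seq_along(node$children)) {
    kid <- node$children[[i]]
    out[[i]] <- list(node = kid, start = offset, end = offset + n_leaves(kid))
    offset <- out[[i]]$end
  }
  out
}

is_prep_pp <- function(node) {
  node_label(node) == "PP" && length(node$children) >= 2L &&
    is_leaf(node$children[[1]]) && node_label(node$children[[1]]) %in% PREP_TAGS &&
    node_label(node$children[[length(node$children)]]) %in% c("NP", "ADJP")
}

# decompose an NP into (core span, list of positioned PP children):
# core = everything before the first PP child; an NP with no PP has itself
# as core. Used both for verb objects and for PP_ONLY chaining.
np_decompose <- function(np, start) {
  kids <- child_offsets(np, start)
  pp_idx <- which(vapply(kids, function(k) is_prep_pp(k$node), logical(1)))
  if (length(pp_idx) == 0L)
    return(list(core = list(node = np, start = start, end = start + n_leaves(np)),
                pps = list()))
  first_pp <- min(pp_idx)
  core_kids <- kids[seq_len(first_pp - 1L)]
  core_start <- start
  core_end <- if (first_pp > 1L) core_kids[[length(core_kids)]]$end else start
  # prefer the single NP child as the core node when the NP is (NP core)(PP ...)
  core_node <- if (first_pp == 2L && node_label(kids[[1]]$node) %in% c("NP", "ADJP"))
    kids[[1]]$node else np
  list(core = list(node = core_node, start = core_start, end = core_end),
       pps = kids[pp_idx])
}

new_triple <- function(subject, relation, object, pattern_id,
                       doc_id = NA_character_, segment_index = NA_integer_,
                       vp_span = NULL, object_full = NULL) {
  subject$role <- "Subject"; object$role <- "Object"
  structure(list(subject = subject, relation = relation, object = object,
                 modifiers = list(), pattern_id = pattern_id,
                 doc_id = doc_id, segment_index = segment_index,
                 vp_span = vp_span,
                 object_full = object_full %||% c(object$start, object$end)),
            class = "sro_triple")
}

# Emit the PP chain hanging off a core span: (core, prep, full-PP-NP), then
# recurse into the PP's NP. Objects of chain triples are full spans.
pp_chain <- function(core_span, pps, tokens, doc_id, segment_index) {
  triples <- list()
  for (pp in pps) {
    kids <- child_offsets(pp$node, pp$start)
    prep_toks <- character(0)
    obj <- NULL
    for (k in kids) {
      if (is_leaf(k$node) && node_label(k$node) %in% PREP_TAGS)
        prep_toks <- c(prep_toks, k$node$token)
      else if (node_label(k$node) %in% c("NP", "ADJP") && is.null(obj)) obj <- k
    }
    if (is.null(obj) || length(prep_toks) == 0L) next
    obj_span <- span_of(tokens, obj$start, obj$end, node_label(obj$node))
    triples[[length(triples) + 1L]] <-
      new_triple(core_span, paste(prep_toks, collapse = " "), obj_span,
                 "PP_ONLY", doc_id, segment_index,
                 vp_span = c(pp$start, pp$end))
    dec <- np_decompose(obj$node, obj$start)
    if (length(dec$pps) > 0L) {
      inner_core <- span_of(tokens, dec$core$start, dec$core$end,
                            node_label(dec$core$node))
      triples <- c(triples, pp_chain(inner_core, dec$pps, tokens,
                                     doc_id, segment_index))
    }
  }
  triples
}

# leading verb tokens among a VP's children (adverbs interleave freely);
# returns list(tokens, rest) where rest holds the phrasal complements
leading_verbs <- function(kids) {
  toks <- character(0)
  i <- 1L
  while (i <= length(kids)) {
    nd <- kids[[i]]$node
    lb <- node_label(nd)
    if (is_leaf(nd) && lb %in% VERB_TAGS) {
      toks <- c(toks, nd$token)
    } else if (!((is_leaf(nd) && lb %in% ADV_TAGS) || lb == "ADVP")) break
    i <- i + 1L
  }
  rest <- if (i <= length(kids)) kids[seq.int(i, length(kids))] else list()
  rest <- Filter(function(k) {
    lb <- node_label(k$node)
    if (is_leaf(k$node)) lb %in% PREP_TAGS else lb != "ADVP"
  }, rest)
  list(verbs = toks, rest = rest)
}

# Extract triples for one VP given its subject span. Pattern precedence is
# structural and most-specific-first: P3 > P1 > P2 > P4 > SIMPLE.
vp_extract <- function(vp, vp_start, subject, tokens, doc_id, segment_index) {
  vp_end <- vp_start + n_leaves(vp)
  lv <- leading_verbs(child_offsets(vp, vp_start))
  verbs <- lv$verbs
  rest <- lv$rest
  # flatten nested VPs, accumulating the verb chain ("is associated", "has become")
  while (length(rest) >= 1L && node_label(rest[[1]]$node) == "VP") {
    inner <- leading_verbs(child_offsets(rest[[1]]$node, rest[[1]]$start))
    if (length(inner$verbs) == 0L) break
    verbs <- c(verbs, inner$verbs)
    rest <- inner$rest
  }
  nested <- length(verbs) > 1L
  if (length(verbs) == 0L || length(rest) == 0L) return(list())
  mk <- function(rel, obj_span, pattern)
    new_triple(subject, rel, obj_span, pattern, doc_id, segment_index,
               vp_span = c(vp_start, vp_end))
  first <- rest[[1]]
  flab <- node_label(first$node)
  triples <- list()
  if (flab == "PP" && is_prep_pp(first$node)) {
    # P3 (verb chain + PP) or P2 (single verb + PP): relation = verbs + prep
    pk <- child_offsets(first$node, first$start)
    prep <- pk[[1]]$node$token
    objk <- pk[[which(vapply(pk, function(k)
      node_label(k$node) %in% c("NP", "ADJP"), logical(1)))[1]]]
    obj_span <- span_of(tokens, objk$start, objk$end, node_label(objk$node))
    rel <- paste(c(verbs, prep), collapse = " ")
    triples[[1]] <- mk(rel, obj_span, if (nested) "P3" else "P2")
    dec <- np_decompose(objk$node, objk$start)
    if (length(dec$pps) > 0L) {
      inner_core <- span_of(tokens, dec$core$start, dec$core$end,
                            node_label(dec$core$node))
      triples <- c(triples, pp_chain(inner_core, dec$pps, tokens,
                                     doc_id, segment_index))
    }
  } else if (flab %in% c("NP", "ADJP")) {
    sibling_pp <- if (length(rest) >= 2L && is_prep_pp(rest[[2]]$node)) rest[[2]]
    if (!nested && !is.null(sibling_pp)) {
      # P4: postpositive structure; object = combined NP + PP span
      comb <- span_of(tokens, first$start, sibling_pp$end, "NP")
      triples[[1]] <- mk(paste(verbs, collapse = " "), comb, "P4")
      dec <- np_decompose(first$node, first$start)
      core <- span_of(tokens, dec$core$start, dec$core$end,
                      node_label(dec$core$node))
      triples <- c(triples, pp_chain(core, list(sibling_pp), tokens,
                                     doc_id, segment_index))
      if (length(dec$pps) > 0L)
        triples <- c(triples, pp_chain(core, dec$pps, tokens,
                                       doc_id, segment_index))
    } else {
      # P1 (verb chain + NP) or SIMPLE (verb + NP); object = NP core,
      # nested PPs chain off it
      dec <- np_decompose(first$node, first$start)
      core <- span_of(tokens, dec$core$start, dec$core$end,
                      node_label(dec$core$node))
      triples[[1]] <- new_triple(subject, paste(verbs, collapse = " "), core,
                                 if (nested) "P1" else "SIMPLE",
                                 doc_id, segment_index,
                                 vp_span = c(vp_start, vp_end),
                                 object_full = c(first$start, first$end))
      if (length(dec$pps) > 0L)
        triples <- c(triples, pp_chain(core, dec$pps, tokens,
                                       doc_id, segment_index))
    }
  }
  triples
}

#' Extract Subject:Relationship:Object triples from a parsed segment
#'
#' Applies the embedded-structure patterns in most-specific-first order
#' (P3 > P1 > P2 > P4 > SIMPLE > PP_ONLY) to a parse tree of one short
#' sentence segment; see the file-level notes for the pattern shapes. A
#' segment with no match yields an empty list.
#'
#' @param tree A [parse_tree()] of a sentence segment.
#' @param doc_id,segment_index Provenance carried into each triple.
#' @return List of `sro_triple` objects: `subject`, `relation`, `object`,
#'   `modifiers`, `pattern_id`, provenance.
#' @examples
#' tr <- read_ptb("(S (NP (NN A)) (VP (VBZ is) (VP (VBN associated) (PP (IN with) (NP (NN B))))))")[[1]]
#' extract_sro(tr)[[1]]$relation  # "is associated with"
#' @export
extract_sro <- function(tree, doc_id = NA_character_, segment_index = NA_integer_) {
  tokens <- tree_tokens(tree)
  triples <- list()
  found_clause <- FALSE
  walk <- function(node, offset, in_entity) {
    if (is_leaf(node)) return(invisible(NULL))
    kids <- child_offsets(node, offset)
    labs <- vapply(kids, function(k) node_label(k$node), character(1))
    vp_idx <- which(labs == "VP")
    if (!in_entity && length(vp_idx) > 0L) {
      for (vi in vp_idx) {
        subj_idx <- which(labs %in% c("NP", "ADJP"))
        subj_idx <- subj_idx[subj_idx < vi]
        if (length(subj_idx) == 0L) next
        si <- max(subj_idx)
        subj <- span_of(tokens, kids[[si]]$start, kids[[si]]$end, labs[si])
        got <- vp_extract(kids[[vi]]$node, kids[[vi]]$start, subj, tokens,
                          doc_id, segment_index)
        if (length(got) > 0L) {
          triples <<- c(triples, got)
          found_clause <<- TRUE
        }
      }
      if (found_clause) return(invisible(NULL))
    }
    for (k in kids)
      walk(k$node, k$start,
           in_entity || node_label(k$node) %in% c("NP", "ADJP"))
  }
  walk(tree, 0L, FALSE)
  if (!found_clause) {
    # verbless segment: PP_ONLY chain from the top maximal NP
    for (ent_rec in tree_spans(tree)) {
      r <- ent_rec
      if (is_leaf(r$node) || !(base_label(r$label) %in% c("NP", "ADJP"))) next
      if (any(r$ancestors %in% c("NP", "ADJP"))) next
      dec <- np_decompose(r$node, r$start)
      if (length(dec$pps) == 0L) next
      core <- span_of(tokens, dec$core$start, dec$core$end,
                      node_label(dec$core$node))
      triples <- c(triples, pp_chain(core, dec$pps, tokens,
                                     doc_id, segment_index))
    }
  }
  triples <- Filter(function(t) t$subject$start < t$object$start, triples)
  triples
}

#' Attach adverb modifiers to extracted triples
#'
#' Each adverb leaf (RB/RBR/RBS, including those under ADVP) is attached,
#' per triple, to the role whose span contains it: inside the subject span
#' it modifies the Subject, inside the object span the Object, and inside the
#' matched VP (but outside both entity spans) the Relationship. Adverbs that
#' fall outside every matched triple are dropped.
#'
#' @param tree The [parse_tree()] the triples came from.
#' @param triples List of `sro_triple` objects from [extract_sro()].
#' @return The triples, with `modifiers` filled: list of
#'   `list(token, attachment)` with attachment in Subject/Relationship/Object.
#' @export
attach_adverbs <- function(tree, triples) {
  advs <- Filter(function(r) is_leaf(r$node) &&
                   base_label(r$label) %in% ADV_TAGS, tree_spans(tree))
  if (length(advs) == 0L || length(triples) == 0L) return(triples)
  for (ti in seq_along(triples)) {
    tr <- triples[[ti]]
    mods <- list()
    for (a in advs) {
      pos <- a$start
      att <- NULL
      obj_lo <- if (!is.null(tr$object_full)) tr$object_full[1] else tr$object$start
      obj_hi <- if (!is.null(tr$object_full)) tr$object_full[2] else tr$object$end
      if (pos >= tr$subject$start && pos < tr$subject$end) att <- "Subject"
      else if (pos >= obj_lo && pos < obj_hi) att <- "Object"
      else if (!is.null(tr$vp_span) && pos >= tr$vp_span[1] && pos < tr$vp_span[2])
        att <- "Relationship"
      if (!is.null(att))
        mods[[length(mods) + 1L]] <- list(token = a$node$token, attachment = att)
    }
    triples[[ti]]$modifiers <- mods
  }
  triples
}

#' Tabulate triples for TSV/JSON-lines export
#'
#' @param triples List of `sro_triple` objects.
#' @return `data.frame` with columns `doc_id`, `segment_index`, `pattern_id`,
#'   `subject`, `relation`, `object`, `modifiers` (JSON list).
#' @export
triples_to_df <- function(triples) {
  if (length(triples) == 0L)
    return(data.frame(doc_id = character(0), segment_index = integer(0),
                      pattern_id = character(0), subject = character(0),
                      relation = character(0), object = character(0),
                      modifiers = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(triples, function(t) {
    mods <- if (length(t$modifiers) == 0L) "[]" else
      as.character(jsonlite::toJSON(lapply(t$modifiers, function(m)
        list(token = m$token, attachment = m$attachment)), auto_unbox = TRUE))
    data.frame(doc_id = t$doc_id, segment_index = t$segment_index,
               pattern_id = t$pattern_id, subject = t$subject$text,
               relation = t$relation, object = t$object$text,
               modifiers = mods, stringsAsFactors = FALSE)
  }))
}
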