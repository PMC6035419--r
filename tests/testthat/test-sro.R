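test_that("find_entities returns maximal NP/ADJP phrases only", {
  # inner NP "breast pain" dominated by the full NP: one entity
  tr <- read_ptb(paste0("(S (NP (JJ right) (NP (NN breast) (NN pain))) ",
                        "(VP (VBZ persists)))"))[[1]]
  ents <- find_entities(tr)
  expect_length(ents, 1L)
  expect_equal(ents[[1]]$text, "right breast pain")
  expect_equal(ents[[1]]$syntactic_label, "NP")

  expect_length(find_entities(read_ptb("(S (VP (VBZ is)))")[[1]]), 0L)

  # sibling NPs are both maximal, in document order
  tr <- read_ptb("(S (NP (NN erythema)) (NP (NN oedema)))")[[1]]
  ents <- find_entities(tr)
  expect_equal(vapply(ents, `[[`, character(1), "text"),
               c("erythema", "oedema"))

  # an ADJP under an NP is not returned separately
  tr <- read_ptb(paste0("(NP (NP (ADJP (RB widely) (VBN separated)) ",
                        "(NNS bones)) (PP (IN with) (NP (NN symphysis))))"))[[1]]
  expect_equal(vapply(find_entities(tr), `[[`, character(1), "text"),
               "widely separated bones with symphysis")
})

test_that("the worked example sentences reproduce their gold extractions", {
  bundle <- example_corpus()
  for (doc in unique(bundle$index$doc_id)) {
    line <- bundle$index$line_number[bundle$index$doc_id == doc]
    got <- triples_to_df(extract_all(bundle$trees[[line]], doc, 0L))
    want <- bundle$gold_triples[bundle$gold_triples$doc_id == doc, ,
                                drop = FALSE]
    cols <- c("pattern_id", "subject", "relation", "object")
    expect_equal(got[, cols], want[, cols], ignore_attr = TRUE,
                 label = paste("extraction for", doc))
  }
})

test_that("triple invariants hold on generated fixtures", {
  spec <- fixture_spec(seed = 11, n_documents = 15, noise = 0)
  b <- suppressMessages(generate_fixtures(spec))
  for (i in seq_len(nrow(b$index))) {
    tree <- b$trees[[b$index$line_number[i]]]
    toks <- tree_tokens(tree)
    for (tr in extract_sro(tree)) {
      # subject precedes object; spans never overlap
      expect_lt(tr$subject$start, tr$object$start)
      expect_lte(tr$subject$end, tr$object$start)
      # phrase text equals the space-joined tokens of its span
      expect_equal(tr$subject$text,
                   paste(toks[(tr$subject$start + 1):tr$subject$end],
                         collapse = " "))
      expect_equal(tr$object$text,
                   paste(toks[(tr$object$start + 1):tr$object$end],
                         collapse = " "))
      # the relation is a contiguous token subsequence between the entities
      gap <- toks[setdiff(seq.int(tr$subject$end + 1, tr$object$start),
                          integer(0))]
      rel_toks <- strsplit(tr$relation, " ", fixed = TRUE)[[1]]
      expect_true(all(rel_toks %in% gap))
      expect_match(paste(gap, collapse = " "), tr$relation, fixed = TRUE)
    }
  }
})

test_that("pattern precedence agrees with exhaustive shape enumeration", {
  set.seed(23)
  for (i in 1:200) {
    tree <- random_clause_tree()
    expect_lte(length(tree_tokens(tree)), 12L)
    got <- extract_sro(tree)
    want <- brute_pattern(tree)
    if (is.na(want)) {
      # verbless tree: only PP_ONLY triples allowed
      pids <- vapply(got, `[[`, character(1), "pattern_id")
      expect_true(all(pids == "PP_ONLY"))
    } else {
      expect_gt(length(got), 0L)
      expect_equal(got[[1]]$pattern_id, want,
                   label = paste("precedence on", write_ptb(list(tree))))
    }
  }
})

test_that("a tree matching both P2 and P3 shapes resolves to P3", {
  # outer VP: verb + inner VP(verb + PP) is P3; the inner VP alone is P2
  tr <- read_ptb(paste0("(S (NP (NN A)) (VP (VBZ is) (VP (VBN associated) ",
                        "(PP (IN with) (NP (NN B))))))"))[[1]]
  got <- extract_sro(tr)
  expect_length(got, 1L)
  expect_equal(got[[1]]$pattern_id, "P3")
  expect_equal(got[[1]]$relation, "is associated with")
})

test_that("adverbs attach to the role whose span contains them", {
  bundle <- example_corpus()
  line <- bundle$index$line_number[bundle$index$doc_id == "ex5"]
  got <- extract_all(bundle$trees[[line]], "ex5", 0L)
  expect_equal(got[[1]]$modifiers[[1]],
               list(token = "widely", attachment = "Object"))
  expect_equal(got[[2]]$modifiers[[1]],
               list(token = "widely", attachment = "Subject"))

  # no adverbs -> no modifiers
  tr <- read_ptb("(S (NP (NN A)) (VP (VBZ shows) (NP (NN B))))")[[1]]
  expect_length(extract_all(tr)[[1]]$modifiers, 0L)

  # adverb directly under the matched VP modifies the Relationship
  tr <- read_ptb(paste0("(S (NP (NN A)) (VP (RB clearly) (VBZ shows) ",
                        "(NP (NN B))))"))[[1]]
  got <- extract_all(tr)
  expect_equal(got[[1]]$relation, "shows")
  expect_equal(got[[1]]$modifiers[[1]],
               list(token = "clearly", attachment = "Relationship"))

  # negation is treated as a Relationship modifier
  tr <- read_ptb(paste0("(S (NP (NN lesion)) (VP (VBZ does) (RB not) ",
                        "(VP (VB enhance) (NP (NN contrast)))))"))[[1]]
  got <- extract_all(tr)
  mods <- got[[1]]$modifiers
  expect_true(any(vapply(mods, function(m) m$token == "not" &&
                           m$attachment == "Relationship", logical(1))))
})
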