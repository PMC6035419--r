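test_that("segmentation splits on punctuation and word delimiters", {
  segs <- segment_text(document("d1",
    "Haemangiomas are benign vascular tumors, complications include vessel thrombosis"))
  expect_equal(segs$text,
               c("Haemangiomas are benign vascular tumors",
                 "complications include vessel thrombosis"))
  expect_equal(segs$segment_index, c(0L, 1L))

  expect_equal(nrow(segment_text(document("d2", ""))), 0L)

  segs <- segment_text(document("d3", "mass measuring 2.5 cm and tenderness"))
  expect_equal(segs$text, c("mass measuring 2.5 cm", "tenderness"))
})

test_that("word splitters match whole tokens only and protections hold", {
  # "android" must not split on "and"
  segs <- segment_text(document("d", "android device in situ"))
  expect_equal(segs$text, "android device in situ")

  # abbreviation period and ratio colon are protected
  segs <- segment_text(document("d", "seen on T. spine view at 1:30 scale"))
  expect_equal(nrow(segs), 1L)

  # multi-word splitter fires as a unit
  segs <- segment_text(document("d", "a lesion with which we are familiar"))
  expect_equal(segs$text, c("a lesion", "we are familiar"))

  # "that" and ";" also split by default
  segs <- segment_text(document("d", "a mass that enhances; no oedema"))
  expect_equal(segs$text, c("a mass", "enhances", "no oedema"))
})

test_that("segment spans are in-bounds, ordered, non-overlapping, idempotent", {
  set.seed(42)
  texts <- c(
    "There are foci of uptake in T9, likely metastatic. Review advised",
    "CT scan of the abdomen and pelvis: unremarkable",
    "lesion measuring 3.2 cm which enhances, and a cyst")
  for (tx in texts) {
    doc <- document("d", tx)
    segs <- segment_text(doc)
    expect_true(all(segs$start >= 0 & segs$end <= nchar(tx)))
    expect_true(all(diff(segs$start) > 0))
    expect_true(all(segs$end > segs$start))
    if (nrow(segs) > 1)
      expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
    expect_lte(sum(nchar(segs$text)), nchar(tx))
    # spans address the original text
    for (i in seq_len(nrow(segs)))
      expect_equal(substr(tx, segs$start[i] + 1, segs$end[i]), segs$text[i])
    # idempotence: re-segmenting any segment yields itself alone
    for (s in segs$text) {
      again <- segment_text(document("d", s))
      expect_equal(again$text, s)
    }
  }
})

test_that("read_ptb parses bracketed trees and reports unbalanced input", {
  trees <- read_ptb("(S (NP (DT A)))")
  expect_length(trees, 1L)
  expect_equal(trees[[1]]$label, "S")
  expect_length(trees[[1]]$children, 1L)
  expect_equal(tree_tokens(trees[[1]]), "A")

  expect_error(read_ptb("(S (NP (DT A)"), "line 1")
  expect_error(read_ptb(c("(S (NN a))", "(S (NN b)) extra")), "line 2")

  three <- c("(S (NN a))", "(S (NN b))", "(S (NN c))")
  expect_equal(vapply(read_ptb(three), tree_tokens, character(1)),
               c("a", "b", "c"))

  expect_warning(got <- read_ptb(c("(S (NN a))", "", "(S (NN b))")), "empty")
  expect_length(got, 2L)
})

test_that("write_ptb round-trips, escapes brackets, rejects invalid nodes", {
  expect_equal(write_ptb(list()), character(0))

  paren <- parse_tree("S", list(parse_tree("SYM", token = "(")))
  line <- write_ptb(list(paren))
  expect_match(line, "-LRB-", fixed = TRUE)
  expect_equal(read_ptb(line)[[1]]$children[[1]]$token, "(")

  # children XOR token is enforced at construction
  expect_error(parse_tree("NP"), "children XOR")
  expect_error(parse_tree("NP", children = list(parse_tree("NN", token = "a")),
                          token = "b"), "children XOR")

  set.seed(7)
  for (i in 1:40) {
    tr <- random_ptb_tree()
    line <- write_ptb(list(tr))
    back <- read_ptb(line)[[1]]
    expect_identical(write_ptb(list(back)), line)
    expect_identical(tree_tokens(back), tree_tokens(tr))
  }
})

test_that("documents round-trip through JSON-lines and .txt directories", {
  docs <- list(document("a", "first report. second clause",
                        metadata = list(modality = "CT")),
               document("b", ""))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_documents(docs, path)
  back <- read_documents(path)
  expect_equal(back[[1]]$doc_id, "a")
  expect_equal(back[[1]]$text, docs[[1]]$text)
  expect_equal(back[[1]]$metadata$modality, "CT")
  expect_equal(back[[2]]$text, "")

  dir <- withr::local_tempdir()
  writeLines("some text", file.path(dir, "case1.txt"))
  got <- read_documents(dir)
  expect_equal(got[[1]]$doc_id, "case1")
  expect_equal(got[[1]]$text, "some text")

  expect_error(segment_corpus(list(document("x", "a"), document("x", "b"))),
               "duplicate")
})
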