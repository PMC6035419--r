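# Independent oracles and random-case generators. Everything here is written
# against the *definitions* (exhaustive enumeration, direct shape predicates),
# not against the package's implementation paths.

quiet_lexicon <- function() suppressMessages(mini_lexicon())

# ---- brute-force window-search tagger ------------------------------------

brute_tag <- function(text, lexicon, scan = "rightmost-end") {
  toks <- strsplit(normalize_term(text), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(list(type = "NONE", term = ""))
  grid <- expand.grid(i = seq_along(toks), j = seq_along(toks))
  grid <- grid[grid$i <= grid$j, , drop = FALSE]
  grid$key <- mapply(function(i, j) paste(toks[i:j], collapse = " "),
                     grid$i, grid$j)
  grid <- grid[grid$key %in% names(lexicon), , drop = FALSE]
  if (nrow(grid) == 0L) return(list(type = "NONE", term = ""))
  grid <- if (scan == "rightmost-end") grid[grid$j == max(grid$j), , drop = FALSE]
          else grid[grid$i == max(grid$i), , drop = FALSE]
  pick <- grid[which.max(grid$j - grid$i), , drop = FALSE]
  list(type = unname(lexicon[pick$key]), term = pick$key)
}

random_phrase <- function(lexicon, max_tokens = 8) {
  vocab <- unique(unlist(strsplit(names(lexicon), " ", fixed = TRUE)))
  junk <- c("xq1", "zzv", "blorp", "qwt")
  n <- sample.int(max_tokens, 1)
  paste(sample(c(vocab, junk), n, replace = TRUE), collapse = " ")
}

# ---- direct shape predicates for pattern precedence ----------------------

bl <- function(node) if (startsWith(node$label, "-")) node$label else
  sub("[-=].*$", "", node$label)
lf <- function(node) !is.null(node$token)
vtags <- c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "MD")

strip_adv <- function(kids) Filter(function(k)
  !((lf(k) && bl(k) %in% c("RB", "RBR", "RBS")) || bl(k) == "ADVP"), kids)

is_v <- function(k) lf(k) && bl(k) %in% vtags
is_np <- function(k) !lf(k) && bl(k) %in% c("NP", "ADJP")
is_pp <- function(k) {
  if (lf(k) || bl(k) != "PP") return(FALSE)
  kk <- strip_adv(k$children)
  length(kk) >= 2L && lf(kk[[1]]) && bl(kk[[1]]) %in% c("IN", "TO") &&
    is_np(kk[[length(kk)]])
}

# which of the five verb-headed shapes does this VP node match?
vp_shapes <- function(vp) {
  kk <- strip_adv(vp$children)
  out <- character(0)
  nverb <- 0L
  while (nverb < length(kk) && is_v(kk[[nverb + 1L]])) nverb <- nverb + 1L
  if (nverb == 0L) return(out)
  rest <- kk[seq.int(nverb + 1L, length.out = length(kk) - nverb)]
  if (length(rest) >= 1L && !lf(rest[[1]]) && bl(rest[[1]]) == "VP") {
    ik <- strip_adv(rest[[1]]$children)
    nv2 <- 0L
    while (nv2 < length(ik) && is_v(ik[[nv2 + 1L]])) nv2 <- nv2 + 1L
    irest <- ik[seq.int(nv2 + 1L, length.out = length(ik) - nv2)]
    if (nv2 > 0L && length(irest) >= 1L) {
      if (is_pp(irest[[1]])) out <- c(out, "P3")
      if (is_np(irest[[1]])) out <- c(out, "P1")
    }
  }
  if (length(rest) >= 1L && is_pp(rest[[1]])) out <- c(out, "P2")
  if (length(rest) >= 2L && is_np(rest[[1]]) && is_pp(rest[[2]]))
    out <- c(out, "P4")
  if (length(rest) >= 1L && is_np(rest[[1]])) out <- c(out, "SIMPLE")
  out
}

# highest-precedence pattern for the first clause VP of a tree, or NA
brute_pattern <- function(tree) {
  precedence <- c("P3", "P1", "P2", "P4", "SIMPLE")
  find_vp <- function(node) {
    if (lf(node)) return(NULL)
    labs <- vapply(node$children, bl, character(1))
    vi <- which(labs == "VP")
    ni <- which(labs %in% c("NP", "ADJP"))
    if (length(vi) > 0L && any(ni < vi[1])) return(node$children[[vi[1]]])
    for (k in node$children) {
      got <- find_vp(k)
      if (!is.null(got)) return(got)
    }
    NULL
  }
  vp <- find_vp(tree)
  if (is.null(vp)) return(NA_character_)
  got <- vp_shapes(vp)
  if (length(got) == 0L) return(NA_character_)
  precedence[min(match(got, precedence))]
}

# ---- random tree generators ----------------------------------------------

leafn <- function(tag, tok) parse_tree(tag, token = tok)
np_of <- function(...) parse_tree("NP", lapply(c(...), function(t) leafn("NN", t)))

# random clause tree over the known shapes (<= 12 leaves), with optional
# adverbs sprinkled in; used for the precedence-equivalence property
random_clause_tree <- function() {
  w <- function(n) paste0("w", sample.int(99, n))
  subj <- np_of(w(sample.int(2, 1)))
  maybe_adv <- function(kids) {
    if (stats::runif(1) < 0.3)
      append(kids, list(leafn("RB", "quickly")), after = sample(0:1, 1))
    else kids
  }
  shape <- sample(c("P1", "P2", "P3", "P4", "SIMPLE", "NOVERB"), 1)
  vp <- switch(shape,
    P1 = parse_tree("VP", maybe_adv(list(leafn("VBZ", "has"),
           parse_tree("VP", list(leafn("VBN", "grown"), np_of(w(2))))))),
    P2 = parse_tree("VP", maybe_adv(list(leafn("VBZ", "presents"),
           parse_tree("PP", list(leafn("IN", "with"), np_of(w(2))))))),
    P3 = parse_tree("VP", maybe_adv(list(leafn("VBZ", "is"),
           parse_tree("VP", list(leafn("VBN", "linked"),
             parse_tree("PP", list(leafn("IN", "to"), np_of(w(2))))))))),
    P4 = parse_tree("VP", maybe_adv(list(leafn("VBD", "showed"), np_of(w(2)),
           parse_tree("PP", list(leafn("IN", "with"), np_of(w(1))))))),
    SIMPLE = parse_tree("VP", maybe_adv(list(leafn("VBZ", "shows"),
               np_of(w(sample.int(3, 1)))))),
    NOVERB = NULL)
  if (is.null(vp))
    parse_tree("NP", list(np_of(w(2)),
      parse_tree("PP", list(leafn("IN", "of"), np_of(w(2))))))
  else parse_tree("S", list(subj, vp))
}

# arbitrary labeled tree for serialization round-trips (depth <= 8)
random_ptb_tree <- function(depth = 1) {
  labels <- c("S", "NP", "VP", "PP", "X", "FRAG")
  tags <- c("NN", "VBZ", "IN", "JJ", "SYM")
  toks <- c("a", "b2", "T9", "x-y", "(", ")", "{", "50%")
  if (depth >= 8 || stats::runif(1) < 0.35)
    return(parse_tree(sample(tags, 1), token = sample(toks, 1)))
  parse_tree(sample(labels, 1),
             children = lapply(seq_len(sample.int(3, 1)),
                               function(i) random_ptb_tree(depth + 1)))
}

# extract + adverbs in one call
extract_all <- function(tree, doc_id = NA_character_, seg = NA_integer_) {
  attach_adverbs(tree, extract_sro(tree, doc_id, seg))
}
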