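#' Construct a constituency parse-tree node
#'
#' A parse tree is an ordered, rooted, labeled tree: internal nodes carry a
#' Penn-Treebank constituent or POS label and an ordered list of children;
#' leaves carry a label (the POS tag) and a single token. A node has children
#' or a token, never both.
#'
#' @param label Constituent or POS label (nonempty string).
#' @param children List of `parse_tree` children, or `NULL` for a leaf.
#' @param token Token string for a leaf node, or `NULL` for an internal node.
#' @return An object of class `parse_tree`.
#' @examples
#' parse_tree("S", list(parse_tree("NP", list(parse_tree("DT", token = "A")))))
#' @export
parse_tree <- function(label, children = NULL, token = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a nonempty string")
  has_children <- !is.null(children) && length(children) > 0L
  has_token <- !is.null(token)
  if (has_children == has_token)
    stop("a parse_tree node must have children XOR a token (label '", label, "')")
  if (has_token && (!is.character(token) || length(token) != 1L))
    stop("'token' must be a single string")
  if (has_children) {
    ok <- vapply(children, inherits, logical(1), what = "parse_tree")
    if (!all(ok)) stop("all children must be parse_tree objects")
  }
  structure(list(label = label, children = if (has_children) children,
                 token = if (has_token) token),
            class = "parse_tree")
}

#' @export
print.parse_tree <- function(x, ...) {
  cat(format_ptb(x), "\n")
  invisible(x)
}

is_leaf <- function(node) !is.null(node$token)

#' Leaf tokens of a parse tree, left to right
#'
#' @param tree A `parse_tree`.
#' @return Character vector of tokens in surface order.
#' @export
tree_tokens <- function(tree) {
  if (is_leaf(tree)) return(tree$token)
  unlist(lapply(tree$children, tree_tokens), use.names = FALSE)
}

n_leaves <- function(tree) length(tree_tokens(tree))

# Base label with any function tags / coindexation stripped ("NP-SBJ" -> "NP").
# Labels that *start* with "-" (e.g. "-NONE-") are kept whole.
base_label <- function(label) {
  if (startsWith(label, "-")) return(label)
  sub("[-=].*$", "", label)
}

## PTB token escaping (brackets cannot appear raw in bracketed notation)
.ptb_escape <- c("(" = "-LRB-", ")" = "-RRB-", "{" = "-LCB-", "}" = "-RCB-",
                 "[" = "-LSB-", "]" = "-RSB-")

escape_token <- function(tok) {
  for (raw in names(.ptb_escape)) tok <- gsub(raw, .ptb_escape[[raw]], tok, fixed = TRUE)
  tok
}

unescape_token <- function(tok) {
  for (raw in names(.ptb_escape)) tok <- gsub(.ptb_escape[[raw]], raw, tok, fixed = TRUE)
  tok
}

format_ptb <- function(tree) {
  if (is_leaf(tree))
    return(paste0("(", tree$label, " ", escape_token(tree$token), ")"))
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, format_ptb, character(1)), collapse = " "),
         ")")
}

#' Read Penn-Treebank bracketed parse trees
#'
#' Reads one bracketed tree per line, e.g.
#' `(S (NP (NN A)) (VP (VBZ is) (NP (NN B))))`. Empty (or whitespace-only)
#' lines are skipped with a warning. Bracket tokens escaped in the usual PTB
#' way (`-LRB-`, `-RRB-`, ...) are unescaped.
#'
#' @param con A file path, connection, or character vector of lines.
#' @return List of `parse_tree` objects in input order.
#' @seealso [write_ptb()]
#' @export
read_ptb <- function(con) {
  lines <- if (is.character(con) && (length(con) > 1L || !file.exists(con[1]))) con
           else readLines(con, warn = FALSE)
  trees <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) {
      warning("line ", i, " is empty; skipped")
      next
    }
    trees[[length(trees) + 1L]] <- parse_ptb_line(line, i)
  }
  trees
}

parse_ptb_line <- function(line, lineno) {
  # tokenize: parens as their own tokens, everything else whitespace-split
  spaced <- gsub(")", " ) ", gsub("(", " ( ", line, fixed = TRUE), fixed = TRUE)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  pos <- 1L
  n <- length(toks)
  bad <- function() stop("unbalanced parentheses in parse tree at line ", lineno,
                         call. = FALSE)
  parse_node <- function() {
    if (pos > n || toks[pos] != "(") bad()
    pos <<- pos + 1L
    if (pos > n || toks[pos] %in% c("(", ")")) bad()
    label <- toks[pos]
    pos <<- pos + 1L
    if (pos > n) bad()
    if (toks[pos] == "(") {
      kids <- list()
      while (pos <= n && toks[pos] == "(") kids[[length(kids) + 1L]] <- parse_node()
      if (pos > n || toks[pos] != ")") bad()
      pos <<- pos + 1L
      parse_tree(label, children = kids)
    } else {
      if (toks[pos] == ")") bad()
      token <- unescape_token(toks[pos])
      pos <<- pos + 1L
      if (pos > n || toks[pos] != ")") bad()
      pos <<- pos + 1L
      parse_tree(label, token = token)
    }
  }
  tree <- parse_node()
  if (pos <= n) bad()
  tree
}

#' Write parse trees in Penn-Treebank bracketed notation
#'
#' One tree per line; inverse of [read_ptb()] up to whitespace normalization.
#' Bracket characters in tokens are escaped (`(` becomes `-LRB-`, etc.).
#'
#' @param trees List of `parse_tree` objects.
#' @param con Optional file path or connection; if `NULL`, the lines are
#'   returned as a character vector.
#' @return Invisibly (or visibly when `con` is `NULL`) the character lines.
#' @export
write_ptb <- function(trees, con = NULL) {
  lines <- vapply(trees, format_ptb, character(1))
  if (is.null(con)) return(lines)
  writeLines(lines, con)
  invisible(lines)
}

# Collect every node together with its half-open token span [start, end)
# (0-based). Returns a list of records (node, label, start, end, depth,
# ancestors = base labels of strict ancestors).
tree_spans <- function(tree) {
  out <- list()
  walk <- function(node, offset, depth, ancestors) {
    if (is_leaf(node)) {
      out[[length(out) + 1L]] <<- list(node = node, label = node$label,
                                       start = offset, end = offset + 1L,
                                       depth = depth, ancestors = ancestors)
      return(offset + 1L)
    }
    start <- offset
    kid_anc <- c(ancestors, base_label(node$label))
    for (kid in node$children) offset <- walk(kid, offset, depth + 1L, kid_anc)
    out[[length(out) + 1L]] <<- list(node = node, label = node$label,
                                     start = start, end = offset,
                                     depth = depth, ancestors = ancestors)
    offset
  }
  walk(tree, 0L, 0L, character(0))
  out
}
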