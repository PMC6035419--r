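#' Delimiter configuration for clause segmentation
#'
#' Report sentences are reorganized into short segments at punctuation
#' delimiters and at whole-word splitters. The delimiter list is open-ended by
#' design: radiology prose varies, so users can extend either list.
#'
#' Protections (all on by default) prevent false splits inside tokens:
#' decimal points (`2.5`), single-capital abbreviation periods (`T. spine`),
#' and colons inside times/ratios (`1:30`).
#'
#' @param punct Characters that split, consumed at the split point.
#' @param words Lowercase word (or multi-word) splitters; matched
#'   case-insensitively as whole tokens only, so "android" never splits.
#' @param protect_decimal,protect_abbrev,protect_ratio Protection toggles.
#' @return A `delimiter_config` list.
#' @export
delimiter_config <- function(punct = c(".", ",", ":", ";"),
                             words = c("and", "which", "with which", "that"),
                             protect_decimal = TRUE,
                             protect_abbrev = TRUE,
                             protect_ratio = TRUE) {
  stopifnot(is.character(punct), is.character(words))
  structure(list(punct = punct, words = tolower(words),
                 protect_decimal = isTRUE(protect_decimal),
                 protect_abbrev = isTRUE(protect_abbrev),
                 protect_ratio = isTRUE(protect_ratio)),
            class = "delimiter_config")
}

#' Create a report document
#'
#' @param doc_id Nonempty identifier, unique within a corpus.
#' @param text Report text (may be empty, yielding zero segments).
#' @param metadata Named character list (body system, modality, keywords, ...);
#'   values are carried through uninterpreted.
#' @return A `document` object.
#' @export
document <- function(doc_id, text = "", metadata = list()) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id))
    stop("'doc_id' must be a nonempty string")
  if (!is.character(text) || length(text) != 1L) stop("'text' must be one string")
  structure(list(doc_id = doc_id, text = text, metadata = as.list(metadata)),
            class = "document")
}

#' Split a document into short sentence segments
#'
#' Splits at punctuation delimiters and whole-word splitters, consuming the
#' delimiters; whitespace-only fragments are dropped. Character spans are
#' 0-based half-open offsets into `doc$text`, so segmentation is idempotent
#' and spans never overlap.
#'
#' @param doc A [document()] (a plain string is also accepted; `doc_id` then
#'   defaults to `"doc"`).
#' @param delimiters A [delimiter_config()].
#' @return `data.frame` with columns `doc_id`, `segment_index` (0-based),
#'   `text`, `start`, `end`.
#' @examples
#' segment_text(document("d1",
#'   "Haemangiomas are benign vascular tumors, complications include vessel thrombosis"))
#' @export
segment_text <- function(doc, delimiters = delimiter_config()) {
  if (is.character(doc)) doc <- document("doc", doc)
  stopifnot(inherits(doc, "document"), inherits(delimiters, "delimiter_config"))
  text <- doc$text
  n <- nchar(text)
  empty <- data.frame(doc_id = character(0), segment_index = integer(0),
                      text = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  cut <- logical(n)

  is_digit <- function(ch) length(ch) == 1L && grepl("[0-9]", ch)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (!(ch %in% delimiters$punct)) next
    prev <- if (i > 1L) chars[i - 1L] else ""
    nxt <- if (i < n) chars[i + 1L] else ""
    if (ch == "." && delimiters$protect_decimal &&
        is_digit(prev) && is_digit(nxt)) next
    if (ch == ":" && delimiters$protect_ratio &&
        is_digit(prev) && is_digit(nxt)) next
    if (ch == "." && delimiters$protect_abbrev && grepl("^[A-Z]$", prev)) {
      before <- if (i > 2L) chars[i - 2L] else ""
      if (before == "" || !grepl("[A-Za-z]", before)) next
    }
    cut[i] <- TRUE
  }

  # word splitters: whole-token, case-insensitive; longer phrases first
  words <- delimiters$words[order(-nchar(delimiters$words))]
  for (w in words) {
    parts <- strsplit(trimws(w), "[[:space:]]+")[[1]]
    parts <- vapply(parts, function(p)
      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p), character(1))
    pat <- paste0("(?<![A-Za-z])", paste(parts, collapse = "[[:space:]]+"),
                  "(?![A-Za-z])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) cut[seq.int(m[k], length.out = len[k])] <- TRUE
  }

  # maximal runs of uncut characters
  runs <- rle(cut)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- !runs$values
  segs <- empty
  idx <- 0L
  for (k in which(keep)) {
    s <- starts[k]; e <- ends[k]
    frag <- substr(text, s, e)
    lead <- nchar(frag) - nchar(sub("^[[:space:]]+", "", frag))
    trail <- nchar(frag) - nchar(sub("[[:space:]]+$", "", frag))
    s2 <- s + lead; e2 <- e - trail
    if (s2 > e2) next
    segs <- rbind(segs, data.frame(doc_id = doc$doc_id, segment_index = idx,
                                   text = substr(text, s2, e2),
                                   start = s2 - 1L, end = e2,
                                   stringsAsFactors = FALSE))
    idx <- idx + 1L
  }
  segs
}

#' Segment every document in a corpus
#'
#' @param docs List of [document()] objects with unique `doc_id`s.
#' @param delimiters A [delimiter_config()].
#' @return Row-bound segment `data.frame` (see [segment_text()]).
#' @export
segment_corpus <- function(docs, delimiters = delimiter_config()) {
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  do.call(rbind, c(lapply(docs, segment_text, delimiters = delimiters),
                   list(make.row.names = FALSE)))
}

#' Read documents from JSON-lines or a directory of text files
#'
#' JSON-lines files hold one object per line with fields `doc_id`, `text` and
#' optional `metadata`. For a directory, every `.txt` file becomes a document
#' whose `doc_id` is the filename stem.
#'
#' @param path A `.jsonl` file or a directory.
#' @return List of [document()] objects.
#' @export
read_documents <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    return(lapply(files, function(f) {
      document(tools::file_path_sans_ext(basename(f)),
               paste(readLines(f, warn = FALSE), collapse = "\n"))
    }))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    document(rec$doc_id, if (is.null(rec$text)) "" else rec$text,
             if (is.null(rec$metadata)) list() else as.list(rec$metadata))
  })
}

#' Write documents as JSON-lines
#'
#' @param docs List of [document()] objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_documents <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, text = d$text, metadata = d$metadata),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
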