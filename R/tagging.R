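#' Normalize a term or phrase for lexicon matching
#'
#' Lowercases, replaces punctuation with spaces, and collapses whitespace,
#' so lexicon keys and phrase windows compare on equal footing.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Load a semantic lexicon from TSV
#'
#' The lexicon maps normalized terms to semantic type names (one type per
#' term). Conflicting duplicate rows are an error; redundant duplicates are
#' collapsed; an empty file yields an empty lexicon with a warning.
#'
#' @param path TSV file with columns `term`, `semantic_type` (header
#'   optional: two unnamed columns are accepted), or a `data.frame` with
#'   those columns.
#' @param provenance Free-text origin note stored on the lexicon.
#' @return A `semantic_lexicon`: named character vector (normalized term ->
#'   type) with attributes `provenance`.
#' @export
load_lexicon <- function(path, provenance = NULL) {
  if (is.data.frame(path)) {
    df <- path
    if (is.null(provenance)) provenance <- "data.frame"
  } else {
    if (is.null(provenance)) provenance <- path
    first <- readLines(path, n = 1L, warn = FALSE)
    has_header <- length(first) == 1L &&
      grepl("^term\t", first, ignore.case = TRUE)
    df <- utils::read.delim(path, header = has_header,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#", blank.lines.skip = TRUE)
    if (!has_header && ncol(df) >= 2L) names(df)[1:2] <- c("term", "semantic_type")
  }
  if (nrow(df) == 0L) {
    warning("empty lexicon")
    return(structure(stats::setNames(character(0), character(0)),
                     class = "semantic_lexicon", provenance = provenance))
  }
  stopifnot(all(c("term", "semantic_type") %in% names(df)))
  key <- normalize_term(df$term)
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      types <- unique(df$semantic_type[key == k])
      if (length(types) > 1L)
        stop("conflicting lexicon entries for term '", k, "': ",
             paste(types, collapse = " vs "))
    }
    df <- df[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  message("loaded lexicon: ", nrow(df), " entries")
  structure(stats::setNames(df$semantic_type, key),
            class = "semantic_lexicon", provenance = provenance)
}

#' The bundled miniature radiology lexicon
#'
#' A small synthetic term list (built for this package, not exported from
#' any licensed vocabulary) covering every UMLS semantic type of the default
#' category map with at least two terms, so fixtures exercise all fourteen
#' semantic categories offline.
#'
#' @return A `semantic_lexicon`.
#' @export
mini_lexicon <- function() {
  load_lexicon(system.file("extdata", "mini_lexicon.tsv", package = "sublangr",
                           mustWork = TRUE),
               provenance = "mini-fixture")
}

match_window <- function(key, lexicon, strip_plural = FALSE) {
  if (!is.na(lexicon[key])) return(unname(lexicon[key]))
  if (strip_plural && grepl("s$", key)) {
    key2 <- sub("s$", "", key)
    if (nzchar(key2) && !is.na(lexicon[key2])) return(unname(lexicon[key2]))
  }
  NA_character_
}

#' Assign one semantic type to an entity phrase
#'
#' Implements the last-recognizable-entity rule: among all token windows of
#' the phrase that match the lexicon, pick the window whose last token is
#' rightmost; ties go to the longest window. The resulting type labels the
#' *whole* phrase ("right breast pain" is one Sign or Symptom, not three
#' tags). No match anywhere gives type `"NONE"`.
#'
#' @param phrase A phrase span (from [find_entities()]/[extract_sro()]) or a
#'   plain string.
#' @param lexicon A `semantic_lexicon`.
#' @param scan `"rightmost-end"` (default) maximizes the window end;
#'   `"rightmost-start"` maximizes the window start instead, i.e. scans for
#'   the last place a recognizable entity *begins*.
#' @param strip_plural Also try the window with a trailing "s" stripped.
#' @return List `phrase`, `semantic_type` (type name or `"NONE"`),
#'   `matched_term` (the normalized key that fired, or `""`).
#' @export
tag_phrase <- function(phrase, lexicon,
                       scan = c("rightmost-end", "rightmost-start"),
                       strip_plural = FALSE) {
  scan <- match.arg(scan)
  text <- if (is.list(phrase)) phrase$text else phrase
  toks <- strsplit(normalize_term(text), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  best <- NULL
  n <- length(toks)
  if (n > 0L) {
    for (j in seq_len(n)) for (i in seq_len(j)) {
      key <- paste(toks[i:j], collapse = " ")
      type <- match_window(key, lexicon, strip_plural)
      if (is.na(type)) next
      cand <- list(i = i, j = j, len = j - i + 1L, key = key, type = type)
      if (is.null(best)) { best <- cand; next }
      better <- if (scan == "rightmost-end")
        cand$j > best$j || (cand$j == best$j && cand$len > best$len)
      else
        cand$i > best$i || (cand$i == best$i && cand$len > best$len)
      if (better) best <- cand
    }
  }
  list(phrase = phrase,
       semantic_type = if (is.null(best)) "NONE" else best$type,
       matched_term = if (is.null(best)) "" else best$key)
}

#' Tag the subject and object of each triple
#'
#' Order-preserving; triples whose subject or object finds no lexicon match
#' keep the type `"NONE"` (they are excluded from the co-occurrence network
#' later but still count for coverage reporting).
#'
#' @param triples List of `sro_triple` objects.
#' @param lexicon A `semantic_lexicon`.
#' @param ... Passed to [tag_phrase()].
#' @return `data.frame`: triple columns (as [triples_to_df()]) plus
#'   `subject_type`, `object_type`, `subject_matched`, `object_matched`.
#' @export
tag_triples <- function(triples, lexicon, ...) {
  df <- triples_to_df(triples)
  if (nrow(df) == 0L) {
    df$subject_type <- character(0); df$object_type <- character(0)
    df$subject_matched <- character(0); df$object_matched <- character(0)
    return(df)
  }
  st <- lapply(df$subject, tag_phrase, lexicon = lexicon, ...)
  ot <- lapply(df$object, tag_phrase, lexicon = lexicon, ...)
  df$subject_type <- vapply(st, `[[`, character(1), "semantic_type")
  df$object_type <- vapply(ot, `[[`, character(1), "semantic_type")
  df$subject_matched <- vapply(st, `[[`, character(1), "matched_term")
  df$object_matched <- vapply(ot, `[[`, character(1), "matched_term")
  df
}
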