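#' One-vs-rest confusion counts for machine vs reference annotations
#'
#' For each label L: TP counts units where machine and reference both say L,
#' FP where only the machine says L, FN where only the reference says L, and
#' TN the remainder, so TP+TN+FP+FN equals the unit count for every label.
#' Overall TP/FP/FN/TN are the sums over labels (micro-averaging).
#'
#' @param records `data.frame` with columns `machine_label`,
#'   `reference_label` (one row per annotated unit).
#' @param label_set Labels to score; a record label outside
#'   `label_set` plus `"OUT_OF_MODEL"` is an error.
#' @param exclude_out_of_model Drop units whose *reference* label is
#'   `OUT_OF_MODEL` before counting (they are outside the model's scope but
#'   still belong in coverage denominators).
#' @return A `confusion_counts` `data.frame`: `label`, `TP`, `TN`, `FP`,
#'   `FN`, with an `"Overall"` row last.
#' @export
confusion_counts <- function(records, label_set,
                             exclude_out_of_model = TRUE) {
  stopifnot(all(c("machine_label", "reference_label") %in% names(records)))
  allowed <- union(label_set, "OUT_OF_MODEL")
  bad <- setdiff(unique(c(records$machine_label, records$reference_label)),
                 allowed)
  if (length(bad) > 0L)
    stop("label(s) outside the label set: ", paste(bad, collapse = ", "))
  if (exclude_out_of_model)
    records <- records[records$reference_label != "OUT_OF_MODEL", ,
                       drop = FALSE]
  n <- nrow(records)
  rows <- lapply(label_set, function(L) {
    tp <- sum(records$machine_label == L & records$reference_label == L)
    fp <- sum(records$machine_label == L & records$reference_label != L)
    fn <- sum(records$machine_label != L & records$reference_label == L)
    data.frame(label = L, TP = tp, TN = n - tp - fp - fn, FP = fp, FN = fn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(label = "Overall", TP = sum(out$TP),
                               TN = sum(out$TN), FP = sum(out$FP),
                               FN = sum(out$FN), stringsAsFactors = FALSE))
  structure(out, class = c("confusion_counts", "data.frame"), n_units = n)
}

#' Precision, recall and F-score from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), F = 2PR/(P+R); any division
#' by zero yields 0 with a warning.
#'
#' @param counts A `confusion_counts` table (or any `data.frame` with
#'   columns `label`, `TP`, `FP`, `FN`).
#' @return `data.frame`: `label`, `TP`, `TN`, `FP`, `FN`, `precision`,
#'   `recall`, `f_score` (all in `[0, 1]`).
#' @export
precision_recall_f <- function(counts) {
  stopifnot(all(c("label", "TP", "FP", "FN") %in% names(counts)))
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning("zero denominator in ", what, " for: ",
              paste(counts$label[den == 0], collapse = ", "))
    out
  }
  p <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  r <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  out <- as.data.frame(counts, stringsAsFactors = FALSE)
  out$precision <- p
  out$recall <- r
  out$f_score <- f
  out
}

#' Round half-up (display convention)
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector; exact halves round away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a metric table the way evaluation tables are printed
#'
#' Percentages to one decimal (half-up), F-score to four decimals.
#'
#' @param metrics Output of [precision_recall_f()].
#' @return `data.frame` with `precision`/`recall` as "86.8%"-style strings
#'   and `f_score` as "0.8299"-style strings.
#' @export
format_metrics <- function(metrics) {
  out <- metrics
  out$precision <- sprintf("%.1f%%", round_half_up(metrics$precision * 100, 1))
  out$recall <- sprintf("%.1f%%", round_half_up(metrics$recall * 100, 1))
  out$f_score <- sprintf("%.4f", round_half_up(metrics$f_score, 4))
  out
}

#' Relationship coverage of a knowledge model
#'
#' The fraction of raters' relationship tags that the knowledge model
#' covers: #(tags present in the model) / #(tags). The uncovered tags are
#' reported as an attribute.
#'
#' @param rater_tags Character vector of relationship tags assigned by
#'   raters (one per annotated pair).
#' @param model_tags Either a `knowledge_model` (labels are taken from its
#'   relationships) or a character vector of tags the model supports.
#' @return Coverage fraction in `[0, 1]`, with attribute `uncovered`.
#' @export
relationship_coverage <- function(rater_tags, model_tags) {
  if (length(rater_tags) == 0L) stop("empty rater tag list")
  if (inherits(model_tags, "knowledge_model"))
    model_tags <- unique(model_tags$relationships$label[
      nzchar(model_tags$relationships$label)])
  covered <- rater_tags %in% model_tags
  structure(sum(covered) / length(rater_tags),
            uncovered = sort(unique(rater_tags[!covered])))
}

#' Inter-rater agreement
#'
#' Two aligned annotation lists agree on a unit when both raters chose the
#' same label; agreement = agreed / (agreed + disagreed).
#'
#' @param rater1,rater2 Equal-length label vectors.
#' @return Agreement fraction in `[0, 1]`.
#' @export
rater_agreement <- function(rater1, rater2) {
  if (length(rater1) != length(rater2))
    stop("rater annotation lists differ in length (",
         length(rater1), " vs ", length(rater2), ")")
  if (length(rater1) == 0L) stop("empty annotation lists")
  mean(rater1 == rater2)
}
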