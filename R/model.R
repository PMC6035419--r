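## Regrouping fine-grained UMLS semantic types into 14 coarse semantic
## categories, lifting the type-level co-occurrence network to category
## level, and attaching physician-assigned relationship labels.

# category -> included semantic types; the four conceptually important
# expert-added types are Body System, Receptor, Organism Function and
# Biomedical or Dental Material.
.default_categories <- list(
  "Abnormality" = c("Anatomical Abnormality", "Acquired Abnormality",
                    "Congenital Abnormality"),
  "Body Part" = c("Body Part Organ or Organ Component", "Body Substance",
                  "Body System", "Tissue", "Cell", "Gene or Genome",
                  "Receptor"),
  "Classification" = "Classification",
  "Functional Concept" = "Functional Concept",
  "Location" = c("Spatial Concept", "Body Location or Region",
                 "Body Space or Junction"),
  "Medical Activity" = c("Diagnostic Procedure",
                         "Therapeutic or Preventive Procedure",
                         "Laboratory Procedure", "Health Care Activity",
                         "Research Activity", "Activity"),
  "Medical Device and Object" = c("Medical Device", "Manufactured Object"),
  "Observation" = c("Finding", "Sign or Symptom", "Injury or Poisoning",
                    "Laboratory or Test Result", "Phenomenon or Process"),
  "Pathology" = c("Disease or Syndrome", "Neoplastic Process",
                  "Mental or Behavioral Dysfunction",
                  "Cell or Molecular Dysfunction", "Pathologic Function"),
  "Physiology" = c("Cell Function", "Organ or Tissue Function",
                   "Organism Function", "Physiologic Function"),
  "Qualitative Concept" = "Qualitative Concept",
  "Quantitative Concept" = "Quantitative Concept",
  "Substance" = c("Pharmacologic Substance", "Substance",
                  "Biologically Active Substance",
                  "Biomedical or Dental Material"),
  "Temporal Concept" = "Temporal Concept")

#' The default semantic-type regrouping (14 categories, 44 types)
#'
#' Five common UMLS types are reused as their own categories (Functional,
#' Qualitative, Quantitative and Temporal Concept, and Classification); the
#' other nine categories regroup related fine-grained types.
#'
#' @return A `category_map`: `data.frame` with columns `semantic_type`,
#'   `category`, and attribute `categories` (ordered category names).
#' @export
default_category_map <- function() {
  df <- do.call(rbind, lapply(names(.default_categories), function(cat)
    data.frame(semantic_type = .default_categories[[cat]], category = cat,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  structure(df, class = c("category_map", "data.frame"),
            categories = names(.default_categories))
}

#' Load a semantic-type to category map
#'
#' @param path TSV with columns `semantic_type`, `category`, or a
#'   `data.frame`; `NULL` returns [default_category_map()].
#' @return A `category_map`.
#' @export
load_category_map <- function(path = NULL) {
  if (is.null(path)) return(default_category_map())
  df <- if (is.data.frame(path)) as.data.frame(path)
        else utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("semantic_type", "category") %in% names(df)))
  dup <- duplicated(df$semantic_type)
  if (any(dup)) {
    bad <- unique(df$semantic_type[dup])
    conf <- vapply(bad, function(t)
      length(unique(df$category[df$semantic_type == t])) > 1L, logical(1))
    if (any(conf)) stop("semantic type mapped to more than one category: ",
                        paste(bad[conf], collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df[, c("semantic_type", "category")],
            class = c("category_map", "data.frame"),
            categories = unique(df$category))
}

#' Category of a semantic type under a map
#'
#' @param map A `category_map`.
#' @param types Character vector of semantic-type names.
#' @return Character vector of categories; types not in the map (rare types
#'   such as "Organism") return `"OUT_OF_MODEL"`.
#' @export
category_of <- function(map, types) {
  idx <- match(types, map$semantic_type)
  out <- map$category[idx]
  out[is.na(idx)] <- "OUT_OF_MODEL"
  out
}

#' Lift a type-level network to category level
#'
#' Category edge weights sum the contributing type-pair weights; node
#' frequencies likewise. Edges with an endpoint outside the map are routed
#' to a residual bucket reported on the result, so total weight is conserved:
#' `total before = total after + residual`.
#'
#' @param network A `cooc_network` over semantic types.
#' @param map A `category_map`.
#' @return A `cooc_network` over categories, with `residual_weight` and
#'   `residual_node_freq` attributes for the out-of-model mass.
#' @export
lift_network <- function(network, map = default_category_map()) {
  stopifnot(inherits(network, "cooc_network"))
  sc <- category_of(map, network$edges$subject_type)
  oc <- category_of(map, network$edges$object_type)
  inm <- sc != "OUT_OF_MODEL" & oc != "OUT_OF_MODEL"
  edges <- if (any(inm)) {
    agg <- stats::aggregate(list(weight = network$edges$weight[inm]),
                            by = list(subject_type = sc[inm],
                                      object_type = oc[inm]), FUN = sum)
    agg <- agg[order(-agg$weight, agg$subject_type, agg$object_type), ,
               drop = FALSE]
    rownames(agg) <- NULL
    agg
  } else data.frame(subject_type = character(0), object_type = character(0),
                    weight = numeric(0), stringsAsFactors = FALSE)
  ncat <- category_of(map, names(network$node_freq))
  inn <- ncat != "OUT_OF_MODEL"
  node_freq <- if (any(inn))
    tapply(as.numeric(network$node_freq)[inn], ncat[inn], sum) else
    stats::setNames(numeric(0), character(0))
  node_freq <- stats::setNames(as.numeric(node_freq), names(node_freq))
  structure(list(node_freq = node_freq, edges = edges,
                 distinct_pair_count = nrow(edges),
                 total_incidence_count = sum(edges$weight),
                 skipped = network$skipped,
                 residual_weight = sum(network$edges$weight[!inm]),
                 residual_node_freq = sum(as.numeric(network$node_freq)[!inn])),
            class = "cooc_network")
}

#' Assemble a knowledge model from a category-level network
#'
#' The knowledge model is the category set plus the relationship set
#' (directed category pairs with weights and optional labels). Significance
#' flags mark the top-`significant_n` relationships by weight and the
#' top-`significant_n` categories by total occurrence; the cutoff is
#' configurable because significance is defined by total occurrence count,
#' not by a fixed threshold.
#'
#' @param lifted A category-level `cooc_network` (see [lift_network()]).
#' @param map A `category_map` supplying the category list.
#' @param significant_n Number of relationships/categories flagged
#'   significant (default 10).
#' @return A `knowledge_model`: `categories` (`data.frame` name,
#'   `significant`), `relationships` (`data.frame` subject, object, label,
#'   weight, significant).
#' @export
knowledge_model <- function(lifted, map = default_category_map(),
                            significant_n = 10L) {
  cats <- attr(map, "categories")
  rel <- lifted$edges
  rel <- data.frame(subject = rel$subject_type, object = rel$object_type,
                    label = character(nrow(rel)), weight = rel$weight,
                    stringsAsFactors = FALSE)
  ord <- order(-rel$weight, rel$subject, rel$object)
  rel <- rel[ord, , drop = FALSE]
  rel$significant <- seq_len(nrow(rel)) <= significant_n
  rownames(rel) <- NULL
  freq <- stats::setNames(rep(0, length(cats)), cats)
  freq[names(lifted$node_freq)] <- lifted$node_freq
  sig_cats <- names(sort(freq, decreasing = TRUE))[
    seq_len(min(significant_n, length(cats)))]
  categories <- data.frame(name = cats,
                           occurrence = as.numeric(freq[cats]),
                           significant = cats %in% sig_cats,
                           stringsAsFactors = FALSE)
  structure(list(categories = categories, relationships = rel),
            class = "knowledge_model")
}

#' @export
print.knowledge_model <- function(x, ...) {
  cat("knowledge model:", nrow(x$categories), "semantic categories,",
      nrow(x$relationships), "relationships",
      sprintf("(%d labeled)\n", sum(nzchar(x$relationships$label))))
  invisible(x)
}

#' Attach relationship labels to a knowledge model
#'
#' Labels come from manual annotation and are loaded, never inferred. A
#' label row names a subject and object category, an optional relation
#' surface form (so "of" can mean Situated_at, Occurs_in or Indicative_of
#' depending on the pair), and the label. Multiple labels per category pair
#' expand to multiple relationship rows sharing the pair's weight.
#'
#' @param model A `knowledge_model`.
#' @param labels TSV path or `data.frame` with columns `subject_category`,
#'   `object_category`, optional `relation_surface`, `label`.
#' @return The model with labels attached (and a `relation_surface` column
#'   on the relationships where given).
#' @export
attach_labels <- function(model, labels) {
  stopifnot(inherits(model, "knowledge_model"))
  df <- if (is.data.frame(labels)) labels
        else utils::read.delim(labels, stringsAsFactors = FALSE, quote = "",
                               comment.char = "#")
  if (nrow(df) == 0L) return(model)
  stopifnot(all(c("subject_category", "object_category", "label") %in% names(df)))
  cats <- model$categories$name
  bad <- setdiff(unique(c(df$subject_category, df$object_category)), cats)
  if (length(bad) > 0L)
    stop("label file names unknown categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  if (!"relation_surface" %in% names(df)) df$relation_surface <- ""
  rel <- model$relationships
  if (!"relation_surface" %in% names(rel)) rel$relation_surface <- ""
  out <- list()
  for (r in seq_len(nrow(rel))) {
    row <- rel[r, , drop = FALSE]
    hits <- df[df$subject_category == row$subject &
               df$object_category == row$object, , drop = FALSE]
    if (nrow(hits) == 0L) { out[[length(out) + 1L]] <- row; next }
    for (h in seq_len(nrow(hits))) {
      lab <- row
      lab$label <- hits$label[h]
      lab$relation_surface <- hits$relation_surface[h]
      out[[length(out) + 1L]] <- lab
    }
  }
  model$relationships <- do.call(rbind, out)
  rownames(model$relationships) <- NULL
  model
}

#' Look up the label for a category pair and relation surface
#'
#' @param model A labeled `knowledge_model`.
#' @param subject,object Category names.
#' @param surface Optional relation surface form ("of", "with", ...).
#' @return Character vector of matching labels (may be empty).
#' @export
lookup_label <- function(model, subject, object, surface = NULL) {
  rel <- model$relationships
  hit <- rel$subject == subject & rel$object == object & nzchar(rel$label)
  if (!is.null(surface) && "relation_surface" %in% names(rel))
    hit <- hit & (rel$relation_surface == surface | !nzchar(rel$relation_surface))
  unique(rel$label[hit])
}

model_to_list <- function(model) {
  rel <- model$relationships
  ord <- order(rel$subject, rel$object, rel$label)
  rel <- rel[ord, , drop = FALSE]
  list(categories = lapply(seq_len(nrow(model$categories)), function(i)
         list(name = model$categories$name[i],
              occurrence = model$categories$occurrence[i],
              significant = model$categories$significant[i])),
       relationships = lapply(seq_len(nrow(rel)), function(i)
         list(subject = rel$subject[i], object = rel$object[i],
              label = rel$label[i], weight = rel$weight[i],
              significant = rel$significant[i])))
}

#' Export a knowledge model
#'
#' JSON uses the schema `{categories: [...], relationships: [{subject,
#' object, label, weight, significant}]}` with deterministic ordering, so
#' exports round-trip byte-identically through [load_model_json()]. DOT
#' renders significant relationships with a dashed edge style.
#'
#' @param model A `knowledge_model`.
#' @param format One of `"json"`, `"graphml"`, `"dot"`.
#' @param file Output path; `NULL` returns the serialized text.
#' @return Invisibly `file`, or the text when `file` is `NULL`.
#' @export
export_model <- function(model, format = c("json", "graphml", "dot"),
                         file = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE,
                            pretty = TRUE, digits = NA)
    if (is.null(file)) return(as.character(txt))
    writeLines(as.character(txt), file)
    return(invisible(file))
  }
  rel <- model$relationships
  if (format == "dot") {
    q <- function(x) paste0("\"", gsub("\"", "\\\"", x, fixed = TRUE), "\"")
    lines <- c("digraph knowledge_model {",
               paste0("  ", q(model$categories$name), ";"),
               vapply(seq_len(nrow(rel)), function(i) {
                 attrs <- c(sprintf("weight=%g", rel$weight[i]),
                            if (nzchar(rel$label[i]))
                              sprintf("label=%s", q(rel$label[i])),
                            if (rel$significant[i]) "style=dashed")
                 paste0("  ", q(rel$subject[i]), " -> ", q(rel$object[i]),
                        " [", paste(attrs, collapse = ", "), "];")
               }, character(1)),
               "}")
    if (is.null(file)) return(lines)
    writeLines(lines, file)
    return(invisible(file))
  }
  # graphml via igraph
  g <- igraph::graph_from_data_frame(
    data.frame(from = rel$subject, to = rel$object, weight = rel$weight,
               label = rel$label, significant = rel$significant,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = model$categories$name,
                          significant = model$categories$significant,
                          stringsAsFactors = FALSE))
  tmp <- file %||% tempfile(fileext = ".graphml")
  igraph::write_graph(g, tmp, format = "graphml")
  if (is.null(file)) { on.exit(unlink(tmp)); return(readLines(tmp, warn = FALSE)) }
  invisible(file)
}

#' Load a knowledge model from its JSON export
#'
#' @param path JSON file or JSON string from [export_model()].
#' @return A `knowledge_model`.
#' @export
load_model_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  categories <- as.data.frame(x$categories, stringsAsFactors = FALSE)
  rel <- as.data.frame(x$relationships, stringsAsFactors = FALSE)
  if (nrow(rel) == 0L)
    rel <- data.frame(subject = character(0), object = character(0),
                      label = character(0), weight = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  structure(list(categories = categories, relationships = rel),
            class = "knowledge_model")
}
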