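#' Build the directed semantic-type co-occurrence network
#'
#' A co-occurrence incidence is one (subject type, object type) pair
#' contributed by one tagged triple. Edge weights count incidences per
#' ordered pair; node frequencies count every typed phrase occurrence
#' (subject or object). Triples with a `NONE`-typed endpoint contribute no
#' edge and are counted separately as skipped.
#'
#' @param tagged `data.frame` from [tag_triples()] (columns `subject_type`,
#'   `object_type`), or any data.frame with those columns.
#' @return A `cooc_network`: `node_freq` (named numeric), `edges`
#'   (`subject_type`, `object_type`, `weight`), `distinct_pair_count`,
#'   `total_incidence_count`, `skipped`.
#' @export
build_network <- function(tagged) {
  stopifnot(all(c("subject_type", "object_type") %in% names(tagged)))
  st <- tagged$subject_type
  ot <- tagged$object_type
  typed <- c(st[st != "NONE"], ot[ot != "NONE"])
  node_freq <- if (length(typed)) {
    tab <- table(typed)
    stats::setNames(as.numeric(tab), names(tab))
  } else stats::setNames(numeric(0), character(0))
  ok <- st != "NONE" & ot != "NONE"
  edges <- if (any(ok)) {
    agg <- stats::aggregate(list(weight = rep(1L, sum(ok))),
                            by = list(subject_type = st[ok],
                                      object_type = ot[ok]), FUN = sum)
    agg <- agg[order(-agg$weight, agg$subject_type, agg$object_type), ,
               drop = FALSE]
    rownames(agg) <- NULL
    agg
  } else data.frame(subject_type = character(0), object_type = character(0),
                    weight = numeric(0), stringsAsFactors = FALSE)
  structure(list(node_freq = node_freq, edges = edges,
                 distinct_pair_count = nrow(edges),
                 total_incidence_count = sum(edges$weight),
                 skipped = sum(!ok)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("co-occurrence network:", length(x$node_freq), "types,",
      x$distinct_pair_count, "distinct pairs,",
      x$total_incidence_count, "incidences",
      if (x$skipped > 0) paste0("(", x$skipped, " untyped pairs skipped)"),
      "\n")
  invisible(x)
}

#' Pruning specification for the co-occurrence network
#'
#' Weight-based selection keeps the most frequent semantic types and the
#' heaviest edges, plus expert-chosen additions that are retained regardless
#' of frequency. The defaults mirror the induction recipe: top 40 types plus
#' the four conceptually important starred types, and the top 100 edges plus
#' expert-chosen relationship pairs.
#'
#' @param top_nodes Number of types kept by frequency (`Inf` keeps all).
#' @param expert_types Types kept regardless of frequency.
#' @param top_edges Number of edges kept by weight (`Inf` keeps all).
#' @param expert_edges `data.frame` (`subject_type`, `object_type`) of edges
#'   kept regardless of weight.
#' @return A `prune_spec` list.
#' @export
prune_spec <- function(top_nodes = 40,
                       expert_types = c("Body System", "Receptor",
                                        "Organism Function",
                                        "Biomedical or Dental Material"),
                       top_edges = 100,
                       expert_edges = NULL) {
  stopifnot(top_nodes >= 0, top_edges >= 0)
  if (is.null(expert_edges))
    expert_edges <- data.frame(subject_type = character(0),
                               object_type = character(0),
                               stringsAsFactors = FALSE)
  structure(list(top_nodes = top_nodes, expert_types = expert_types,
                 top_edges = top_edges, expert_edges = expert_edges),
            class = "prune_spec")
}

#' Prune a co-occurrence network to its dominant structure
#'
#' Keeps the `top_nodes` highest-frequency types (ties broken
#' lexicographically) plus the expert types, then the `top_edges` heaviest
#' edges among surviving nodes plus the expert edges. Kept edge weights are
#' untouched. The entity-coverage fraction of the kept nodes (kept frequency
#' mass / total) is recorded as `entity_coverage`.
#'
#' @param network A `cooc_network` from [build_network()].
#' @param spec A [prune_spec()].
#' @param known_types Type names considered valid for `expert_types`
#'   (defaults to the network's nodes plus the default category map's types);
#'   an expert type outside this universe is an error, but a known type with
#'   zero frequency is retained at frequency 0.
#' @return A pruned `cooc_network` with `entity_coverage` set.
#' @export
prune_network <- function(network, spec = prune_spec(),
                          known_types = NULL) {
  stopifnot(inherits(network, "cooc_network"), inherits(spec, "prune_spec"))
  if (is.null(known_types))
    known_types <- union(names(network$node_freq),
                         default_category_map()$semantic_type)
  unknown <- setdiff(spec$expert_types, known_types)
  if (length(unknown) > 0L)
    stop("unknown semantic type(s) in prune spec: ",
         paste(unknown, collapse = ", "))
  freq <- network$node_freq
  ord <- order(-freq, names(freq))
  n_keep <- min(length(freq), spec$top_nodes)
  if (n_keep < length(freq))
    message("top-node cutoff at rank ", n_keep, "; ties broken lexicographically")
  kept_names <- names(freq)[ord][seq_len(n_keep)]
  kept_names <- union(kept_names, spec$expert_types)
  node_freq <- stats::setNames(ifelse(kept_names %in% names(freq),
                                      freq[kept_names], 0), kept_names)
  node_freq[is.na(node_freq)] <- 0

  edges <- network$edges
  surv <- edges$subject_type %in% kept_names & edges$object_type %in% kept_names
  edges <- edges[surv, , drop = FALSE]
  ord_e <- order(-edges$weight, edges$subject_type, edges$object_type)
  top <- edges[ord_e, , drop = FALSE][seq_len(min(nrow(edges), spec$top_edges)), ,
                                      drop = FALSE]
  if (nrow(spec$expert_edges) > 0L) {
    ekey <- paste(network$edges$subject_type, network$edges$object_type, sep = "\r")
    xkey <- paste(spec$expert_edges$subject_type, spec$expert_edges$object_type,
                  sep = "\r")
    extra <- network$edges[ekey %in% xkey, , drop = FALSE]
    miss <- spec$expert_edges[!(xkey %in% ekey), , drop = FALSE]
    if (nrow(miss) > 0L) {
      miss$weight <- 0
      extra <- rbind(extra, miss)
    }
    tkey <- paste(top$subject_type, top$object_type, sep = "\r")
    add <- extra[!(paste(extra$subject_type, extra$object_type, sep = "\r")
                   %in% tkey), , drop = FALSE]
    top <- rbind(top, add)
  }
  rownames(top) <- NULL
  total_mass <- sum(network$node_freq)
  structure(list(node_freq = node_freq, edges = top,
                 distinct_pair_count = nrow(top),
                 total_incidence_count = sum(top$weight),
                 skipped = network$skipped,
                 entity_coverage = if (total_mass > 0)
                   sum(node_freq) / total_mass else NA_real_),
            class = "cooc_network")
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("subject_type", "object_type", "weight"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = names(network$node_freq),
                          freq = as.numeric(network$node_freq),
                          stringsAsFactors = FALSE))
  igraph::V(g)$size <- igraph::degree(g, mode = "all")
  g
}

#' Export a co-occurrence network
#'
#' GraphML and DOT carry a node `size` attribute equal to connectivity
#' (degree) and an edge `weight` attribute, matching the usual rendering
#' where node size shows connectivity and edge thickness shows weight.
#'
#' @param network A `cooc_network`.
#' @param format One of `"graphml"`, `"dot"`, `"edge-tsv"`.
#' @param file Output path; if `NULL` the serialized lines are returned.
#' @return Invisibly `file`, or the character lines when `file` is `NULL`.
#' @export
export_network <- function(network, format = c("graphml", "dot", "edge-tsv"),
                           file = NULL) {
  format <- match.arg(format)
  tmp <- file %||% tempfile(fileext = paste0(".", format))
  if (format == "edge-tsv") {
    utils::write.table(network$edges, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, tmp,
                        format = if (format == "graphml") "graphml" else "dot")
  }
  if (is.null(file)) {
    on.exit(unlink(tmp))
    return(readLines(tmp, warn = FALSE))
  }
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
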