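## Stage-wise pipeline runner. Each stage reads the previous stage's flat
## TSV/JSON artifacts from the output directory and writes its own, so runs
## are diffable and re-entrant; no stage mutates an upstream artifact.

#' Pipeline configuration
#'
#' @param out_dir Directory artifacts are written to.
#' @param corpus Path to documents (`.jsonl` or a directory of `.txt`);
#'   `NULL` when the `fixtures` stage generates the corpus.
#' @param trees Path to a PTB tree file aligned with `index`.
#' @param index Path to the tree index TSV (`doc_id`, `segment_index`,
#'   `line_number`).
#' @param lexicon Path to the lexicon TSV; `NULL` uses [mini_lexicon()].
#' @param category_map Path to a category-map TSV; `NULL` uses the default.
#' @param labels Path to a relationship-label TSV; `NULL` uses the bundled
#'   defaults.
#' @param delimiters A [delimiter_config()].
#' @param prune A [prune_spec()].
#' @param fixture A [fixture_spec()] for the `fixtures` stage.
#' @param significant_n Significance cutoff for [knowledge_model()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, corpus = NULL, trees = NULL,
                            index = NULL, lexicon = NULL,
                            category_map = NULL, labels = NULL,
                            delimiters = delimiter_config(),
                            prune = prune_spec(),
                            fixture = fixture_spec(),
                            significant_n = 10L) {
  structure(list(out_dir = out_dir, corpus = corpus, trees = trees,
                 index = index, lexicon = lexicon,
                 category_map = category_map, labels = labels,
                 delimiters = delimiters, prune = prune, fixture = fixture,
                 significant_n = significant_n),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `delimiters`,
#' `prune` and `fixture` may be given as nested maps of their constructor
#' arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(out_dir = y$out_dir %||% ".")
  for (k in c("corpus", "trees", "index", "lexicon", "category_map", "labels"))
    args[[k]] <- y[[k]]
  if (!is.null(y$delimiters)) args$delimiters <- do.call(delimiter_config, y$delimiters)
  if (!is.null(y$prune)) args$prune <- do.call(prune_spec, y$prune)
  if (!is.null(y$fixture)) args$fixture <- do.call(fixture_spec, y$fixture)
  if (!is.null(y$significant_n)) args$significant_n <- y$significant_n
  do.call(pipeline_config, args)
}

artifact <- function(config, name) file.path(config$out_dir, name)

need_artifact <- function(config, name, stage) {
  p <- artifact(config, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "'; run stage '", stage, "' first")
  p
}

read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE,
                                             quote = "")
write_tsv <- function(df, path) utils::write.table(df, path, sep = "\t",
                                                   quote = FALSE,
                                                   row.names = FALSE)

config_lexicon <- function(config) {
  if (is.null(config$lexicon)) mini_lexicon() else load_lexicon(config$lexicon)
}

config_map <- function(config) load_category_map(config$category_map)

write_manifest <- function(config, stage, counts) {
  inputs <- Filter(Negate(is.null),
                   config[c("corpus", "trees", "index", "lexicon",
                            "category_map", "labels")])
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  saveRDS(config[order(names(config))], cfg_file)
  manifest <- list(stage = stage, inputs = inputs,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   counts = counts)
  jsonlite::write_json(manifest, artifact(config, paste0("manifest_", stage,
                                                         ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `fixtures` (generate a synthetic corpus), `segment`, `extract`,
#' `tag`, `network`, `model`, `evaluate`, `all`. Each stage writes its
#' artifacts plus a run manifest under `config$out_dir`.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()] or YAML path.
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("fixtures", "segment", "extract", "tag", "network", "model",
              "evaluate", "all")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; one of: ", paste(stages, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- character(0)
    first <- if (is.null(config$corpus)) "fixtures" else "segment"
    seqn <- c(if (first == "fixtures") "fixtures", "segment", "extract", "tag",
              "network", "model", "evaluate")
    for (s in seqn) out <- c(out, run_stage(s, config))
    return(invisible(out))
  }
  written <- switch(stage,
    fixtures = {
      bundle <- generate_fixtures(config$fixture,
                                  lexicon = config_lexicon(config))
      fdir <- artifact(config, "fixtures")
      write_fixture_bundle(bundle, fdir)
      config$corpus <- file.path(fdir, "documents.jsonl")
      config$trees <- file.path(fdir, "trees.ptb")
      config$index <- file.path(fdir, "index.tsv")
      write_manifest(config, stage,
                     list(documents = length(bundle$documents),
                          trees = length(bundle$trees)))
      fdir
    },
    segment = {
      corpus <- config$corpus %||% artifact(config, "fixtures/documents.jsonl")
      if (!file.exists(corpus))
        stop("missing corpus; run stage 'fixtures' first or set 'corpus'")
      docs <- read_documents(corpus)
      segs <- segment_corpus(docs, config$delimiters)
      p <- artifact(config, "segments.tsv")
      write_tsv(segs, p)
      write_manifest(config, stage, list(documents = length(docs),
                                         segments = nrow(segs)))
      p
    },
    extract = {
      trees_path <- config$trees %||% artifact(config, "fixtures/trees.ptb")
      index_path <- config$index %||% artifact(config, "fixtures/index.tsv")
      if (!file.exists(trees_path) || !file.exists(index_path))
        stop("missing trees/index; run stage 'fixtures' first or set paths")
      trees <- read_ptb(trees_path)
      idx <- read_tsv(index_path)
      triples <- list()
      uncovered <- 0L
      for (i in seq_len(nrow(idx))) {
        tree <- trees[[idx$line_number[i]]]
        got <- extract_sro(tree, idx$doc_id[i], idx$segment_index[i])
        got <- attach_adverbs(tree, got)
        if (length(got) == 0L) uncovered <- uncovered + 1L
        triples <- c(triples, got)
      }
      p <- artifact(config, "triples.tsv")
      write_tsv(triples_to_df(triples), p)
      write_manifest(config, stage, list(segments = nrow(idx),
                                         triples = length(triples),
                                         uncovered_segments = uncovered))
      p
    },
    tag = {
      tp <- need_artifact(config, "triples.tsv", "extract")
      df <- read_tsv(tp)
      lex <- config_lexicon(config)
      st <- lapply(df$subject, tag_phrase, lexicon = lex)
      ot <- lapply(df$object, tag_phrase, lexicon = lex)
      df$subject_type <- vapply(st, `[[`, character(1), "semantic_type")
      df$object_type <- vapply(ot, `[[`, character(1), "semantic_type")
      df$subject_matched <- vapply(st, `[[`, character(1), "matched_term")
      df$object_matched <- vapply(ot, `[[`, character(1), "matched_term")
      p <- artifact(config, "tagged_triples.tsv")
      write_tsv(df, p)
      write_manifest(config, stage,
                     list(triples = nrow(df),
                          untyped_phrases = sum(df$subject_type == "NONE") +
                            sum(df$object_type == "NONE")))
      p
    },
    network = {
      tp <- need_artifact(config, "tagged_triples.tsv", "tag")
      net <- build_network(read_tsv(tp))
      pruned <- prune_network(net, config$prune,
                              known_types = union(names(net$node_freq),
                                                  config_map(config)$semantic_type))
      p1 <- artifact(config, "network_full.tsv")
      p2 <- artifact(config, "network_pruned.tsv")
      export_network(net, "edge-tsv", p1)
      export_network(pruned, "edge-tsv", p2)
      export_network(pruned, "graphml", artifact(config, "network.graphml"))
      write_manifest(config, stage,
                     list(types = length(net$node_freq),
                          distinct_pairs = net$distinct_pair_count,
                          incidences = net$total_incidence_count,
                          entity_coverage = pruned$entity_coverage))
      c(p1, p2)
    },
    model = {
      tp <- need_artifact(config, "tagged_triples.tsv", "tag")
      net <- build_network(read_tsv(tp))
      map <- config_map(config)
      lifted <- lift_network(net, map)
      model <- knowledge_model(lifted, map,
                               significant_n = config$significant_n)
      labels <- config$labels %||%
        system.file("extdata", "default_labels.tsv", package = "sublangr")
      model <- attach_labels(model, labels)
      p <- artifact(config, "model.json")
      export_model(model, "json", p)
      export_model(model, "dot", artifact(config, "model.dot"))
      write_manifest(config, stage,
                     list(categories = nrow(model$categories),
                          relationships = nrow(model$relationships),
                          residual_weight = lifted$residual_weight))
      p
    },
    evaluate = {
      mp <- need_artifact(config, "model.json", "model")
      model <- load_model_json(mp)
      raters_path <- artifact(config, "fixtures/raters.tsv")
      if (!file.exists(raters_path))
        stop("missing rater annotations; run stage 'fixtures' first ",
             "or place raters.tsv under the output directory")
      raters <- read_tsv(raters_path)
      records <- data.frame(machine_label = raters$machine_label,
                            reference_label = raters$consensus_label,
                            stringsAsFactors = FALSE)
      counts <- confusion_counts(records, model$categories$name)
      metrics <- precision_recall_f(counts)
      agree <- rater_agreement(raters$rater1_label, raters$rater2_label)
      tags_path <- artifact(config, "fixtures/relationship_tags.txt")
      cov <- if (file.exists(tags_path)) {
        tags <- readLines(tags_path, warn = FALSE)
        relationship_coverage(tags, c(unique(model$relationships$label),
                                      "Related_to"))
      } else NA_real_
      p1 <- artifact(config, "metrics.tsv")
      write_tsv(format_metrics(metrics), p1)
      p2 <- artifact(config, "metrics.json")
      overall <- metrics[metrics$label == "Overall", ]
      jsonlite::write_json(
        list(overall = list(precision = overall$precision,
                            recall = overall$recall,
                            f_score = overall$f_score),
             agreement = agree,
             relationship_coverage = as.numeric(cov)),
        p2, auto_unbox = TRUE, digits = NA)
      write_manifest(config, stage, list(units = attr(counts, "n_units"),
                                         agreement = agree))
      c(p1, p2)
    })
  invisible(written)
}

#' Run the whole pipeline end to end
#'
#' Convenience wrapper for `run_stage("all", config)`.
#'
#' @param config A [pipeline_config()] or YAML path.
#' @return Invisibly, the artifact paths.
#' @export
run_pipeline <- function(config) run_stage("all", config)
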