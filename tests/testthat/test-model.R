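test_that("the default category map regroups 44 types into 14 categories", {
  map <- default_category_map()
  expect_equal(length(attr(map, "categories")), 14L)
  expect_equal(nrow(map), 44L)
  counts <- table(map$category)
  want <- c("Abnormality" = 3, "Body Part" = 7, "Classification" = 1,
            "Functional Concept" = 1, "Location" = 3, "Medical Activity" = 6,
            "Medical Device and Object" = 2, "Observation" = 5,
            "Pathology" = 5, "Physiology" = 4, "Qualitative Concept" = 1,
            "Quantitative Concept" = 1, "Substance" = 4,
            "Temporal Concept" = 1)
  expect_equal(counts[names(want)], as.table(want), ignore_attr = TRUE)

  expect_equal(category_of(map, "Neoplastic Process"), "Pathology")
  expect_equal(category_of(map, "Temporal Concept"), "Temporal Concept")
  expect_equal(category_of(map, "Organism"), "OUT_OF_MODEL")

  expect_error(load_category_map(data.frame(
    semantic_type = c("Tissue", "Tissue"),
    category = c("Body Part", "Substance"))), "more than one")
})

test_that("lift_network aggregates by category and conserves weight", {
  map <- load_category_map(data.frame(
    semantic_type = c("X", "Y", "Z"), category = c("C", "C", "D")))
  net <- build_network(data.frame(
    subject_type = c(rep("X", 2), rep("Y", 3), "W"),
    object_type = c(rep("Y", 2), rep("X", 3), "Z"),
    stringsAsFactors = FALSE))
  lifted <- lift_network(net, map)
  cc <- lifted$edges$weight[lifted$edges$subject_type == "C" &
                              lifted$edges$object_type == "C"]
  expect_equal(cc, 5)  # (X->Y):2 + (Y->X):3
  # out-of-model endpoint (W) routed to the residual, conserving total mass
  expect_equal(lifted$residual_weight, 1)
  expect_equal(net$total_incidence_count,
               lifted$total_incidence_count + lifted$residual_weight)

  empty <- lift_network(build_network(data.frame(subject_type = character(0),
                                                 object_type = character(0))),
                        map)
  expect_equal(empty$distinct_pair_count, 0L)
})

test_that("relationship labels attach by category pair and surface form", {
  map <- default_category_map()
  net <- build_network(data.frame(
    subject_type = c("Spatial Concept", "Finding", "Finding"),
    object_type = c("Body Part Organ or Organ Component",
                    "Disease or Syndrome", "Disease or Syndrome"),
    stringsAsFactors = FALSE))
  model <- knowledge_model(lift_network(net, map), map)

  # empty label set leaves the model unchanged
  same <- attach_labels(model, data.frame(subject_category = character(0),
                                          object_category = character(0),
                                          label = character(0)))
  expect_equal(same$relationships$label, model$relationships$label)

  labeled <- attach_labels(model, system.file("extdata", "default_labels.tsv",
                                              package = "sublangr"))
  expect_true("Situated_at" %in%
                lookup_label(labeled, "Location", "Body Part", "of"))
  expect_true("Indicative_of" %in%
                lookup_label(labeled, "Observation", "Pathology", "of"))

  expect_error(attach_labels(model, data.frame(
    subject_category = "Nonesuch", object_category = "Body Part",
    label = "X")), "unknown categor")
})

test_that("model JSON export round-trips byte-identically", {
  map <- default_category_map()
  b <- suppressMessages(generate_fixtures(fixture_spec(seed = 3,
                                                       n_documents = 10)))
  net <- build_network(b$gold_triples)
  model <- attach_labels(knowledge_model(lift_network(net, map), map),
                         system.file("extdata", "default_labels.tsv",
                                     package = "sublangr"))
  json1 <- export_model(model, "json")
  back <- load_model_json(json1)
  json2 <- export_model(back, "json")
  expect_identical(json1, json2)

  # empty model exports valid JSON with empty relationship array
  empty <- knowledge_model(lift_network(build_network(
    data.frame(subject_type = character(0), object_type = character(0))),
    map), map)
  parsed <- jsonlite::fromJSON(export_model(empty, "json"))
  expect_length(parsed$relationships, 0L)
  expect_equal(length(parsed$categories$name), 14L)

  dot <- export_model(model, "dot")
  expect_true(any(grepl("style=dashed", dot)))  # significant edges dashed
  sig_n <- sum(model$relationships$significant)
  expect_equal(sum(grepl("style=dashed", dot)), sig_n)
})

test_that("the two report sentences lift to the expected category chains", {
  bundle <- example_corpus()
  lex <- quiet_lexicon()
  map <- default_category_map()
  chains <- list()
  for (doc in c("ex5", "ex6")) {
    line <- bundle$index$line_number[bundle$index$doc_id == doc]
    tagged <- tag_triples(extract_sro(bundle$trees[[line]], doc, 0L), lex)
    chains[[doc]] <- data.frame(
      s = category_of(map, tagged$subject_type), r = tagged$relation,
      o = category_of(map, tagged$object_type), stringsAsFactors = FALSE)
  }
  # "Serial IVU films showing widely separated pubic bones with absent symphysis"
  expect_equal(chains$ex5$s, c("Medical Activity", "Observation"))
  expect_equal(chains$ex5$o, c("Observation", "Body Part"))
  # "Complex L-transposition of the great arteries with cardiac pacemaker"
  expect_equal(chains$ex6$s, c("Abnormality", "Body Part"))
  expect_equal(chains$ex6$o, c("Medical Device and Object",
                               "Medical Device and Object"))
})
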