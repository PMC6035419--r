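test_that("one-vs-rest confusion counts follow the definitions", {
  # perfect agreement: FP = FN = 0 for every label
  rec <- data.frame(machine_label = rep(c("A", "B"), 5),
                    reference_label = rep(c("A", "B"), 5))
  cc <- confusion_counts(rec, c("A", "B"))
  expect_true(all(cc$FP == 0) && all(cc$FN == 0))
  expect_equal(cc$TP[cc$label == "Overall"], 10)

  # single disagreeing unit
  cc <- confusion_counts(data.frame(machine_label = "A",
                                    reference_label = "B"), c("A", "B"))
  expect_equal(unlist(cc[cc$label == "A", c("TP", "TN", "FP", "FN")]),
               c(TP = 0, TN = 0, FP = 1, FN = 0))
  expect_equal(unlist(cc[cc$label == "B", c("TP", "TN", "FP", "FN")]),
               c(TP = 0, TN = 0, FP = 0, FN = 1))

  # per-label TP+TN+FP+FN equals the unit count (one-vs-rest)
  set.seed(31)
  labels <- LETTERS[1:4]
  rec <- data.frame(machine_label = sample(labels, 20, replace = TRUE),
                    reference_label = sample(labels, 20, replace = TRUE))
  cc <- confusion_counts(rec, labels)
  per <- cc[cc$label != "Overall", ]
  expect_true(all(per$TP + per$TN + per$FP + per$FN == 20))
  # micro sums match an independent tally
  expect_equal(cc$TP[cc$label == "Overall"],
               sum(rec$machine_label == rec$reference_label))
  for (L in labels) {
    expect_equal(per$TP[per$label == L],
                 sum(rec$machine_label == L & rec$reference_label == L))
    expect_equal(per$FP[per$label == L],
                 sum(rec$machine_label == L & rec$reference_label != L))
    expect_equal(per$FN[per$label == L],
                 sum(rec$machine_label != L & rec$reference_label == L))
  }

  expect_error(confusion_counts(data.frame(machine_label = "Q",
                                           reference_label = "A"),
                                c("A", "B")), "outside the label set")

  # OUT_OF_MODEL reference units are excluded from the counts
  rec <- data.frame(machine_label = c("A", "A"),
                    reference_label = c("A", "OUT_OF_MODEL"))
  cc <- confusion_counts(rec, c("A"))
  expect_equal(attr(cc, "n_units"), 1L)
})

test_that("precision/recall/F arithmetic and degenerate cases", {
  m <- precision_recall_f(data.frame(label = "Abnormality", TP = 16,
                                     TN = 1660, FP = 4, FN = 12))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 16 / 28)
  expect_equal(round_half_up(m$f_score, 4), 0.6667)

  w <- capture_warnings(
    z <- precision_recall_f(data.frame(label = "X", TP = 0, TN = 0,
                                       FP = 0, FN = 0)))
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(unlist(z[, c("precision", "recall", "f_score")]),
               c(precision = 0, recall = 0, f_score = 0))

  # metric bounds and F <= max(P, R) on random counts
  set.seed(12)
  counts <- data.frame(label = paste0("L", 1:50),
                       TP = sample(0:40, 50, TRUE), TN = sample(0:40, 50, TRUE),
                       FP = sample(0:40, 50, TRUE), FN = sample(0:40, 50, TRUE))
  m <- suppressWarnings(precision_recall_f(counts))
  expect_true(all(m$precision >= 0 & m$precision <= 1))
  expect_true(all(m$recall >= 0 & m$recall <= 1))
  expect_true(all(m$f_score <= pmax(m$precision, m$recall) + 1e-12))
})

test_that("metric display formatting rounds half-up", {
  m <- precision_recall_f(data.frame(label = "Temporal Concept", TP = 56,
                                     TN = 1620, FP = 2, FN = 0))
  fm <- format_metrics(m)
  expect_equal(fm$precision, "96.6%")
  expect_equal(fm$recall, "100.0%")
  expect_equal(fm$f_score, "0.9825")
  expect_equal(round_half_up(0.15, 1), 0.2)  # exact half rounds up
})

test_that("relationship coverage and rater agreement", {
  expect_equal(as.numeric(relationship_coverage(c("a", "b"), c("a", "b", "c"))),
               1.0)

  tags <- c(rep("Occurs_in", 60), rep("Situated_at", 37), paste0("new", 1:3))
  cov <- relationship_coverage(tags, c("Occurs_in", "Situated_at"))
  expect_equal(as.numeric(cov), 0.97)
  expect_equal(attr(cov, "uncovered"), c("new1", "new2", "new3"))

  cov <- relationship_coverage(c("Occurs_in",
                                 "Biomedical Occupation or Discipline-related"),
                               c("Occurs_in"))
  expect_true("Biomedical Occupation or Discipline-related" %in%
                attr(cov, "uncovered"))

  expect_error(relationship_coverage(character(0), c("a")), "empty")

  expect_equal(rater_agreement(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(rater_agreement(c("a", "b", "c", "d"), c("a", "b", "c", "x")),
               0.75)
  expect_error(rater_agreement(c("a"), c("a", "b")), "length")

  set.seed(4)
  r1 <- sample(letters[1:5], 100, TRUE)
  r2 <- sample(letters[1:5], 100, TRUE)
  expect_equal(rater_agreement(r1, r2), sum(r1 == r2) / 100)
})
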