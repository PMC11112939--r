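test_that("grade assignment respects the declared boundary convention", {
  expect_equal(assign_grade(c(0.95, 0.94, 0.9399, 0.80, 0.7001, 0.70, 0.3)),
               c("A", "A", "B", "B", "B", "C", "C"))
  expect_error(assign_grade(1.2), "\\[0, 1\\]")
  expect_error(assign_grade(-0.1), "\\[0, 1\\]")
  # partition: every p maps to exactly one grade
  grid <- seq(0, 1, by = 0.001)
  gr <- assign_grade(grid)
  expect_true(all(gr %in% c("A", "B", "C")))
  expect_equal(sum(gr == "A"), sum(grid >= 0.94))
  expect_equal(sum(gr == "C"), sum(grid <= 0.7))
})

test_that("classifier separates separable data and is seed-deterministic", {
  g <- make_genome()
  # perfectly separable: euploid vs full multi-signal aneuploid
  params <- karyotype_params(0.5, 0.25, 0.15, 0.1, p_full_event = 1)
  tr <- make_training_set(600, g, params, noise_sd = 0.02, seed = 1)
  idx <- seq_len(400)
  model <- train_classifier(tr$features[idx, ], tr$labels[idx],
                            n_trees = 300, seed = 2)
  p <- predict_euploid_probability(model, tr$features[-idx, ])
  acc <- mean((p >= 0.5) == tr$labels[-idx])
  expect_gte(acc, 0.99)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(model$oob_accuracy, 0.95)

  # same seed twice -> identical predictions
  model2 <- train_classifier(tr$features[idx, ], tr$labels[idx],
                             n_trees = 300, seed = 2)
  expect_identical(predict_euploid_probability(model2, tr$features[-idx, ]), p)

  expect_error(train_classifier(tr$features[idx, ], rep(TRUE, 400)),
               "single class")
})

test_that("shuffled labels destroy the signal (permutation null)", {
  g <- make_genome()
  tr <- make_training_set(1200, g, seed = 3)
  set.seed(4)
  shuffled <- sample(tr$labels)
  idx <- seq_len(800)
  model <- train_classifier(tr$features[idx, ], shuffled[idx],
                            n_trees = 300, seed = 5)
  p <- predict_euploid_probability(model, tr$features[-idx, ])
  acc <- mean((p >= 0.5) == shuffled[-idx])
  prior <- max(mean(shuffled[-idx]), 1 - mean(shuffled[-idx]))
  # balanced-bootstrap forests predict ~ coin flips under the null; accuracy
  # cannot beat the class prior by more than noise
  expect_lt(acc, prior + 0.05)
  expect_gt(acc, 0.4)
})

test_that("well-trained grader is confident at the extremes", {
  g <- make_genome()
  tr <- make_training_set(1500, g, seed = 6)
  model <- train_classifier(tr$features, tr$labels, n_trees = 400, seed = 7)

  eup <- extract_features(callset_from_truth(make_truth(g), g, noise_sd = 0))
  expect_gt(predict_euploid_probability(model, eup), 0.9)

  multi <- make_truth(g, events = data.frame(
    chrom = c("chr1", "chr5", "chr9"), start = 0,
    end = default_genome_table()$length[c(1, 5, 9)],
    copy_change = c(1L, -1L, 1L), mosaic_fraction = 1,
    scope = "whole_chromosome"))
  aneu <- extract_features(callset_from_truth(multi, g, noise_sd = 0))
  expect_lt(predict_euploid_probability(model, aneu), 0.1)
})

test_that("transfer ranking follows grade, probability and morphology", {
  res <- data.frame(
    embryo_id = c("b", "a", "c"),
    p_euploid = c(0.85, 0.96, 0.30),
    grade = c("B", "A", "C"),
    stringsAsFactors = FALSE
  )
  ranked <- rank_embryos(res)
  expect_equal(ranked$embryo_id, c("a", "b"))
  expect_equal(ranked$transfer_rank, 1:2)

  expect_equal(nrow(rank_embryos(res[0, ])), 0)

  two_a <- data.frame(embryo_id = c("x", "y"), p_euploid = c(0.95, 0.96),
                      grade = "A", stringsAsFactors = FALSE)
  expect_equal(rank_embryos(two_a)$embryo_id, c("y", "x"))

  # morphology tie-break at equal p: high-quality Gardner set first
  tie <- data.frame(embryo_id = c("low", "high"), p_euploid = 0.9,
                    grade = "B", morphology_grade = c("4BC", "4AB"),
                    stringsAsFactors = FALSE)
  expect_equal(rank_embryos(tie)$embryo_id, c("high", "low"))

  # permutation stability under unique keys
  set.seed(8)
  big <- data.frame(embryo_id = sprintf("e%02d", 1:20),
                    p_euploid = round(seq(0.5, 0.99, length.out = 20), 3),
                    stringsAsFactors = FALSE)
  big$grade <- assign_grade(big$p_euploid)
  ref <- rank_embryos(big)$embryo_id
  for (r in 1:5) {
    perm <- big[sample(nrow(big)), ]
    expect_equal(rank_embryos(perm)$embryo_id, ref)
  }
})

test_that("cohort grade summary reports counts and A+B utilization", {
  s <- cohort_grade_summary(rep(c("A", "B", "C"), c(222, 112, 172)))
  expect_equal(unname(s$counts), c(222, 112, 172))
  expect_equal(s$utilization_pct, 66.0)
  expect_equal(cohort_grade_summary(rep("C", 10))$utilization_pct, 0.0)
  s2 <- cohort_grade_summary(rep(c("A", "B", "C"), c(161, 58, 59)))
  expect_equal(s2$utilization_pct, 78.8)
})

test_that("model archives round-trip through JSON", {
  g <- make_genome()
  tr <- make_training_set(300, g, seed = 9)
  model <- train_classifier(tr$features, tr$labels, n_trees = 50, seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  p1 <- predict_euploid_probability(model, tr$features)
  p2 <- predict_euploid_probability(back, tr$features)
  expect_equal(p2, p1, tolerance = 1e-12)
  expect_error(load_model(withr::local_tempfile(fileext = ".json",
                                                lines = "{}")),
               "archive")
})
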