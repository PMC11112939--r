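#' Train the random-forest euploidy classifier
#'
#' Fits a bagged ensemble of CART trees on the 11-feature representation
#' with balanced class bootstraps (the synthetic-cohort classes are
#' imbalanced) and reports the out-of-bag accuracy. The predicted euploidy
#' probability of a sample is the average terminal-node euploid proportion
#' across trees.
#'
#' @param features Data.frame containing the 11 feature columns (see
#'   [feature_names()]).
#' @param labels Logical vector, `TRUE` for euploid, aligned with rows.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(11))` = 3).
#' @param min_node Minimum node size to attempt a split (default 1).
#' @param balanced Balanced per-class bootstrap (default TRUE).
#' @param seed Optional integer seed.
#' @return An object of class `nics_rf` with elements `trees`,
#'   `oob_accuracy`, `n_trees`, `mtry`, `feature_names`, `class_balance`,
#'   `seed`.
#' @export
train_classifier <- function(features, labels, n_trees = 500,
                             mtry = floor(sqrt(11)), min_node = 1,
                             balanced = TRUE, seed = NULL) {
  X <- .feature_matrix(features)
  y <- as.integer(as.logical(labels))
  if (length(y) != nrow(X)) stop("labels do not align with feature rows")
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- .rf_train(X, y, as.integer(n_trees), as.integer(mtry),
                   as.integer(min_node), isTRUE(balanced))
  structure(list(
    trees = fit$trees,
    oob_accuracy = fit$oob_accuracy,
    oob_prob = fit$oob_prob,
    n_trees = n_trees, mtry = mtry, min_node = min_node,
    balanced = balanced, feature_names = feature_names(),
    class_balance = c(aneuploid = sum(y == 0), euploid = sum(y == 1)),
    seed = seed
  ), class = "nics_rf")
}

.feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (ncol(features) != 11) stop("feature matrix must have 11 columns")
    return(features)
  }
  missing <- setdiff(feature_names(), names(features))
  if (length(missing)) {
    stop("feature data is missing columns: ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(
    data.frame(lapply(features[, feature_names(), drop = FALSE], as.numeric)))
  colnames(X) <- feature_names()
  X
}

#' Predict euploidy probability
#'
#' @param model A `nics_rf` from [train_classifier()].
#' @param features Feature data.frame or 11-column matrix.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_euploid_probability <- function(model, features) {
  stopifnot(inherits(model, "nics_rf"))
  X <- .feature_matrix(features)
  .rf_predict(model$trees, X)
}

#' @export
print.nics_rf <- function(x, ...) {
  cat("<nics_rf> ", x$n_trees, " trees, mtry ", x$mtry,
      ", OOB accuracy ", round(x$oob_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' Assign an A/B/C transfer grade from a euploidy probability
#'
#' Grade A for p >= 0.94, grade C for p <= 0.7, grade B in between (the two
#' closed inequalities are the declared boundary convention).
#'
#' @param p_euploid Numeric vector of probabilities in [0, 1].
#' @return Character vector of grades "A"/"B"/"C".
#' @export
assign_grade <- function(p_euploid) {
  if (any(is.na(p_euploid)) || any(p_euploid < 0) || any(p_euploid > 1)) {
    stop("p_euploid must lie in [0, 1]")
  }
  ifelse(p_euploid >= 0.94, "A", ifelse(p_euploid <= 0.7, "C", "B"))
}

# Gardner-grade priority: inner cell mass + trophectoderm letters.
# High-quality (AA, AB, BA, BB) -> 1; other usable (AC, BC, CA, CB) -> 2;
# anything else / missing -> 3.
.morphology_priority <- function(morphology) {
  lett <- toupper(gsub("[^A-Za-z]", "", ifelse(is.na(morphology), "",
                                               morphology)))
  lett <- substr(lett, pmax(1, nchar(lett) - 1), nchar(lett))
  ifelse(lett %in% c("AA", "AB", "BA", "BB"), 1L,
         ifelse(lett %in% c("AC", "BC", "CA", "CB"), 2L, 3L))
}

#' Rank embryos for transfer
#'
#' A-grade embryos first, then B-grade; C-grade embryos are excluded from
#' transfer. Within a grade embryos are ordered by descending euploidy
#' probability, ties broken by morphology priority (high-quality Gardner
#' grades AA/AB/BA/BB before AC/BC/CA/CB), then by input order (stable).
#'
#' @param results Data.frame with `embryo_id`, `p_euploid`, `grade` and
#'   optionally `morphology_grade`.
#' @return The transferable rows, ordered, with a `transfer_rank` column.
#' @export
rank_embryos <- function(results) {
  if (!nrow(results)) {
    out <- results
    out$transfer_rank <- integer()
    return(out)
  }
  keep <- results$grade %in% c("A", "B")
  out <- results[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$transfer_rank <- integer()
    return(out)
  }
  morph <- if ("morphology_grade" %in% names(out)) {
    .morphology_priority(out$morphology_grade)
  } else rep(3L, nrow(out))
  ord <- order(match(out$grade, c("A", "B")), -out$p_euploid, morph)
  out <- out[ord, , drop = FALSE]
  out$transfer_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize grades across a cohort
#'
#' Per-grade counts and the A+B utilization share reported to one decimal.
#'
#' @param grades Character vector of grades, or a data.frame with a `grade`
#'   column (e.g. from [grade_embryos()]).
#' @return List with `counts` (named A/B/C), `total` and
#'   `utilization_pct` (A+B share of total, half-up to 1 decimal).
#' @export
cohort_grade_summary <- function(grades) {
  if (is.data.frame(grades)) grades <- grades$grade
  counts <- vapply(c("A", "B", "C"), function(g) sum(grades == g), 1L)
  total <- length(grades)
  util <- if (total == 0) 0 else .round_half_up(100 * (counts[["A"]] +
                                                         counts[["B"]]) / total, 1)
  list(counts = counts, total = total, utilization_pct = util)
}

#' Grade a feature table
#'
#' @param model A `nics_rf`.
#' @param features Feature data.frame with `embryo_id`.
#' @param morphology Optional character vector of Gardner grades.
#' @return Data.frame `embryo_id`, `p_euploid`, `grade`, `morphology_grade`.
#' @export
grade_embryos <- function(model, features, morphology = NULL) {
  p <- predict_euploid_probability(model, features)
  data.frame(
    embryo_id = features$embryo_id,
    p_euploid = p,
    grade = assign_grade(p),
    morphology_grade = if (is.null(morphology)) NA_character_ else morphology,
    stringsAsFactors = FALSE
  )
}

#' Build a labelled synthetic training cohort
#'
#' Simulates karyotypes, converts each to a callset via
#' [callset_from_truth()] (noisy truth-derived calls, no read-level
#' simulation) and extracts features and labels.
#'
#' @param n Number of embryos.
#' @param genome A `nics_genome`.
#' @param params Karyotype parameters, [karyotype_params()].
#' @param noise_sd Measurement noise on copy-number shifts.
#' @param seed Optional integer seed.
#' @return List with `features` (data.frame), `labels` (logical vector) and
#'   `truths` (list of `nics_truth`).
#' @export
make_training_set <- function(n, genome, params = karyotype_params(),
                              noise_sd = 0.04, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truths <- lapply(seq_len(n), function(i) {
    simulate_karyotype(genome, params, embryo_id = sprintf("embryo_%04d", i))
  })
  feats <- do.call(rbind, lapply(truths, function(tr) {
    extract_features(callset_from_truth(tr, genome, noise_sd = noise_sd))
  }))
  list(features = feats,
       labels = vapply(truths, `[[`, TRUE, "label_euploid"),
       truths = truths)
}

#' Persist / load a trained grader
#'
#' The model is stored as a JSON archive with version, hyperparameters,
#' seed and a hash of the tree ensemble.
#'
#' @param model A `nics_rf`.
#' @param path JSON path.
#' @return `path` (save) or a `nics_rf` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nics_rf"))
  payload <- list(
    format = "nicsgrade_rf", version = 1L,
    n_trees = model$n_trees, mtry = model$mtry, min_node = model$min_node,
    balanced = model$balanced, seed = model$seed,
    feature_names = model$feature_names,
    class_balance = as.list(model$class_balance),
    oob_accuracy = model$oob_accuracy,
    trees = model$trees
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "nicsgrade_rf")) {
    stop("not a nicsgrade random-forest archive: ", path)
  }
  trees <- x$trees
  if (is.data.frame(trees)) {
    trees <- lapply(seq_len(nrow(trees)), function(i) as.list(trees[i, ]))
  }
  trees <- lapply(trees, function(tr) {
    list(feat = as.integer(unlist(tr$feat)), thr = as.numeric(unlist(tr$thr)),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         pred = as.numeric(unlist(tr$pred)))
  })
  structure(list(
    trees = trees, oob_accuracy = x$oob_accuracy, n_trees = x$n_trees,
    mtry = x$mtry, min_node = x$min_node, balanced = x$balanced,
    feature_names = x$feature_names,
    class_balance = unlist(x$class_balance), seed = x$seed
  ), class = "nics_rf")
}

# round-half-up to `digits` decimals (matches how the clinical tables print)
.round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
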