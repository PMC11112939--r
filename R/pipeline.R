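#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one list: simulation, CBS, feature
#' thresholds, grade cuts and classifier hyperparameters. Validated by
#' [validate_config()]; serialized as YAML next to every run's outputs.
#'
#' @param n_embryos Embryos to simulate and grade.
#' @param seed Master seed for the run.
#' @param depth Reads per sample.
#' @param n_reference Euploid reference-panel size.
#' @param n_training Labelled synthetic embryos for classifier training.
#' @param out_dir Output directory.
#' @return A named list (class `nics_config`).
#' @export
default_config <- function(n_embryos = 50, seed = 7, depth = 2e6,
                           n_reference = 8, n_training = 1500,
                           out_dir = "nics_run") {
  structure(list(
    version = 1L,
    seed = seed,
    out_dir = out_dir,
    simulation = list(n_embryos = n_embryos, depth = depth,
                      dispersion = 0.05, gc_bias_strength = 4,
                      n_reference = n_reference),
    cbs = list(alpha = 0.01, n_perm = 1000, min_bins = 3, undo_sd = 1),
    calling = list(call_margin = 0.3, min_size_mb = 10),
    features = list(redefine_threshold = 0.5, full_threshold = 0.8),
    grading = list(grade_a = 0.94, grade_c = 0.7, n_trees = 500,
                   mtry = 3, n_training = n_training, training_noise_sd = 0.04)
  ), class = "nics_config")
}

#' Validate a pipeline configuration
#'
#' @param config A config list (e.g. [default_config()] or read from YAML).
#' @return The config, invisibly; errors on violations.
#' @export
validate_config <- function(config) {
  th <- c(config$features$redefine_threshold, config$features$full_threshold,
          config$grading$grade_a, config$grading$grade_c, config$cbs$alpha)
  if (any(!is.finite(th)) || any(th <= 0) || any(th >= 1)) {
    stop("all thresholds must lie in (0, 1)")
  }
  if (config$grading$grade_c >= config$grading$grade_a) {
    stop("grade thresholds must satisfy grade_c < grade_a ",
         "(got C cut ", config$grading$grade_c, " >= A cut ",
         config$grading$grade_a, ")")
  }
  if (config$simulation$n_embryos <= 0) stop("n_embryos must be positive")
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @param config Config list.
#' @return Config list (read) or `path` (write).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "nics_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate -> normalize/segment -> features -> grade -> summarize, writing
#' every artifact plus a manifest with content hashes and a resolved copy of
#' the configuration. Reruns with the same config produce identical hashes.
#'
#' @param config A `nics_config` (or path to a YAML config).
#' @param genome Optional `nics_genome`; default bundled human-like genome.
#' @param quiet Suppress progress lines.
#' @return The manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), genome = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, msg) {
    if (!quiet) {
      cat(jsonlite::toJSON(list(level = "INFO", stage = stage, msg = msg),
                           auto_unbox = TRUE), "\n")
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(genome)) genome <- make_genome()
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, 5)

  sim <- config$simulation
  gcb <- gc_bias_quadratic(sim$gc_bias_strength)

  log_line("simulate", paste("simulating", sim$n_embryos, "embryos"))
  paths <- character()
  truths <- counts <- vector("list", sim$n_embryos)
  stage("simulate", {
    set.seed(seeds[1])
    for (i in seq_len(sim$n_embryos)) {
      truths[[i]] <- simulate_karyotype(genome,
                                        embryo_id = sprintf("embryo_%03d", i))
      counts[[i]] <- simulate_read_counts(truths[[i]], genome,
                                          depth = sim$depth,
                                          dispersion = sim$dispersion,
                                          gc_bias = gcb)
      p <- file.path(config$out_dir, sprintf("embryo_%03d.counts.tsv", i))
      write_bin_counts(counts[[i]], genome, p)
      write_truth(truths[[i]],
                  file.path(config$out_dir,
                            sprintf("embryo_%03d.truth.json", i)))
      paths <- c(paths, p,
                 file.path(config$out_dir,
                           sprintf("embryo_%03d.truth.json", i)))
    }
  })

  log_line("reference", paste("building", sim$n_reference,
                              "euploid reference profiles"))
  reference <- stage("reference", {
    set.seed(seeds[2])
    lapply(seq_len(sim$n_reference), function(i) {
      tr <- make_truth(genome, sex = if (i %% 2) "XX" else "XY",
                       embryo_id = sprintf("ref_%02d", i))
      gc_normalize(simulate_read_counts(tr, genome, depth = sim$depth,
                                        dispersion = sim$dispersion,
                                        gc_bias = gcb), genome)
    })
  })

  log_line("segment", "normalizing and segmenting")
  callsets <- stage("segment", {
    set.seed(seeds[3])
    lapply(counts, function(ct) {
      call_sample(ct, genome, reference = reference,
                  alpha = config$cbs$alpha, n_perm = config$cbs$n_perm,
                  min_bins = config$cbs$min_bins,
                  undo_sd = config$cbs$undo_sd,
                  call_margin = config$calling$call_margin,
                  min_size_mb = config$calling$min_size_mb)
    })
  })
  seg_path <- file.path(config$out_dir, "segments.seg.tsv")
  stage("segment", {
    segs <- do.call(rbind, lapply(callsets, function(cs) {
      cbind(sample = cs$sample_id, cs$segments)
    }))
    write.table(segs, seg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  paths <- c(paths, seg_path)

  log_line("features", "extracting 11-feature vectors")
  feats <- stage("features", {
    do.call(rbind, lapply(callsets, extract_features,
                          redefine_threshold = config$features$redefine_threshold,
                          full_threshold = config$features$full_threshold))
  })
  feat_path <- file.path(config$out_dir, "features.csv")
  write_features(feats, feat_path)
  paths <- c(paths, feat_path)

  log_line("grade", paste("training grader on",
                          config$grading$n_training, "synthetic embryos"))
  grades <- stage("grade", {
    train <- make_training_set(config$grading$n_training, genome,
                               noise_sd = config$grading$training_noise_sd,
                               seed = seeds[4])
    model <- train_classifier(train$features, train$labels,
                              n_trees = config$grading$n_trees,
                              mtry = config$grading$mtry, seed = seeds[5])
    save_model(model, file.path(config$out_dir, "model.json"))
    g <- grade_embryos(model, feats)
    g
  })
  grades_path <- file.path(config$out_dir, "grades.csv")
  ranked <- rank_embryos(grades)
  grades$transfer_rank <- ranked$transfer_rank[match(grades$embryo_id,
                                                     ranked$embryo_id)]
  write.csv(grades[, c("embryo_id", "p_euploid", "grade", "transfer_rank")],
            grades_path, row.names = FALSE, quote = FALSE)
  paths <- c(paths, file.path(config$out_dir, "model.json"), grades_path)

  summary <- cohort_grade_summary(grades)
  summary_path <- file.path(config$out_dir, "grade_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(config$out_dir, "config.resolved.yaml")
  write_config(config, cfg_path)
  paths <- c(paths, summary_path, cfg_path)

  manifest <- list(
    config = unclass(config),
    artifacts = lapply(sort(paths), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    grade_summary = summary
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("done", paste("manifest written to",
                         file.path(config$out_dir, "manifest.json")))
  invisible(manifest)
}

.schemas <- c("bin_counts_tsv", "seg_tsv", "features_csv", "patients_csv",
              "grades_csv")

#' Validate a file against a named schema
#'
#' @param path File to check.
#' @param schema One of `bin_counts_tsv`, `seg_tsv`, `features_csv`,
#'   `patients_csv`, `grades_csv`.
#' @return List with `pass` (logical) and `violations` (data.frame `line`,
#'   `message`; line 0 refers to the whole file / header).
#' @export
validate_formats <- function(path, schema) {
  if (!schema %in% .schemas) {
    stop("unknown schema: ", schema, " (expected one of ",
         paste(.schemas, collapse = ", "), ")")
  }
  viol <- list()
  add <- function(line, msg) {
    viol[[length(viol) + 1]] <<- data.frame(line = line, message = msg,
                                            stringsAsFactors = FALSE)
  }
  sep <- if (grepl("tsv$", schema)) "\t" else ","
  lines <- tryCatch(readLines(path), error = function(e) NULL)
  if (is.null(lines) || !length(lines)) {
    add(0, "file is empty or unreadable")
  } else {
    header <- gsub('"', "", strsplit(lines[1], sep, fixed = TRUE)[[1]],
                   fixed = TRUE)
    need <- switch(schema,
      bin_counts_tsv = c("chrom", "start", "end", "gc", "count"),
      seg_tsv = c("sample", "chrom", "start", "end", "n_bins", "mean_cn",
                  "mosaic_est", "direction"),
      features_csv = c("embryo_id", feature_names()),
      patients_csv = .patient_columns,
      grades_csv = c("embryo_id", "p_euploid", "grade", "transfer_rank"))
    missing <- setdiff(need, header)
    if (length(missing)) {
      add(1, paste("missing column(s):", paste(missing, collapse = ", ")))
    } else {
      col <- function(df, name) df[[name]]
      df <- tryCatch(
        read.delim(path, sep = sep, stringsAsFactors = FALSE),
        error = function(e) NULL)
      if (is.null(df)) {
        add(0, "failed to parse file body")
      } else {
        nfield <- vapply(strsplit(lines[-1], sep, fixed = TRUE), length, 1L)
        short <- which(nfield != length(header))
        for (k in head(short, 10)) {
          add(k + 1, paste("expected", length(header), "fields, found",
                           nfield[k]))
        }
        if (schema == "bin_counts_tsv" && !length(short)) {
          bad <- which(is.na(df$count) | df$count < 0)
          for (k in head(bad, 10)) add(k + 1, "negative or missing count")
          bad <- which(df$end <= df$start)
          for (k in head(bad, 10)) add(k + 1, "end must exceed start")
        }
        if (schema == "patients_csv" && !length(short)) {
          bad <- which(!(df$live_birth <= df$ongoing &
                           df$ongoing <= df$clinical &
                           df$clinical <= df$biochemical))
          for (k in head(bad, 10)) {
            add(k + 1, paste("outcome nesting violated: require live_birth",
                             "<= ongoing <= clinical <= biochemical"))
          }
        }
        if (schema == "grades_csv" && !length(short)) {
          bad <- which(is.na(df$p_euploid) | df$p_euploid < 0 |
                         df$p_euploid > 1)
          for (k in head(bad, 10)) add(k + 1, "p_euploid outside [0, 1]")
          bad <- which(!df$grade %in% c("A", "B", "C"))
          for (k in head(bad, 10)) add(k + 1, "grade must be A, B or C")
        }
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(line = integer(), message = character(),
               stringsAsFactors = FALSE)
  list(pass = nrow(violations) == 0, violations = violations)
}
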