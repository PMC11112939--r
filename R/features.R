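.resolution_scope <- c("10mb" = "segmental", "arm" = "arm",
                       "chromosome" = "whole_chromosome")

.ordinal_levels <- c(euploid = 0, mosaic_abnormal = 1, full_abnormal = 2)

#' CNV call ordinal at one resolution
#'
#' The worst call among events whose scope matches the resolution:
#' `full_abnormal` (2) if any such event has mosaic fraction at or above
#' `full_threshold`, `mosaic_abnormal` (1) if any is below it, `euploid` (0)
#' otherwise.
#'
#' @param callset A `nics_callset`.
#' @param resolution One of "10mb", "arm", "chromosome".
#' @param full_threshold Fraction separating mosaic from full abnormality in
#'   the un-redefined features (default 0.8).
#' @return Integer ordinal 0/1/2.
#' @export
calls_at_resolution <- function(callset, resolution,
                                full_threshold = 0.8) {
  if (!resolution %in% names(.resolution_scope)) {
    stop("unknown resolution: ", resolution,
         " (expected one of 10mb, arm, chromosome)")
  }
  fr <- callset$calls$mosaic_fraction[
    callset$calls$scope == .resolution_scope[[resolution]]]
  if (!length(fr)) return(0L)
  if (any(fr >= full_threshold)) 2L else 1L
}

#' Redefined CNV call at one resolution (50% mosaicism threshold)
#'
#' Events below `threshold` are treated as euploid, events at or above it as
#' full abnormalities; the resolution ordinal is recomputed accordingly, so
#' the result is 0 or 2.
#'
#' @param callset A `nics_callset`.
#' @param resolution One of "10mb", "arm", "chromosome".
#' @param threshold Redefinition threshold in (0, 1); default 0.5, with the
#'   boundary counted as abnormal (>= rule).
#' @return Integer ordinal 0 or 2.
#' @export
redefine_by_threshold <- function(callset, resolution, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (!resolution %in% names(.resolution_scope)) {
    stop("unknown resolution: ", resolution)
  }
  fr <- callset$calls$mosaic_fraction[
    callset$calls$scope == .resolution_scope[[resolution]]]
  if (any(fr >= threshold)) 2L else 0L
}

#' Extract the 11-feature embryo representation
#'
#' The feature vector consumed by the euploidy grader:
#' f1/f3/f5 are the CNV ordinals at 10 Mb, arm and whole-chromosome
#' resolution; f2/f4/f6 are the same ordinals redefined by the 50%
#' mosaicism threshold; f7 counts the resolutions whose redefined call is
#' euploid (0-3); f8 counts distinct chromosomes carrying any call; f9 is
#' the highest mosaic fraction among calls; f10 is the span (Mb) of the
#' largest call attaining f9; f11 flags a sex-chromosome abnormality.
#'
#' @param callset A `nics_callset`.
#' @param redefine_threshold 50% mosaicism redefinition threshold.
#' @param full_threshold Mosaic/full boundary for the raw ordinals.
#' @return One-row data.frame with `embryo_id` and columns `f1_cnv_10mb`,
#'   `f2_cnv_10mb_redef`, `f3_cnv_arm`, `f4_cnv_arm_redef`, `f5_cnv_chrom`,
#'   `f6_cnv_chrom_redef`, `f7_euploid_resolution_count`,
#'   `f8_abnormal_chrom_count`, `f9_max_mosaic_fraction`,
#'   `f10_largest_fragment_at_max_mosaic_mb`, `f11_sex_chrom_abnormal`.
#' @export
extract_features <- function(callset, redefine_threshold = 0.5,
                             full_threshold = 0.8) {
  raw <- vapply(names(.resolution_scope), function(r) {
    calls_at_resolution(callset, r, full_threshold)
  }, 1L)
  redef <- vapply(names(.resolution_scope), function(r) {
    redefine_by_threshold(callset, r, redefine_threshold)
  }, 1L)
  calls <- callset$calls
  f8 <- length(unique(calls$chrom))
  f9 <- if (nrow(calls)) max(calls$mosaic_fraction) else 0
  f10 <- if (nrow(calls) && f9 > 0) {
    at_max <- calls$length_mb[calls$mosaic_fraction >= f9 - 1e-12]
    max(at_max)
  } else 0
  data.frame(
    embryo_id = callset$sample_id,
    f1_cnv_10mb = raw[["10mb"]],
    f2_cnv_10mb_redef = redef[["10mb"]],
    f3_cnv_arm = raw[["arm"]],
    f4_cnv_arm_redef = redef[["arm"]],
    f5_cnv_chrom = raw[["chromosome"]],
    f6_cnv_chrom_redef = redef[["chromosome"]],
    f7_euploid_resolution_count = sum(redef == 0L),
    f8_abnormal_chrom_count = f8,
    f9_max_mosaic_fraction = f9,
    f10_largest_fragment_at_max_mosaic_mb = f10,
    f11_sex_chrom_abnormal = callset$sex_call == "abnormal",
    stringsAsFactors = FALSE
  )
}

#' Names of the 11 feature columns
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("f1_cnv_10mb", "f2_cnv_10mb_redef", "f3_cnv_arm", "f4_cnv_arm_redef",
    "f5_cnv_chrom", "f6_cnv_chrom_redef", "f7_euploid_resolution_count",
    "f8_abnormal_chrom_count", "f9_max_mosaic_fraction",
    "f10_largest_fragment_at_max_mosaic_mb", "f11_sex_chrom_abnormal")
}

#' Write / read a feature table as CSV
#'
#' @param features Data.frame of feature rows (from [extract_features()]).
#' @param path CSV path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_features <- function(features, path) {
  stopifnot(all(c("embryo_id", feature_names()) %in% names(features)))
  write.csv(features[, c("embryo_id", feature_names())], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("embryo_id", feature_names()), names(df))
  if (length(missing)) {
    stop("feature CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df$f11_sex_chrom_abnormal <- as.logical(df$f11_sex_chrom_abnormal)
  df
}
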