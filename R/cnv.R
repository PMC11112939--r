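#' Load per-bin counts from TSV
#'
#' Validates the file against the genome model bin-by-bin and rejects any
#' mismatch naming the first discrepancy.
#'
#' @param path TSV with header `chrom start end gc count`.
#' @param genome The `nics_genome` the counts must align to.
#' @param sample_id Sample identifier (default: file base name).
#' @return A `nics_bincounts`.
#' @export
load_bin_counts <- function(path, genome,
                            sample_id = sub("\\.tsv$", "", basename(path))) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "count")
  if (!all(need %in% names(df))) {
    stop("bin-counts file must have columns: ", paste(need, collapse = ", "))
  }
  bins <- genome$bins
  if (nrow(df) != nrow(bins)) {
    stop("bin count mismatch: file has ", nrow(df), " bins, genome has ",
         nrow(bins))
  }
  bad <- which(df$chrom != bins$chrom | df$start != bins$start |
                 df$end != bins$end)
  if (length(bad)) {
    stop("bin ", bad[1], " does not match the genome model (file: ",
         df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]],
         ", genome: ", bins$chrom[bad[1]], ":", bins$start[bad[1]], "-",
         bins$end[bad[1]], ")")
  }
  if (any(is.na(df$count)) || any(df$count < 0)) {
    stop("negative or missing count at bin ",
         which(is.na(df$count) | df$count < 0)[1])
  }
  structure(list(sample_id = sample_id, counts = as.integer(df$count)),
            class = "nics_bincounts")
}

#' GC-normalize per-bin counts to a copy-number profile
#'
#' Counts are corrected by a smoothed per-GC-stratum median factor (2%-wide
#' GC strata over autosomal bins, linearly interpolated), then scaled so the
#' autosomal median equals 2 copies.
#'
#' @param counts A `nics_bincounts`.
#' @param genome The matching `nics_genome`.
#' @param gc_stratum_width Width of the GC strata (default 0.02).
#' @return An object of class `nics_profile`: list with `sample_id`, per-bin
#'   `cn` (copy number) and `weight`.
#' @export
gc_normalize <- function(counts, genome, gc_stratum_width = 0.02) {
  x <- counts$counts
  if (sum(x) <= 0) stop("all-zero counts cannot be normalized")
  bins <- genome$bins
  rate <- x / ifelse(bins$mappability > 0, bins$mappability, NA)
  auto <- .autosomal(genome)

  stratum <- floor(bins$gc / gc_stratum_width)
  med <- tapply(rate[auto], stratum[auto], median, na.rm = TRUE)
  centers <- (as.numeric(names(med)) + 0.5) * gc_stratum_width
  keep <- is.finite(med) & med > 0
  if (sum(keep) >= 2) {
    # light linear smoothing across strata, then interpolate per bin
    sm <- med[keep]
    if (length(sm) >= 3) {
      sm <- stats::filter(sm, rep(1 / 3, 3), sides = 2)
      sm[is.na(sm)] <- med[keep][is.na(sm)]
    }
    fac <- approx(centers[keep], as.numeric(sm), xout = bins$gc,
                  rule = 2)$y
    fac <- fac / median(fac[auto])
  } else {
    fac <- rep(1, nrow(bins))
  }
  corrected <- rate / pmax(fac, 1e-6)
  cn <- 2 * corrected / median(corrected[auto], na.rm = TRUE)
  cn[is.na(cn)] <- 0
  structure(list(sample_id = counts$sample_id, cn = as.numeric(cn),
                 weight = rep(1, length(cn))),
            class = "nics_profile")
}

#' Normalize a profile against a reference panel
#'
#' Divides each bin by the panel's per-bin median copy number (rescaled to
#' the diploid baseline), attenuating recurrent positional biases shared
#' between sample and panel. Bins where the panel median is near zero (for
#' example chrY in an all-XX panel) are left unscaled.
#'
#' @param profile A `nics_profile`.
#' @param reference List of `nics_profile` objects from euploid samples on
#'   the same genome; at least one required, five or more recommended.
#' @param genome The matching `nics_genome`.
#' @return A `nics_profile`.
#' @export
reference_normalize <- function(profile, reference, genome) {
  if (length(reference) == 0) stop("reference panel is empty")
  n <- length(profile$cn)
  if (any(vapply(reference, function(r) length(r$cn), 1L) != n)) {
    stop("reference profiles do not match the sample's bin count")
  }
  if (length(reference) < 5) {
    warning("reference panel has fewer than 5 profiles; ",
            "positional correction will be noisy")
  }
  panel <- do.call(cbind, lapply(reference, `[[`, "cn"))
  ref <- apply(panel, 1, median)
  auto <- .autosomal(genome)
  usable <- ref > 0.1
  cn <- profile$cn
  cn[usable] <- 2 * cn[usable] / ref[usable]
  cn <- 2 * cn / median(cn[auto & usable])
  structure(list(sample_id = profile$sample_id, cn = cn,
                 weight = profile$weight),
            class = "nics_profile")
}

# Merge adjacent segments whose mean difference is below undo_sd * noise SD.
.undo_merge <- function(bp, x, undo_sd, sigma) {
  repeat {
    if (length(bp) <= 2) return(bp)
    means <- vapply(seq_len(length(bp) - 1), function(k) {
      mean(x[(bp[k] + 1):bp[k + 1]])
    }, 1.0)
    d <- abs(diff(means))
    if (!length(d) || min(d) >= undo_sd * sigma) return(bp)
    k <- which.min(d)
    bp <- bp[-(k + 1)]
  }
}

#' Segment a copy-number profile with circular binary segmentation
#'
#' Recursive CBS per chromosome: at each step the arc maximizing the scaled
#' two-sample mean-difference statistic between arc and complement is found;
#' the split is accepted when its permutation p-value is below `alpha`
#' (`n_perm` permutations, early-terminated once rejection is certain), and
#' the algorithm recurses into the resulting pieces. Adjacent segments whose
#' means differ by less than `undo_sd` times the estimated noise SD are
#' re-merged. Chromosomes shorter than `2 * min_bins` are returned as a
#' single segment.
#'
#' @param profile A `nics_profile`.
#' @param genome The matching `nics_genome`.
#' @param alpha Permutation significance level (default 0.01).
#' @param n_perm Number of permutations (default 1000).
#' @param min_bins Minimum bins per segment piece (default 3).
#' @param undo_sd Merge threshold in noise-SD units (default 1).
#' @param seed Optional integer seed for the permutation stream.
#' @return A data.frame of segments: `chrom`, `start_bin`, `end_bin`
#'   (genome-wide bin indices, 0-based half-open), `n_bins`, `start`, `end`
#'   (bp), `mean_cn`, `mosaic_est`, `direction`, `length_mb`.
#' @export
segment_cbs <- function(profile, genome, alpha = 0.01, n_perm = 1000,
                        min_bins = 3, undo_sd = 1, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1, min_bins >= 1)
  if (!is.null(seed)) set.seed(seed)
  bins <- genome$bins
  out <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    x <- profile$cn[idx]
    n <- length(x)
    bp <- c(0L, n)
    if (n >= 2 * min_bins) {
      splits <- .cbs_recurse(x, 0L, n, alpha, n_perm, min_bins)
      bp <- sort(unique(c(0L, splits, n)))
      sigma <- if (n >= 3) mad(diff(x)) / sqrt(2) else 0
      if (sigma > 0) bp <- .undo_merge(bp, x, undo_sd, sigma)
    }
    for (k in seq_len(length(bp) - 1)) {
      lo <- bp[k]
      hi <- bp[k + 1]
      seg_bins <- idx[(lo + 1):hi]
      m <- mean(profile$cn[seg_bins])
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start_bin = idx[1] - 1L + lo,
        end_bin = idx[1] - 1L + hi,
        n_bins = hi - lo,
        start = bins$start[seg_bins[1]],
        end = bins$end[seg_bins[length(seg_bins)]],
        mean_cn = m,
        stringsAsFactors = FALSE
      )
    }
  }
  seg <- do.call(rbind, out)
  est <- estimate_mosaicism(seg$mean_cn)
  seg$mosaic_est <- est$fraction
  seg$direction <- est$direction
  seg$length_mb <- (seg$end - seg$start) / 1e6
  seg
}

# Recursive split search; returns global breakpoints (bin offsets within the
# chromosome vector x) strictly inside (s, e).
.cbs_recurse <- function(x, s, e, alpha, n_perm, min_bins) {
  n <- e - s
  if (n < 2 * min_bins) return(integer())
  res <- .cbs_find_split(x[(s + 1):e], alpha, n_perm, min_bins)
  if (!isTRUE(res$accept)) return(integer())
  i <- s + res$i
  j <- s + res$j
  bps <- integer()
  if (i > s) bps <- c(bps, i)
  if (j < e) bps <- c(bps, j)
  for (piece in list(c(s, i), c(i, j), c(j, e))) {
    if (piece[2] - piece[1] >= 2 * min_bins) {
      bps <- c(bps, .cbs_recurse(x, piece[1], piece[2], alpha, n_perm,
                                 min_bins))
    }
  }
  sort(unique(bps))
}

#' Mosaic-fraction estimate from a segment mean
#'
#' Under the single-aberrant-copy model a segment carrying an event at
#' mosaic fraction m has mean copy number 2 + m (gain) or 2 - m (loss) on
#' autosomes, so the fraction estimate is `min(|mean_cn - baseline|, 1)`.
#' Direction is gain/loss when the mean deviates from baseline by more than
#' `call_margin`, else neutral.
#'
#' @param mean_cn Numeric vector of segment mean copy numbers.
#' @param call_margin Neutral zone half-width (default 0.3).
#' @param baseline Expected copy number (2 for autosomes).
#' @return List with `fraction` and `direction` vectors.
#' @export
estimate_mosaicism <- function(mean_cn, call_margin = 0.3, baseline = 2) {
  dev <- mean_cn - baseline
  list(
    fraction = pmin(abs(dev), 1),
    direction = ifelse(dev > call_margin, "gain",
                       ifelse(dev < -call_margin, "loss", "neutral"))
  )
}

# Expected sex-chromosome copy numbers per sex call.
.sex_expectation <- function(sex) {
  if (sex == "XX") c(X = 2, Y = 0) else c(X = 1, Y = 1)
}

.is_x <- function(chrom) chrom %in% c("chrX", "X")
.is_y <- function(chrom) chrom %in% c("chrY", "Y")

# scope of one call on its chromosome: whole_chromosome if it covers >= 90%
# of the chromosome's bins, arm if >= 90% of exactly one arm, else segmental.
.call_scope <- function(start_bin, end_bin, chrom_bins, arm) {
  nb <- end_bin - start_bin
  covered <- seq(start_bin, end_bin - 1)
  if (nb >= 0.9 * length(chrom_bins)) return("whole_chromosome")
  for (a in c("p", "q")) {
    arm_bins <- chrom_bins[arm == a]
    if (length(arm_bins) == 0) next
    frac_arm <- sum(covered %in% arm_bins) / length(arm_bins)
    if (frac_arm >= 0.9 && sum(!(covered %in% arm_bins)) <= 0.1 * nb) {
      return("arm")
    }
  }
  "segmental"
}

#' Call CNVs from segments
#'
#' Filters segments to reportable calls (deviation at least `call_margin`
#' copies and span at least `min_size_mb`), assigns each call a scope
#' (whole-chromosome / arm / segmental by 90% coverage), classes each
#' chromosome by its worst call, and calls sample sex from the chrX/chrY
#' medians (abnormal when the medians are more than 0.35 copies away from
#' both the XX and the XY expectation).
#'
#' @param segments Segment data.frame from [segment_cbs()].
#' @param genome The matching `nics_genome`.
#' @param profile Optional `nics_profile` used for sex-chromosome medians;
#'   if omitted, segment means weighted by bins are used.
#' @param call_margin Minimum copy-number deviation (default 0.3).
#' @param min_size_mb Minimum call span in Mb (default 10).
#' @param sex_margin Maximum deviation from a sex expectation (default 0.35).
#' @return An object of class `nics_callset`: list with `sample_id`,
#'   `calls` (data.frame incl. `mosaic_fraction` and `scope`),
#'   `chrom_class` (named vector: euploid/segmental/arm/whole_chromosome),
#'   `sex_call` ("XX"/"XY"/"abnormal") and the input `segments`.
#' @export
call_cnvs <- function(segments, genome, profile = NULL, call_margin = 0.3,
                      min_size_mb = 10, sex_margin = 0.35) {
  bins <- genome$bins
  seg <- segments

  seg_med <- function(mask_chrom) {
    s <- seg[mask_chrom(seg$chrom), , drop = FALSE]
    if (!nrow(s)) return(NA_real_)
    rep_means <- rep(s$mean_cn, s$n_bins)
    median(rep_means)
  }
  med_x <- seg_med(.is_x)
  med_y <- seg_med(.is_y)
  sex_call <- "abnormal"
  fit_xx <- fit_xy <- Inf
  if (!is.na(med_x)) {
    exp_xx <- .sex_expectation("XX")
    exp_xy <- .sex_expectation("XY")
    dev_y <- function(expect) if (is.na(med_y)) 0 else abs(med_y - expect)
    fit_xx <- max(abs(med_x - exp_xx["X"]), dev_y(exp_xx["Y"]))
    fit_xy <- max(abs(med_x - exp_xy["X"]), dev_y(exp_xy["Y"]))
    if (min(fit_xx, fit_xy) <= sex_margin) {
      sex_call <- if (fit_xx <= fit_xy) "XX" else "XY"
    }
  } else if (is.na(med_x) && is.na(med_y)) {
    sex_call <- "XX" # no sex chromosomes in this genome model
    fit_xx <- 0
  }

  # baseline per segment: 2 on autosomes; sex expectation (under the closer
  # sex model) on chrX/chrY
  base <- rep(2, nrow(seg))
  nearest_sex <- if (fit_xx <= fit_xy) "XX" else "XY"
  expct <- .sex_expectation(nearest_sex)
  base[.is_x(seg$chrom)] <- expct["X"]
  base[.is_y(seg$chrom)] <- expct["Y"]

  dev <- seg$mean_cn - base
  frac <- pmin(abs(dev), 1)
  direction <- ifelse(dev > call_margin, "gain",
                      ifelse(dev < -call_margin, "loss", "neutral"))
  is_call <- direction != "neutral" & frac >= call_margin &
    seg$length_mb >= min_size_mb

  calls <- seg[is_call, , drop = FALSE]
  chrom_levels <- unique(bins$chrom)
  chrom_class <- setNames(rep("euploid", length(chrom_levels)), chrom_levels)
  if (nrow(calls)) {
    calls$mosaic_fraction <- frac[is_call]
    calls$direction <- direction[is_call]
    arm_by_chrom <- split(bins$arm, factor(bins$chrom, levels = chrom_levels))
    idx_by_chrom <- split(seq_len(nrow(bins)) - 1L,
                          factor(bins$chrom, levels = chrom_levels))
    calls$scope <- vapply(seq_len(nrow(calls)), function(k) {
      ch <- calls$chrom[k]
      .call_scope(calls$start_bin[k], calls$end_bin[k],
                  idx_by_chrom[[ch]], arm_by_chrom[[ch]])
    }, "")
    rank <- c(segmental = 1, arm = 2, whole_chromosome = 3)
    for (ch in unique(calls$chrom)) {
      sc <- calls$scope[calls$chrom == ch]
      chrom_class[ch] <- names(rank)[max(rank[sc])]
    }
  } else {
    calls <- cbind(calls, data.frame(mosaic_fraction = numeric(),
                                     direction = character(),
                                     scope = character()))
  }
  rownames(calls) <- NULL
  structure(list(
    sample_id = attr(segments, "sample_id") %||% "sample",
    calls = calls, chrom_class = chrom_class, sex_call = sex_call,
    segments = seg
  ), class = "nics_callset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full CNV-calling chain on one sample
#'
#' [gc_normalize()] then optional [reference_normalize()], [segment_cbs()]
#' and [call_cnvs()].
#'
#' @param counts A `nics_bincounts`.
#' @param genome A `nics_genome`.
#' @param reference Optional list of euploid `nics_profile`s.
#' @param alpha,n_perm,min_bins,undo_sd CBS parameters; see [segment_cbs()].
#' @param call_margin,min_size_mb Call filters; see [call_cnvs()].
#' @param seed Optional seed for the CBS permutations.
#' @return A `nics_callset`.
#' @export
call_sample <- function(counts, genome, reference = NULL, alpha = 0.01,
                        n_perm = 1000, min_bins = 3, undo_sd = 1,
                        call_margin = 0.3, min_size_mb = 10, seed = NULL) {
  prof <- gc_normalize(counts, genome)
  if (!is.null(reference) && length(reference)) {
    prof <- reference_normalize(prof, reference, genome)
  }
  seg <- segment_cbs(prof, genome, alpha = alpha, n_perm = n_perm,
                     min_bins = min_bins, undo_sd = undo_sd, seed = seed)
  attr(seg, "sample_id") <- counts$sample_id
  call_cnvs(seg, genome, profile = prof, call_margin = call_margin,
            min_size_mb = min_size_mb)
}

#' Write segments as a SEG-style TSV
#'
#' Columns `sample chrom start end n_bins mean_cn mosaic_est direction`.
#'
#' @param segments Segment data.frame from [segment_cbs()].
#' @param sample_id Sample identifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, sample_id, path) {
  df <- data.frame(sample = sample_id, chrom = segments$chrom,
                   start = format(segments$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(segments$end, scientific = FALSE,
                                trim = TRUE),
                   n_bins = segments$n_bins,
                   mean_cn = round(segments$mean_cn, 4),
                   mosaic_est = round(segments$mosaic_est, 4),
                   direction = segments$direction)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CNV callset as JSON
#'
#' @param callset A `nics_callset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(callset, path) {
  jsonlite::write_json(list(
    sample_id = callset$sample_id,
    sex_call = callset$sex_call,
    chrom_class = as.list(callset$chrom_class),
    calls = callset$calls
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a CNV callset directly from a simulated truth
#'
#' Converts the true events of a `nics_truth` into calls with a small
#' Gaussian measurement error on the mosaic-fraction estimate, emulating the
#' output of the sequencing + segmentation chain without its cost. Used to
#' build large labelled training cohorts for the grader; the fidelity of the
#' full chain itself is established by the segmentation and recovery tests.
#'
#' @param truth A `nics_truth`.
#' @param genome A `nics_genome`.
#' @param noise_sd SD of the error added to the true copy-number shift
#'   (default 0.04, matching the per-chromosome shallow-sequencing error at
#'   around 2M reads).
#' @param call_margin,min_size_mb Call filters as in [call_cnvs()].
#' @return A `nics_callset`.
#' @export
callset_from_truth <- function(truth, genome, noise_sd = 0.04,
                               call_margin = 0.3, min_size_mb = 10) {
  bins <- genome$bins
  chrom_levels <- unique(bins$chrom)
  ev <- truth$events
  calls <- list()
  arm_by_chrom <- split(bins$arm, factor(bins$chrom, levels = chrom_levels))
  idx_by_chrom <- split(seq_len(nrow(bins)) - 1L,
                        factor(bins$chrom, levels = chrom_levels))
  chrom_class <- setNames(rep("euploid", length(chrom_levels)), chrom_levels)
  sex_abnormal <- FALSE
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      ch <- ev$chrom[k]
      in_chrom <- which(bins$chrom == ch)
      hit <- in_chrom[bins$start[in_chrom] < ev$end[k] &
                        bins$end[in_chrom] > ev$start[k]]
      if (!length(hit)) next
      shift <- ev$copy_change[k] * ev$mosaic_fraction[k] + rnorm(1, 0, noise_sd)
      frac <- min(abs(shift), 1)
      length_mb <- (bins$end[max(hit)] - bins$start[min(hit)]) / 1e6
      if (frac < call_margin || length_mb < min_size_mb) next
      scope <- .call_scope(min(hit) - 1L, max(hit), idx_by_chrom[[ch]],
                           arm_by_chrom[[ch]])
      calls[[length(calls) + 1]] <- data.frame(
        chrom = ch, start_bin = min(hit) - 1L, end_bin = max(hit),
        n_bins = length(hit), start = bins$start[min(hit)],
        end = bins$end[max(hit)],
        mean_cn = 2 + shift, mosaic_est = frac,
        direction = if (shift > 0) "gain" else "loss",
        length_mb = length_mb, mosaic_fraction = frac, scope = scope,
        stringsAsFactors = FALSE
      )
      rank <- c(euploid = 0, segmental = 1, arm = 2, whole_chromosome = 3)
      if (rank[scope] > rank[chrom_class[ch]]) chrom_class[ch] <- scope
      if ((.is_x(ch) || .is_y(ch)) && frac >= 0.35) sex_abnormal <- TRUE
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start_bin = integer(),
               end_bin = integer(), n_bins = integer(),
               start = numeric(), end = numeric(), mean_cn = numeric(),
               mosaic_est = numeric(), direction = character(),
               length_mb = numeric(), mosaic_fraction = numeric(),
               scope = character(), stringsAsFactors = FALSE)
  structure(list(
    sample_id = truth$embryo_id, calls = calls, chrom_class = chrom_class,
    sex_call = if (sex_abnormal) "abnormal" else truth$sex,
    segments = NULL
  ), class = "nics_callset")
}
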