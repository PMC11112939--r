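#' Default karyotype-simulation parameters
#'
#' Event-category probabilities and mosaic-fraction model for
#' [simulate_karyotype()]. The taxonomy (whole-chromosome, arm-level and
#' segmental events of at least 10 Mb, with a continuous mosaic fraction)
#' mirrors the resolutions the grading features are defined on.
#'
#' @param p_euploid,p_whole,p_arm,p_segmental Probabilities of drawing an
#'   embryo with no event, a whole-chromosome event, an arm-level event or a
#'   segmental event. Must sum to 1.
#' @param p_full_event Probability that an event is non-mosaic (fraction 1).
#' @param mosaic_range Range of the uniform mosaic-fraction draw for mosaic
#'   events.
#' @param min_segment_mb,max_segment_mb Segmental event span bounds in Mb.
#' @param p_male Probability of an XY embryo.
#' @param contamination_range Range of the uniform maternal-contamination
#'   fraction; `c(0, 0)` disables contamination (the sampling protocol is
#'   designed to remove maternal DNA, so the default is none).
#' @return A named list of parameters.
#' @export
karyotype_params <- function(p_euploid = 0.4, p_whole = 0.3, p_arm = 0.15,
                             p_segmental = 0.15, p_full_event = 0.5,
                             mosaic_range = c(0.2, 0.8),
                             min_segment_mb = 10, max_segment_mb = 60,
                             p_male = 0.5, contamination_range = c(0, 0)) {
  p <- c(p_euploid, p_whole, p_arm, p_segmental)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("event-category probabilities must be non-negative and sum to 1")
  }
  if (min_segment_mb < 10) {
    stop("segmental events must span at least 10 Mb")
  }
  list(p_euploid = p_euploid, p_whole = p_whole, p_arm = p_arm,
       p_segmental = p_segmental, p_full_event = p_full_event,
       mosaic_range = mosaic_range, min_segment_mb = min_segment_mb,
       max_segment_mb = max_segment_mb, p_male = p_male,
       contamination_range = contamination_range)
}

.sample1 <- function(v) v[sample.int(length(v), 1)]

.empty_events <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             copy_change = integer(), mosaic_fraction = numeric(),
             scope = character(), stringsAsFactors = FALSE)
}

#' Whether an event list is labelled euploid for classifier training
#'
#' The training label calls an embryo aneuploid iff it carries any event
#' with mosaic fraction >= 0.5 (including full, non-mosaic events);
#' low-fraction mosaics are labelled euploid-compatible, consistent with the
#' 50%-threshold redefinition used in the grading features.
#'
#' @param events Event data.frame as in [simulate_karyotype()].
#' @return Logical scalar.
#' @export
label_euploid <- function(events) {
  nrow(events) == 0 || all(events$mosaic_fraction < 0.5)
}

#' Simulate an embryo karyotype
#'
#' Draws an embryo sex, an event category (euploid / whole-chromosome /
#' arm / segmental), event coordinates and a mosaic fraction, and the
#' maternal-contamination fraction of the medium sample.
#'
#' @param genome A `nics_genome`.
#' @param params Parameters from [karyotype_params()].
#' @param embryo_id Sample identifier.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `nics_truth`: list with `embryo_id`, `sex`
#'   ("XX"/"XY"), `events` (data.frame `chrom`, `start`, `end`,
#'   `copy_change`, `mosaic_fraction`, `scope`), `contamination_fraction`
#'   and `label_euploid`.
#' @export
simulate_karyotype <- function(genome, params = karyotype_params(),
                               embryo_id = "embryo", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- genome$chromosomes
  sex <- if (runif(1) < params$p_male) "XY" else "XX"
  type <- sample(c("euploid", "whole_chromosome", "arm", "segmental"), 1,
                 prob = c(params$p_euploid, params$p_whole, params$p_arm,
                          params$p_segmental))
  events <- .empty_events()
  if (type != "euploid") {
    mosaic <- if (runif(1) < params$p_full_event) 1 else
      runif(1, params$mosaic_range[1], params$mosaic_range[2])
    delta <- sample(c(-1L, 1L), 1)
    # an XX embryo carries no Y material, so Y events would be invisible
    allowed <- if (sex == "XX") !(tab$name %in% c("chrY", "Y")) else
      rep(TRUE, nrow(tab))
    if (type == "segmental") {
      # segmental events need room for >= min_segment_mb
      ok <- allowed & tab$length / 1e6 > params$min_segment_mb + 1
      k <- .sample1(which(ok))
      span_mb <- runif(1, params$min_segment_mb,
                       min(params$max_segment_mb, tab$length[k] / 1e6))
      start <- runif(1, 0, tab$length[k] - span_mb * 1e6)
      ev <- data.frame(chrom = tab$name[k], start = start,
                       end = start + span_mb * 1e6)
    } else if (type == "arm") {
      k <- .sample1(which(allowed))
      arm <- sample(c("p", "q"), 1)
      ev <- if (arm == "p") {
        data.frame(chrom = tab$name[k], start = 0, end = tab$centromere[k])
      } else {
        data.frame(chrom = tab$name[k], start = tab$centromere[k],
                   end = tab$length[k])
      }
    } else {
      k <- .sample1(which(allowed))
      ev <- data.frame(chrom = tab$name[k], start = 0, end = tab$length[k])
    }
    ev$copy_change <- delta
    ev$mosaic_fraction <- mosaic
    ev$scope <- type
    events <- ev
  }
  contamination <- if (diff(params$contamination_range) > 0 ||
                       params$contamination_range[1] > 0) {
    runif(1, params$contamination_range[1], params$contamination_range[2])
  } else 0
  structure(list(
    embryo_id = embryo_id, sex = sex, events = events,
    contamination_fraction = contamination,
    label_euploid = label_euploid(events)
  ), class = "nics_truth")
}

#' Construct a karyotype truth object directly
#'
#' Bypass the random generator and state the events explicitly; used to set
#' up controlled scenarios.
#'
#' @param genome A `nics_genome`.
#' @param events Event data.frame (`chrom`, `start`, `end`, `copy_change`,
#'   `mosaic_fraction`, `scope`); NULL for euploid.
#' @param sex "XX" or "XY".
#' @param contamination_fraction Maternal-contamination fraction in [0, 1).
#' @param embryo_id Sample identifier.
#' @return A `nics_truth`.
#' @export
make_truth <- function(genome, events = NULL, sex = "XX",
                       contamination_fraction = 0, embryo_id = "embryo") {
  if (is.null(events) || nrow(events) == 0) events <- .empty_events()
  stopifnot(sex %in% c("XX", "XY"),
            contamination_fraction >= 0, contamination_fraction < 1)
  if (nrow(events)) {
    stopifnot(all(events$chrom %in% genome$chromosomes$name),
              all(events$mosaic_fraction > 0),
              all(events$mosaic_fraction <= 1),
              all(events$copy_change %in% c(-1L, 1L)))
    seg <- events$scope == "segmental"
    if (any(seg & (events$end - events$start) < 10e6)) {
      stop("segmental events must span at least 10 Mb")
    }
    for (ch in unique(events$chrom)) {
      e <- events[events$chrom == ch, , drop = FALSE]
      if (nrow(e) > 1) {
        e <- e[order(e$start), ]
        if (any(e$start[-1] < e$end[-nrow(e)])) {
          stop("events overlap on ", ch)
        }
      }
    }
  }
  structure(list(
    embryo_id = embryo_id, sex = sex, events = events,
    contamination_fraction = contamination_fraction,
    label_euploid = label_euploid(events)
  ), class = "nics_truth")
}

# Per-bin local copy number implied by a truth object (no contamination).
.truth_copy_number <- function(truth, genome) {
  bins <- genome$bins
  base <- rep(2, nrow(bins))
  x <- bins$chrom %in% c("chrX", "X")
  y <- bins$chrom %in% c("chrY", "Y")
  if (truth$sex == "XY") {
    base[x] <- 1
    base[y] <- 1
  } else {
    base[y] <- 0
  }
  ev <- truth$events
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      hit <- bins$chrom == ev$chrom[k] & bins$start < ev$end[k] &
        bins$end > ev$start[k]
      m <- ev$mosaic_fraction[k]
      base[hit] <- pmax(0, base[hit] + ev$copy_change[k] * m)
    }
  }
  base
}

#' Default GC-bias curve
#'
#' Unimodal quadratic relative-coverage curve peaking at GC = 0.45, the
#' standard shape of amplification/coverage bias in shallow WGS.
#'
#' @param strength Curvature; 0 gives a flat curve.
#' @return A function mapping GC fraction to a positive relative rate.
#' @export
gc_bias_quadratic <- function(strength = 4) {
  function(gc) pmax(0.05, 1 - strength * (gc - 0.45)^2)
}

#' Simulate per-bin read counts for one embryo sample
#'
#' Counts are drawn per bin from a negative binomial whose mean is
#' proportional to local copy number x GC bias x mappability, where the
#' local copy number of a bin under an event with mosaic fraction m and copy
#' change d is `base + d * m` (base 2 on autosomes). The embryo profile is
#' mixed with a diploid-XX maternal contamination profile at the truth's
#' contamination fraction, and the genome-wide expected total equals
#' `depth`. Dispersion d gives variance `mu * (1 + d)` (mildly
#' over-Poisson), i.e. a negative binomial with size `mu / d`.
#'
#' @param truth A `nics_truth`.
#' @param genome A `nics_genome`.
#' @param depth Expected total read count (default 2e6, the typical library
#'   yield for spent-medium NICS sequencing).
#' @param gc_bias Function GC -> relative rate; see [gc_bias_quadratic()].
#' @param dispersion Extra-Poisson variance coefficient (> 0); default 0.05.
#' @param seed Optional integer seed.
#' @return An object of class `nics_bincounts`: list with `sample_id` and
#'   integer `counts` aligned to `genome$bins`.
#' @export
simulate_read_counts <- function(truth, genome, depth = 2e6,
                                 gc_bias = gc_bias_quadratic(),
                                 dispersion = 0.05, seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (depth < 0) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  bins <- genome$bins
  cn <- .truth_copy_number(truth, genome)
  contam_cn <- .truth_copy_number(
    make_truth(genome, sex = "XX", embryo_id = "contaminant"), genome)
  cfrac <- truth$contamination_fraction
  mix <- (1 - cfrac) * cn + cfrac * contam_cn
  w <- mix * gc_bias(bins$gc) * bins$mappability * (bins$end - bins$start) /
    genome$bin_size
  counts <- integer(nrow(bins))
  if (depth > 0 && sum(w) > 0) {
    mu <- depth * w / sum(w)
    pos <- mu > 0
    counts[pos] <- rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / dispersion)
  }
  structure(list(sample_id = truth$embryo_id, counts = as.integer(counts)),
            class = "nics_bincounts")
}

#' Write per-bin counts as TSV
#'
#' Columns `chrom  start  end  gc  count`, 0-based half-open coordinates.
#'
#' @param counts A `nics_bincounts`.
#' @param genome The matching `nics_genome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(counts, genome, path) {
  stopifnot(length(counts$counts) == nrow(genome$bins))
  df <- data.frame(chrom = genome$bins$chrom,
                   start = format(genome$bins$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(genome$bins$end, scientific = FALSE,
                                trim = TRUE),
                   gc = round(genome$bins$gc, 4),
                   count = counts$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an embryo truth set as JSON
#'
#' @param truth A `nics_truth`.
#' @param path JSON path.
#' @return `path` (write) or a `nics_truth` (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    embryo_id = truth$embryo_id, sex = truth$sex,
    contamination_fraction = truth$contamination_fraction,
    label_euploid = truth$label_euploid,
    events = truth$events
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- if (length(x$events)) as.data.frame(x$events) else .empty_events()
  if (nrow(ev)) ev$copy_change <- as.integer(ev$copy_change)
  structure(list(embryo_id = x$embryo_id, sex = x$sex, events = ev,
                 contamination_fraction = x$contamination_fraction,
                 label_euploid = x$label_euploid),
            class = "nics_truth")
}
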