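#' Bundled human-like genome geometry
#'
#' Chromosome lengths and approximate centromere midpoints for the 24 human
#' chromosomes (GRCh38 scale, rounded centromeres). This is the default
#' coordinate frame for the simulator and the CNV caller; at a 1 Mb bin size
#' it yields roughly 3,100 bins genome-wide.
#'
#' @return A data.frame with columns `name`, `length` (bp) and
#'   `centromere` (bp).
#' @export
default_genome_table <- function() {
  data.frame(
    name = c(paste0("chr", 1:22), "chrX", "chrY"),
    length = c(
      248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
      159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
      114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
      58617616, 64444167, 46709983, 50818468, 156040895, 57227415
    ),
    centromere = c(
      123400000, 93900000, 90900000, 50000000, 48800000, 59800000,
      60100000, 45200000, 43000000, 39800000, 53400000, 35500000,
      17700000, 17200000, 19000000, 36800000, 25100000, 18500000,
      26200000, 28100000, 12000000, 15000000, 60600000, 10400000
    ),
    stringsAsFactors = FALSE
  )
}

# Smooth deterministic per-chromosome GC profile: a slowly varying sinusoid
# around a genome-typical mean, phased per chromosome so profiles differ but
# are reproducible without an RNG.
.gc_profile <- function(chrom_index, mid, len) {
  phase <- (chrom_index * 2.399963) %% (2 * pi) # golden-angle spacing
  waves <- 1.5 + (chrom_index %% 3)
  0.41 + 0.07 * sin(2 * pi * waves * mid / len + phase) +
    0.02 * cos(2 * pi * 7 * mid / len)
}

#' Build a binned genome model
#'
#' Tiles each chromosome with fixed-size bins, assigns each bin a smooth
#' deterministic GC fraction and a mappability weight of 1, and records arm
#' membership (p/q) from the centromere position. The result is the shared
#' coordinate frame for read-count simulation, normalization and
#' segmentation.
#'
#' @param config A data.frame with columns `name`, `length`, `centromere`
#'   (bp), or a path to a YAML file with a `chromosomes` list carrying those
#'   fields. Defaults to the bundled human-like table.
#' @param bin_size Bin width in bp (default 1e6, i.e. 1 Mb).
#' @return An object of class `nics_genome`: a list with `bins` (data.frame
#'   `chrom`, `start`, `end`, `gc`, `mappability`, `arm`), `chromosomes`
#'   (the config table) and `bin_size`.
#' @export
make_genome <- function(config = default_genome_table(), bin_size = 1e6) {
  if (is.character(config) && length(config) == 1) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(rbind, lapply(cfg$chromosomes, function(ch) {
      data.frame(name = ch$name, length = as.numeric(ch$length),
                 centromere = as.numeric(ch$centromere))
    }))
    if (!is.null(cfg$bin_size)) bin_size <- as.numeric(cfg$bin_size)
  }
  stopifnot(is.data.frame(config),
            all(c("name", "length", "centromere") %in% names(config)))
  if (bin_size <= 0) stop("bin_size must be positive")
  bad <- config$centromere <= 0 | config$centromere >= config$length
  if (any(bad)) {
    stop("centromere outside chromosome: ",
         paste(config$name[bad], collapse = ", "))
  }
  if (anyDuplicated(config$name)) stop("duplicated chromosome names")

  bins <- do.call(rbind, lapply(seq_len(nrow(config)), function(k) {
    len <- config$length[k]
    start <- seq(0, len - 1, by = bin_size)
    end <- pmin(start + bin_size, len)
    mid <- (start + end) / 2
    data.frame(
      chrom = config$name[k],
      start = start,
      end = end,
      gc = pmin(0.75, pmax(0.25, .gc_profile(k, mid, len))),
      mappability = 1,
      arm = ifelse(mid < config$centromere[k], "p", "q"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(bins) <- NULL
  structure(
    list(bins = bins, chromosomes = config, bin_size = bin_size),
    class = "nics_genome"
  )
}

#' @export
print.nics_genome <- function(x, ...) {
  cat("<nics_genome> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$bins), " bins of ", x$bin_size / 1e6, " Mb\n", sep = "")
  invisible(x)
}

#' Write a genome configuration to YAML
#'
#' @param genome A `nics_genome` or a chromosome table as in [make_genome()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_genome_config <- function(genome, path) {
  tab <- if (inherits(genome, "nics_genome")) genome$chromosomes else genome
  bin_size <- if (inherits(genome, "nics_genome")) genome$bin_size else 1e6
  yaml::write_yaml(list(
    bin_size = bin_size,
    chromosomes = lapply(seq_len(nrow(tab)), function(k) {
      # bp coordinates are integral; avoid YAML float formatting loss
      list(name = tab$name[k], length = as.integer(tab$length[k]),
           centromere = as.integer(tab$centromere[k]))
    })
  ), path)
  invisible(path)
}

# Logical mask of autosomal bins.
.autosomal <- function(genome) {
  !(genome$bins$chrom %in% c("chrX", "chrY", "X", "Y"))
}

# Convenience used throughout: per-chromosome bin index ranges in the
# genome-wide (0-based, half-open) bin coordinate system.
.chrom_bin_ranges <- function(genome) {
  chrom <- genome$bins$chrom
  idx <- split(seq_along(chrom) - 1L, factor(chrom, levels = unique(chrom)))
  lapply(idx, function(i) c(first = min(i), last_excl = max(i) + 1L))
}
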