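test_that("bin-counts TSV round-trips and is validated on load", {
  g <- toy_genome(with_sex = TRUE)
  tr <- simulate_karyotype(g, seed = 1)
  ct <- simulate_read_counts(tr, g, depth = 1e5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_counts(ct, g, path)

  back <- load_bin_counts(path, g, sample_id = ct$sample_id)
  expect_identical(back$counts, ct$counts)

  df <- read.delim(path)
  df$count[5] <- -1
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_bin_counts(bad, g), "negative or missing count")

  df <- read.delim(path)[-3, ] # drop one bin
  write.table(df, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_bin_counts(bad, g), "bin")
})

test_that("GC normalization flattens known bias and centres at 2 copies", {
  g <- make_genome()
  tr <- make_truth(g, sex = "XX")
  ct <- simulate_read_counts(tr, g, depth = 2e6,
                             gc_bias = gc_bias_quadratic(4), seed = 3)
  auto <- !(g$bins$chrom %in% c("chrX", "chrY"))

  raw_rate <- ct$counts
  expect_gt(abs(cor(raw_rate[auto], g$bins$gc[auto])), 0.2) # bias present

  prof <- gc_normalize(ct, g)
  expect_lt(abs(cor(prof$cn[auto], g$bins$gc[auto])), 0.05)
  expect_lt(abs(median(prof$cn[auto]) - 2), 0.05)

  # euploid XY: chrX median ~ 1 after autosomal scaling
  trm <- make_truth(g, sex = "XY")
  ctm <- simulate_read_counts(trm, g, depth = 2e6, seed = 4)
  profm <- gc_normalize(ctm, g)
  expect_lt(abs(median(profm$cn[g$bins$chrom == "chrX"]) - 1), 0.05)

  expect_error(
    gc_normalize(structure(list(sample_id = "z",
                                counts = rep(0L, nrow(g$bins))),
                           class = "nics_bincounts"), g),
    "all-zero")
})

test_that("reference normalization removes shared positional artifacts", {
  g <- toy_genome(n_chrom = 3)
  tr <- make_truth(g, sex = "XX")
  ct <- simulate_read_counts(tr, g, depth = 5e5, gc_bias = flat_gc_bias(),
                             seed = 5)
  prof <- gc_normalize(ct, g)

  # panel of copies of the test profile -> flat 2 (self-division)
  flat <- reference_normalize(prof, rep(list(prof), 5), g)
  expect_true(all(abs(flat$cn - 2) < 1e-9))

  expect_error(reference_normalize(prof, list(), g), "empty")

  # inject a shared artifact into sample and panel; residual must shrink >= 5x
  artifact_bins <- 41:60
  bias <- rep(1, nrow(g$bins))
  bias[artifact_bins] <- 1.4
  set.seed(6)
  biased_profile <- function(id) {
    tr <- make_truth(g, sex = "XX", embryo_id = id)
    ct <- simulate_read_counts(tr, g, depth = 5e5, gc_bias = flat_gc_bias())
    ct$counts <- as.integer(round(ct$counts * bias))
    gc_normalize(ct, g)
  }
  sample_prof <- biased_profile("s")
  panel <- lapply(sprintf("ref%02d", 1:8), biased_profile)
  before <- mean(sample_prof$cn[artifact_bins]) - 2
  corrected <- reference_normalize(sample_prof, panel, g)
  after <- mean(corrected$cn[artifact_bins]) - 2
  expect_gt(before, 0.3)
  expect_lt(abs(after), abs(before) / 5)

  # a mosaic sample's segment mean is preserved by an euploid panel
  trm <- wc_truth(g, "chr2", 0.5)
  ctm <- simulate_read_counts(trm, g, depth = 5e5,
                              gc_bias = flat_gc_bias(), seed = 8)
  pm <- gc_normalize(ctm, g)
  set.seed(9)
  panel2 <- lapply(1:6, function(i) {
    gc_normalize(simulate_read_counts(make_truth(g, sex = "XX"), g,
                                      depth = 5e5,
                                      gc_bias = flat_gc_bias()), g)
  })
  pmr <- reference_normalize(pm, panel2, g)
  m_before <- mean(pm$cn[g$bins$chrom == "chr2"])
  m_after <- mean(pmr$cn[g$bins$chrom == "chr2"])
  expect_lt(abs(m_after - m_before), 0.05)
})

test_that("mosaicism estimator is the clipped deviation from baseline", {
  est <- estimate_mosaicism(c(2.5, 1.0, 2.0, 3.4))
  expect_equal(est$fraction, c(0.5, 1.0, 0.0, 1.0))
  expect_equal(est$direction, c("gain", "loss", "neutral", "gain"))
})

test_that("call filters, scope classing and sex calls behave as specified", {
  g <- toy_genome(n_chrom = 2, with_sex = TRUE)

  # constructed segments (autosome-only genome): sub-margin deviations
  # yield no calls
  ga <- toy_genome(n_chrom = 2, with_sex = FALSE)
  prof_ok <- structure(list(sample_id = "s", cn = rep(2, nrow(ga$bins)),
                            weight = rep(1, nrow(ga$bins))),
                       class = "nics_profile")
  seg <- segment_cbs(prof_ok, ga, seed = 1)
  seg$mean_cn <- ifelse(seg$chrom == "chr1", 2.2, seg$mean_cn) # below 0.3
  cs <- call_cnvs(seg, ga)
  expect_equal(nrow(cs$calls), 0)
  expect_true(all(cs$chrom_class[c("chr1", "chr2")] == "euploid"))

  # 8 Mb full deletion stays below the 10 Mb reporting floor
  g1 <- toy_genome(n_chrom = 2, length_mb = 120, centromere_mb = 50)
  tr <- make_truth(g1, events = data.frame(
    chrom = "chr1", start = 60e6, end = 75e6, copy_change = -1L,
    mosaic_fraction = 1, scope = "segmental"))
  cn <- rep(2, nrow(g1$bins))
  hit <- g1$bins$chrom == "chr1" & g1$bins$start >= 60e6 &
    g1$bins$end <= 68e6 # only 8 Mb affected
  cn[hit] <- 1
  prof <- structure(list(sample_id = "s", cn = cn + rnorm(length(cn), 0, 0.03),
                         weight = rep(1, length(cn))),
                    class = "nics_profile")
  set.seed(2)
  seg8 <- segment_cbs(prof, g1, seed = 3)
  cs8 <- call_cnvs(seg8, g1)
  expect_true(all(cs8$calls$length_mb >= 10) || nrow(cs8$calls) == 0)
  expect_false(any(cs8$calls$chrom == "chr1" & cs8$calls$length_mb < 10))

  # end-to-end: 60% whole-chromosome mosaic gain recovered within 0.1
  g2 <- make_genome()
  tr2 <- wc_truth(g2, "chr9", 0.6, sex = "XX")
  errs <- vapply(1:3, function(r) {
    ct <- simulate_read_counts(tr2, g2, depth = 2e6, seed = 100 + r)
    cs <- call_sample(ct, g2, seed = 200 + r)
    hit <- cs$calls[cs$calls$chrom == "chr9", , drop = FALSE]
    expect_equal(unname(cs$chrom_class["chr9"]), "whole_chromosome")
    abs(max(hit$mosaic_fraction) - 0.6)
  }, 1.0)
  expect_lt(mean(errs), 0.1)

  # sex calls: XX, XY, and an abnormal (X monosomy) profile
  trx <- make_truth(g, sex = "XX")
  ctx <- simulate_read_counts(trx, g, depth = 5e5, seed = 11)
  expect_equal(call_sample(ctx, g, seed = 12)$sex_call, "XX")
  try_ <- make_truth(g, sex = "XY")
  cty <- simulate_read_counts(try_, g, depth = 5e5, seed = 13)
  expect_equal(call_sample(cty, g, seed = 14)$sex_call, "XY")
  tr45x <- wc_truth(g, "chrX", 1, copy_change = -1L, sex = "XX")
  ct45x <- simulate_read_counts(tr45x, g, depth = 5e5, seed = 15)
  cs45x <- call_sample(ct45x, g, seed = 16)
  expect_equal(cs45x$sex_call, "abnormal")
})

test_that("segment means are a partition-consistent summary", {
  g <- toy_genome(n_chrom = 2, with_sex = FALSE)
  set.seed(20)
  for (rep in 1:5) {
    tr <- simulate_karyotype(g, karyotype_params(0.3, 0.5, 0.1, 0.1))
    ct <- simulate_read_counts(tr, g, depth = 3e5, gc_bias = flat_gc_bias())
    prof <- gc_normalize(ct, g)
    seg <- segment_cbs(prof, g, seed = rep)
    pooled <- sum(seg$mean_cn * seg$n_bins) / sum(seg$n_bins)
    expect_equal(pooled, mean(prof$cn), tolerance = 1e-9)
    # segments per chromosome are contiguous, ordered, cover the chromosome
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      expect_equal(s$start_bin[-1], s$end_bin[-nrow(s)])
      expect_equal(sum(s$n_bins), sum(g$bins$chrom == ch))
    }
  }
})

test_that("SEG and callset writers emit valid files", {
  g <- toy_genome()
  tr <- wc_truth(g, "chr1", 1)
  ct <- simulate_read_counts(tr, g, depth = 3e5, seed = 30)
  cs <- call_sample(ct, g, seed = 31)
  seg_path <- withr::local_tempfile(fileext = ".tsv")
  write_seg(cs$segments, cs$sample_id, seg_path)
  expect_true(validate_formats(seg_path, "seg_tsv")$pass)
  js_path <- withr::local_tempfile(fileext = ".json")
  write_callset(cs, js_path)
  back <- jsonlite::read_json(js_path, simplifyVector = TRUE)
  expect_equal(back$sex_call, cs$sex_call)
})
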