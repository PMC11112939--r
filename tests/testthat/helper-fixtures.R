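# Small genomes and constructed objects shared across tests.

toy_genome <- function(n_chrom = 2, length_mb = 100, centromere_mb = 40,
                       bin_size = 1e6, with_sex = FALSE) {
  names <- paste0("chr", seq_len(n_chrom))
  if (with_sex) names <- c(names, "chrX", "chrY")
  tab <- data.frame(
    name = names,
    length = rep(length_mb * 1e6, length(names)),
    centromere = rep(centromere_mb * 1e6, length(names))
  )
  make_genome(tab, bin_size = bin_size)
}

# one whole-chromosome event truth on a given chromosome
wc_truth <- function(genome, chrom, mosaic, copy_change = 1L, sex = "XX",
                     id = "embryo", contamination = 0) {
  k <- match(chrom, genome$chromosomes$name)
  make_truth(genome, events = data.frame(
    chrom = chrom, start = 0, end = genome$chromosomes$length[k],
    copy_change = as.integer(copy_change), mosaic_fraction = mosaic,
    scope = "whole_chromosome"
  ), sex = sex, contamination_fraction = contamination, embryo_id = id)
}

flat_gc_bias <- function() function(gc) rep(1, length(gc))
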