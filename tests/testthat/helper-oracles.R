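suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(Biostrings)
})

# Independent two-sided Fisher oracle: enumerate the hypergeometric support
# and sum probabilities not exceeding that of the observed table (with the
# conventional 1e-7 relative tie tolerance).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  k <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(k, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Scalar per-variant channel oracle, independent of countContexts internals.
manual_channel <- function(seq_string, pos, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  f5 <- substr(seq_string, pos - 1, pos - 1)
  ctr <- substr(seq_string, pos, pos)
  f3 <- substr(seq_string, pos + 1, pos + 1)
  stopifnot(ctr == ref)
  if (ref %in% c("A", "G")) {
    tmp <- comp[[f5]]
    f5 <- comp[[f3]]; f3 <- tmp
    ref <- comp[[ref]]; alt <- comp[[alt]]
  }
  paste0(f5, "[", ref, ">", alt, "]", f3)
}

# Small deterministic annotation for unit tests: two chromosomes with arms,
# six genes, one blacklist interval.
small_annotation <- function() {
  GenomeAnnotation(
    chrom_lengths = c(chrA = 10e6, chrB = 8e6),
    arms = data.frame(
      chrom = c("chrA", "chrA", "chrB", "chrB"),
      start = c(0, 5e6, 0, 4e6),
      end = c(4e6, 10e6, 3e6, 8e6),
      arm = c("chrAp", "chrAq", "chrBp", "chrBq")),
    genes = data.frame(
      chrom = c("chrA", "chrA", "chrA", "chrB", "chrB", "chrB"),
      start = c(1e6, 2e6, 6e6, 0.5e6, 5e6, 6.5e6),
      end = c(1.2e6, 2.2e6, 6.2e6, 0.7e6, 5.2e6, 6.7e6),
      gene_id = c("GA1", "GA2", "GA3", "GB1", "GB2", "GB3"),
      expressed = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)),
    blacklist = data.frame(chrom = "chrA", start = 8e6, end = 9e6)
  )
}

mk_segments <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  mcols(gr) <- DataFrame(patient_id = df$patient_id,
                         cnv_type = df$cnv_type,
                         source = if (is.null(df$source)) "wgs" else df$source)
  gr
}

mk_groups <- function(ids, sides, levels = c("g1", "g2")) {
  out <- factor(sides, levels = levels)
  names(out) <- ids
  out
}
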