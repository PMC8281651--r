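# Shared fixtures, built in code at test time.

# One estimate_ccf-style row without going through the estimator (for
# classify_variant unit tests).
ccf_row <- function(ccf, ci_high = ccf + 0.1, ci_low = max(ccf - 0.1, 0)) {
  data.frame(ccf = ccf, ci_low = ci_low, ci_high = ci_high,
             multiplicity = 1L, purity = 1, total_cn = 2)
}

# Minimal variant table for pairing tests.
variant_table <- function(n, alt, depth, chrom = "chr1",
                          genes = sprintf("G%03d", seq_len(n))) {
  data.frame(chrom = chrom, pos = 1000L + seq_len(n), ref = "A", alt = "T",
             alt_count = rep_len(alt, n), depth = rep_len(depth, n),
             gene = genes, cancer_gene = FALSE, stringsAsFactors = FALSE)
}

# Segment table helper.
seg_table <- function(chrom, start, end, total, major, minor, cf) {
  data.frame(chrom = chrom, start = start, end = end, total_cn = total,
             major_cn = major, minor_cn = minor, cellular_fraction = cf,
             stringsAsFactors = FALSE)
}

# Map pair_clonality keys back to true categories of a clone_sim.
true_categories <- function(cs, keys) {
  mut_key <- stats::setNames(
    cs$mutations$mutation,
    paste(cs$mutations$chrom, cs$mutations$pos, cs$mutations$ref,
          cs$mutations$alt, sep = ":"))
  cs$truth$category[mut_key[keys]]
}
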