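# Brute-force oracles and small shared fixtures. Oracles are deliberately
# naive (double loops, direct formulas) and independent of the package's
# implementation paths.

# Spearman via the textbook rank-Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all-pairs promoter assignment scan (no tie-break)
oracle_promoter_links <- function(peaks, genes, upstream = 1000,
                                  proximal_gap = 100) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    s1 <- peaks$summit[i] + 1 # 1-based summit
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      tss <- genes$tss[j]
      if (genes$strand[j] == "+") {
        lo <- max(tss - upstream, 1); hi <- tss - proximal_gap
      } else {
        lo <- tss + proximal_gap; hi <- tss + upstream
      }
      if (s1 >= lo && s1 <= hi) {
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
          distance = abs(s1 - tss), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  }
  do.call(rbind, out)
}

# all-pairs distal candidate scan (strict < max_dist)
oracle_distal_pairs <- function(peaks, genes, max_dist = 500000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    s1 <- peaks$summit[i] + 1
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      d <- abs(s1 - genes$tss[j])
      if (d < max_dist) {
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  }
  do.call(rbind, out)
}

# small toy genome fixture used across linking tests
toy_genome <- epistroma::generate_genome(n_chrom = 2, chrom_length = 2e6)

# canonical sorted key for link-set comparison
link_key <- function(df) {
  sort(paste(df$peak_id, df$gene_id, sep = "::"))
}
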