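test_that("promoter windows follow the strand-aware upstream rule", {
  expect_equal(promoter_window(10000, "+"), data.frame(start = 9000, end = 9900))
  expect_equal(promoter_window(10000, "-"),
               data.frame(start = 10100, end = 11000))
  expect_warning(w <- promoter_window(500, "+"), "truncated")
  expect_equal(w, data.frame(start = 1, end = 400))
  expect_error(promoter_window(0, "+"), "tss")
  expect_error(promoter_window(100, "*"), "strand")
})

test_that("promoter assignment matches the window examples", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000,
                      strand = "+", stringsAsFactors = FALSE)
  mk_peak <- function(summit1) {
    # summit is 0-based; summit1 is the 1-based position being tested
    data.frame(peak_id = "p1", chrom = "chr1", start = summit1 - 51,
               end = summit1 + 50, summit = summit1 - 1,
               stringsAsFactors = FALSE)
  }
  hit <- assign_promoter_peaks(mk_peak(9500), genes)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$kind, "promoter")
  expect_equal(hit$distance, 500)
  # inside the excluded 100 bp proximal gap
  expect_equal(nrow(assign_promoter_peaks(mk_peak(9950), genes)), 0L)
  # just outside the upstream edge
  expect_equal(nrow(assign_promoter_peaks(mk_peak(8999), genes)), 0L)
})

test_that("promoter and distal assignment equal brute-force all-pairs oracles", {
  for (seed in c(3, 8, 15)) {
    peaks <- generate_peaks(40, toy_genome, seed = seed)
    genes <- generate_genes(25, toy_genome, seed = seed + 50)
    # move some TSSs next to peak summits so promoter hits actually occur
    k <- seq_len(10)
    genes$tss[k] <- ifelse(genes$strand[k] == "+",
                           peaks$summit[k] + 1 + 500,
                           pmax(1, peaks$summit[k] + 1 - 500))
    oracle <- oracle_promoter_links(peaks, genes)
    got <- assign_promoter_peaks(peaks, genes, tie_break = FALSE)
    expect_setequal(link_key(got), link_key(oracle))

    oracle_d <- oracle_distal_pairs(peaks, genes, max_dist = 300000)
    got_d <- candidate_distal_pairs(peaks, genes, max_dist = 300000)
    expect_setequal(link_key(got_d), link_key(oracle_d))
    expect_equal(got_d$distance[order(link_key(got_d))],
                 oracle_d$distance[order(link_key(oracle_d))])
  }
})

test_that("promoter tie-break keeps the nearest gene, then lexicographic id", {
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 9400,
                      end = 9901, summit = 9499, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gB", "gA", "gC"), chrom = "chr1",
                      tss = c(10000, 10300, 10000), strand = "+",
                      stringsAsFactors = FALSE)
  # summit1 = 9500: distances 500 (gB), 800 (gA), 500 (gC)
  got <- assign_promoter_peaks(peaks, genes)
  expect_equal(nrow(got), 1L)
  expect_equal(got$gene_id, "gB")
  all3 <- assign_promoter_peaks(peaks, genes, tie_break = FALSE)
  expect_equal(nrow(all3), 3L)
})

test_that("distal candidates respect the strict 500 kbp bound", {
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 950,
                      end = 1451, summit = 999, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("near", "far", "edge"), chrom = "chr1",
                      tss = c(400000, 600000, 501000), strand = "+",
                      stringsAsFactors = FALSE)
  got <- candidate_distal_pairs(peaks, genes)
  expect_equal(got$gene_id, "near")
  expect_equal(got$distance, 399000)
  # exactly at the bound is excluded (strict <)
  genes2 <- data.frame(gene_id = "at", chrom = "chr1", tss = 501000,
                       strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(candidate_distal_pairs(peaks, genes2)), 0L)
  expect_equal(nrow(candidate_distal_pairs(
    peaks, data.frame(gene_id = "at", chrom = "chr1", tss = 500999,
                      strand = "+", stringsAsFactors = FALSE))), 1L)
})

test_that("link sets are invariant under genome reflection with strand flip", {
  L <- toy_genome$length[1]
  for (seed in c(4, 9)) {
    peaks <- generate_peaks(30, toy_genome, seed = seed)
    genes <- generate_genes(20, toy_genome, seed = seed + 5)
    k <- seq_len(8)
    genes$tss[k] <- ifelse(genes$strand[k] == "+",
                           peaks$summit[k] + 1 + 500,
                           pmax(1, peaks$summit[k] + 1 - 500))
    mirror_peaks <- peaks
    mirror_peaks$start <- L - peaks$end
    mirror_peaks$end <- L - peaks$start
    mirror_peaks$summit <- L - 1 - peaks$summit
    mirror_genes <- genes
    mirror_genes$tss <- L - genes$tss + 1
    mirror_genes$strand <- ifelse(genes$strand == "+", "-", "+")

    a <- assign_promoter_peaks(peaks, genes, tie_break = FALSE)
    b <- assign_promoter_peaks(mirror_peaks, mirror_genes, tie_break = FALSE)
    expect_setequal(link_key(a), link_key(b))

    da <- candidate_distal_pairs(peaks, genes, max_dist = 200000)
    db <- candidate_distal_pairs(mirror_peaks, mirror_genes,
                                 max_dist = 200000)
    expect_setequal(link_key(da), link_key(db))
  }
})

test_that("distal linking recovers planted links and applies both filters", {
  s <- simulate_study(n_samples = 54, n_peaks = 400, n_genes = 60,
                      n_planted = 20, n_promoter_links = 3,
                      n_distal_links = 4, n_cn_links = 2, seed = 6)
  scr <- screen_peaks(s$acc, s$cohort)
  sig <- scr$peak_id[scr$significant]
  dist <- link_peaks_to_genes(s$peaks, s$genes, unique(c(sig, s$truth$effects$peak_id)),
                              s$acc, s$expr, cn = s$cn)
  truth <- s$truth$links

  planted_distal <- truth[truth$kind == "distal" & !truth$cn_driven, ]
  got <- dist[dist$surviving, ]
  expect_true(all(paste(planted_distal$peak_id, planted_distal$gene_id) %in%
                    paste(got$peak_id, got$gene_id)))

  # cn-driven links are flagged and excluded
  cn_links <- truth[truth$cn_driven, ]
  rows <- dist[paste(dist$peak_id, dist$gene_id) %in%
                 paste(cn_links$peak_id, cn_links$gene_id), ]
  expect_true(all(rows$cnv_driven))
  expect_true(!any(rows$surviving))
  expect_true(all(abs(rows$rho) > 0.5))  # marginally strong, hence spurious

  # every surviving link satisfies all three predicates
  expect_true(all(got$distance < 500000))
  expect_true(all(got$fdr <= 0.01))
  expect_true(!any(got$cnv_driven | got$promoter_overlap))

  # without a CN matrix the filter is skipped with a warning
  expect_warning(
    link_peaks_to_genes(s$peaks, s$genes, sig[1:5], s$acc, s$expr),
    "CNV filter skipped")
})

test_that("peaks overlapping any promoter are excluded from distal links", {
  # gene gOther's promoter window contains the peak summit; the peak's
  # correlation partner is gTarget, 200 kbp away
  peaks <- data.frame(peak_id = "p1", chrom = "chr1", start = 8950,
                      end = 9451, summit = 9199, stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gTarget", "gOther"), chrom = "chr1",
                      tss = c(209200, 9700), strand = "+",
                      stringsAsFactors = FALSE)
  co <- generate_cohort(30, 0.5, seed = 44)
  eff <- planted_effects("p1", 1L, 0.9)
  acc <- generate_accessibility(peaks, co, eff, seed = 45)
  truth <- list(links = data.frame(peak_id = "p1", gene_id = "gTarget"))
  expr <- generate_expression(genes, co, truth, acc, seed = 46, coupling = 1,
                              noise_sd = 1e-9)
  expect_warning(
    dist <- link_peaks_to_genes(peaks, genes, "p1", acc, expr),
    "CNV filter skipped")
  row <- dist[dist$gene_id == "gTarget", ]
  expect_true(row$promoter_overlap)
  expect_false(row$surviving)
  expect_lt(row$fdr, 0.01)  # excluded by the filter, not by the FDR cut
})

test_that("collapse_targets dedups genes and signs them by proportion correlation", {
  s <- simulate_study(n_samples = 40, n_peaks = 200, n_genes = 40,
                      n_planted = 16, n_promoter_links = 5,
                      n_distal_links = 3, n_cn_links = 0, seed = 12)
  truth <- s$truth$links
  prom <- data.frame(peak_id = truth$peak_id[truth$kind == "promoter"],
                     gene_id = truth$gene_id[truth$kind == "promoter"],
                     kind = "promoter", distance = 500,
                     stringsAsFactors = FALSE)
  dist <- data.frame(peak_id = truth$peak_id[truth$kind == "distal"],
                     gene_id = truth$gene_id[truth$kind == "distal"],
                     kind = "distal", distance = 200000,
                     stringsAsFactors = FALSE)
  tg <- collapse_targets(prom, dist, s$expr, s$cohort)
  # disjoint planted links: 5 promoter + 3 distal genes
  expect_equal(nrow(tg), 8L)
  expect_true(!anyDuplicated(tg$gene_id))
  expect_equal(sum(tg$n_links), nrow(prom) + nrow(dist))

  # sign follows the planted direction of the upstream peak
  eff <- s$truth$effects
  dir_of <- setNames(eff$direction, eff$peak_id)
  want <- ifelse(dir_of[truth$peak_id] == 1, "positive", "negative")
  expect_equal(tg$sign[match(truth$gene_id, tg$gene_id)], unname(want))

  # three links to one gene collapse to one row with n_links = 3
  prom3 <- data.frame(peak_id = c("a", "b", "c"), gene_id = "gX",
                      kind = "promoter", distance = 1, stringsAsFactors = FALSE)
  expect_warning(tg3 <- collapse_targets(prom3, NULL, s$expr, s$cohort),
                 "sign unknown")
  expect_equal(tg3$n_links, 3L)
  expect_equal(tg3$sign, "unknown")
})
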