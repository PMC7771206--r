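test_that("cohort generator matches the requested low fraction", {
  co <- generate_cohort(54, 0.87, seed = 1)
  expect_true(all(co$proportion >= 0 & co$proportion <= 1))
  # 47/54 below 0.5 is the expected count; allow binomial sampling error
  expect_lte(abs(sum(co$proportion < 0.5) - 0.87 * 54),
             3 * sqrt(54 * 0.87 * 0.13))

  expect_true(all(generate_cohort(10, 0, seed = 1)$proportion >= 0.5))
  expect_true(all(generate_cohort(10, 1, seed = 1)$proportion < 0.5))

  # binomial 99% interval at n = 1000, p = 0.5
  n_low <- sum(generate_cohort(1000, 0.5, seed = 7)$proportion < 0.5)
  expect_gte(n_low, 450)
  expect_lte(n_low, 550)

  expect_identical(generate_cohort(54, 0.87, seed = 3),
                   generate_cohort(54, 0.87, seed = 3))
  expect_error(generate_cohort(1, 0.5), "n_samples")
})

test_that("peak atlases are disjoint fixed-width intervals with centred summits", {
  peaks <- generate_peaks(300, seed = 5)
  expect_equal(nrow(peaks), 300L)
  expect_true(all(peaks$end - peaks$start == 501L))
  expect_true(all(peaks$start <= peaks$summit & peaks$summit < peaks$end))
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, ]
    p <- p[order(p$start), ]
    expect_true(all(diff(p$start) >= 501L))
  }
  expect_identical(peaks, generate_peaks(300, seed = 5))
})

test_that("planted accessibility effects have the stated sign and strength", {
  peaks <- generate_peaks(20, seed = 2)
  co <- generate_cohort(40, 0.5, seed = 2)
  eff <- planted_effects(peaks$peak_id[1:2], c(1L, -1L), 1.0)

  # noiseless monotone transform: sample rho is exactly the direction
  acc0 <- generate_accessibility(peaks, co, eff, noise_sd = 1e-12, seed = 3)
  expect_equal(spearman_rho(acc0[1, ], co$proportion), 1)
  expect_equal(spearman_rho(acc0[2, ], co$proportion), -1)
  expect_true(all(acc0 > 0))

  # intermediate strength lands near the copula target at large n
  big <- generate_cohort(4000, 0.5, seed = 4)
  eff2 <- planted_effects(peaks$peak_id[1], 1L, 0.6)
  acc2 <- generate_accessibility(peaks, big, eff2, seed = 5)
  expect_equal(spearman_rho(acc2[1, ], big$proportion), 0.6, tolerance = 0.05)

  expect_identical(generate_accessibility(peaks, co, eff, seed = 9),
                   generate_accessibility(peaks, co, eff, seed = 9))
  bad <- planted_effects("nope", 1L, 0.5)
  expect_error(generate_accessibility(peaks, co, bad), "not in atlas")
})

test_that("unplanted rows behave like the Spearman null", {
  peaks <- generate_peaks(400, seed = 6)
  co <- generate_cohort(30, 0.5, seed = 6)
  acc <- generate_accessibility(peaks, co, NULL, seed = 7)
  obs <- apply(acc, 1L, spearman_rho, y = co$proportion)
  # oracle: null |rho| distribution simulated at the same n
  null_med <- with(list(n = 30), {
    set.seed(42)
    median(abs(replicate(2000, cor(sample(n), sample(n),
                                   method = "spearman"))))
  })
  expect_equal(median(abs(obs)), null_med, tolerance = 0.03)
})

test_that("expression couples linked genes and leaves others independent", {
  peaks <- generate_peaks(10, seed = 8)
  genes <- generate_genes(10, seed = 8)
  co <- generate_cohort(40, 0.5, seed = 8)
  eff <- planted_effects(peaks$peak_id[1], 1L, 0.8)
  acc <- generate_accessibility(peaks, co, eff, seed = 9)
  truth <- list(links = data.frame(peak_id = peaks$peak_id[1],
                                   gene_id = genes$gene_id[1]))

  # perfect coupling, zero noise: rank-identical rows
  e1 <- generate_expression(genes, co, truth, acc, seed = 10, coupling = 1,
                            noise_sd = 1e-12)
  expect_equal(spearman_rho(e1[1, ], acc[1, ]), 1)

  # unlinked genes stay near the null against any peak
  e2 <- generate_expression(genes, co, truth, acc, seed = 11)
  others <- vapply(2:10, function(i) abs(spearman_rho(e2[i, ], acc[1, ])),
                   numeric(1))
  expect_lt(median(others), 0.35)

  expect_identical(generate_expression(genes, co, truth, acc, seed = 12),
                   generate_expression(genes, co, truth, acc, seed = 12))
  bad <- list(links = data.frame(peak_id = peaks$peak_id[1],
                                 gene_id = "missing"))
  expect_error(generate_expression(genes, co, bad, acc), "not in annotation")
})

test_that("copy-number driven pairs lose their association after CN adjustment", {
  peaks <- generate_peaks(10, seed = 13)
  genes <- generate_genes(5, seed = 13)
  co <- generate_cohort(60, 0.5, seed = 13)
  cn_id <- peaks$peak_id[3]
  cn <- generate_copy_number(peaks, co, cn_id, seed = 14)
  eff <- planted_effects(cn_id, 1L, 0, cn_driven = TRUE)
  acc <- generate_accessibility(peaks, co, eff, seed = 15, cn = cn)
  truth <- list(links = data.frame(peak_id = cn_id,
                                   gene_id = genes$gene_id[1]),
                effects = eff)
  expr <- generate_expression(genes, co, truth, acc, seed = 16, cn = cn)

  r_ae <- spearman_rho(acc[cn_id, ], expr[1, ])
  r_ac <- spearman_rho(acc[cn_id, ], cn[cn_id, ])
  r_ec <- spearman_rho(expr[1, ], cn[cn_id, ])
  partial <- (r_ae - r_ac * r_ec) / sqrt((1 - r_ac^2) * (1 - r_ec^2))
  expect_gt(abs(r_ae), 0.6)
  expect_lt(abs(partial), 0.5 * abs(r_ae))

  # rows without planted CN effects do not depend on the CN matrix at all
  acc_nocn <- generate_accessibility(peaks, co, eff, seed = 15,
                                     cn = cn[, sample(ncol(cn))])
  expect_identical(acc[-3, ], acc_nocn[-3, ])

  expect_identical(cn, generate_copy_number(peaks, co, cn_id, seed = 14))
  expect_error(generate_copy_number(peaks, co, "nope"), "not in atlas")
})

test_that("survival generator honours censoring and planted hazards", {
  genes <- generate_genes(5, seed = 17)
  co <- generate_cohort(200, 0.5, seed = 17)
  expr <- generate_expression(genes, co, list(links = NULL), NULL, seed = 18)

  sv0 <- generate_survival(co, expr, NULL, censor_rate = 0, seed = 19)
  expect_true(all(sv0$event == 1L))
  expect_true(all(sv0$time > 0))

  sv <- generate_survival(co, expr, NULL, censor_rate = 0.6, seed = 19)
  expect_equal(mean(sv$event == 0L), 0.6, tolerance = 0.12)

  # a strong planted coefficient separates the median-split groups
  prog <- data.frame(gene_id = genes$gene_id[1], coef = 1.2)
  hits <- 0L
  for (seed in 1:10) {
    big <- generate_cohort(600, 0.5, seed = 100 + seed)
    be <- generate_expression(genes, big, list(links = NULL), NULL,
                              seed = 200 + seed)
    bs <- generate_survival(big, be, prog, censor_rate = 0.5,
                            seed = 300 + seed)
    grp <- median_split(be[1, ])
    hits <- hits + (logrank_test(grp, bs$time, bs$event)$p < 0.05)
  }
  expect_gte(hits, 9L)

  expect_error(generate_survival(co[0, ], expr, NULL), "empty cohort")
  expect_identical(generate_survival(co, expr, prog, seed = 21),
                   generate_survival(co, expr, prog, seed = 21))
})

test_that("tissue masks hit their target proportion by construction", {
  m <- generate_tissue_mask(100, 100, 0.6, seed = 1)
  expect_lte(abs(epithelial_proportion(m) - 0.6), 0.01)
  expect_setequal(unique(as.integer(m)), 0:2)

  m1 <- generate_tissue_mask(50, 50, 1, seed = 1)
  expect_equal(sum(m1 == 2L), 0L)

  expect_identical(generate_tissue_mask(40, 30, 0.3, seed = 2),
                   generate_tissue_mask(40, 30, 0.3, seed = 2))
  expect_error(generate_tissue_mask(0, 10, 0.5), "positive area")
})

test_that("the study bundle is internally consistent and round-trips to disk", {
  s <- simulate_study(n_samples = 20, n_peaks = 100, n_genes = 30,
                      n_planted = 12, n_promoter_links = 2,
                      n_distal_links = 2, n_cn_links = 1, seed = 4)
  expect_true(all(s$truth$effects$peak_id %in% s$peaks$peak_id))
  expect_true(all(s$truth$links$gene_id %in% s$genes$gene_id))
  # linked genes sit within the distal horizon of their peak summit
  idx_p <- match(s$truth$links$peak_id, s$peaks$peak_id)
  idx_g <- match(s$truth$links$gene_id, s$genes$gene_id)
  expect_true(all(abs((s$peaks$summit[idx_p] + 1) - s$genes$tss[idx_g]) <
                    500000))
  expect_equal(dim(s$acc), c(100L, 20L))
  expect_equal(dim(s$expr), c(30L, 20L))

  d <- withr::local_tempdir()
  write_study(s, d)
  expect_equal(read_matrix_tsv(file.path(d, "accessibility.tsv")), s$acc,
               tolerance = 1e-12)
  expect_equal(read_peaks(file.path(d, "peaks.tsv")), s$peaks)
  expect_equal(read_cohort(file.path(d, "cohort.tsv")), s$cohort)
  expect_equal(read_survival(file.path(d, "survival.tsv"))$time,
               s$survival$time)
})
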