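# Synthetic multi-omics cohort generator.
#
# Every generator is a pure function of its arguments plus an explicit seed,
# evaluated under with_seed() so identical seeds give bit-identical output
# and nothing perturbs the caller's RNG stream.
#
# Monotone coupling uses a Gaussian copula: to plant a target Spearman
# correlation s between a peak row and the proportion, the latent Pearson
# correlation is set to r = 2 sin(pi s / 6) (the exact bivariate-normal
# relation between Pearson and Spearman), and the row is emitted through a
# strictly increasing transform (2^latent), which leaves ranks untouched.

#' A toy genome for synthetic atlases
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @return data.frame with columns `name`, `length`.
#' @export
generate_genome <- function(n_chrom = 2L, chrom_length = 1e7) {
  check_scalar_number(n_chrom, "n_chrom", 1)
  check_scalar_number(chrom_length, "chrom_length", 1)
  data.frame(name = paste0("chr", seq_len(n_chrom)),
             length = rep(as.numeric(chrom_length), n_chrom),
             stringsAsFactors = FALSE)
}

#' Sample a non-overlapping peak atlas
#'
#' Peaks are fixed-width intervals (default 501 bp) placed uniformly at
#' random without overlap; the summit sits at the midpoint. Coordinates are
#' 0-based half-open, the summit an absolute 0-based position.
#'
#' @param n_peaks number of peaks.
#' @param genome genome table from [generate_genome()].
#' @param width peak width in bp.
#' @param seed RNG seed.
#' @return peak data.frame (`peak_id`, `chrom`, `start`, `end`, `summit`).
#' @export
generate_peaks <- function(n_peaks, genome = generate_genome(), width = 501L,
                           seed = 1L) {
  check_scalar_number(n_peaks, "n_peaks", 1)
  check_scalar_number(width, "width", 1)
  with_seed(seed, {
    # allocate peaks across chromosomes proportionally to length
    alloc <- floor(n_peaks * genome$length / sum(genome$length))
    rem <- n_peaks - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
    rows <- vector("list", nrow(genome))
    for (i in seq_len(nrow(genome))) {
      k <- alloc[i]
      if (k == 0) next
      L <- genome$length[i]
      if (k * width > L) stop_invalid("chromosome %s too small for %d peaks",
                                      genome$name[i], k)
      # sorted draws plus cumulative width offsets => disjoint intervals
      slack <- floor(L - k * width)
      x <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
      start <- x + (seq_len(k) - 1L) * width
      rows[[i]] <- data.frame(chrom = genome$name[i], start = start,
                              end = start + width,
                              summit = start + width %/% 2L,
                              stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, rows)
    peaks <- data.frame(
      peak_id = sprintf("peak_%05d", seq_len(nrow(peaks))), peaks,
      stringsAsFactors = FALSE)
    validate_peaks(peaks)
    peaks
  })
}

#' Sample a toy gene annotation
#'
#' @param n_genes number of genes.
#' @param genome genome table.
#' @param seed RNG seed.
#' @return gene data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
generate_genes <- function(n_genes, genome = generate_genome(), seed = 1L) {
  check_scalar_number(n_genes, "n_genes", 1)
  with_seed(seed, {
    idx <- sample.int(nrow(genome), n_genes, replace = TRUE,
                      prob = genome$length / sum(genome$length))
    tss <- floor(runif(n_genes, 1, genome$length[idx])) + 1
    data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
               chrom = genome$name[idx], tss = tss,
               strand = sample(c("+", "-"), n_genes, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Declare planted peak effects
#'
#' @param peak_id peak identifiers.
#' @param direction +1 or -1, sign of the planted association with the
#'   epithelial proportion.
#' @param strength target absolute Spearman correlation in `[0, 1]`.
#' @param linked_gene optional gene id whose expression tracks the peak.
#' @param cn_driven logical; when TRUE both accessibility and expression are
#'   driven by the copy-number signal instead of the proportion.
#' @return data.frame of effects.
#' @export
planted_effects <- function(peak_id, direction = 1L, strength = 0.8,
                            linked_gene = NA_character_, cn_driven = FALSE) {
  df <- data.frame(peak_id = as.character(peak_id),
                   direction = as.integer(direction),
                   strength = as.numeric(strength),
                   linked_gene = as.character(linked_gene),
                   cn_driven = as.logical(cn_driven),
                   stringsAsFactors = FALSE)
  if (!all(df$direction %in% c(-1L, 1L))) stop_invalid("direction must be +1 or -1")
  if (any(df$strength < 0 | df$strength > 1)) stop_invalid("strength must lie in [0, 1]")
  df
}

#' Generate a synthetic cohort of epithelial proportions
#'
#' Proportions are drawn from a Beta(2, b) distribution with b solved so
#' that `P(X < 0.5)` equals `low_fraction`; degenerate fractions 0 and 1
#' fall back to a Beta(2, 2) truncated to the corresponding half-interval.
#'
#' @param n_samples cohort size (>= 2).
#' @param low_fraction target probability mass below proportion 0.5.
#' @param seed RNG seed.
#' @return cohort data.frame (`sample_id`, `proportion`, `group`).
#' @export
generate_cohort <- function(n_samples, low_fraction = 0.87, seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2) {
    stop_invalid("`n_samples` must be a single number >= 2")
  }
  check_scalar_number(low_fraction, "low_fraction", 0, 1)
  a <- 2
  props <- with_seed(seed, {
    if (low_fraction <= 0) {
      qbeta(runif(n_samples, pbeta(0.5, a, a), 1), a, a)
    } else if (low_fraction >= 1) {
      qbeta(runif(n_samples, 0, pbeta(0.5, a, a)), a, a)
    } else {
      b <- uniroot(function(b) pbeta(0.5, a, b) - low_fraction,
                   lower = 1e-3, upper = 1e4, tol = 1e-12)$root
      stats::rbeta(n_samples, a, b)
    }
  })
  make_cohort(sprintf("S%04d", seq_len(n_samples)), props)
}

#' Generate a peak-by-sample accessibility matrix with planted associations
#'
#' Planted peaks receive a latent value correlated with the cohort's
#' proportion through the Gaussian copula described above; copy-number-driven
#' peaks instead track the matching row of `cn`. All rows pass through
#' `2^(mu + latent)` so values are strictly positive and rank structure is
#' exactly the latent one.
#'
#' @param peaks peak atlas.
#' @param cohort cohort table.
#' @param effects data.frame from [planted_effects()] (or NULL for pure
#'   noise).
#' @param noise_sd standard deviation multiplier of the independent noise
#'   component (> 0; as it approaches 0 a planted row becomes a noiseless
#'   monotone transform of the proportion).
#' @param seed RNG seed.
#' @param cn optional copy-number matrix (required when any effect has
#'   `cn_driven = TRUE`).
#' @return numeric matrix, peaks x samples.
#' @export
generate_accessibility <- function(peaks, cohort, effects = NULL,
                                   noise_sd = 1, seed = 1L, cn = NULL) {
  check_scalar_number(noise_sd, "noise_sd", 0, Inf, strict_lower = TRUE)
  n <- nrow(cohort)
  if (!is.null(effects) && nrow(effects) > 0) {
    missing_ids <- setdiff(effects$peak_id, peaks$peak_id)
    if (length(missing_ids) > 0) {
      stop_invalid("effect peak id(s) not in atlas: %s",
                   paste(missing_ids, collapse = ", "))
    }
    if (any(effects$cn_driven) && is.null(cn)) {
      stop_invalid("`cn` matrix required for cn_driven effects")
    }
  }
  z <- normal_scores(cohort$proportion)
  with_seed(seed, {
    mu <- runif(nrow(peaks), 2, 8)
    eps <- matrix(rnorm(nrow(peaks) * n), nrow(peaks), n)
    latent <- eps
    if (!is.null(effects) && nrow(effects) > 0) {
      for (i in seq_len(nrow(effects))) {
        row <- match(effects$peak_id[i], peaks$peak_id)
        if (effects$cn_driven[i]) {
          zc <- normal_scores(cn[effects$peak_id[i], cohort$sample_id])
          latent[row, ] <- zc + 0.3 * eps[row, ]
        } else {
          r <- 2 * sin(pi * effects$strength[i] / 6)
          latent[row, ] <- effects$direction[i] * r * z +
            noise_sd * sqrt(pmax(0, 1 - r^2)) * eps[row, ]
        }
      }
    }
    m <- 2^(mu + latent)
    dimnames(m) <- list(peaks$peak_id, cohort$sample_id)
    m
  })
}

#' Generate a gene-by-sample expression matrix coupled to accessibility
#'
#' Genes named in `truth$links` track their peak's accessibility (Spearman
#' coupling `coupling`); copy-number-driven links track the copy-number row
#' with independent noise; all other genes are independent noise.
#'
#' @param genes gene annotation.
#' @param cohort cohort table.
#' @param truth list with elements `links` (columns `peak_id`, `gene_id`)
#'   and optionally `effects` (to identify `cn_driven` links).
#' @param acc accessibility matrix the linked genes couple to.
#' @param seed RNG seed.
#' @param coupling target Spearman correlation between a linked gene and its
#'   peak (1 = perfect coupling).
#' @param noise_sd noise multiplier, as in [generate_accessibility()].
#' @param cn optional copy-number matrix for cn_driven links.
#' @return numeric matrix, genes x samples.
#' @export
generate_expression <- function(genes, cohort, truth, acc, seed = 1L,
                                coupling = 0.9, noise_sd = 1, cn = NULL) {
  check_scalar_number(coupling, "coupling", 0, 1)
  n <- nrow(cohort)
  links <- truth$links %||% data.frame(peak_id = character(0),
                                       gene_id = character(0))
  if (nrow(links) > 0) {
    missing_g <- setdiff(links$gene_id, genes$gene_id)
    if (length(missing_g) > 0) {
      stop_invalid("linked gene(s) not in annotation: %s",
                   paste(missing_g, collapse = ", "))
    }
    missing_p <- setdiff(links$peak_id, rownames(acc))
    if (length(missing_p) > 0) {
      stop_invalid("linked peak(s) not in accessibility matrix: %s",
                   paste(missing_p, collapse = ", "))
    }
  }
  cn_peaks <- character(0)
  if (!is.null(truth$effects)) {
    cn_peaks <- truth$effects$peak_id[truth$effects$cn_driven]
  }
  with_seed(seed, {
    mu <- runif(nrow(genes), 2, 10)
    eps <- matrix(rnorm(nrow(genes) * n), nrow(genes), n)
    latent <- eps
    if (nrow(links) > 0) {
      for (i in seq_len(nrow(links))) {
        row <- match(links$gene_id[i], genes$gene_id)
        if (links$peak_id[i] %in% cn_peaks) {
          if (is.null(cn)) stop_invalid("`cn` required for cn_driven links")
          zc <- normal_scores(cn[links$peak_id[i], cohort$sample_id])
          latent[row, ] <- zc + 0.3 * eps[row, ]
        } else {
          za <- normal_scores(acc[links$peak_id[i], cohort$sample_id])
          r <- 2 * sin(pi * coupling / 6)
          if (coupling == 1) r <- 1
          latent[row, ] <- r * za +
            noise_sd * sqrt(pmax(0, 1 - r^2)) * eps[row, ]
        }
      }
    }
    m <- 2^(mu + latent)
    dimnames(m) <- list(genes$gene_id, cohort$sample_id)
    m
  })
}

#' Generate a copy-number matrix
#'
#' Rows listed in `cn_driven_ids` carry a strong sample-level copy-number
#' signal (sd 0.5 around the neutral value 2); all other rows are neutral
#' with small noise.
#'
#' @param peaks peak atlas.
#' @param cohort cohort table.
#' @param cn_driven_ids peak ids carrying copy-number variation.
#' @param seed RNG seed.
#' @return numeric matrix, peaks x samples.
#' @export
generate_copy_number <- function(peaks, cohort, cn_driven_ids = character(0),
                                 seed = 1L) {
  missing_ids <- setdiff(cn_driven_ids, peaks$peak_id)
  if (length(missing_ids) > 0) {
    stop_invalid("cn_driven id(s) not in atlas: %s",
                 paste(missing_ids, collapse = ", "))
  }
  n <- nrow(cohort)
  with_seed(seed, {
    m <- 2 + 0.05 * matrix(rnorm(nrow(peaks) * n), nrow(peaks), n)
    dimnames(m) <- list(peaks$peak_id, cohort$sample_id)
    for (id in cn_driven_ids) {
      m[id, ] <- pmax(0, 2 + 0.5 * rnorm(n))
    }
    m
  })
}

#' Generate survival times under a proportional-hazards construction
#'
#' Event times are exponential with per-sample rate
#' `h0 * exp(sum coef_g z(expr_g) + proportion_coef * z(proportion))`;
#' censoring times are independent exponentials whose rate is solved so the
#' expected censored fraction equals `censor_rate`.
#'
#' @param cohort cohort table (provides sample ids and the proportion term).
#' @param expr expression matrix containing all prognostic genes.
#' @param prognostic data.frame with columns `gene_id`, `coef` (may have 0
#'   rows).
#' @param censor_rate expected fraction censored, in `[0, 1)`.
#' @param seed RNG seed.
#' @param baseline_hazard events per day at linear predictor 0.
#' @param proportion_coef hazard coefficient on the standardized epithelial
#'   proportion (0 disables the image term).
#' @return survival data.frame (`sample_id`, `time`, `event`).
#' @export
generate_survival <- function(cohort, expr, prognostic = NULL,
                              censor_rate = 0.7, seed = 1L,
                              baseline_hazard = log(2) / 1500,
                              proportion_coef = 0) {
  if (is.null(cohort) || nrow(cohort) == 0L) stop_invalid("empty cohort")
  check_scalar_number(censor_rate, "censor_rate", 0, 1, strict_upper = TRUE)
  lp <- rep(0, nrow(cohort))
  if (!is.null(prognostic) && nrow(prognostic) > 0) {
    missing_g <- setdiff(prognostic$gene_id, rownames(expr))
    if (length(missing_g) > 0) {
      stop_invalid("prognostic gene(s) not in expression: %s",
                   paste(missing_g, collapse = ", "))
    }
    for (i in seq_len(nrow(prognostic))) {
      g <- expr[prognostic$gene_id[i], cohort$sample_id]
      lp <- lp + prognostic$coef[i] * as.numeric(scale(g))
    }
  }
  if (proportion_coef != 0) {
    lp <- lp + proportion_coef * as.numeric(scale(cohort$proportion))
  }
  h <- baseline_hazard * exp(lp)
  with_seed(seed, {
    t_event <- rexp(nrow(cohort)) / h
    if (censor_rate == 0) {
      time <- t_event
      event <- rep(1L, nrow(cohort))
    } else {
      # P(censored | h_i) = c / (c + h_i); solve the mean for c
      f <- function(logc) mean(exp(logc) / (exp(logc) + h)) - censor_rate
      logc <- uniroot(f, lower = log(min(h)) - 20, upper = log(max(h)) + 20,
                      tol = 1e-12)$root
      t_cens <- rexp(nrow(cohort)) / exp(logc)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    data.frame(sample_id = cohort$sample_id, time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Generate a tissue label mask with a target epithelial proportion
#'
#' Tissue occupies a centered ellipse; within it, a smoothed random field is
#' thresholded at the exact pixel count giving the requested epithelial
#' fraction, so the measured proportion matches the target up to pixel
#' rounding (within 0.01 for masks of at least ~100 tissue pixels).
#'
#' @param height,width mask size in pixels (>= 1).
#' @param target_proportion requested epithelial/(epithelial+stromal)
#'   fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return integer matrix with labels 0/1/2.
#' @export
generate_tissue_mask <- function(height, width, target_proportion = 0.5,
                                 seed = 1L) {
  if (!is.numeric(height) || !is.numeric(width) || height < 1 || width < 1) {
    stop_invalid("mask must have positive area")
  }
  check_scalar_number(target_proportion, "target_proportion", 0, 1)
  h <- as.integer(height); w <- as.integer(width)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- max(h * 0.45, 0.5); rx <- max(w * 0.45, 0.5)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  tissue <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
  n_tissue <- sum(tissue)
  if (n_tissue == 0L) stop_invalid("mask must have positive area")
  box1d <- function(v, k) {
    n <- length(v); half <- k %/% 2L
    cs <- cumsum(c(0, v))
    lo <- pmax(0L, seq_len(n) - half - 1L)
    hi <- pmin(n, seq_len(n) + half)
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  with_seed(seed, {
    field <- matrix(rnorm(h * w), h, w)
    k <- max(3L, as.integer(round(min(h, w) / 8)))
    field <- apply(field, 2L, box1d, k = k)
    field <- t(apply(field, 1L, box1d, k = k))
    n_epi <- round(target_proportion * n_tissue)
    mask <- matrix(MASK_BACKGROUND, h, w)
    vals <- field[tissue]
    ord <- order(vals, seq_along(vals), decreasing = TRUE)
    lab <- rep(MASK_STROMAL, n_tissue)
    if (n_epi > 0) lab[ord[seq_len(n_epi)]] <- MASK_EPITHELIAL
    mask[tissue] <- lab
    storage.mode(mask) <- "integer"
    mask
  })
}

#' Simulate a complete synthetic study bundle
#'
#' Builds a matched cohort: peak atlas on a toy genome, cohort of epithelial
#' proportions with the characteristic low skew, accessibility with planted
#' positive/negative associations, genes placed so a subset is linkable
#' through promoter windows and distal correlation, expression coupled to
#' those peaks, copy-number rows driving a few spurious links, and survival
#' times whose hazard depends on selected genes and optionally the
#' proportion. Optionally a second, larger survival cohort is generated
#' (mirroring a study where the expression/survival set is bigger than the
#' matched ATAC set).
#'
#' @param n_samples matched-cohort size.
#' @param low_fraction target fraction of epithelial-low samples.
#' @param n_peaks,n_genes atlas sizes.
#' @param n_planted number of proportion-associated peaks.
#' @param strength planted |Spearman| target.
#' @param frac_positive fraction of planted peaks with positive direction.
#' @param n_promoter_links,n_distal_links planted links of each kind.
#' @param n_cn_links copy-number-driven spurious links.
#' @param coupling peak-gene expression coupling for planted links.
#' @param noise_sd generator noise multiplier.
#' @param n_prognostic number of linked genes given a hazard coefficient.
#' @param prognostic_coef hazard coefficient for those genes.
#' @param proportion_coef hazard coefficient on the image feature.
#' @param censor_rate expected censored fraction.
#' @param n_survival optional size of a separate survival cohort.
#' @param seed master seed; stage seeds are small fixed offsets from it.
#' @param out_dir optional directory; when given all artifacts are written
#'   as the pipeline's TSV/JSON formats.
#' @return list with elements `genome`, `peaks`, `genes`, `cohort`, `acc`,
#'   `expr`, `cn`, `survival`, `truth`, and when `n_survival` is set,
#'   `survival_cohort`, `expr_survival`, `survival2`.
#' @export
simulate_study <- function(n_samples = 54L, low_fraction = 0.87,
                           n_peaks = 2000L, n_genes = 200L,
                           n_planted = 50L, strength = 0.8,
                           frac_positive = 0.25,
                           n_promoter_links = 5L, n_distal_links = 5L,
                           n_cn_links = 3L, coupling = 0.9, noise_sd = 1,
                           n_prognostic = 3L, prognostic_coef = 0.7,
                           proportion_coef = 0.5, censor_rate = 0.7,
                           n_survival = NULL, seed = 1L, out_dir = NULL) {
  genome <- generate_genome()
  peaks <- generate_peaks(n_peaks, genome, seed = seed + 11L)
  cohort <- generate_cohort(n_samples, low_fraction, seed = seed + 12L)
  genes <- generate_genes(n_genes, genome, seed = seed + 14L)

  n_linked <- n_promoter_links + n_distal_links
  if (n_planted + n_cn_links > n_peaks) {
    stop_invalid("n_planted + n_cn_links (%d) exceeds n_peaks (%d)",
                 n_planted + n_cn_links, n_peaks)
  }
  if (n_planted < n_linked) stop_invalid("n_planted < number of planted links")
  if (n_genes < n_linked + n_cn_links) stop_invalid("not enough genes for links")
  picked <- with_seed(seed + 13L,
                      sample(peaks$peak_id, n_planted + n_cn_links))
  planted_ids <- picked[seq_len(n_planted)]
  cn_ids <- if (n_cn_links > 0) picked[n_planted + seq_len(n_cn_links)] else character(0)
  n_pos <- round(frac_positive * n_planted)
  # spread the positive directions across the planted set so linked genes
  # (attached to the leading peaks) carry both signs
  direction <- rep(-1L, n_planted)
  if (n_pos > 0) {
    direction[unique(round(seq(1, n_planted, length.out = n_pos)))] <- 1L
  }

  # place linkable genes deterministically relative to their peak summits:
  # promoter genes put the summit inside the [tss-1000, tss-100] window,
  # distal (and cn) genes sit well inside the 500 kbp horizon
  link_rows <- seq_len(n_linked + n_cn_links)
  link_peaks <- c(planted_ids[seq_len(n_linked)], cn_ids)
  kinds <- c(rep("promoter", n_promoter_links),
             rep("distal", n_distal_links), rep("distal", n_cn_links))
  offsets <- ifelse(kinds == "promoter", 500L, 200000L)
  pk_idx <- match(link_peaks, peaks$peak_id)
  genes$chrom[link_rows] <- peaks$chrom[pk_idx]
  genes$tss[link_rows] <- peaks$summit[pk_idx] + 1L + offsets
  genes$strand[link_rows] <- "+"
  validate_genes(genes)

  effects <- rbind(
    planted_effects(planted_ids, direction, strength,
                    linked_gene = c(genes$gene_id[seq_len(n_linked)],
                                    rep(NA_character_, n_planted - n_linked)),
                    cn_driven = FALSE),
    if (n_cn_links > 0) {
      planted_effects(cn_ids, 1L, 0,
                      linked_gene = genes$gene_id[n_linked + seq_len(n_cn_links)],
                      cn_driven = TRUE)
    }
  )
  links <- data.frame(peak_id = link_peaks,
                      gene_id = genes$gene_id[link_rows],
                      kind = kinds,
                      cn_driven = c(rep(FALSE, n_linked),
                                    rep(TRUE, n_cn_links)),
                      stringsAsFactors = FALSE)
  prognostic <- if (n_prognostic > 0) {
    data.frame(gene_id = genes$gene_id[seq_len(min(n_prognostic, n_linked))],
               coef = prognostic_coef, stringsAsFactors = FALSE)
  } else NULL
  truth <- list(effects = effects, links = links, prognostic = prognostic,
                params = list(n_samples = n_samples, n_peaks = n_peaks,
                              strength = strength, coupling = coupling,
                              seed = seed))

  cn <- generate_copy_number(peaks, cohort, cn_ids, seed = seed + 15L)
  acc <- generate_accessibility(peaks, cohort, effects, noise_sd,
                                seed = seed + 16L, cn = cn)
  expr <- generate_expression(genes, cohort, truth, acc, seed = seed + 17L,
                              coupling = coupling, noise_sd = noise_sd,
                              cn = cn)
  survival <- generate_survival(cohort, expr, prognostic, censor_rate,
                                seed = seed + 18L,
                                proportion_coef = proportion_coef)
  out <- list(genome = genome, peaks = peaks, genes = genes, cohort = cohort,
              acc = acc, expr = expr, cn = cn, survival = survival,
              truth = truth)

  if (!is.null(n_survival)) {
    co2 <- generate_cohort(n_survival, low_fraction, seed = seed + 19L)
    cn2 <- generate_copy_number(peaks, co2, cn_ids, seed = seed + 20L)
    acc2 <- generate_accessibility(peaks, co2, effects, noise_sd,
                                   seed = seed + 21L, cn = cn2)
    expr2 <- generate_expression(genes, co2, truth, acc2, seed = seed + 22L,
                                 coupling = coupling, noise_sd = noise_sd,
                                 cn = cn2)
    out$survival_cohort <- co2
    out$expr_survival <- expr2
    out$survival2 <- generate_survival(co2, expr2, prognostic, censor_rate,
                                       seed = seed + 23L,
                                       proportion_coef = proportion_coef)
  }

  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' Write a simulated study bundle to disk in the pipeline's formats
#'
#' @param study list from [simulate_study()].
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_peaks(study$peaks, p("peaks.tsv"))
  data.table::fwrite(study$genes, p("genes.tsv"), sep = "\t")
  write_cohort(study$cohort, p("cohort.tsv"))
  write_matrix_tsv(study$acc, p("accessibility.tsv"), "peak_id")
  write_matrix_tsv(study$expr, p("expression.tsv"), "gene_id")
  write_matrix_tsv(study$cn, p("copy_number.tsv"), "peak_id")
  write_survival(study$survival, p("survival.tsv"))
  truth <- study$truth
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(study$survival_cohort)) {
    write_cohort(study$survival_cohort, p("survival_cohort.tsv"))
    write_matrix_tsv(study$expr_survival, p("expression_survival.tsv"),
                     "gene_id")
    write_survival(study$survival2, p("survival_large.tsv"))
  }
  invisible(out_dir)
}
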