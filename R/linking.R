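# Peak-to-gene linking: strand-aware promoter windows, distal candidate
# pairs within a 500 kbp horizon, correlation-based distal links with
# copy-number and promoter-overlap filters, and the collapse to a signed
# target-gene table.
#
# Interval overlap is delegated to IRanges/GenomicRanges; tests retain
# brute-force all-pairs oracles.

#' Strand-aware promoter window
#'
#' The promoter is the region 1000 to 100 bp upstream of the TSS: for a `+`
#' strand gene `[tss - 1000, tss - 100]`, for a `-` strand gene
#' `[tss + 100, tss + 1000]`, both ends inclusive in 1-based coordinates.
#' Windows running off the chromosome start are truncated at 1 with a
#' warning.
#'
#' @param tss 1-based TSS positions.
#' @param strand `"+"` or `"-"`, recycled against `tss`.
#' @param upstream,proximal_gap window bounds in bp upstream of the TSS.
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @examples
#' promoter_window(10000, "+") # [9000, 9900]
#' @export
promoter_window <- function(tss, strand, upstream = 1000L,
                            proximal_gap = 100L) {
  if (any(tss < 1)) stop_invalid("tss must be >= 1")
  if (!all(strand %in% c("+", "-"))) stop_invalid("strand must be + or -")
  if (proximal_gap >= upstream) stop_invalid("proximal_gap must be < upstream")
  strand <- rep_len(strand, length(tss))
  start <- ifelse(strand == "+", tss - upstream, tss + proximal_gap)
  end <- ifelse(strand == "+", tss - proximal_gap, tss + upstream)
  if (any(start < 1)) {
    warning("promoter window truncated at chromosome start", call. = FALSE)
    start <- pmax(start, 1)
    end <- pmax(end, 1)
  }
  data.frame(start = start, end = end)
}

# GRanges of 1-based summit positions
summit_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$summit + 1L,
                              width = 1L))
}

#' Assign peaks to genes through promoter windows
#'
#' A promoter link is created for every (peak, gene) pair whose peak summit
#' lies inside the gene's promoter window. A summit hitting several genes'
#' windows is assigned to the gene with the nearest TSS (ties broken by
#' lexicographic gene id) unless `tie_break = FALSE`.
#'
#' @param peaks peak atlas (0-based half-open, absolute `summit`).
#' @param genes gene annotation (1-based `tss`, `strand`).
#' @param upstream,proximal_gap promoter window definition.
#' @param tie_break keep only the nearest gene per peak (default TRUE).
#' @return data.frame of links (`peak_id`, `gene_id`, `kind = "promoter"`,
#'   `distance` in bp between summit and TSS).
#' @export
assign_promoter_peaks <- function(peaks, genes, upstream = 1000L,
                                  proximal_gap = 100L, tie_break = TRUE) {
  win <- promoter_window(genes$tss, genes$strand, upstream, proximal_gap)
  gr_win <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(win$start, win$end))
  hits <- GenomicRanges::findOverlaps(summit_granges(peaks), gr_win)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  links <- data.frame(
    peak_id = peaks$peak_id[pi],
    gene_id = genes$gene_id[gi],
    kind = rep("promoter", length(pi)),
    distance = abs((peaks$summit[pi] + 1L) - genes$tss[gi]),
    stringsAsFactors = FALSE
  )
  if (tie_break && nrow(links) > 1L) {
    links <- links[order(links$peak_id, links$distance, links$gene_id), ]
    links <- links[!duplicated(links$peak_id), ]
  }
  rownames(links) <- NULL
  links
}

#' Candidate distal peak-gene pairs within a distance horizon
#'
#' All same-chromosome pairs whose summit-to-TSS distance is strictly less
#' than `max_dist` (default 500 kbp).
#'
#' @param peaks peak atlas.
#' @param genes gene annotation.
#' @param max_dist distance horizon in bp (strict upper bound).
#' @return data.frame (`peak_id`, `gene_id`, `distance`).
#' @export
candidate_distal_pairs <- function(peaks, genes, max_dist = 500000L) {
  check_scalar_number(max_dist, "max_dist", 0, Inf, strict_lower = TRUE)
  start <- pmax(genes$tss - (max_dist - 1L), 1)
  gr_win <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start, genes$tss + (max_dist - 1L)))
  hits <- GenomicRanges::findOverlaps(summit_granges(peaks), gr_win)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    peak_id = peaks$peak_id[pi],
    gene_id = genes$gene_id[gi],
    distance = abs((peaks$summit[pi] + 1L) - genes$tss[gi]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$peak_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# partial Spearman correlation of (x, y) given z: Pearson partial
# correlation applied to the three pairwise Spearman correlations
partial_spearman <- function(r_xy, r_xz, r_yz) {
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (den < .Machine$double.eps) return(0)
  (r_xy - r_xz * r_yz) / den
}

#' Correlation-based distal links with CNV and promoter-overlap filters
#'
#' For every candidate pair, the Spearman correlation between peak
#' accessibility and gene expression is computed across the shared samples;
#' BH q-values are taken over all tested pairs and links with
#' `q <= fdr_cut` survive. Surviving links are then dropped when (i) the
#' association is judged copy-number driven — the partial Spearman
#' correlation given the peak's copy-number row retains less than
#' `attenuation` of the marginal correlation — or (ii) the peak summit lies
#' in any gene's promoter window.
#'
#' @param pairs candidate pairs from [candidate_distal_pairs()].
#' @param acc accessibility matrix (peaks x samples).
#' @param expr expression matrix (genes x samples).
#' @param cn optional copy-number matrix; when absent the CNV filter is
#'   skipped with a warning.
#' @param fdr_cut BH q-value cutoff for a surviving link.
#' @param genes gene annotation for the promoter-overlap filter (skipped
#'   with a warning when absent).
#' @param attenuation CNV-filter threshold: flag when
#'   `|partial rho| < attenuation * |rho|`.
#' @param upstream,proximal_gap promoter window definition for the overlap
#'   filter.
#' @return data.frame of all tested pairs with columns `peak_id`,
#'   `gene_id`, `kind = "distal"`, `distance`, `rho`, `p_value`, `fdr`,
#'   `cnv_driven`, `promoter_overlap`, `surviving`.
#' @export
link_distal <- function(pairs, acc, expr, cn = NULL, fdr_cut = 0.01,
                        genes = NULL, attenuation = 0.5, upstream = 1000L,
                        proximal_gap = 100L) {
  check_scalar_number(fdr_cut, "fdr_cut", 0, 1)
  if (nrow(pairs) == 0L) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      kind = character(0), distance = numeric(0),
                      rho = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), cnv_driven = logical(0),
                      promoter_overlap = logical(0), surviving = logical(0)))
  }
  shared <- sort(intersect(colnames(acc), colnames(expr)))
  if (!is.null(cn)) shared <- sort(intersect(shared, colnames(cn)))
  if (length(shared) < 3L) stop_invalid("matrices share fewer than 3 samples")
  n <- length(shared)

  rho <- numeric(nrow(pairs))
  partial <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- rank(acc[pairs$peak_id[i], shared], ties.method = "average")
    e <- rank(expr[pairs$gene_id[i], shared], ties.method = "average")
    if (sd(a) == 0 || sd(e) == 0) {
      rho[i] <- NA_real_
      next
    }
    rho[i] <- cor(a, e)
    if (!is.null(cn) && pairs$peak_id[i] %in% rownames(cn)) {
      z <- rank(cn[pairs$peak_id[i], shared], ties.method = "average")
      if (sd(z) > 0) {
        partial[i] <- partial_spearman(rho[i], cor(a, z), cor(e, z))
      }
    }
  }
  testable <- !is.na(rho)
  p <- rep(NA_real_, nrow(pairs))
  p[testable] <- spearman_p_t(rho[testable], n)
  q <- rep(NA_real_, nrow(pairs))
  q[testable] <- bh_fdr(p[testable])

  cnv_driven <- rep(FALSE, nrow(pairs))
  if (is.null(cn)) {
    warning("no copy-number matrix: CNV filter skipped", call. = FALSE)
  } else {
    has_cn <- !is.na(partial)
    cnv_driven[has_cn] <- abs(partial[has_cn]) <
      attenuation * abs(rho[has_cn])
  }

  promoter_overlap <- rep(FALSE, nrow(pairs))
  if (is.null(genes)) {
    warning("no gene annotation: promoter-overlap filter skipped",
            call. = FALSE)
  } else {
    win <- promoter_window(genes$tss, genes$strand, upstream, proximal_gap)
    gr_win <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(win$start, win$end))
    upk <- unique(pairs$peak_id)
    # any-promoter membership per peak, via the summit position
    acc_peaks <- data.frame(peak_id = upk, stringsAsFactors = FALSE)
    summ <- attr(pairs, "summit")
    if (is.null(summ)) {
      stop_invalid("`pairs` lacks the summit attribute; build them with candidate_distal_pairs() via link_peaks_to_genes(), or attach attr(pairs, 'summit')")
    }
    gr_s <- GenomicRanges::GRanges(
      summ$chrom[match(upk, summ$peak_id)],
      IRanges::IRanges(summ$summit[match(upk, summ$peak_id)] + 1L, width = 1L))
    in_prom <- GenomicRanges::countOverlaps(gr_s, gr_win) > 0
    promoter_overlap <- in_prom[match(pairs$peak_id, upk)]
  }

  out <- data.frame(
    peak_id = pairs$peak_id, gene_id = pairs$gene_id, kind = "distal",
    distance = pairs$distance, rho = rho, p_value = p, fdr = q,
    cnv_driven = cnv_driven, promoter_overlap = promoter_overlap,
    stringsAsFactors = FALSE
  )
  out$surviving <- testable & !is.na(q) & q <= fdr_cut &
    !out$cnv_driven & !out$promoter_overlap
  out
}

#' Build distal links end to end from peaks and annotation
#'
#' Convenience wrapper: candidate pairs restricted to `peak_ids`, then
#' [link_distal()] with the summit information attached for the
#' promoter-overlap filter.
#'
#' @param peaks peak atlas.
#' @param genes gene annotation.
#' @param peak_ids peaks to link (typically the screen's significant set).
#' @inheritParams link_distal
#' @param max_dist distance horizon in bp.
#' @return as [link_distal()].
#' @export
link_peaks_to_genes <- function(peaks, genes, peak_ids, acc, expr, cn = NULL,
                                fdr_cut = 0.01, max_dist = 500000L,
                                attenuation = 0.5, upstream = 1000L,
                                proximal_gap = 100L) {
  sub <- peaks[peaks$peak_id %in% peak_ids, , drop = FALSE]
  pairs <- candidate_distal_pairs(sub, genes, max_dist)
  attr(pairs, "summit") <- sub[, c("peak_id", "chrom", "summit")]
  link_distal(pairs, acc, expr, cn = cn, fdr_cut = fdr_cut, genes = genes,
              attenuation = attenuation, upstream = upstream,
              proximal_gap = proximal_gap)
}

#' Collapse links to a signed target-gene table
#'
#' One row per distinct gene across promoter links and surviving distal
#' links. The sign is the sign of the Spearman correlation between the
#' gene's expression and the epithelial proportion over the cohort samples;
#' an exactly-zero correlation is labeled positive by convention (with a
#' message); genes missing from the expression matrix are retained with
#' sign `"unknown"` and a warning.
#'
#' @param promoter_links data.frame from [assign_promoter_peaks()].
#' @param distal_links data.frame from [link_distal()]; only rows with
#'   `surviving = TRUE` are used (a data.frame without that column is taken
#'   as all surviving).
#' @param expr expression matrix.
#' @param cohort cohort table.
#' @return data.frame (`gene_id`, `sign`, `n_links`) with attribute
#'   `"links"` holding the supporting link rows.
#' @export
collapse_targets <- function(promoter_links, distal_links, expr, cohort) {
  dl <- distal_links
  if (!is.null(dl) && nrow(dl) > 0 && "surviving" %in% names(dl)) {
    dl <- dl[dl$surviving, , drop = FALSE]
  }
  keep <- c("peak_id", "gene_id", "kind", "distance")
  all_links <- rbind(
    if (!is.null(promoter_links) && nrow(promoter_links) > 0)
      promoter_links[, keep],
    if (!is.null(dl) && nrow(dl) > 0) dl[, keep]
  )
  if (is.null(all_links) || nrow(all_links) == 0L) {
    out <- data.frame(gene_id = character(0), sign = character(0),
                      n_links = integer(0), stringsAsFactors = FALSE)
    attr(out, "links") <- all_links
    return(out)
  }
  shared <- sort(intersect(colnames(expr), cohort$sample_id))
  prop <- cohort$proportion[match(shared, cohort$sample_id)]
  gene_ids <- sort(unique(all_links$gene_id))
  sign_of <- vapply(gene_ids, function(g) {
    if (!(g %in% rownames(expr))) {
      warning(sprintf("gene %s absent from expression; sign unknown", g),
              call. = FALSE)
      return("unknown")
    }
    e <- expr[g, shared]
    if (length(unique(e)) < 2L || length(unique(prop)) < 2L) {
      return("unknown")
    }
    r <- spearman_rho(e, prop)
    if (r == 0) {
      message(sprintf("gene %s has rho exactly 0; labeled positive", g))
      return("positive")
    }
    if (r > 0) "positive" else "negative"
  }, character(1))
  out <- data.frame(
    gene_id = gene_ids,
    sign = unname(sign_of),
    n_links = as.integer(table(all_links$gene_id)[gene_ids]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "links") <- all_links
  out
}
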