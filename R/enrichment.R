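# Over-representation analysis of target genes against a gene-set
# collection: one-sided hypergeometric (Fisher exact upper tail), BH across
# sets. A generic stand-in for proprietary pathway knowledge bases.

#' Hypergeometric over-representation test
#'
#' For each set, the p-value is the upper-tail hypergeometric probability of
#' observing at least the actual overlap between `hits` and the set, drawing
#' `|hits|` genes from the universe. Sets are restricted to the universe
#' first; hits outside the universe are dropped with a warning.
#'
#' @param hits character vector of interesting gene ids.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe background gene ids; defaults to the union of all sets
#'   and hits.
#' @return data.frame with columns `set`, `set_size`, `overlap`, `p_value`,
#'   `fdr`, `neg_log10_p`, ordered by p-value.
#' @examples
#' hypergeometric_enrich(letters[1:5],
#'   list(s = letters[1:5]), universe = letters[1:10])
#' @export
hypergeometric_enrich <- function(hits, sets, universe = NULL) {
  if (is.null(universe)) universe <- unique(c(unlist(sets), hits))
  universe <- unique(as.character(universe))
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, universe)
  if (length(outside) > 0) {
    warning(sprintf("%d hit gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    hits <- setdiff(hits, outside)
  }
  if (length(hits) == 0L) {
    stop("no hit genes remain after restriction to the universe",
         call. = FALSE)
  }
  if (length(sets) == 0L || is.null(names(sets))) {
    stop_invalid("`sets` must be a non-empty named list")
  }
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- vapply(sets, length, 0L) == 0L
  if (any(empty)) {
    warning(sprintf("%d set(s) empty after restriction dropped", sum(empty)),
            call. = FALSE)
    sets <- sets[!empty]
  }
  N <- length(universe)
  n <- length(hits)
  res <- lapply(sort(names(sets)), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(hits, sets[[nm]]))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  out$neg_log10_p <- -log10(out$p_value)
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out
}

#' Enrichment split by target-gene sign
#'
#' Runs [hypergeometric_enrich()] separately for the positively and
#' negatively correlated target genes, mirroring the usual PosCor/NegCor
#' presentation.
#'
#' @param targets target-gene table from [collapse_targets()].
#' @param sets named list of gene sets.
#' @param universe background gene ids.
#' @return data.frame with an extra `group` column (`"positive"` /
#'   `"negative"`); groups with no usable genes are omitted.
#' @export
enrich_by_sign <- function(targets, sets, universe = NULL) {
  out <- list()
  for (g in c("positive", "negative")) {
    ids <- targets$gene_id[targets$sign == g]
    ids <- intersect(ids, universe %||% ids)
    if (length(ids) == 0L) next
    tab <- hypergeometric_enrich(ids, sets, universe)
    tab$group <- g
    out[[g]] <- tab
  }
  if (length(out) == 0L) {
    stop("no target genes usable for enrichment", call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
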