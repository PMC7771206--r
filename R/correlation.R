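# Peak-phenotype correlation screen: Spearman rho, permutation / t-based
# p-values, Benjamini-Hochberg FDR, and the genome-wide screen driver.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with at least
#'   two distinct values.
#' @return correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_invalid("`x` and `y` must have equal length")
  if (n < 3L) stop_invalid("need n >= 3 observations")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values not allowed")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  }
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# all permutations of 1..n as a (n!) x n integer matrix; n <= 8 enforced
# by callers, so at most 40320 x 8
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, factorial(n), n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Two-tailed p-value for a Spearman correlation
#'
#' `method = "exhaustive"` enumerates the full permutation distribution of
#' the rank pairing (all `n!` permutations) and is refused for `n > 8`.
#' `method = "approximate"` uses the t approximation with `n - 2` degrees of
#' freedom. `method = "permutation"` is a seeded Monte-Carlo permutation
#' test. `method = "auto"` picks exhaustive for `n <= 8`, otherwise the t
#' approximation.
#'
#' @inheritParams spearman_rho
#' @param method one of `"auto"`, `"exhaustive"`, `"approximate"`,
#'   `"permutation"`.
#' @param n_perm Monte-Carlo permutation count (`method = "permutation"`).
#' @param seed seed for the Monte-Carlo draw.
#' @return p-value in `(0, 1]`.
#' @export
spearman_pvalue <- function(x, y,
                            method = c("auto", "exhaustive", "approximate",
                                       "permutation"),
                            n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (method == "auto") method <- if (n <= 8L) "exhaustive" else "approximate"
  switch(method,
    exhaustive = {
      if (n > 8L) {
        stop("exhaustive enumeration refused for n > 8 (combinatorial explosion)",
             call. = FALSE)
      }
      rx <- as.numeric(scale(rank(x, ties.method = "average")))
      ry <- as.numeric(scale(rank(y, ties.method = "average")))
      P <- perm_matrix(n)
      rho_perm <- as.vector(matrix(ry[P], nrow(P)) %*% rx) / (n - 1)
      mean(abs(rho_perm) >= abs(rho) - 1e-12)
    },
    approximate = spearman_p_t(rho, n),
    permutation = {
      check_scalar_number(n_perm, "n_perm", 1)
      rx <- rank(x, ties.method = "average")
      ry <- rank(y, ties.method = "average")
      obs <- abs(cor(rx, ry))
      hits <- with_seed(seed, {
        sum(vapply(seq_len(n_perm), function(i) {
          abs(cor(rx, ry[sample.int(n)])) >= obs - 1e-12
        }, logical(1)))
      })
      (1 + hits) / (n_perm + 1)
    })
}

# vectorized t-approximation p for Spearman rho at sample size n
spearman_p_t <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.xmin))
  p <- 2 * pt(-abs(tt), df = n - 2)
  pmax(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment: for the i-th smallest p-value,
#' `q_(i) = min_{j >= i} m p_(j) / j`, clipped to 1 and mapped back to the
#' input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * pvals[o]))
  q[order(o)]
}

#' Screen peaks for association with the epithelial proportion
#'
#' Computes, for every peak row of the accessibility matrix, the Spearman
#' correlation with the cohort's epithelial proportion across the shared
#' samples, a two-tailed p-value, and BH q-values over all testable peaks.
#' Peaks with constant accessibility have no defined correlation; they are
#' reported with `NA` statistics and excluded from the multiple-testing
#' universe, with a warning.
#'
#' @param acc numeric matrix, peaks x samples, with dimnames.
#' @param cohort cohort data.frame (`sample_id`, `proportion`).
#' @param alpha FDR significance threshold (significant iff `q < alpha`).
#' @param method p-value method passed to [spearman_pvalue()]; the default
#'   `"auto"` uses the t approximation at the usual cohort sizes.
#' @param rho_cut optional additional `|rho|` threshold (default off).
#' @param peaks optional peak annotation merged into the result.
#' @param seed seed used only by `method = "permutation"`.
#' @param n_perm Monte-Carlo permutations for `method = "permutation"`.
#' @return data.frame with columns `peak_id`, `rho`, `p_value`, `fdr`,
#'   `direction`, `significant` (plus coordinates when `peaks` is given);
#'   attribute `"counts"` holds the screen funnel numbers.
#' @export
screen_peaks <- function(acc, cohort, alpha = 0.05,
                         method = c("auto", "approximate", "exhaustive",
                                    "permutation"),
                         rho_cut = NULL, peaks = NULL, seed = 1L,
                         n_perm = 1e5) {
  method <- match.arg(method)
  check_scalar_number(alpha, "alpha", 0, 1)
  stopifnot(is.matrix(acc), !is.null(rownames(acc)), !is.null(colnames(acc)))
  shared <- sort(intersect(colnames(acc), cohort$sample_id))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared samples between matrix and cohort", call. = FALSE)
  }
  a <- acc[, shared, drop = FALSE]
  prop <- cohort$proportion[match(shared, cohort$sample_id)]
  n <- length(shared)

  constant <- apply(a, 1L, function(r) length(unique(r)) < 2L)
  if (any(constant)) {
    warning(sprintf("%d peak(s) with constant accessibility dropped from testing",
                    sum(constant)), call. = FALSE)
  }
  testable <- !constant
  rho <- rep(NA_real_, nrow(a))
  p <- rep(NA_real_, nrow(a))
  if (any(testable)) {
    ranks <- t(apply(a[testable, , drop = FALSE], 1L, rank,
                     ties.method = "average"))
    rp <- rank(prop, ties.method = "average")
    rho[testable] <- as.vector(cor(rp, t(ranks)))
    if (method %in% c("auto", "approximate") && !(method == "auto" && n <= 8L)) {
      p[testable] <- spearman_p_t(rho[testable], n)
    } else {
      idx <- which(testable)
      p[idx] <- vapply(seq_along(idx), function(i) {
        spearman_pvalue(a[idx[i], ], prop, method = method,
                        n_perm = n_perm, seed = seed + i)
      }, numeric(1))
    }
  }
  q <- rep(NA_real_, nrow(a))
  q[testable] <- bh_fdr(p[testable])
  sig <- !is.na(q) & q < alpha
  if (!is.null(rho_cut)) sig <- sig & abs(rho) > rho_cut

  res <- data.frame(
    peak_id = rownames(a),
    rho = rho,
    p_value = p,
    fdr = q,
    direction = ifelse(is.na(rho), NA_character_,
                       ifelse(rho >= 0, "positive", "negative")),
    significant = sig,
    stringsAsFactors = FALSE
  )
  if (!is.null(peaks)) {
    idx <- match(res$peak_id, peaks$peak_id)
    res$chrom <- peaks$chrom[idx]
    res$start <- peaks$start[idx]
    res$end <- peaks$end[idx]
    res <- res[, c("peak_id", "chrom", "start", "end", "rho", "p_value",
                   "fdr", "direction", "significant")]
  }
  attr(res, "counts") <- list(
    n_peaks = nrow(a),
    n_tested = sum(testable),
    n_constant = sum(constant),
    n_significant = sum(sig),
    n_positive = sum(sig & res$direction == "positive"),
    n_negative = sum(sig & res$direction == "negative")
  )
  res
}
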