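# Survival analysis: product-limit curves, the two-group log-rank test,
# median-split univariate screening, and k-means multivariate risk
# grouping. The Kaplan-Meier and log-rank statistics are implemented
# directly from their closed forms; the test suite cross-checks them
# against survival::survfit / survdiff.

#' Kaplan-Meier product-limit curve
#'
#' @param time positive follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival` (right-continuous step heights;
#'   `S(0) = 1` before the first row).
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) stop_invalid("need at least one record")
  if (any(time <= 0)) stop_invalid("times must be positive")
  if (!all(event %in% c(0, 1))) stop_invalid("event must be 0 or 1")
  tj <- sort(unique(time[event == 1]))
  if (length(tj) == 0L) {
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  }
  n_risk <- vapply(tj, function(t) sum(time >= t), integer(1))
  n_event <- vapply(tj, function(t) sum(time == t & event == 1), integer(1))
  data.frame(time = tj, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

# survival probability at time t from a km_curve table (S(0) = 1)
km_surv_at <- function(km, t) {
  if (nrow(km) == 0L || t < km$time[1]) return(1)
  km$survival[max(which(km$time <= t))]
}

# Nelson-Aalen cumulative hazard at time t
nelson_aalen_at <- function(time, event, t) {
  km <- km_curve(time, event)
  keep <- km$time <= t
  if (!any(keep)) return(0)
  sum(km$n_event[keep] / km$n_risk[keep])
}

#' Two-group log-rank test
#'
#' Standard statistic `(sum(O - E))^2 / V` over the distinct event times,
#' with the hypergeometric variance at each time, referred to a chi-square
#' distribution with 1 df.
#'
#' @param group two-level grouping vector aligned with `time`.
#' @param time positive follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @return list with `chi2`, `p`, `n_events`.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L || any(table(group) == 0L)) {
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  }
  if (any(time <= 0)) stop_invalid("times must be positive")
  if (sum(event) < 1) stop("log-rank test needs at least one event", call. = FALSE)
  g1 <- group == lev[1]
  tj <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in tj) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & g1)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + (d1j - dj * n1j / nj)
    if (nj > 1) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       n_events = sum(event))
}

#' Median split of a feature into low/high groups
#'
#' Values strictly above the median go to `"high"`; values at or below the
#' median go to `"low"` (ties at the median go low).
#'
#' @param x numeric feature vector with at least two distinct values.
#' @return character vector of `"low"` / `"high"`.
#' @export
median_split <- function(x) {
  if (length(unique(x)) < 2L) {
    stop_invalid("constant feature cannot be median-split")
  }
  ifelse(x > median(x), "high", "low")
}

#' Univariate median-split log-rank screen
#'
#' Each feature row is median-split over the shared samples and the two
#' groups compared with the log-rank test. The epithelial proportion can be
#' screened alongside the genes by passing the cohort.
#'
#' @param features numeric matrix, features x samples, with dimnames.
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @param cohort optional cohort table; adds a `proportion_epi` feature.
#' @param alpha significance level for the flag column.
#' @return data.frame (`feature`, `p_value`, `significant`); features that
#'   are constant or produce one-sided splits get `NA` p-values.
#' @export
univariate_screen <- function(features, surv, cohort = NULL, alpha = 0.05) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  if (!is.null(cohort)) {
    extra <- setNames(cohort$proportion, cohort$sample_id)
    common <- intersect(colnames(features), names(extra))
    features <- rbind(features[, common, drop = FALSE],
                      proportion_epi = extra[common])
  }
  shared <- sort(intersect(colnames(features), surv$sample_id))
  if (length(shared) < 2L) stop("fewer than 2 shared samples", call. = FALSE)
  f <- features[, shared, drop = FALSE]
  sv <- surv[match(shared, surv$sample_id), ]
  p <- vapply(rownames(f), function(nm) {
    x <- f[nm, ]
    if (length(unique(x)) < 2L) return(NA_real_)
    grp <- median_split(x)
    if (length(unique(grp)) < 2L || sum(sv$event) < 1) return(NA_real_)
    logrank_test(grp, sv$time, sv$event)$p
  }, numeric(1))
  data.frame(feature = rownames(f), p_value = unname(p),
             significant = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Multivariate k-means risk stratification
#'
#' Features are z-scored per feature, samples clustered with k-means
#' (k = 2, seeded, `nstart` restarts, best inertia kept); the cluster with
#' the higher Nelson-Aalen cumulative hazard at the median follow-up time is
#' labeled high-risk, and the two clusters are compared with the log-rank
#' test.
#'
#' @param features numeric matrix, features x samples (the significant
#'   features, optionally including the epithelial proportion row).
#' @param surv survival data.frame.
#' @param seed RNG seed for the k-means initialization.
#' @param nstart number of k-means restarts.
#' @return list with `grouping` (data.frame `sample_id`, `group`), `p`,
#'   `chi2`, `cluster_sizes`.
#' @export
multivariate_stratify <- function(features, surv, seed = 1L, nstart = 10L) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  shared <- sort(intersect(colnames(features), surv$sample_id))
  if (length(shared) < 4L) stop_invalid("need at least 4 shared samples")
  if (nrow(features) < 1L) stop_invalid("need at least one feature")
  f <- features[, shared, drop = FALSE]
  sv <- surv[match(shared, surv$sample_id), ]
  z <- t(apply(f, 1L, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  km <- with_seed(seed, kmeans(t(z), centers = 2L, nstart = nstart,
                               iter.max = 100L))
  if (any(km$size == 0L)) {
    stop("degenerate clustering: empty cluster after restarts", call. = FALSE)
  }
  cl <- km$cluster
  t_med <- median(sv$time)
  haz <- vapply(1:2, function(k) {
    nelson_aalen_at(sv$time[cl == k], sv$event[cl == k], t_med)
  }, numeric(1))
  # tie on cumulative hazard: fall back to raw event rate, then cluster 1
  hi <- if (haz[1] != haz[2]) {
    which.max(haz)
  } else {
    rates <- vapply(1:2, function(k) mean(sv$event[cl == k]), numeric(1))
    if (rates[1] != rates[2]) which.max(rates) else 1L
  }
  grp <- ifelse(cl == hi, "high_risk", "low_risk")
  lr <- logrank_test(grp, sv$time, sv$event)
  list(grouping = data.frame(sample_id = shared, group = grp,
                             stringsAsFactors = FALSE),
       p = lr$p, chi2 = lr$chi2, cluster_sizes = unname(km$size))
}
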